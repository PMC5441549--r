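---
title: "Methods: cross-cell-type case-control methylation and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cell-type case-control methylation and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicross)
```

## The problem

Case-control epigenome studies that profile several cell types derived from
the same subjects — for example induced pluripotent stem (iPS) cells,
olfactory neurosphere-derived (ONS) cells and fibroblasts, with an embryonic
stem (ES) cell line as a comparator — ask two linked questions: which CpG
loci and genes differ between patients and controls within each cell type,
and whether anything is shared across cell types, which would hint at a
signal robust to tissue context. epicross implements this analysis end to
end for Infinium 27K-style beta-value matrices and coupled expression
arrays, together with the statistics that make the cross-cell-type claims
testable: a Monte-Carlo test for the k-way overlap of differential lists, a
directional methylation-expression concordance filter, gene-set
over-representation, and a binomial Z-test for enrichment of hits in a
seed-gene protein-protein-interaction (PPI) network.

## Scales and transforms

A beta value is the methylated fluorescence intensity divided by total
intensity, a fraction in [0, 1]. It is intuitive but heteroscedastic near
its boundaries, so all statistics run on the M-value, the logit2 transform
`M = log2(beta / (1 - beta))`. Betas are clipped into
`[epsilon, 1 - epsilon]` first; `epsilon` defaults to 1e-3, which maps a
fully unmethylated probe to M ~ -9.97 instead of -Inf while perturbing no
realistic interior value. The transform is strictly monotone and exactly
invertible on the clipped range (`m_to_beta()`), which the test suite
verifies to 1e-12.

For descriptive summaries, probes are binned by beta into three states with
inclusive outer boundaries: hypermethylated at >= 70%, hypomethylated at
<= 30%, mid-methylated in between.

Expression arrays enter as raw non-negative fluorescence. `normalize_expression()`
subtracts a constant background offset, floors at a small positive value,
quantile-normalizes across samples (via limma, so every column shares one
distribution) and log2-transforms. The concrete background model of vendor
pipelines is scanner-specific; a constant offset plus floor is the simplest
member of that family and is recorded in the matrix's `normalized` state
flag so the pipeline cannot normalize twice silently.

## Replicate structure and quality control

Consecutive culture passages of one line are technical replicates: they
share subject, clone and cell type, and are averaged into one column per
biological unit before model fitting (`collapse_technical_replicates()`,
policy `"average"`). Distinct iPS clones of a subject are biological
replicates and remain separate units. A duplicate-correlation "block" policy
is reserved in the interface but deliberately unimplemented: with triplicate
passages of nearly noiseless arrays (replicate r-squared typically ~0.99,
which `replicate_correlation()` quantifies), averaging loses almost nothing
and keeps the per-probe model a plain two-group comparison with an exact
small-sample reference distribution.

PCA (`pca_scores()`, column-centered, no scaling, all probes) serves two QC
roles: confirming that samples organize by cell type on the leading
components, and finding aberrant single arrays. Because the leading global
components carry the cell-type separation, outlier screening is done within
cell type: a sample is flagged when its distance from the score centroid on
components 1-2 exceeds `k_sd` (default 4) robust SDs (MAD) above the median
distance. Flagged samples are only reported; removal is an explicit
configuration choice (`remove_outliers`), mirroring how an analyst inspects
a PCA plot before dropping an array.

When a detection p-value matrix is available, a probe counts as detected at
p < 0.01 in at least one sample (`detected_probes()`); otherwise all probes
are analyzed.

## Differential model

For each probe the two-group effect is the difference of group means of
M-values (or normalized log2 fluorescence), with pooled within-group
variance on n1 + n2 - 2 degrees of freedom. Variances are then moderated
empirically-Bayes style: per-probe sample variances are modeled as
`s^2 ~ s0^2 F(df, d0)` (equivalently, true variances follow a scaled
inverse-chi-square prior), the hyperparameters `(d0, s0^2)` are fitted by
matching the mean and variance of `log s^2` (with a Newton inversion of the
trigamma function), and each probe's posterior variance is
`(d0 s0^2 + df s^2) / (d0 + df)` with moderated degrees of freedom
`df + d0`. Two limits anchor the implementation: with no excess dispersion
in the log-variances `d0 = Inf` and every posterior variance equals `s0^2`;
as `d0 -> 0` the ordinary pooled t-test is recovered, which the acceptance
suite checks to 1e-8. The test suite also cross-checks the fitted
hyperparameters against limma's independent implementation and verifies
recovery of planted `(d0, s0^2)` on 10,000 simulated probes (within 25% and
10% respectively).

P-values are two-sided (both hyper- and hypomethylation matter) and
adjusted by Benjamini-Hochberg step-up (`bh_adjust()`, a validated wrapper
over `stats::p.adjust`; the suite proves equality with the brute-force
"largest k with p(k) <= k alpha / n" rejection set on 1,000 random
vectors). Default thresholds follow the study design the package targets:
BH-adjusted p < 1e-4 for cell-type contrasts, p < 0.05 for patient-control
contrasts. Calling returns probes and unique gene symbols with the
direction carried along (hyper/hypo for methylation, up/down for
expression); symbols are matched case-insensitively everywhere because
methylation, expression and network resources rarely agree on case.

## The overlap test

The headline cross-cell-type claim — k differential lists sharing m loci —
is tested by simulation: each of `n_sims` (default 10,000) rounds draws k
lists of the observed sizes uniformly without replacement from the common
identifier pool and counts the k-way intersection; the empirical p is the
plain fraction of rounds with intersection at least the observed overlap.
The plain proportion (not (r+1)/(n+1)) is the default so the p-value has
exactly 1/n_sims granularity; the conservative estimator is a flag.
Directions are ignored in the null: the simulation draws unlabeled lists.

A Poisson approximation provides a fast analytic cross-check
(`overlap_pvalue_analytic()`): each pool identifier lands in all k lists
with probability `prod(n_i / N)`, so the overlap count is approximately
Poisson with `lambda = N prod(n_i / N)`. For the reference configuration —
lists of 883, 1328 and 952 from a pool of 27,578, observed overlap 5 —
lambda is 1.468 and the upper tail at 5 is 0.017, consistent with the
Monte-Carlo value (~0.016) at its standard error (~0.0013 at 10,000
rounds). For k = 2 the exact null is hypergeometric, which the tests use as
an enumeration oracle on tiny pools. An exact k >= 3 combinatorial tail at
27K scale is out of scope. Note the directional intersection
(`intersect_directional()`) that produces the observed overlap requires the
same direction in every list; an identifier flipping direction between cell
types does not count as shared.

One granularity question is left open deliberately: the reference analysis
quotes its overlap p against a pool of 27,578 "genes", but only the
CpG-locus list sizes (883/1328/952), not the gene-level sizes
(689/1221/859), reproduce the quoted p under any standard tail. The API
takes sizes and pool explicitly, so either binding can be run; the
package's own checks use the locus-level configuration.

## Enrichment statistics

`fisher_ora()` is a right-tailed Fisher's exact test of a query list
against each set of a GMT collection within a stated universe
(hypergeometric upper tail at the observed overlap), BH-corrected across
sets; the suite proves it equal to exhaustive enumeration of all possible
query draws on universes up to 15. The activation z-score is the
sign-consistency statistic `z = sum(signs) / sqrt(n)` over contributing
genes, with |z| >= 2 called significant (Increased / Decreased); unit
weights are used — literature-typed edge weights of commercial knowledge
bases are not reproducible from open inputs.

The seed-PPI test takes a seed gene list, induces the subnetwork of seeds
plus first-degree neighbors (`build_seed_network()`), and asks whether a
query list hits that subnetwork more often than chance:

    Z = (O - E) / sqrt((N - 1) p q)

with p the fraction of the gene universe inside the subnetwork, q = 1 - p,
O the observed query hits, E = n_query * p, one-tailed normal P, and
critical value Z >= 1.65 for 5% significance. The symbol N is
underdetermined in this formula as usually printed ("total number of gene
variants"); epicross binds it to the universe size by default and offers
`n_convention = "query"`, under which the statistic is exactly the normal
approximation to Bin(n_query, p). The (N - 1) factor is kept as printed
rather than replaced by the conventional n. Under the query binding the
one-tailed P tracks the exact binomial tail within a factor of 2 for
|Z| <= 3 (absolute error < 0.02) at study scale (universe 20,000, query
500, p = 0.1), the band the tests enforce; in the far tail the normal
approximation is anti-conservative, which is why extreme printed values
(e.g. P = 2e-37 at Z = 12.73) should be read as normal-tail quantities, as
`z_to_p_one_tailed()` computes them.

## Concordance network and clustering

`build_concordance_network()` restricts a user-supplied interactome to
differential genes and applies the direction rule: an edge joining a
methylation-only node to an expression-only node survives only as
activation (hypomethylated with up-regulated) or inhibition
(hypermethylated with down-regulated). Edges whose endpoints are
differential in the same assay, or involve a gene differential in both,
are kept on adjacency alone — the printed rule only constrains mixed
pairs. Every adjacent differential pair is classified and rejected edges
carry a reason, so the filter is auditable; it is idempotent and
order-independent. `degree_stats()` reports both the edge/node ratio E/V
and the mean degree 2E/V, labeled distinctly, because figure legends in
this literature sometimes quote the former where the latter would be
expected.

Hierarchical clustering follows the Cluster 3.0 / Java TreeView
convention: agglomerative, average linkage, distance 1 minus the
uncentered correlation (a zero-norm column is defined to be at distance 1,
with a warning). Cutting the column tree at 3 recovers the three planted
cell types exactly (adjusted Rand index 1) on default-strength synthetic
signal. Row trees are optional and skipped above 2,000 rows (rows are then
ordered by variance) because an all-pairs distance matrix over tens of
thousands of probes serves no statistical purpose here.

## The synthetic-data generator

`sim_config()` encodes the study design the package emulates: 27,578
probes; iPS, ONS and fibroblast lines from 4 patients and 4 controls plus
one ES comparator line; every line measured in triplicate (consecutive
passages as technical replicates); two subjects per group carrying a second
iPS clone (biological replicates). Baseline betas come from a three-mode
Beta mixture (30% hypo ~ Beta(2,10), 40% mid ~ Beta(8,8), 30% hyper ~
Beta(10,2)) so the binning operation has mass in every state. Cell-type
effects sit on 7,854 probes (offsets N(0, 1.5) on the M scale); disease
effects are planted per cell type at the counts the reference analysis
calls significant (883/1328/952) including a 5-probe shared core with
consistent direction (4 hypo, 1 hyper in patients). Effects are added on
the M scale — where the statistics operate — and back-transformed, so betas
stay in (0, 1); the disease effect is quoted as a beta shift (default 0.2
at beta = 0.5) and applied as the equivalent constant M shift (~1.17).
Biological and replicate noise default to SD 0.25 and 0.15 on the M scale,
chosen so technical-replicate r-squared lands near the ~0.97-0.99 range
good arrays show. An optional planted outlier array (one fibroblast
control, globally shifted) exercises the QC path.

Coupled expression is generated over the same samples: a configured
fraction (default 0.5) of planted DM genes receive an expression effect in
the same cell type, direction-concordant with probability 0.9, plus
independently planted DE genes; the interactome is a preferential-attachment
(Barabasi-Albert) graph whose members and seeds can be biased toward
disease-affected genes by `seed_enrichment` (0 gives a calibrated null —
mean PPI Z ~ 0 — which the tests verify).

The generator's betas are exchangeable across probes: real 27K data have
genomic autocorrelation, probe-specific dynamic ranges and chip/batch
effects that are deliberately not modeled. Passing tests therefore
demonstrate the statistics are implemented correctly and calibrated under
the declared model, not that the pipeline is robust to artifacts absent
from that model.

All generation is deterministic given the master seed; the expression and
interactome generators offset the seed by 1 and 2 so the three data sets
are mutually independent draws.

## Pipeline and problem sizes

`run_pipeline()` executes inputs -> QC -> differential (methylation and
expression per cell type) -> overlap -> enrichment -> concordance ->
PPI-enrichment, with every table written under one run directory and a
manifest recording package version, seed and an MD5 hash of the canonical
config. Stages read only files written by earlier stages, so any stage can
be rerun alone; a missing prerequisite fails by file name. All randomness
flows from the single config seed, and reruns are byte-identical, which
the acceptance suite checks with file hashes.

The package's own checks run at reduced problem sizes chosen to exercise
every code path while keeping the default suite quick: 600-2,000 probes
and 250-600-gene interactomes for pipeline runs, 10,000 probes for
hyperparameter recovery, 10,000-100,000 rounds for Monte-Carlo
comparisons, 25-50 replicate studies for power, FDR and null-calibration
estimates. The full 27,578-probe default is used where the quantity under
test depends on it (the overlap test and the I/O round trip).

## Known limitations

- The moderated model assumes a single shared residual-variance prior
  across probes; strongly heterogeneous variance strata would call for
  robust or trended variants, which are not implemented.
- The overlap null treats all identifiers as exchangeable; probe-density
  differences between genes are ignored (consistent with the test it
  reproduces).
- The Eq.-style Z-test inherits the normal approximation's
  anti-conservatism deep in the tail; exact binomial tails are available
  in the tests but the reported statistic follows the printed formula.
- IDAT parsing, probe masking (SNPs, cross-reactivity) and batch
  correction are out of scope; inputs are taken as exported matrices.
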