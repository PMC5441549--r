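#' Collapse technical replicates to one column per biological unit
#'
#' Consecutive culture passages of one line are technical replicates of the
#' same biological unit (subject, clone, cell type). Policy \code{"average"}
#' replaces each technical group by its per-probe mean; distinct iPS clones of
#' a subject are biological replicates and stay separate. Policy
#' \code{"block"} is reserved for a duplicate-correlation model and is not yet
#' implemented.
#'
#' @param mat Probe x sample matrix.
#' @param sheet Sample sheet covering the matrix columns.
#' @param policy \code{"average"} (default) or \code{"block"}.
#' @return List: \code{values} (probe x unit matrix), \code{samples} (collapsed
#'   sheet, one row per unit, sample_id = unit id).
#' @export
collapse_technical_replicates <- function(mat, sheet, policy = c("average", "block")) {
  policy <- match.arg(policy)
  if (policy == "block") {
    stop("policy 'block' (duplicate-correlation model) not implemented; use 'average'",
         call. = FALSE)
  }
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(mat), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sheet$sample_id))) {
    stop("matrix has columns absent from the sample sheet", call. = FALSE)
  }
  unit <- ifelse(sheet$replicate_role == "technical",
                 paste(sheet$subject_id, sheet$clone_id, sheet$cell_type, sep = "|"),
                 sheet$sample_id)
  units <- unique(unit)
  out <- matrix(NA_real_, nrow(mat), length(units),
                dimnames = list(rownames(mat), units))
  for (u in units) {
    cols <- which(unit == u)
    out[, u] <- if (length(cols) == 1) mat[, cols] else
      rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
  }
  first <- sheet[match(units, unit), , drop = FALSE]
  first$sample_id <- units
  first$passage <- NA_integer_
  rownames(first) <- NULL
  list(values = out, samples = first)
}

#' Per-probe two-group linear model
#'
#' For each probe, fits the two-group mean model by least squares: the effect
#' is \code{mean(group1) - mean(group2)}, the residual variance is the pooled
#' within-group variance on \code{n1 + n2 - 2} degrees of freedom.
#'
#' @param mat Probe x unit matrix (replicates already collapsed).
#' @param sheet Collapsed sample sheet matching the matrix columns.
#' @param contrast Ordered pair of group labels, e.g. \code{c("patient",
#'   "control")}: effect is first minus second.
#' @param group_col Sheet column holding the group labels (default
#'   \code{"status"}).
#' @return data.frame: probe_id, effect, s2, df, n1, n2.
#' @export
fit_group_model <- function(mat, sheet, contrast = c("patient", "control"),
                            group_col = "status") {
  stopifnot(length(contrast) == 2)
  sheet <- sheet[match(colnames(mat), sheet$sample_id), , drop = FALSE]
  g1 <- which(sheet[[group_col]] == contrast[1])
  g2 <- which(sheet[[group_col]] == contrast[2])
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) {
    stop(sprintf("need >=2 units per group (got %d '%s', %d '%s')",
                 n1, contrast[1], n2, contrast[2]), call. = FALSE)
  }
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  ss1 <- rowSums((mat[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, g2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  data.frame(probe_id = rownames(mat),
             effect = m1 - m2,
             s2 = (ss1 + ss2) / df,
             df = df, n1 = n1, n2 = n2,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Newton inversion of the trigamma function, used by the moment-matching
# fit of the variance prior. Monotone decreasing on (0, Inf).
.trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x           # good starting value: trigamma(y) ~ 1/y + 1/(2y^2)
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Assumes the per-probe sample variances follow a scaled F distribution,
#' \eqn{s^2 \sim s_0^2 F(df, d_0)}, i.e. the true residual variances are drawn
#' from a scaled inverse-chi-square prior with \eqn{d_0} degrees of freedom
#' and scale \eqn{s_0^2}. The hyperparameters are fitted by matching the
#' moments of \eqn{\log s^2}; the posterior variance for each probe is the
#' precision-weighted combination
#' \deqn{\tilde{s}^2 = (d_0 s_0^2 + df\, s^2) / (d_0 + df).}
#' When the observed log-variances are no more dispersed than the sampling
#' distribution alone allows, \eqn{d_0 = \infty} and all posterior variances
#' equal \eqn{s_0^2}.
#'
#' @param s2 Vector of per-probe sample variances (>= 10 probes).
#' @param df Residual degrees of freedom (scalar, shared across probes).
#' @return List: \code{s2_post}, \code{d0}, \code{s0_2}.
#' @export
moderate_variances <- function(s2, df) {
  stopifnot(length(s2) >= 10, df >= 1)
  if (any(s2 < 0)) stop("negative variance", call. = FALSE)
  pos <- s2[s2 > 0]
  if (length(pos) < 10) {
    # (near-)degenerate data, e.g. noise-free fixtures: nothing to fit
    return(list(s2_post = s2, d0 = Inf,
                s0_2 = if (length(pos) > 0) stats::median(pos) else 0))
  }
  z <- log(pos)
  if (stats::var(z) < .Machine$double.eps) {
    # degenerate: no spread, no shrinkage needed
    return(list(s2_post = s2, d0 = Inf, s0_2 = pos[1]))
  }
  evar <- stats::var(z) - trigamma(df / 2)
  if (evar <= 0) {
    s0_2 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
    return(list(s2_post = rep(s0_2, length(s2)), d0 = Inf, s0_2 = s0_2))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s0_2 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
              digamma(d0 / 2) - log(d0 / 2))
  s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
  list(s2_post = s2_post, d0 = d0, s0_2 = s0_2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()], with input validation.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NA", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Full per-probe differential test for one contrast
#'
#' Collapses technical replicates, fits the two-group model per probe,
#' moderates the variances empirically-Bayes style, computes moderated
#' t-statistics on \code{df + d0} degrees of freedom, two-sided p-values and
#' BH q-values, and attaches gene symbols and a direction call.
#'
#' @param mat Probe x sample matrix on the analysis scale (M-values for
#'   methylation, normalized log2 fluorescence for expression).
#' @param sheet Sample sheet covering the matrix columns.
#' @param annotation Optional probe annotation data.frame (probe_id,
#'   gene_symbol); without it gene_symbol = probe_id.
#' @param contrast Ordered pair of group labels; effect = first - second.
#' @param group_col Sheet column with the group labels.
#' @param moderate Apply variance moderation (default TRUE); FALSE gives the
#'   ordinary pooled-variance t-test.
#' @param direction_labels Labels for positive / negative effects, e.g.
#'   \code{c("hyper", "hypo")} for methylation, \code{c("up", "down")} for
#'   expression.
#' @return data.frame: probe_id, gene_symbol, effect, s2, t, df_total, p, q,
#'   direction; attributes \code{d0}, \code{s0_2}.
#' @export
run_differential <- function(mat, sheet, annotation = NULL,
                             contrast = c("patient", "control"),
                             group_col = "status", moderate = TRUE,
                             direction_labels = c("hyper", "hypo")) {
  collapsed <- collapse_technical_replicates(mat, sheet)
  fit <- fit_group_model(collapsed$values, collapsed$samples,
                         contrast = contrast, group_col = group_col)
  df <- fit$df[1]
  if (moderate && nrow(fit) >= 10) {
    mod <- moderate_variances(fit$s2, df)
    s2_use <- mod$s2_post
    d0 <- mod$d0
    s0_2 <- mod$s0_2
  } else {
    s2_use <- fit$s2
    d0 <- 0
    s0_2 <- NA_real_
  }
  se <- sqrt(s2_use * (1 / fit$n1 + 1 / fit$n2))
  t_mod <- fit$effect / se
  df_total <- df + d0          # pt() handles df = Inf (normal reference)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[!is.finite(t_mod)] <- NA_real_
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_adjust(p[ok])
  gene <- if (is.null(annotation)) fit$probe_id else {
    annotation$gene_symbol[match(fit$probe_id, annotation$probe_id)]
  }
  res <- data.frame(probe_id = fit$probe_id,
                    gene_symbol = gene,
                    effect = fit$effect,
                    s2 = fit$s2,
                    t = t_mod,
                    df_total = df_total,
                    p = p, q = q,
                    direction = ifelse(fit$effect > 0, direction_labels[1],
                                       direction_labels[2]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0_2") <- s0_2
  res
}

#' Call significant probes and genes at an FDR level
#'
#' @param results Differential result data.frame with columns \code{q},
#'   \code{probe_id}, \code{gene_symbol}, \code{direction}.
#' @param alpha FDR level; probes with \code{q < alpha} are called.
#' @return List: \code{probes} (subset of \code{results}), \code{genes}
#'   (data.frame gene_symbol, direction; unique, direction carried from the
#'   most significant probe of each gene).
#' @export
call_differential <- function(results, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  hit <- results[!is.na(results$q) & results$q < alpha, , drop = FALSE]
  hit <- hit[order(hit$p), , drop = FALSE]
  genes <- hit[!duplicated(toupper(hit$gene_symbol)) & !is.na(hit$gene_symbol),
               c("gene_symbol", "direction"), drop = FALSE]
  rownames(genes) <- NULL
  list(probes = hit, genes = genes)
}
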