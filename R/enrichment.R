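#' Gene-set over-representation analysis
#'
#' Right-tailed Fisher's exact test of a query gene list against every set in
#' a collection, within a stated gene universe, with Benjamini-Hochberg
#' correction across sets. The p-value for a set is the hypergeometric upper
#' tail \eqn{P(X \ge \mathrm{overlap})}. Gene symbols are matched
#' case-insensitively; sets are intersected with the universe first.
#'
#' @param query Character vector of query gene symbols (subset of universe).
#' @param annotation Named list of gene sets (see [read_gene_sets()]).
#' @param universe Character vector: all assayable gene symbols.
#' @return data.frame sorted by p: set_name, overlap, set_size, query_size,
#'   universe_size, p, q.
#' @export
fisher_ora <- function(query, annotation, universe) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (length(query) == 0) stop("empty query", call. = FALSE)
  extra <- setdiff(query, universe)
  if (length(extra) > 0) {
    stop(sprintf("query gene(s) not in universe: %s",
                 paste(utils::head(extra, 5), collapse = ", ")), call. = FALSE)
  }
  N <- length(universe)
  n_q <- length(query)
  recs <- lapply(names(annotation), function(nm) {
    set <- intersect(unique(toupper(annotation[[nm]])), universe)
    ov <- length(intersect(set, query))
    K <- length(set)
    p <- if (K == 0) 1 else
      stats::phyper(ov - 1, K, N - K, n_q, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = K,
               query_size = n_q, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Activation z-score from direction-consistency signs
#'
#' Sign-consistency statistic predicting whether a function is increased or
#' decreased: \eqn{z = \sum_i s_i / \sqrt{n}} over the contributing genes'
#' consistency signs \eqn{s_i \in \{+1, -1\}}. An absolute z of at least 2 is
#' deemed significant: \code{Increased} at \eqn{z \ge 2}, \code{Decreased} at
#' \eqn{z \le -2}, otherwise \code{none}.
#'
#' @param consistency_signs Vector of +1/-1 (one per contributing gene).
#' @return List: \code{z}, \code{state}. Empty input gives \code{z = NA},
#'   state \code{"none"}.
#' @export
activation_zscore <- function(consistency_signs) {
  if (length(consistency_signs) == 0) {
    return(list(z = NA_real_, state = "none"))
  }
  if (!all(consistency_signs %in% c(-1, 1))) {
    stop("consistency signs must be +1 or -1", call. = FALSE)
  }
  z <- sum(consistency_signs) / sqrt(length(consistency_signs))
  state <- if (z >= 2) "Increased" else if (z <= -2) "Decreased" else "none"
  list(z = z, state = state)
}

#' Build a seed-gene PPI subnetwork
#'
#' Induces the subgraph of an interactome on the seed genes plus their
#' first-degree interacting neighbors. Seeds absent from the interactome are
#' reported via message; isolated seeds (present but with no edges) are kept
#' as singleton nodes.
#'
#' @param seeds Character vector of seed gene symbols.
#' @param interactome Undirected igraph interactome with named vertices.
#' @return igraph subnetwork with logical vertex attribute \code{seed}.
#' @export
build_seed_network <- function(seeds, interactome) {
  vnames <- igraph::V(interactome)$name
  if (is.null(vnames)) stop("interactome vertices must be named", call. = FALSE)
  idx <- match(toupper(seeds), toupper(vnames))
  absent <- seeds[is.na(idx)]
  if (length(absent) == length(seeds)) {
    stop("no seed gene present in the interactome", call. = FALSE)
  }
  if (length(absent) > 0) {
    message(sprintf("%d seed gene(s) absent from interactome: %s",
                    length(absent),
                    paste(utils::head(absent, 5), collapse = ", ")))
  }
  seed_v <- vnames[idx[!is.na(idx)]]
  nb <- unique(unlist(lapply(seed_v, function(v) {
    igraph::neighbors(interactome, v)$name
  })))
  keep <- unique(c(seed_v, nb))
  g <- igraph::induced_subgraph(interactome, keep)
  igraph::V(g)$seed <- igraph::V(g)$name %in% seed_v
  g
}

#' Binomial enrichment Z statistic from raw counts
#'
#' Direct evaluation of \eqn{Z = (O - E) / \sqrt{(N - 1) p q}} with
#' \eqn{q = 1 - p}. Exposed separately from [ppi_enrichment_ztest()] so the
#' statistic can be computed from published counts.
#'
#' @param O Observed count.
#' @param E Expected count.
#' @param N Total count bound to the denominator's N.
#' @param p Expected frequency in (0, 1).
#' @return The Z score.
#' @export
enrichment_zscore <- function(O, E, N, p) {
  stopifnot(N >= 2)
  if (p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)", call. = FALSE)
  (O - E) / sqrt((N - 1) * p * (1 - p))
}

#' Binomial Z-test for enrichment of a gene list in a PPI network
#'
#' Tests whether a query gene list hits the nodes of a (seed-derived) PPI
#' network more often than expected by chance, using the binomial-approximation
#' statistic
#' \deqn{Z = (O - E) / \sqrt{(N - 1)\,p\,q}}
#' with \eqn{p} the fraction of the gene universe inside the network,
#' \eqn{q = 1 - p}, \eqn{O} the number of query genes in the network and
#' \eqn{E = n_{query} \cdot p} the expected count. The one-tailed p-value is
#' the standard-normal upper tail at Z; the result is significant at the 5%
#' level when \eqn{Z \ge 1.65}. The symbol N in the denominator is bound to
#' the gene-universe size by default; \code{n_convention = "query"} binds it
#' to the query size instead, which is the plain normal approximation to the
#' binomial count \eqn{\mathrm{Bin}(n_{query}, p)}.
#'
#' @param query Character vector of gene symbols.
#' @param network igraph network (e.g. from [build_seed_network()]).
#' @param universe_size Total number of genes in the universe (N >= 2).
#' @param n_convention Which count the denominator's N refers to:
#'   \code{"universe"} (default) or \code{"query"}.
#' @return Object of class \code{ppi_enrich}: O, E, N, p, q, Z, P_one_tailed,
#'   significant (Z >= 1.65), n_query, n_network, n_convention.
#' @export
ppi_enrichment_ztest <- function(query, network, universe_size,
                                 n_convention = c("universe", "query")) {
  n_convention <- match.arg(n_convention)
  stopifnot(universe_size >= 2)
  n_net <- igraph::vcount(network)
  if (n_net > universe_size) {
    stop("network has more nodes than the gene universe", call. = FALSE)
  }
  query <- unique(toupper(query))
  n_q <- length(query)
  if (n_q == 0) stop("empty query", call. = FALSE)
  p <- n_net / universe_size
  if (p <= 0 || p >= 1) {
    stop("network fraction p must lie strictly in (0, 1)", call. = FALSE)
  }
  q <- 1 - p
  O <- length(intersect(query, toupper(igraph::V(network)$name)))
  E <- n_q * p
  N <- if (n_convention == "universe") universe_size else n_q
  if (N < 2) stop("denominator N must be >= 2", call. = FALSE)
  Z <- enrichment_zscore(O, E, N, p)
  structure(list(O = O, E = E, N = N, p = p, q = q, Z = Z,
                 P_one_tailed = z_to_p_one_tailed(Z),
                 significant = Z >= 1.65,
                 n_query = n_q, n_network = n_net,
                 n_convention = n_convention),
            class = "ppi_enrich")
}

#' @export
print.ppi_enrich <- function(x, ...) {
  cat(sprintf("PPI enrichment: O = %d, E = %.3f (network %d / universe-N %d, p = %.4g)\n",
              x$O, x$E, x$n_network, x$N, x$p))
  cat(sprintf("Z = %.3f, one-tailed P = %.3g%s\n", x$Z, x$P_one_tailed,
              if (x$significant) "  (significant, Z >= 1.65)" else ""))
  invisible(x)
}

#' One-tailed normal p-value for a Z-score
#'
#' Upper tail of the standard normal, \eqn{P = 1 - \Phi(Z)}, computed via the
#' complementary error function machinery in [stats::pnorm()] so extreme
#' scores (|Z| up to ~40) give representable p-values such as 2e-37.
#'
#' @param z Finite Z-score (vectorized).
#' @return Upper-tail probability.
#' @export
z_to_p_one_tailed <- function(z) {
  stopifnot(all(is.finite(z)))
  stats::pnorm(z, lower.tail = FALSE)
}
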