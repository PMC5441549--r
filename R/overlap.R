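#' Directional intersection of differential gene lists
#'
#' Returns the identifiers called differential in every list with the same
#' direction in all of them; an id present everywhere but with inconsistent
#' direction is excluded. Matching is case-insensitive on the ids.
#'
#' @param lists Named list (one element per cell type) of named character
#'   vectors: names are gene/probe ids, values are direction labels
#'   (e.g. \code{"hyper"}/\code{"hypo"} or \code{"up"}/\code{"down"}).
#' @return List: \code{shared} (named character vector id -> direction),
#'   \code{by_direction} (table of directions among shared ids).
#' @export
intersect_directional <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2)
  norm <- lapply(lists, function(x) {
    stats::setNames(as.character(x), toupper(names(x)))
  })
  common <- Reduce(intersect, lapply(norm, names))
  # report ids in the first list's original spelling
  orig <- stats::setNames(names(lists[[1]]), toupper(names(lists[[1]])))
  keep <- character()
  for (id in common) {
    dirs <- vapply(norm, function(x) x[[id]], character(1))
    if (length(unique(dirs)) == 1) keep[orig[[id]]] <- dirs[1]
  }
  list(shared = keep,
       by_direction = table(factor(unname(keep), levels = unique(unname(keep)))))
}

#' Monte-Carlo test for k-way overlap of gene lists
#'
#' Tests whether \code{observed} or more identifiers shared by k differential
#' lists could arise by chance. Each simulation draws k lists of the given
#' sizes uniformly without replacement from a common pool of
#' \code{pool_size} identifiers and counts the k-way intersection; the
#' empirical p-value is the fraction of simulations whose intersection is at
#' least \code{observed} (plain proportion, matching a granularity of
#' 1/\code{n_sims}; \code{conservative = TRUE} uses (r+1)/(n+1)).
#'
#' @param list_sizes Integer vector of list sizes (k >= 2 entries).
#' @param pool_size Size of the identifier pool the lists are drawn from.
#' @param observed Observed k-way overlap.
#' @param n_sims Number of simulations (default 10000).
#' @param seed Integer seed for reproducibility; NULL leaves the RNG alone.
#' @param conservative Use the (r+1)/(n+1) estimator (default FALSE).
#' @return Object of class \code{overlap_test}: observed, list_sizes,
#'   pool_size, n_sims, seed, null_counts (named integer histogram),
#'   p_empirical, p_poisson (analytic cross-check).
#' @export
overlap_permutation_test <- function(list_sizes, pool_size, observed,
                                     n_sims = 10000, seed = NULL,
                                     conservative = FALSE) {
  list_sizes <- as.integer(list_sizes)
  stopifnot(length(list_sizes) >= 2, all(list_sizes >= 1),
            all(list_sizes <= pool_size), n_sims >= 1)
  if (observed > min(list_sizes)) {
    stop("observed overlap exceeds the smallest list size", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(list_sizes)
  null_overlap <- integer(n_sims)
  for (i in seq_len(n_sims)) {
    drawn <- unlist(lapply(list_sizes, function(sz) sample.int(pool_size, sz)))
    null_overlap[i] <- sum(tabulate(drawn, nbins = pool_size) == k)
  }
  r <- sum(null_overlap >= observed)
  p <- if (conservative) (r + 1) / (n_sims + 1) else r / n_sims
  structure(list(observed = observed,
                 list_sizes = list_sizes,
                 pool_size = pool_size,
                 n_sims = n_sims,
                 seed = seed,
                 null_counts = table(null_overlap),
                 p_empirical = p,
                 p_poisson = overlap_pvalue_analytic(list_sizes, pool_size, observed)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("k-way overlap test: %d lists (sizes %s) from pool of %d\n",
              length(x$list_sizes), paste(x$list_sizes, collapse = ", "),
              x$pool_size))
  cat(sprintf("observed overlap %d; %d simulations\n", x$observed, x$n_sims))
  cat(sprintf("empirical p = %.4g (Poisson approximation %.4g)\n",
              x$p_empirical, x$p_poisson$p))
  invisible(x)
}

#' Poisson approximation to the k-way overlap p-value
#'
#' Each pool identifier lands in all k random lists with probability
#' \eqn{\prod_i (n_i / N)}; for list sizes much smaller than the pool the
#' k-way overlap count is approximately Poisson with
#' \eqn{\lambda = N \prod_i (n_i / N)}, and the p-value is the upper tail
#' \eqn{P(X \ge O)}. Fast analytic cross-check of the Monte-Carlo test; the
#' approximation error is negligible for study-scale parameters but grows
#' when list sizes approach the pool size.
#'
#' @inheritParams overlap_permutation_test
#' @return List: \code{p}, \code{lambda}.
#' @export
overlap_pvalue_analytic <- function(list_sizes, pool_size, observed) {
  list_sizes <- as.integer(list_sizes)
  stopifnot(length(list_sizes) >= 2, all(list_sizes <= pool_size))
  if (observed > min(list_sizes)) {
    stop("observed overlap exceeds the smallest list size", call. = FALSE)
  }
  lambda <- pool_size * prod(list_sizes / pool_size)
  p <- if (observed <= 0) 1 else stats::ppois(observed - 1, lambda, lower.tail = FALSE)
  list(p = p, lambda = lambda)
}
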