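#' Convert beta values to M-values
#'
#' The M-value is the logit2 of the methylation fraction,
#' \eqn{M = \log_2(\beta / (1 - \beta))}. Beta values are heteroscedastic near
#' 0 and 1, so all statistics in this package operate on the M scale. Values
#' are clipped into \eqn{[\epsilon, 1-\epsilon]} first so that \eqn{\beta \in
#' \{0, 1\}} maps to a finite M.
#'
#' @param beta Numeric vector or matrix of methylation fractions in \[0, 1\].
#' @param epsilon Clipping bound in (0, 0.5); default 1e-3.
#' @return M-values, same shape as \code{beta}; NAs propagate.
#' @seealso [m_to_beta()]
#' @export
beta_to_m <- function(beta, epsilon = 1e-3) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon > 0, epsilon < 0.5)
  if (any(!is.na(beta) & (beta < 0 | beta > 1))) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()] on the unclipped range:
#' \eqn{\beta = 2^M / (2^M + 1)}.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Methylation fractions in (0, 1).
#' @export
m_to_beta <- function(m) {
  # expit in base 2, written to avoid overflow for large |m|
  ifelse(m >= 0, 1 / (1 + 2^(-m)), 2^m / (1 + 2^m))
}

#' Bin methylation fractions into hypo / mid / hyper states
#'
#' A probe (or a group mean) is called hypermethylated at beta >= 0.70,
#' hypomethylated at beta <= 0.30, and mid-methylated in between. The
#' boundaries are inclusive on the outer states.
#'
#' @param beta Numeric vector of fractions in \[0, 1\].
#' @return Factor with levels \code{hypo}, \code{mid}, \code{hyper}.
#' @export
bin_methylation_state <- function(beta) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1))) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  state <- ifelse(is.na(beta), NA_character_,
           ifelse(beta >= 0.70, "hyper",
           ifelse(beta <= 0.30, "hypo", "mid")))
  factor(state, levels = c("hypo", "mid", "hyper"))
}

#' Normalize a raw expression matrix
#'
#' Background-corrects (subtract a constant offset, floor at a small positive
#' value), quantile-normalizes across samples so every column shares one
#' distribution, then log2-transforms. The returned matrix carries
#' \code{attr(, "normalized") == TRUE}.
#'
#' @param raw Probe x sample matrix of non-negative fluorescence values.
#' @param background_offset Constant subtracted from every value before
#'   flooring; default 0 (offset already removed by the scanner software).
#' @param floor Small positive floor applied after background subtraction.
#' @param log2_transform Apply log2 after quantile normalization (default TRUE).
#' @return Normalized matrix, same dimnames, with the state flag set.
#' @export
normalize_expression <- function(raw, background_offset = 0, floor = 1,
                                 log2_transform = TRUE) {
  stopifnot(is.matrix(raw))
  if (ncol(raw) < 2) stop("need at least 2 samples to quantile-normalize", call. = FALSE)
  if (isTRUE(attr(raw, "normalized"))) {
    warning("matrix already flagged normalized; normalizing again", call. = FALSE)
  }
  x <- pmax(raw - background_offset, floor)
  x <- limma::normalizeQuantiles(x)
  if (log2_transform) x <- log2(x)
  dimnames(x) <- dimnames(raw)
  attr(x, "normalized") <- TRUE
  x
}

#' Pairwise correlation between technical replicates
#'
#' Technical-replicate groups are samples that share subject, clone and cell
#' type (consecutive culture passages of one line). For every within-group
#' pair the squared Pearson correlation of their profiles is computed; arrays
#' behaving well typically show r^2 near 0.99.
#'
#' @param mat Probe x sample matrix (values on any consistent scale).
#' @param sheet Sample sheet data.frame (see [read_sample_sheet()]).
#' @return List with \code{pairs} (data.frame: group, sample_1, sample_2,
#'   r_squared) and \code{summary} (mean, min, max over pairs). Empty with a
#'   warning when no group has two or more samples.
#' @export
replicate_correlation <- function(mat, sheet) {
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[sheet$sample_id %in% colnames(mat), , drop = FALSE]
  tech <- sheet[sheet$replicate_role == "technical", , drop = FALSE]
  key <- paste(tech$subject_id, tech$clone_id, tech$cell_type, sep = "|")
  groups <- split(tech$sample_id, key)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) {
    warning("no technical-replicate group with >=2 samples", call. = FALSE)
    return(list(pairs = data.frame(group = character(), sample_1 = character(),
                                   sample_2 = character(), r_squared = double()),
                summary = c(mean = NA_real_, min = NA_real_, max = NA_real_)))
  }
  rows <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    cmb <- utils::combn(ids, 2)
    for (j in seq_len(ncol(cmb))) {
      r <- stats::cor(mat[, cmb[1, j]], mat[, cmb[2, j]],
                      use = "pairwise.complete.obs")
      rows[[length(rows) + 1]] <- data.frame(
        group = g, sample_1 = cmb[1, j], sample_2 = cmb[2, j],
        r_squared = r^2, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  list(pairs = pairs,
       summary = c(mean = mean(pairs$r_squared),
                   min = min(pairs$r_squared),
                   max = max(pairs$r_squared)))
}

#' Principal components of a probe x sample matrix
#'
#' Columns (samples) are the observations; the data are column-centered per
#' probe and decomposed without scaling, using every probe supplied (rows
#' containing missing values are dropped with a message).
#'
#' @param mat Probe x sample matrix.
#' @param n_components Number of components to return.
#' @return List: \code{scores} (sample x component matrix), \code{var_explained}
#'   (proportion per returned component), \code{sdev} (all singular values /
#'   sqrt(n-1)).
#' @export
pca_scores <- function(mat, n_components = 2) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2) stop("need >=2 samples for PCA", call. = FALSE)
  keep <- stats::complete.cases(mat)
  if (!all(keep)) {
    message(sprintf("dropping %d probe(s) with missing values before PCA", sum(!keep)))
    mat <- mat[keep, , drop = FALSE]
  }
  if (n_components > min(dim(mat))) {
    stop(sprintf("n_components (%d) exceeds min(dim) = %d",
                 n_components, min(dim(mat))), call. = FALSE)
  }
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  ve <- if (total > 0) pc$sdev^2 / total else rep(0, length(pc$sdev))
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- colnames(mat)
  list(scores = scores,
       var_explained = ve[seq_len(n_components)],
       sdev = pc$sdev)
}

#' Flag outlying samples in PCA score space
#'
#' Samples whose Euclidean distance from the score centroid on the first two
#' components is more than \code{k_sd} robust standard deviations (MAD) above
#' the median distance are flagged. Flagged samples are reported, never
#' removed automatically; dropping them is an explicit caller decision.
#'
#' @param scores Sample x component score matrix from [pca_scores()].
#' @param k_sd Robust-SD multiplier; default 4. \code{Inf} flags nothing.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_outlier_samples <- function(scores, k_sd = 4) {
  stopifnot(is.matrix(scores), ncol(scores) >= 2)
  if (nrow(scores) < 4) {
    warning("fewer than 4 samples; outlier flagging skipped", call. = FALSE)
    return(character())
  }
  s <- scores[, 1:2, drop = FALSE]
  centroid <- apply(s, 2, stats::median)
  d <- sqrt(rowSums(sweep(s, 2, centroid)^2))
  scale <- stats::mad(d)
  med <- stats::median(d)
  if (scale == 0) {
    flagged <- d > med & is.finite(k_sd)   # all-identical bulk: any excess distance
  } else {
    flagged <- (d - med) / scale > k_sd
  }
  rownames(s)[flagged]
}

#' Detected probes from a detection p-value matrix
#'
#' A probe counts as detected when its detection p-value is below \code{p_cut}
#' in at least \code{min_samples} samples. With no detection matrix every
#' probe is treated as detected.
#'
#' @param detection_p Probe x sample matrix of detection p-values, or NULL.
#' @param probe_ids Probe ids to report on when \code{detection_p} is NULL.
#' @param p_cut Detection threshold; default 0.01.
#' @param min_samples Minimum number of samples below threshold; default 1.
#' @return Character vector of detected probe ids.
#' @export
detected_probes <- function(detection_p = NULL, probe_ids = NULL,
                            p_cut = 0.01, min_samples = 1) {
  if (is.null(detection_p)) {
    if (is.null(probe_ids)) stop("supply detection_p or probe_ids", call. = FALSE)
    return(as.character(probe_ids))
  }
  stopifnot(is.matrix(detection_p))
  hits <- rowSums(detection_p < p_cut, na.rm = TRUE) >= min_samples
  rownames(detection_p)[hits]
}
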