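test_that("beta to M conversion matches the logit2 closed form", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)                      # log2(0.8/0.2) = log2 4
  expect_equal(beta_to_m(0, epsilon = 1e-3), log2(0.001 / 0.999))
  expect_error(beta_to_m(1.5), "\\[0, 1\\]")
  expect_error(beta_to_m(0.5, epsilon = 0.6))
})

test_that("beta/M transform is strictly monotone and invertible", {
  eps <- 1e-3
  b <- seq(eps, 1 - eps, length.out = 201)
  m <- beta_to_m(b, epsilon = eps)
  expect_true(all(diff(m) > 0))
  expect_equal(m_to_beta(m), b, tolerance = 1e-12)
})

test_that("methylation binning uses inclusive 70/30 boundaries, exhaustively", {
  expect_equal(as.character(bin_methylation_state(0.70)), "hyper")
  expect_equal(as.character(bin_methylation_state(0.30)), "hypo")
  expect_equal(as.character(bin_methylation_state(0.5)), "mid")
  grid <- seq(0, 1, by = 0.005)
  states <- bin_methylation_state(grid)
  expect_false(anyNA(states))                           # exhaustive over [0,1]
  expect_identical(as.character(states),
                   ifelse(grid >= 0.7, "hyper", ifelse(grid <= 0.3, "hypo", "mid")))
  expect_error(bin_methylation_state(-0.1), "\\[0, 1\\]")
})

test_that("quantile normalization has the defining fixed point and invariant", {
  # identical value multisets: normalization keeps sorted columns equal
  a <- c(5, 1, 3); b <- c(1, 3, 5)
  m <- cbind(S1 = a, S2 = b)
  rownames(m) <- paste0("p", 1:3)
  norm <- normalize_expression(m, log2_transform = FALSE)
  expect_equal(sort(norm[, 1]), sort(m[, 1]), ignore_attr = TRUE)
  expect_equal(rank(norm[, 2]), rank(m[, 2]))

  # hand-computed 2x2 case: sorted columns both become (1.5, 3.5)
  m2 <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(c("p1", "p2"), c("S1", "S2")))
  norm2 <- normalize_expression(m2, log2_transform = FALSE)
  expect_equal(unname(sort(norm2[, 1])), c(1.5, 3.5))
  expect_equal(unname(sort(norm2[, 2])), c(1.5, 3.5))

  # any input: per-column sorted vectors identical after normalization
  set.seed(9)
  m3 <- matrix(rexp(60, 1 / 50), 15, 4,
               dimnames = list(paste0("p", 1:15), paste0("S", 1:4)))
  norm3 <- normalize_expression(m3)
  sorted <- apply(norm3, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_true(isTRUE(attr(norm3, "normalized")))

  expect_error(normalize_expression(m3[, 1, drop = FALSE]), "2 samples")
})

test_that("replicate correlation handles exact and simulated replicates", {
  sheet <- toy_sheet(n_subj = 1, n_reps = 2)
  x <- rnorm(200)
  m <- cbind(x, x, rnorm(200), rnorm(200))
  colnames(m) <- sheet$sample_id
  rc <- replicate_correlation(m, sheet)
  r2_dup <- rc$pairs$r_squared[rc$pairs$sample_1 == sheet$sample_id[1]]
  expect_equal(r2_dup, 1)

  m2 <- cbind(x, -x, rnorm(200), rnorm(200))
  colnames(m2) <- sheet$sample_id
  rc2 <- replicate_correlation(m2, sheet)
  expect_equal(rc2$pairs$r_squared[rc2$pairs$sample_1 == sheet$sample_id[1]],
               1)                            # r^2 is sign-invariant

  # simulation oracle: r = var_s / (var_s + var_n) for shared-signal replicates
  set.seed(21)
  n <- 20000; sd_s <- 1; sd_n <- 0.5
  signal <- rnorm(n, sd = sd_s)
  m3 <- cbind(signal + rnorm(n, sd = sd_n), signal + rnorm(n, sd = sd_n),
              rnorm(n), rnorm(n))
  colnames(m3) <- sheet$sample_id
  rc3 <- replicate_correlation(m3, sheet)
  expected_r2 <- (sd_s^2 / (sd_s^2 + sd_n^2))^2
  expect_equal(rc3$pairs$r_squared[rc3$pairs$sample_1 == sheet$sample_id[1]],
               expected_r2, tolerance = 0.02)

  none <- sheet; none$replicate_role <- "biological"
  expect_warning(rc4 <- replicate_correlation(m, none), "no technical-replicate")
  expect_equal(nrow(rc4$pairs), 0L)
})

test_that("PCA scores match an independent eigendecomposition", {
  set.seed(5)
  m <- matrix(rnorm(120), 20, 6,
              dimnames = list(paste0("p", 1:20), paste0("S", 1:6)))
  pc <- pca_scores(m, n_components = 5)
  # oracle: eigendecomposition of the sample covariance of the columns
  x <- t(m); xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(cov(xc), symmetric = TRUE)
  oracle <- xc %*% ev$vectors[, 1:5]
  for (k in 1:5) {
    expect_lt(min(max(abs(pc$scores[, k] - oracle[, k])),
                  max(abs(pc$scores[, k] + oracle[, k]))), 1e-8)
  }
  expect_true(all(diff(pc$var_explained) <= 1e-12))

  # two identical samples: zero variance everywhere
  m2 <- cbind(S1 = rnorm(10), S2 = 0); m2[, 2] <- m2[, 1]
  rownames(m2) <- paste0("p", 1:10)
  pc2 <- pca_scores(m2, n_components = 2)
  expect_equal(unname(pc2$scores), matrix(0, 2, 2), tolerance = 1e-12)

  # 3 samples on a line in probe space: all variance on component 1
  base <- rnorm(15); dir <- rnorm(15)
  m3 <- cbind(S1 = base, S2 = base + dir, S3 = base + 2 * dir)
  rownames(m3) <- paste0("p", 1:15)
  pc3 <- pca_scores(m3, n_components = 2)
  expect_equal(pc3$var_explained[1], 1, tolerance = 1e-12)

  expect_error(pca_scores(m, n_components = 10), "exceeds")
})

test_that("PCA scores are invariant (up to sign) under probe reordering", {
  set.seed(6)
  m <- matrix(rnorm(200), 40, 5,
              dimnames = list(paste0("p", 1:40), paste0("S", 1:5)))
  pc1 <- pca_scores(m, 2)
  pc2 <- pca_scores(m[sample(nrow(m)), ], 2)
  for (k in 1:2) {
    expect_lt(min(max(abs(pc1$scores[, k] - pc2$scores[, k])),
                  max(abs(pc1$scores[, k] + pc2$scores[, k]))), 1e-8)
  }
})

test_that("outlier flagging finds a planted outlier and nothing else", {
  set.seed(8)
  scores <- cbind(rnorm(12, sd = 1), rnorm(12, sd = 1))
  rownames(scores) <- sprintf("S%02d", 1:12)
  scores[12, ] <- c(30, 30)    # ~10 bulk SDs away
  flagged <- flag_outlier_samples(scores, k_sd = 4)
  expect_identical(flagged, "S12")
  expect_identical(flag_outlier_samples(scores, k_sd = Inf), character())

  same <- matrix(1, 8, 2, dimnames = list(paste0("S", 1:8), NULL))
  expect_identical(flag_outlier_samples(same, k_sd = 4), character())

  expect_warning(few <- flag_outlier_samples(scores[1:3, ], 4), "fewer than 4")
  expect_identical(few, character())
})

test_that("detected-probe rule applies the detection p-value threshold", {
  dp <- matrix(c(0.5, 0.5, 0.005, 0.5, 0.02, 0.02), nrow = 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  expect_identical(detected_probes(dp), "b")
  expect_identical(detected_probes(NULL, probe_ids = c("x", "y")), c("x", "y"))
})
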