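test_that("technical replicates collapse to per-unit means", {
  sheet <- toy_sheet(n_subj = 2, n_reps = 2)
  x <- rnorm(50)
  m <- sapply(seq_len(nrow(sheet)), function(i) x)
  colnames(m) <- sheet$sample_id; rownames(m) <- paste0("p", 1:50)
  col <- collapse_technical_replicates(m, sheet)
  expect_equal(ncol(col$values), 4L)           # 4 subject-clone-celltype units
  expect_equal(unname(col$values[, 1]), x)     # identical reps stay identical

  m2 <- m; m2[, 1] <- 1; m2[, 2] <- 3
  col2 <- collapse_technical_replicates(m2, sheet)
  expect_true(all(col2$values[, 1] == 2))      # mean(1, 3) = 2

  cfg <- small_sim_config()
  st <- simulate_methylation_study(cfg)
  col3 <- collapse_technical_replicates(st$beta, st$sheet)
  units <- unique(st$sheet[, c("subject_id", "clone_id", "cell_type")])
  expect_equal(ncol(col3$values), nrow(units))

  expect_error(collapse_technical_replicates(m, sheet, policy = "block"),
               "not implemented")
})

test_that("the two-group fit reproduces hand arithmetic and OLS", {
  sheet <- toy_sheet(n_subj = 2, n_reps = 1)
  m <- matrix(c(0, 0, 1, 1,      # patients 0, controls 1
                1, 2, 4, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("pA", "pB"), sheet$sample_id))
  fit <- fit_group_model(m, sheet)
  expect_equal(fit$effect[1], -1)
  expect_equal(fit$s2[1], 0)

  sheet3 <- toy_sheet(n_subj = 3, n_reps = 1)
  m3 <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
               dimnames = list("pA", sheet3$sample_id))
  fit3 <- fit_group_model(m3, sheet3)
  expect_equal(fit3$effect, -3)
  expect_equal(fit3$s2, 1)
  expect_equal(fit3$df, 4)

  # OLS oracle on a random fixture
  set.seed(31)
  sheetr <- toy_sheet(n_subj = 4, n_reps = 1)
  mr <- matrix(rnorm(100 * 8), 100, 8,
               dimnames = list(paste0("p", 1:100), sheetr$sample_id))
  fitr <- fit_group_model(mr, sheetr)
  grp <- factor(sheetr$status, levels = c("control", "patient"))
  for (i in c(1, 17, 50, 100)) {
    ols <- lm(mr[i, ] ~ grp)
    expect_equal(fitr$effect[i], unname(coef(ols)[2]), tolerance = 1e-10)
    expect_equal(fitr$s2[i], sum(residuals(ols)^2) / ols$df.residual,
                 tolerance = 1e-10)
  }

  one <- sheetr[sheetr$subject_id %in% c("PA1", "CO1", "CO2"), ]
  expect_error(fit_group_model(mr[, one$sample_id], one), ">=2 units")
})

test_that("variance moderation shrinks toward the prior and handles limits", {
  s2 <- rep(2, 20)
  mod <- moderate_variances(s2, df = 4)
  expect_equal(mod$s2_post, s2)
  expect_identical(mod$d0, Inf)

  # d0 -> 0 recovers the ordinary statistic: shrinkage weight df/(df+d0) -> 1
  set.seed(1)
  s2r <- rchisq(100, 4) / 4
  d0 <- 1e-9; s0 <- 1
  manual <- (d0 * s0 + 4 * s2r) / (d0 + 4)
  expect_equal(manual, s2r, tolerance = 1e-9)
})

test_that("moment matching recovers planted hyperparameters", {
  set.seed(77)
  d0_true <- 4; s0_true <- 2; df <- 10; n <- 10000
  sigma2 <- d0_true * s0_true / rchisq(n, d0_true)
  s2 <- sigma2 * rchisq(n, df) / df
  mod <- moderate_variances(s2, df)
  expect_lt(abs(mod$d0 - d0_true) / d0_true, 0.25)
  expect_lt(abs(mod$s0_2 - s0_true) / s0_true, 0.10)

  # independent cross-check against limma's empirical-Bayes fit
  sq <- limma::squeezeVar(s2, df = df)
  expect_equal(mod$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(mod$s0_2, sq$var.prior, tolerance = 0.05)
  expect_equal(mod$s2_post, sq$var.post, tolerance = 1e-6)
})

test_that("without moderation the pipeline equals the pooled-variance t-test", {
  set.seed(12)
  sheet <- toy_sheet(n_subj = 3, n_reps = 1)
  m <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(paste0("p", 1:50), sheet$sample_id))
  res <- run_differential(m, sheet, moderate = FALSE)
  for (i in c(2, 25, 50)) {
    tt <- t.test(m[i, sheet$status == "patient"], m[i, sheet$status == "control"],
                 var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-8)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-8)
  }
})

test_that("BH adjustment matches hand computation and the brute-force step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  # oracle: rejection set = largest k with p_(k) <= k alpha / n
  bh_reject_brute <- function(p, alpha) {
    n <- length(p); o <- order(p); ps <- p[o]
    k <- suppressWarnings(max(which(ps <= seq_len(n) * alpha / n)))
    rej <- logical(n)
    if (is.finite(k) && k >= 1) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  set.seed(14)
  for (rep in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    for (alpha in c(0.01, 0.05, 0.2, 0.5)) {
      expect_identical(q <= alpha, bh_reject_brute(p, alpha))
    }
    expect_true(all(diff(q[order(p)]) >= -1e-15))   # order-preserving
  }
})

test_that("differential calling filters by q and keeps directions", {
  res <- data.frame(probe_id = paste0("p", 1:4), gene_symbol = paste0("G", 1:4),
                    effect = c(1, -1, 2, -2), p = c(1, 1, 1e-8, 1),
                    q = c(1, 1, 4e-8, 1),
                    direction = c("hyper", "hypo", "hyper", "hypo"))
  none <- call_differential(transform(res, q = 1), 0.05)
  expect_equal(nrow(none$probes), 0L)
  one <- call_differential(res, 0.05)
  expect_equal(one$probes$probe_id, "p3")
  expect_equal(one$genes$direction, "hyper")
})

test_that("no q<0.05 calls arise under a planted global null", {
  cfg <- small_sim_config(seed = 19, n_probes = 2000,
                          celltype_n = 0,
                          disease_n = c(iPS = 0, ONS = 0, fibroblast = 0),
                          shared_core_size = 0, shared_core_n_hyper = 0)
  st <- simulate_methylation_study(cfg)
  ips <- st$sheet[st$sheet$cell_type == "iPS", ]
  m <- beta_to_m(st$beta[, ips$sample_id])
  res <- run_differential(m, ips, annotation = st$annotation)
  expect_equal(sum(res$q < 0.05, na.rm = TRUE), 0L)
})
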