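test_that("generation is deterministic and respects bookkeeping invariants", {
  cfg <- small_sim_config(seed = 101)
  a <- simulate_methylation_study(cfg)
  b <- simulate_methylation_study(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$truth, b$truth)

  expect_true(all(a$beta >= 0 & a$beta <= 1))
  # columns = units x tech reps: (8 subjects x 3 cell types + 4 second
  # iPS clones + 1 ES line) x 3 passages
  units <- unique(a$sheet[, c("subject_id", "clone_id", "cell_type")])
  expect_equal(ncol(a$beta), nrow(units) * cfg$tech_reps)
  expect_identical(colnames(a$beta), a$sheet$sample_id)

  core <- a$truth$shared_core
  expect_equal(nrow(core), cfg$shared_core_size)
  for (ct in cfg$cell_types) {
    dis <- a$truth$disease[[ct]]
    expect_equal(nrow(dis), unname(cfg$disease_n[[ct]]))
    # shared core present with the same direction in every cell type
    idx <- match(core$probe_id, dis$probe_id)
    expect_false(anyNA(idx))
    expect_identical(dis$direction[idx], core$direction)
  }
  expect_equal(sum(core$direction == "hyper"), cfg$shared_core_n_hyper)
})

test_that("a null, noise-free configuration is exactly degenerate downstream", {
  cfg <- small_sim_config(seed = 102, n_probes = 300,
                          celltype_n = 0,
                          disease_n = c(iPS = 0, ONS = 0, fibroblast = 0),
                          shared_core_size = 0, shared_core_n_hyper = 0,
                          bio_sd = 0, noise_sd = 0, include_es = FALSE)
  st <- simulate_methylation_study(cfg)
  m <- beta_to_m(st$beta)
  rc <- replicate_correlation(m, st$sheet)
  expect_true(all(rc$pairs$r_squared == 1))
  ips <- st$sheet[st$sheet$cell_type == "iPS", ]
  res <- run_differential(m[, ips$sample_id], ips)
  expect_equal(sum(res$q < 0.05, na.rm = TRUE), 0L)
})

test_that("planted disease loci are recovered with the power a t-test predicts", {
  # scaled-down study: delta-beta 0.1 at 4 vs 4 subjects, no moderation, so
  # the per-probe test is exactly the pooled two-sample t with known power
  n_rep <- 25
  delta_beta <- 0.1
  hits <- numeric(n_rep)
  # no second iPS clone: the oracle is the 4-vs-4 pooled t-test exactly
  cfg0 <- small_sim_config(n_probes = 400, celltype_n = 0,
                           disease_n = c(iPS = 50, ONS = 0, fibroblast = 0),
                           shared_core_size = 0, shared_core_n_hyper = 0,
                           disease_delta_beta = delta_beta,
                           second_clone_subjects = 0,
                           include_es = FALSE)
  for (r in seq_len(n_rep)) {
    cfg <- small_sim_config(seed = 200 + r, n_probes = 400, celltype_n = 0,
                            disease_n = c(iPS = 50, ONS = 0, fibroblast = 0),
                            shared_core_size = 0, shared_core_n_hyper = 0,
                            disease_delta_beta = delta_beta,
                            second_clone_subjects = 0,
                            include_es = FALSE)
    st <- simulate_methylation_study(cfg)
    ips <- st$sheet[st$sheet$cell_type == "iPS", ]
    m <- beta_to_m(st$beta[, ips$sample_id])
    res <- run_differential(m, ips, moderate = FALSE)
    planted <- res$probe_id %in% st$truth$disease$iPS$probe_id
    hits[r] <- mean(res$p[planted] < 0.05, na.rm = TRUE)
  }
  delta_m <- log2((0.5 + delta_beta / 2) / (0.5 - delta_beta / 2)) -
    log2((0.5 - delta_beta / 2) / (0.5 + delta_beta / 2))
  unit_sd <- sqrt(cfg0$bio_sd^2 + cfg0$noise_sd^2 / cfg0$tech_reps)
  expected <- power.t.test(n = 4, delta = delta_m, sd = unit_sd,
                           sig.level = 0.05)$power
  se <- sd(hits) / sqrt(n_rep)
  expect_lt(abs(mean(hits) - expected), 3 * se + 0.03)
})

test_that("expression coupling obeys the configured concordance", {
  cfg <- small_sim_config(seed = 103, coupling_fraction = 1, concordance_prob = 1)
  st <- simulate_methylation_study(cfg)
  ex <- simulate_expression_study(cfg, st)
  for (ct in cfg$cell_types) {
    coupled <- ex$truth[[ct]][ex$truth[[ct]]$coupled, ]
    expect_equal(nrow(coupled), nrow(st$truth$disease[[ct]]))
    dm_dir <- setNames(st$truth$disease[[ct]]$direction,
                       st$truth$disease[[ct]]$gene_symbol)
    expect_true(all(ifelse(dm_dir[coupled$gene_symbol] == "hypo", "up", "down")
                    == coupled$direction))
  }
  expect_equal(dim(ex$expression), c(cfg$n_probes, nrow(st$sheet)))
  expect_true(all(ex$expression > 0))

  cfg0 <- small_sim_config(seed = 104, coupling_fraction = 0)
  ex0 <- simulate_expression_study(cfg0, simulate_methylation_study(cfg0))
  expect_false(any(unlist(lapply(ex0$truth, `[[`, "coupled"))))

  # concordance 0.8: observed concordant fraction within the binomial 99% CI
  cfg8 <- small_sim_config(seed = 105, coupling_fraction = 1,
                           concordance_prob = 0.8,
                           disease_n = c(iPS = 200, ONS = 200, fibroblast = 200),
                           n_probes = 2000)
  ex8 <- simulate_expression_study(cfg8, simulate_methylation_study(cfg8))
  conc <- ex8$truth$iPS$concordant[ex8$truth$iPS$coupled]
  ci <- qbinom(c(0.005, 0.995), length(conc), 0.8) / length(conc)
  expect_gte(mean(conc), ci[1])
  expect_lte(mean(conc), ci[2])
})

test_that("interactome generator yields trees at m = 1 and keeps determinism", {
  cfg <- small_sim_config(seed = 106, interactome_m = 1)
  net <- simulate_interactome(cfg)
  expect_equal(igraph::ecount(net$network),
               igraph::vcount(net$network) - 1L)
  net2 <- simulate_interactome(cfg)
  expect_identical(igraph::as_edgelist(net$network),
                   igraph::as_edgelist(net2$network))
  expect_identical(net$seeds, net2$seeds)
  expect_equal(length(net$seeds), cfg$n_seed_genes)
})

test_that("seed enrichment moves the PPI Z-score as designed", {
  # null draw: no association between network membership and disease genes
  zs <- numeric(20)
  for (r in seq_len(20)) {
    cfg <- small_sim_config(seed = 300 + r, seed_enrichment = 0)
    st <- simulate_methylation_study(cfg)
    disease <- unique(unlist(lapply(st$truth$disease, `[[`, "gene_symbol")))
    net <- simulate_interactome(cfg, disease_genes = disease)
    sn <- suppressMessages(build_seed_network(net$seeds, net$network))
    res <- ppi_enrichment_ztest(disease, sn, cfg$n_probes,
                                n_convention = "query")
    zs[r] <- res$Z
  }
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(20))

  # strong enrichment: significant in the large majority of draws
  sig <- logical(10)
  for (r in seq_len(10)) {
    cfg <- small_sim_config(seed = 400 + r, seed_enrichment = 8)
    st <- simulate_methylation_study(cfg)
    disease <- unique(unlist(lapply(st$truth$disease, `[[`, "gene_symbol")))
    net <- simulate_interactome(cfg, disease_genes = disease)
    sn <- suppressMessages(build_seed_network(net$seeds, net$network))
    res <- ppi_enrichment_ztest(disease, sn, cfg$n_probes,
                                n_convention = "query")
    sig[r] <- res$Z >= 1.65
  }
  expect_gte(mean(sig), 0.9)
})

test_that("the planted outlier array is flagged by within-cell-type PCA QC", {
  cfg <- small_sim_config(seed = 107, plant_outlier = TRUE)
  st <- simulate_methylation_study(cfg)
  m <- beta_to_m(st$beta)
  # global leading components carry cell-type separation, so QC inspects
  # each cell type's score space on its own
  fb <- st$sheet$sample_id[st$sheet$cell_type == "fibroblast"]
  pc <- pca_scores(m[, fb], 2)
  flagged <- flag_outlier_samples(pc$scores, k_sd = 4)
  target <- st$sheet$sample_id[st$sheet$cell_type == "fibroblast" &
                               st$sheet$status == "control"][1]
  expect_identical(flagged, target)
})
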