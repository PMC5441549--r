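#' Simulation configuration for a synthetic case-control methylation study
#'
#' Defaults mirror the study design this package targets: 27,578 CpG probes
#' (one 27K array), three patient-derived cell types (iPS, ONS, fibroblast)
#' plus an ES comparator line, 4 patients and 4 controls, every line measured
#' in triplicate (consecutive passages as technical replicates), and two
#' subjects per group carrying a second iPS clone (biological replicates).
#' Disease effects are planted per cell type at the counts the study reports
#' as significant (883 / 1328 / 952 loci) including a 5-probe core shared by
#' all three cell types with consistent direction (4 hypo, 1 hyper).
#'
#' @param n_probes Number of CpG probes.
#' @param cell_types Patient-derived cell types to simulate.
#' @param include_es Add a triplicate ES comparator line (QC only).
#' @param n_patients,n_controls Subjects per group.
#' @param tech_reps Technical replicates (consecutive passages) per line.
#' @param second_clone_subjects Subjects per group with a second iPS clone.
#' @param baseline_weights Mixture weights of the hypo/mid/hyper baseline
#'   beta modes.
#' @param celltype_n Probes carrying cell-type effects.
#' @param celltype_sd SD (M scale) of per-cell-type offsets on those probes.
#' @param disease_n Named integer vector: planted disease-affected probes per
#'   cell type.
#' @param shared_core_size Probes affected in all cell types, same direction.
#' @param shared_core_n_hyper How many core probes are hypermethylated in
#'   patients (rest hypo).
#' @param disease_delta_beta Planted patient-control difference quoted as a
#'   beta shift at beta = 0.5; applied as the equivalent constant M shift.
#' @param bio_sd Between-unit biological SD on the M scale.
#' @param noise_sd Technical-replicate noise SD on the M scale.
#' @param plant_outlier Add one aberrant fibroblast control array (globally
#'   shifted) for QC-path testing.
#' @param expr_baseline_mean,expr_baseline_sd Gene-level baseline of log2
#'   fluorescence.
#' @param expr_celltype_n,expr_celltype_sd Cell-type expression effects.
#' @param expr_effect_log2 Planted disease log2 fold change for DE genes.
#' @param expr_bio_sd,expr_noise_sd Biological / replicate SD, log2 scale.
#' @param coupling_fraction Fraction of planted DM genes that also get a DE
#'   effect in the same cell type.
#' @param concordance_prob Probability that a coupled DE effect is
#'   direction-concordant (hypo with up, hyper with down).
#' @param de_extra_n Additional DE genes planted independently of DM.
#' @param interactome_n_genes,interactome_m Preferential-attachment
#'   interactome size and edges added per new node.
#' @param n_seed_genes Seed genes designated in the interactome.
#' @param seed_enrichment Sampling-weight multiplier making disease-affected
#'   genes more likely to be picked as network genes/seeds (0 = null).
#' @param seed Master RNG seed; every generator derives from it.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_probes = 27578,
                       cell_types = c("iPS", "ONS", "fibroblast"),
                       include_es = TRUE,
                       n_patients = 4, n_controls = 4,
                       tech_reps = 3,
                       second_clone_subjects = 2,
                       baseline_weights = c(hypo = 0.3, mid = 0.4, hyper = 0.3),
                       celltype_n = 7854, celltype_sd = 1.5,
                       disease_n = c(iPS = 883, ONS = 1328, fibroblast = 952),
                       shared_core_size = 5, shared_core_n_hyper = 1,
                       disease_delta_beta = 0.2,
                       bio_sd = 0.25, noise_sd = 0.15,
                       plant_outlier = FALSE,
                       expr_baseline_mean = 8, expr_baseline_sd = 1,
                       expr_celltype_n = 3000, expr_celltype_sd = 1.2,
                       expr_effect_log2 = 1.2,
                       expr_bio_sd = 0.35, expr_noise_sd = 0.15,
                       coupling_fraction = 0.5,
                       concordance_prob = 0.9,
                       de_extra_n = 300,
                       interactome_n_genes = 2000, interactome_m = 3,
                       n_seed_genes = 50, seed_enrichment = 0,
                       seed = 1) {
  cfg <- as.list(environment())
  # tolerate YAML-style list inputs
  cfg$disease_n <- unlist(cfg$disease_n)
  cfg$baseline_weights <- unlist(cfg$baseline_weights)
  cfg$cell_types <- unlist(cfg$cell_types)
  stopifnot(cfg$n_probes >= 1, cfg$tech_reps >= 1,
            all(names(cfg$disease_n) %in% cfg$cell_types) || is.null(names(cfg$disease_n)),
            cfg$shared_core_size <= min(cfg$disease_n),
            cfg$shared_core_n_hyper <= cfg$shared_core_size,
            cfg$coupling_fraction >= 0, cfg$coupling_fraction <= 1,
            cfg$concordance_prob >= 0, cfg$concordance_prob <= 1,
            abs(sum(cfg$baseline_weights) - 1) < 1e-8,
            cfg$second_clone_subjects <= min(cfg$n_patients, cfg$n_controls))
  if (is.null(names(cfg$disease_n))) names(cfg$disease_n) <- cfg$cell_types
  if (any(cfg$disease_n > cfg$n_probes)) stop("disease_n exceeds n_probes", call. = FALSE)
  if (cfg$celltype_n > cfg$n_probes) stop("celltype_n exceeds n_probes", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# constant M shift equivalent to a beta shift of delta at beta = 0.5
.delta_m_from_delta_beta <- function(delta) {
  log2((0.5 + delta / 2) / (0.5 - delta / 2)) -
    log2((0.5 - delta / 2) / (0.5 + delta / 2))
}

.probe_ids <- function(n) sprintf("cg%07d", seq_len(n))
.gene_ids <- function(n) sprintf("GENE%05d", seq_len(n))

#' Simulate a full methylation study with planted ground truth
#'
#' Draws per-probe baseline betas from a three-mode (hypo/mid/hyper) Beta
#' mixture, adds cell-type and case-control effects on the M scale, then
#' back-transforms so every value stays in (0, 1). Each biological unit
#' (subject x clone x cell type) gets its own latent profile; technical
#' replicates are that latent profile plus replicate noise. Fully
#' deterministic given \code{config$seed}.
#'
#' @param config A [sim_config()] object.
#' @return List: \code{beta} (probe x sample matrix), \code{sheet} (sample
#'   sheet data.frame), \code{annotation} (probe_id -> gene_symbol, 1:1),
#'   \code{truth} (celltype_probes; disease: per-cell-type data.frame of
#'   probe_id, gene_symbol, direction; shared_core).
#' @export
simulate_methylation_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_probes
  probes <- .probe_ids(n)
  genes <- .gene_ids(n)

  # baseline mixture: component then Beta draw
  comp <- sample(c("hypo", "mid", "hyper"), n, replace = TRUE,
                 prob = config$baseline_weights)
  b0 <- numeric(n)
  b0[comp == "hypo"] <- stats::rbeta(sum(comp == "hypo"), 2, 10)
  b0[comp == "mid"] <- stats::rbeta(sum(comp == "mid"), 8, 8)
  b0[comp == "hyper"] <- stats::rbeta(sum(comp == "hyper"), 10, 2)
  m0 <- beta_to_m(b0)

  cts <- config$cell_types
  ct_probes <- sample.int(n, config$celltype_n)
  ct_offset <- matrix(0, n, length(cts), dimnames = list(NULL, cts))
  for (ct in cts) {
    ct_offset[ct_probes, ct] <- stats::rnorm(length(ct_probes), 0, config$celltype_sd)
  }

  # disease effects: shared core first, then per-cell-type specific probes
  delta_m <- .delta_m_from_delta_beta(config$disease_delta_beta)
  core_idx <- sample.int(n, config$shared_core_size)
  core_dir <- c(rep("hyper", config$shared_core_n_hyper),
                rep("hypo", config$shared_core_size - config$shared_core_n_hyper))
  core_dir <- sample(core_dir)
  remaining <- setdiff(seq_len(n), core_idx)
  dis_idx <- list(); dis_dir <- list()
  for (ct in cts) {
    extra <- sample(remaining, config$disease_n[[ct]] - config$shared_core_size)
    remaining <- setdiff(remaining, extra)   # specific probes unique to one cell type
    dis_idx[[ct]] <- c(core_idx, extra)
    dis_dir[[ct]] <- c(core_dir,
                       sample(c("hyper", "hypo"), length(extra), replace = TRUE))
  }

  units <- .study_units(config)
  n_units <- nrow(units)
  sample_rows <- list(); cols <- list()
  for (i in seq_len(n_units)) {
    u <- units[i, ]
    m_lat <- m0
    if (u$cell_type %in% cts) {
      m_lat <- m_lat + ct_offset[, u$cell_type]
    } else {
      # ES comparator: tracks the pluripotent profile, with a small private shift
      plurip <- if ("iPS" %in% cts) "iPS" else cts[1]
      m_lat <- m_lat + ct_offset[, plurip] + stats::rnorm(n, 0, 0.2)
    }
    if (u$status == "patient" && u$cell_type %in% cts) {
      idx <- dis_idx[[u$cell_type]]
      sgn <- ifelse(dis_dir[[u$cell_type]] == "hyper", 1, -1)
      m_lat[idx] <- m_lat[idx] + sgn * delta_m
    }
    m_lat <- m_lat + stats::rnorm(n, 0, config$bio_sd)
    for (r in seq_len(config$tech_reps)) {
      sid <- sprintf("%s_%s_%s_P%d", u$subject_id, u$cell_type, u$clone_id,
                     u$passage0 + r - 1)
      m_rep <- m_lat + stats::rnorm(n, 0, config$noise_sd)
      cols[[sid]] <- m_to_beta(m_rep)
      sample_rows[[sid]] <- data.frame(
        sample_id = sid, subject_id = u$subject_id, cell_type = u$cell_type,
        status = u$status, passage = u$passage0 + r - 1L,
        clone_id = u$clone_id, replicate_role = "technical",
        stringsAsFactors = FALSE)
    }
  }
  beta <- do.call(cbind, cols)
  rownames(beta) <- probes
  sheet <- do.call(rbind, c(sample_rows, make.row.names = FALSE))

  if (config$plant_outlier) {
    fb_ctrl <- sheet$sample_id[sheet$cell_type == "fibroblast" &
                               sheet$status == "control"]
    if (length(fb_ctrl) > 0) {
      tgt <- fb_ctrl[1]
      beta[, tgt] <- m_to_beta(beta_to_m(beta[, tgt]) +
                               stats::rnorm(n, 3, 0.5))
    }
  }

  truth <- list(
    celltype_probes = probes[ct_probes],
    disease = stats::setNames(lapply(cts, function(ct) {
      data.frame(probe_id = probes[dis_idx[[ct]]],
                 gene_symbol = genes[dis_idx[[ct]]],
                 direction = dis_dir[[ct]],
                 stringsAsFactors = FALSE)
    }), cts),
    shared_core = data.frame(probe_id = probes[core_idx],
                             gene_symbol = genes[core_idx],
                             direction = core_dir,
                             stringsAsFactors = FALSE))
  list(beta = beta, sheet = sheet,
       annotation = data.frame(probe_id = probes, gene_symbol = genes,
                               stringsAsFactors = FALSE),
       truth = truth)
}

# one row per biological unit (subject x clone x cell type), plus ES line
.study_units <- function(config) {
  rows <- list()
  add <- function(subject, status, ct, clone, passage0) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject_id = subject, status = status, cell_type = ct,
      clone_id = clone, passage0 = passage0, stringsAsFactors = FALSE)
  }
  groups <- list(patient = config$n_patients, control = config$n_controls)
  for (status in names(groups)) {
    for (j in seq_len(groups[[status]])) {
      subject <- sprintf("%s%02d", if (status == "patient") "PT" else "CT", j)
      for (ct in config$cell_types) {
        add(subject, status, ct, "c1", 4L)
        if (ct == "iPS" && j <= config$second_clone_subjects) {
          add(subject, status, ct, "c2", 4L)
        }
      }
    }
  }
  if (config$include_es) add("ES01", "control", "ES", "c1", 10L)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Simulate a coupled expression study
#'
#' Builds a gene x sample raw-fluorescence matrix over the same samples as a
#' simulated methylation study. A configured fraction of the planted
#' differentially methylated genes receive an expression effect in the same
#' cell type, direction-concordant (hypomethylated with up-regulated,
#' hypermethylated with down-regulated) with probability
#' \code{concordance_prob}; further DE genes are planted independently of
#' methylation. Deterministic given \code{config$seed} (offset so the draws
#' are independent of the methylation draws).
#'
#' @param config A [sim_config()] object.
#' @param meth A result of [simulate_methylation_study()] (for the sample
#'   sheet and the methylation ground truth).
#' @return List: \code{expression} (raw fluorescence matrix, gene x sample,
#'   \code{normalized = FALSE}), \code{truth} (per-cell-type data.frame:
#'   gene_symbol, direction, coupled, concordant).
#' @export
simulate_expression_study <- function(config, meth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- .gene_ids(config$n_probes)
  n <- length(genes)
  sheet <- meth$sheet
  cts <- config$cell_types

  mu <- stats::rnorm(n, config$expr_baseline_mean, config$expr_baseline_sd)
  ct_genes <- sample.int(n, min(config$expr_celltype_n, n))
  ct_off <- matrix(0, n, length(cts), dimnames = list(NULL, cts))
  for (ct in cts) {
    ct_off[ct_genes, ct] <- stats::rnorm(length(ct_genes), 0, config$expr_celltype_sd)
  }

  truth <- list()
  de_idx <- list(); de_sgn <- list()
  for (ct in cts) {
    dm <- meth$truth$disease[[ct]]
    n_coupled <- round(config$coupling_fraction * nrow(dm))
    coupled_rows <- if (n_coupled > 0) sample.int(nrow(dm), n_coupled) else integer()
    coupled_genes <- dm$gene_symbol[coupled_rows]
    concordant <- stats::runif(n_coupled) < config$concordance_prob
    # concordance rule: hypo -> up, hyper -> down
    conc_dir <- ifelse(dm$direction[coupled_rows] == "hypo", "up", "down")
    dirs <- ifelse(concordant, conc_dir,
                   ifelse(conc_dir == "up", "down", "up"))
    pool <- setdiff(seq_len(n), match(dm$gene_symbol, genes))
    extra <- if (config$de_extra_n > 0) sample(pool, min(config$de_extra_n, length(pool))) else integer()
    extra_dir <- sample(c("up", "down"), length(extra), replace = TRUE)
    idx <- c(match(coupled_genes, genes), extra)
    dir_all <- c(dirs, extra_dir)
    de_idx[[ct]] <- idx
    de_sgn[[ct]] <- ifelse(dir_all == "up", 1, -1)
    truth[[ct]] <- data.frame(
      gene_symbol = genes[idx],
      direction = dir_all,
      coupled = c(rep(TRUE, length(coupled_genes)), rep(FALSE, length(extra))),
      concordant = c(concordant, rep(NA, length(extra))),
      stringsAsFactors = FALSE)
  }

  units <- unique(sheet[, c("subject_id", "clone_id", "cell_type", "status")])
  cols <- list()
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    x <- mu
    if (u$cell_type %in% cts) {
      x <- x + ct_off[, u$cell_type]
      if (u$status == "patient") {
        x[de_idx[[u$cell_type]]] <- x[de_idx[[u$cell_type]]] +
          de_sgn[[u$cell_type]] * config$expr_effect_log2
      }
    } else {
      x <- x + ct_off[, if ("iPS" %in% cts) "iPS" else cts[1]]
    }
    x <- x + stats::rnorm(n, 0, config$expr_bio_sd)
    sids <- sheet$sample_id[sheet$subject_id == u$subject_id &
                            sheet$clone_id == u$clone_id &
                            sheet$cell_type == u$cell_type]
    for (sid in sids) {
      cols[[sid]] <- 2^(x + stats::rnorm(n, 0, config$expr_noise_sd))
    }
  }
  expr <- do.call(cbind, cols)
  rownames(expr) <- genes
  expr <- expr[, sheet$sample_id, drop = FALSE]
  attr(expr, "normalized") <- FALSE
  list(expression = expr, truth = truth)
}

#' Simulate a scale-free interactome with designated seed genes
#'
#' Preferential-attachment (Barabasi-Albert) graph over a sample of the gene
#' universe, with \code{n_seed_genes} seeds. When \code{seed_enrichment > 0}
#' and a disease gene list is supplied, both the genes placed in the network
#' and the seeds are sampled with weight \code{1 + seed_enrichment} for
#' disease-affected genes, so downstream PPI enrichment is positive by
#' construction; at 0 the network is a null draw.
#'
#' @param config A [sim_config()] object.
#' @param disease_genes Optional character vector of disease-affected gene
#'   symbols to enrich for.
#' @return List: \code{network} (igraph with named vertices), \code{seeds}
#'   (character vector).
#' @export
simulate_interactome <- function(config, disease_genes = NULL) {
  stopifnot(inherits(config, "sim_config"),
            config$interactome_n_genes >= config$interactome_m + 1)
  set.seed(config$seed + 2L)
  universe <- .gene_ids(config$n_probes)
  n_net <- min(config$interactome_n_genes, length(universe))
  w <- rep(1, length(universe))
  if (!is.null(disease_genes) && config$seed_enrichment > 0) {
    w[universe %in% disease_genes] <- 1 + config$seed_enrichment
  }
  members <- sample(universe, n_net, prob = w)
  g <- igraph::sample_pa(n_net, m = config$interactome_m, directed = FALSE)
  igraph::V(g)$name <- members
  ws <- w[match(members, universe)]
  seeds <- sample(members, min(config$n_seed_genes, n_net), prob = ws)
  list(network = g, seeds = seeds)
}

#' Write every synthetic input of a study to a fixture directory
#'
#' Generates methylation, expression, annotation, sample sheet, interactome
#' (+ seed list), a gene-set collection derived from the ground truth plus
#' random sets, and the truth itself as JSON.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
simulate_study_files <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meth <- simulate_methylation_study(config)
  expr <- simulate_expression_study(config, meth)
  net <- simulate_interactome(
    config, disease_genes = unique(unlist(lapply(meth$truth$disease,
                                                 `[[`, "gene_symbol"))))
  set.seed(config$seed + 3L)
  universe <- .gene_ids(config$n_probes)
  sets <- lapply(seq_len(20), function(i) sample(universe, 50))
  names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(20))
  for (ct in config$cell_types) {
    sets[[paste0("PLANTED_DM_", ct)]] <- meth$truth$disease[[ct]]$gene_symbol
  }
  paths <- list(
    beta = file.path(dir, "beta.tsv"),
    expression = file.path(dir, "expression.tsv"),
    sheet = file.path(dir, "samples.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    network = file.path(dir, "interactome.tsv"),
    seeds = file.path(dir, "seeds.txt"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json"))
  write_matrix(meth$beta, paths$beta)
  write_matrix(expr$expression, paths$expression)
  utils::write.table(meth$sheet, paths$sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(meth$annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(net$network, paths$network)
  writeLines(net$seeds, paths$seeds)
  write_gene_sets(sets, paths$gene_sets)
  jsonlite::write_json(list(
    shared_core = meth$truth$shared_core,
    disease = meth$truth$disease,
    celltype_probes = meth$truth$celltype_probes,
    expression = expr$truth), paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
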