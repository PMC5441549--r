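#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Thresholds default to the
#' study's: p < 1e-4 (BH) for cell-type contrasts, p < 0.05 (BH) for
#' patient-control contrasts, 10,000 overlap simulations. In
#' \code{mode = "simulate"} all inputs are generated by the synthetic-data
#' module (per \code{sim}); in \code{mode = "files"} the \code{inputs} list
#' must name existing beta/sheet/annotation/expression/network/seeds/gene_sets
#' files.
#'
#' @param mode \code{"simulate"} or \code{"files"}.
#' @param inputs Named list of input file paths (mode "files").
#' @param sim A [sim_config()] or list of overrides for one (mode "simulate").
#' @param alpha_celltype FDR level for cell-type contrasts.
#' @param alpha_disease FDR level for patient-control contrasts.
#' @param epsilon Beta clipping bound for the M transform.
#' @param k_sd Robust-SD multiplier for PCA outlier flagging.
#' @param remove_outliers Drop flagged samples before differential analysis.
#' @param n_sims Monte-Carlo simulations for the overlap test.
#' @param ppi_n_convention Denominator binding for the PPI Z-test.
#' @param replicate_policy Technical-replicate policy.
#' @param seed Master seed for every stochastic stage.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            inputs = list(),
                            sim = list(),
                            alpha_celltype = 1e-4,
                            alpha_disease = 0.05,
                            epsilon = 1e-3,
                            k_sd = 4,
                            remove_outliers = FALSE,
                            n_sims = 10000,
                            ppi_n_convention = "universe",
                            replicate_policy = "average",
                            seed = 1) {
  mode <- match.arg(mode)
  stopifnot(alpha_celltype > 0, alpha_celltype < 1,
            alpha_disease >= 0, alpha_disease < 1,
            n_sims >= 1)
  if (mode == "simulate" && !inherits(sim, "sim_config")) {
    sim <- do.call(sim_config, utils::modifyList(list(seed = seed), sim))
  }
  structure(list(mode = mode, inputs = inputs, sim = sim,
                 alpha_celltype = alpha_celltype,
                 alpha_disease = alpha_disease,
                 epsilon = epsilon, k_sd = k_sd,
                 remove_outliers = remove_outliers,
                 n_sims = n_sims,
                 ppi_n_convention = ppi_n_convention,
                 replicate_policy = replicate_policy,
                 seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; \code{sim:} may hold [sim_config()] overrides and
#' \code{inputs:} input paths.
#'
#' @param path Path to the YAML file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

.PIPELINE_STAGES <- c("inputs", "qc", "differential", "overlap",
                      "enrichment", "concordance", "ppi")

#' Run the full pipeline
#'
#' Executes the stages in order: inputs (simulate or link user files) -> QC
#' (replicate correlation, PCA, outlier flagging) -> differential methylation
#' and expression per cell type -> cross-cell-type overlap test -> gene-set
#' over-representation -> methylation-expression concordance network and
#' hierarchical clustering -> seed-PPI enrichment Z-test. Every table is
#' written under \code{out_dir}; a manifest records package version, seed,
#' config hash and completed stages. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config A \code{pipeline_config} (or path to a YAML config).
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  completed <- character()
  for (stage in .PIPELINE_STAGES) {
    tryCatch(run_stage(stage, config, out_dir),
             error = function(e) {
               stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                    call. = FALSE)
             })
    completed <- c(completed, stage)
  }
  manifest <- list(
    package = "epicross",
    version = as.character(utils::packageVersion("epicross")),
    seed = config$seed,
    config_hash = .config_hash(config),
    stages = completed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(rapply(config, unclass, how = "replace")), tmp)
  unname(tools::md5sum(tmp))
}

.require_files <- function(paths) {
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing) > 0) {
    stop(sprintf("missing prerequisite file(s): %s",
                 paste(unlist(missing), collapse = ", ")), call. = FALSE)
  }
}

.input_paths <- function(out_dir) {
  d <- file.path(out_dir, "inputs")
  list(beta = file.path(d, "beta.tsv"),
       expression = file.path(d, "expression.tsv"),
       sheet = file.path(d, "samples.tsv"),
       annotation = file.path(d, "annotation.tsv"),
       network = file.path(d, "interactome.tsv"),
       seeds = file.path(d, "seeds.txt"),
       gene_sets = file.path(d, "gene_sets.gmt"))
}

# load the shared inputs a downstream stage needs
.load_inputs <- function(config, out_dir) {
  paths <- .input_paths(out_dir)
  .require_files(paths[c("beta", "sheet", "annotation")])
  beta <- suppressMessages(read_beta_matrix(paths$beta))
  sheet <- read_sample_sheet(paths$sheet)
  ann <- read_probe_annotation(paths$annotation)
  list(paths = paths, beta = beta, sheet = sheet, annotation = ann)
}

.analysis_cell_types <- function(sheet) {
  cts <- setdiff(unique(sheet$cell_type), "ES")
  cts[vapply(cts, function(ct) {
    sub <- sheet[sheet$cell_type == ct, ]
    length(unique(sub$subject_id[sub$status == "patient"])) >= 2 &&
      length(unique(sub$subject_id[sub$status == "control"])) >= 2
  }, logical(1))]
}

.dropped_samples <- function(config, out_dir) {
  f <- file.path(out_dir, "qc", "outliers.txt")
  if (config$remove_outliers && file.exists(f)) readLines(f) else character()
}

#' Run a single pipeline stage
#'
#' Stages depend only on files written by earlier stages under
#' \code{out_dir}, so any stage can be rerun in isolation; a missing
#' prerequisite is reported by file name.
#'
#' @param name One of \code{"inputs"}, \code{"qc"}, \code{"differential"},
#'   \code{"overlap"}, \code{"enrichment"}, \code{"concordance"},
#'   \code{"ppi"}.
#' @param config A \code{pipeline_config}.
#' @param out_dir Pipeline output directory.
#' @return Invisibly NULL; outputs are files.
#' @export
run_stage <- function(name, config, out_dir) {
  name <- match.arg(name, .PIPELINE_STAGES)
  switch(name,
         inputs = .stage_inputs(config, out_dir),
         qc = .stage_qc(config, out_dir),
         differential = .stage_differential(config, out_dir),
         overlap = .stage_overlap(config, out_dir),
         enrichment = .stage_enrichment(config, out_dir),
         concordance = .stage_concordance(config, out_dir),
         ppi = .stage_ppi(config, out_dir))
  invisible(NULL)
}

.stage_inputs <- function(config, out_dir) {
  d <- file.path(out_dir, "inputs")
  if (config$mode == "simulate") {
    simulate_study_files(config$sim, d)
  } else {
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    need <- c("beta", "sheet", "annotation")
    missing <- setdiff(need, names(config$inputs))
    if (length(missing) > 0) {
      stop(sprintf("mode 'files' config lacks input path(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    .require_files(config$inputs)
    tgt <- .input_paths(out_dir)
    for (k in names(config$inputs)) file.copy(config$inputs[[k]], tgt[[k]],
                                              overwrite = TRUE)
  }
}

.stage_qc <- function(config, out_dir) {
  inp <- .load_inputs(config, out_dir)
  d <- file.path(out_dir, "qc")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  m <- beta_to_m(inp$beta, epsilon = config$epsilon)
  rc <- suppressWarnings(replicate_correlation(m, inp$sheet))
  write_results_table(rc$pairs, file.path(d, "replicate_r2.tsv"))
  pc <- pca_scores(m, n_components = min(4, ncol(m) - 1, nrow(m)))
  scores <- data.frame(sample_id = rownames(pc$scores), pc$scores,
                       stringsAsFactors = FALSE)
  write_results_table(scores, file.path(d, "pca_scores.tsv"))
  # outliers are judged within cell type: the leading global components
  # carry the cell-type separation, not aberrant single arrays
  flags <- character()
  for (ct in unique(inp$sheet$cell_type)) {
    ids <- inp$sheet$sample_id[inp$sheet$cell_type == ct]
    if (length(ids) < 4) next
    pct <- pca_scores(m[, ids, drop = FALSE], n_components = 2)
    flags <- c(flags,
               suppressWarnings(flag_outlier_samples(pct$scores,
                                                     k_sd = config$k_sd)))
  }
  writeLines(sort(flags), file.path(d, "outliers.txt"))
}

.stage_differential <- function(config, out_dir) {
  inp <- .load_inputs(config, out_dir)
  d <- file.path(out_dir, "differential")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  drop <- .dropped_samples(config, out_dir)
  sheet <- inp$sheet[!inp$sheet$sample_id %in% drop, , drop = FALSE]
  m <- beta_to_m(inp$beta[, sheet$sample_id, drop = FALSE],
                 epsilon = config$epsilon)
  has_expr <- file.exists(inp$paths$expression)
  if (has_expr) {
    raw <- suppressMessages(read_expression_matrix(inp$paths$expression))
    expr <- normalize_expression(raw[, sheet$sample_id, drop = FALSE])
  }
  for (ct in .analysis_cell_types(sheet)) {
    sub <- sheet[sheet$cell_type == ct, , drop = FALSE]
    dm <- run_differential(m[, sub$sample_id, drop = FALSE], sub,
                           annotation = inp$annotation,
                           direction_labels = c("hyper", "hypo"))
    write_results_table(dm, file.path(d, sprintf("dm_%s.tsv", ct)))
    calls <- call_differential(dm, config$alpha_disease)
    write_results_table(calls$probes, file.path(d, sprintf("dm_%s_called.tsv", ct)))
    if (has_expr) {
      de <- run_differential(expr[, sub$sample_id, drop = FALSE], sub,
                             annotation = NULL,
                             direction_labels = c("up", "down"))
      names(de)[names(de) == "probe_id"] <- "gene_symbol_probe"
      de$gene_symbol <- de$gene_symbol_probe
      write_results_table(de, file.path(d, sprintf("de_%s.tsv", ct)))
      de_calls <- call_differential(de, config$alpha_disease)
      write_results_table(de_calls$probes,
                          file.path(d, sprintf("de_%s_called.tsv", ct)))
    }
  }
}

.read_called <- function(out_dir, prefix) {
  d <- file.path(out_dir, "differential")
  files <- list.files(d, pattern = sprintf("^%s_.*_called\\.tsv$", prefix),
                      full.names = TRUE)
  if (length(files) == 0) {
    stop(sprintf("missing prerequisite file(s): %s",
                 file.path(d, sprintf("%s_<celltype>_called.tsv", prefix))),
         call. = FALSE)
  }
  names(files) <- sub(sprintf("^%s_(.*)_called\\.tsv$", prefix), "\\1",
                      basename(files))
  lapply(files, utils::read.delim, stringsAsFactors = FALSE)
}

.stage_overlap <- function(config, out_dir) {
  inp <- .load_inputs(config, out_dir)
  called <- .read_called(out_dir, "dm")
  d <- file.path(out_dir, "overlap")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  lists <- lapply(called, function(x) {
    stats::setNames(x$direction, x$probe_id)
  })
  sizes <- vapply(called, nrow, integer(1))
  if (length(lists) >= 2 && all(sizes > 0)) {
    inter <- intersect_directional(lists)
    observed <- length(inter$shared)
    res <- overlap_permutation_test(sizes, pool_size = nrow(inp$beta),
                                    observed = observed,
                                    n_sims = config$n_sims,
                                    seed = config$seed)
    shared <- data.frame(probe_id = names(inter$shared),
                         direction = unname(inter$shared),
                         stringsAsFactors = FALSE)
  } else {
    observed <- 0
    res <- list(observed = 0, list_sizes = sizes, pool_size = nrow(inp$beta),
                n_sims = config$n_sims, seed = config$seed,
                null_counts = table(integer()), p_empirical = 1,
                p_poisson = list(p = 1, lambda = 0))
    shared <- data.frame(probe_id = character(), direction = character())
  }
  write_results_table(shared, file.path(d, "shared_loci.tsv"))
  hist_df <- data.frame(overlap = as.integer(names(res$null_counts)),
                        count = as.integer(res$null_counts))
  write_results_table(hist_df, file.path(d, "null_histogram.tsv"))
  jsonlite::write_json(list(observed = res$observed,
                            list_sizes = as.list(res$list_sizes),
                            pool_size = res$pool_size,
                            n_sims = res$n_sims,
                            p_empirical = res$p_empirical,
                            p_poisson = res$p_poisson$p,
                            lambda_poisson = res$p_poisson$lambda),
                       file.path(d, "overlap.json"),
                       auto_unbox = TRUE, digits = NA)
}

.stage_enrichment <- function(config, out_dir) {
  inp <- .load_inputs(config, out_dir)
  .require_files(list(inp$paths$gene_sets))
  sets <- suppressMessages(read_gene_sets(inp$paths$gene_sets))
  universe <- unique(unlist(strsplit(inp$annotation$gene_symbol, ";", fixed = TRUE)))
  called <- .read_called(out_dir, "dm")
  d <- file.path(out_dir, "enrichment")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  for (ct in names(called)) {
    genes <- unique(called[[ct]]$gene_symbol)
    if (length(genes) == 0) next
    ora <- fisher_ora(genes, sets, universe)
    write_results_table(ora, file.path(d, sprintf("ora_dm_%s.tsv", ct)))
  }
}

.stage_concordance <- function(config, out_dir) {
  inp <- .load_inputs(config, out_dir)
  d <- file.path(out_dir, "concordance")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  dm_called <- .read_called(out_dir, "dm")

  # hierarchical clustering of the union of called probes (samples in columns)
  union_probes <- unique(unlist(lapply(dm_called, `[[`, "probe_id")))
  m <- beta_to_m(inp$beta, epsilon = config$epsilon)
  if (length(union_probes) >= 2) {
    sig <- m[rownames(m) %in% union_probes, , drop = FALSE]
    cl <- suppressWarnings(hierarchical_cluster(sig, k_columns = 3))
    memb <- data.frame(sample_id = names(cl$col_clusters),
                       cluster = unname(cl$col_clusters),
                       stringsAsFactors = FALSE)
    write_results_table(memb, file.path(d, "column_clusters.tsv"))
    write_clustered_matrix(sig, cl, file.path(d, "clustered_matrix.tsv"))
  }

  if (!file.exists(inp$paths$network)) return(invisible(NULL))
  net <- suppressWarnings(read_network(inp$paths$network))
  de_called <- tryCatch(.read_called(out_dir, "de"), error = function(e) NULL)
  if (is.null(de_called)) return(invisible(NULL))
  for (ct in intersect(names(dm_called), names(de_called))) {
    dm <- dm_called[[ct]][, c("gene_symbol", "direction", "effect")]
    de <- de_called[[ct]][, c("gene_symbol", "direction", "effect")]
    if (nrow(dm) == 0 || nrow(de) == 0) next
    cn <- build_concordance_network(de, dm, net)
    write_results_table(cn$edges, file.path(d, sprintf("edges_%s.tsv", ct)))
    write_results_table(cn$nodes, file.path(d, sprintf("nodes_%s.tsv", ct)))
    ds <- degree_stats(cn)
    jsonlite::write_json(list(n_nodes = ds$n_nodes, n_edges = ds$n_edges,
                              min_degree = ds$min, max_degree = ds$max,
                              edges_per_node = ds$edges_per_node,
                              mean_degree = ds$mean_degree),
                         file.path(d, sprintf("degree_%s.json", ct)),
                         auto_unbox = TRUE, digits = NA)
  }
}

.stage_ppi <- function(config, out_dir) {
  inp <- .load_inputs(config, out_dir)
  .require_files(list(inp$paths$network, inp$paths$seeds))
  net <- suppressWarnings(read_network(inp$paths$network))
  seeds <- readLines(inp$paths$seeds)
  seed_net <- suppressMessages(build_seed_network(seeds, net))
  universe <- unique(unlist(strsplit(inp$annotation$gene_symbol, ";", fixed = TRUE)))
  d <- file.path(out_dir, "ppi")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  write_network(seed_net, file.path(d, "seed_network.tsv"))
  rows <- list()
  for (prefix in c("dm", "de")) {
    called <- tryCatch(.read_called(out_dir, prefix), error = function(e) NULL)
    if (is.null(called)) next
    for (ct in names(called)) {
      genes <- unique(called[[ct]]$gene_symbol)
      if (length(genes) == 0) next
      res <- ppi_enrichment_ztest(genes, seed_net, length(universe),
                                  n_convention = config$ppi_n_convention)
      rows[[paste(prefix, ct)]] <- data.frame(
        assay = prefix, cell_type = ct, O = res$O, E = res$E, N = res$N,
        p = res$p, Z = res$Z, P_one_tailed = res$P_one_tailed,
        significant = res$significant, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) > 0) {
    write_results_table(do.call(rbind, c(rows, make.row.names = FALSE)),
                        file.path(d, "ppi_enrichment.tsv"))
  }
}
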