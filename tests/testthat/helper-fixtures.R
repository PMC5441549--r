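# Shared fixture builders for the test suite. Everything is generated in
# code; sizes are kept small so the default run stays fast.

# a reduced study configuration exercising every structural feature
small_sim_config <- function(seed = 11, ...) {
  defaults <- list(
    n_probes = 800,
    celltype_n = 200,
    disease_n = c(iPS = 60, ONS = 80, fibroblast = 70),
    shared_core_size = 5,
    interactome_n_genes = 300,
    n_seed_genes = 30,
    seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# minimal valid sample sheet: n_subj subjects per group, one cell type,
# n_reps technical replicates each
toy_sheet <- function(n_subj = 2, n_reps = 2, cell_type = "iPS") {
  rows <- list()
  for (status in c("patient", "control")) {
    for (j in seq_len(n_subj)) {
      subj <- sprintf("%s%d", toupper(substr(status, 1, 2)), j)
      for (r in seq_len(n_reps)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_%s_P%d", subj, cell_type, r),
          subject_id = subj, cell_type = cell_type, status = status,
          passage = r, clone_id = "c1", replicate_role = "technical",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# write a probe x sample matrix as the package's TSV dialect and return path
write_tmp_matrix <- function(mat) {
  f <- tempfile(fileext = ".tsv")
  write_matrix(mat, f)
  f
}

write_tmp_lines <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
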