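#' Read a probe x sample beta-value matrix
#'
#' Reads a GenomeStudio-style export: a delimited text file whose first column
#' holds probe identifiers and whose header row holds sample identifiers.
#' Beta values are methylation fractions, methylated intensity divided by the
#' sum of methylated and unmethylated intensity, so every non-missing value
#' must lie in \[0, 1\]. Missing values are encoded as \code{NA} and kept
#' missing (never coerced to 0).
#'
#' @param path Path to the matrix file.
#' @param delimiter Field delimiter; tab by default, use \code{","} for CSV.
#' @return Numeric matrix (probes x samples) with probe ids as row names and
#'   sample ids as column names.
#' @export
read_beta_matrix <- function(path, delimiter = "\t") {
  mat <- .read_matrix(path, delimiter)
  bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]],
      mat[bad[1, 1], bad[1, 2]]
    ), call. = FALSE)
  }
  message(sprintf("read beta matrix: %d probes x %d samples", nrow(mat), ncol(mat)))
  mat
}

#' Read a probe x sample expression fluorescence matrix
#'
#' Same dialect as [read_beta_matrix()] but values are non-negative raw
#' fluorescence intensities (or any reals once normalized upstream).
#'
#' @inheritParams read_beta_matrix
#' @param raw If \code{TRUE} (default) values are validated as non-negative
#'   raw intensities and the returned matrix is flagged unnormalized.
#' @return Numeric matrix with attribute \code{normalized} (logical).
#' @export
read_expression_matrix <- function(path, delimiter = "\t", raw = TRUE) {
  mat <- .read_matrix(path, delimiter)
  if (raw) {
    bad <- which(!is.na(mat) & mat < 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "negative raw fluorescence at probe '%s', sample '%s'",
        rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]
      ), call. = FALSE)
    }
  }
  message(sprintf("read expression matrix: %d probes x %d samples", nrow(mat), ncol(mat)))
  attr(mat, "normalized") <- !raw
  mat
}

.read_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  if (ncol(dt) < 2) stop("matrix file needs a probe id column plus >=1 sample column", call. = FALSE)
  ids <- as.character(dt[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate probe_id in '%s': %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric values in matrix body", call. = FALSE)
  rownames(mat) <- ids
  mat
}

.CELL_TYPES <- c("iPS", "ONS", "fibroblast", "ES")
.STATUSES <- c("patient", "control")

#' Read and validate a sample sheet
#'
#' The sample sheet carries the study design: one row per array, with the
#' subject it came from, the cell type (iPS, ONS, fibroblast or the ES
#' comparator line), disease status, culture passage and clone. Consecutive
#' passages of the same line are technical replicates; distinct iPS clones of
#' one subject are biological replicates.
#'
#' @param path Path to a tab-separated file with columns \code{sample_id},
#'   \code{subject_id}, \code{cell_type}, \code{status} and optionally
#'   \code{passage}, \code{clone_id}, \code{replicate_role}.
#' @return A data.frame with validated columns; \code{passage} integer (NA
#'   allowed), \code{clone_id} character (NA allowed), \code{replicate_role}
#'   one of \code{"technical"}/\code{"biological"}.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (nrow(df) == 0) stop("no samples in sample sheet", call. = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample-sheet data.frame
#'
#' @param df A data.frame with the columns documented in [read_sample_sheet()].
#' @return The validated (and type-normalized) data.frame, invisibly usable
#'   anywhere a sample sheet is expected.
#' @export
validate_sample_sheet <- function(df) {
  required <- c("sample_id", "subject_id", "cell_type", "status")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("sample sheet missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate sample_id: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  bad_ct <- setdiff(unique(df$cell_type), .CELL_TYPES)
  if (length(bad_ct) > 0) {
    stop(sprintf("unknown cell_type '%s' (expected one of %s)",
                 bad_ct[1], paste(.CELL_TYPES, collapse = ", ")), call. = FALSE)
  }
  bad_st <- setdiff(unique(df$status), .STATUSES)
  if (length(bad_st) > 0) {
    stop(sprintf("unknown status '%s' (expected one of %s)",
                 bad_st[1], paste(.STATUSES, collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(df$cell_type)) || any(is.na(df$status))) {
    stop("every sample needs a cell_type and a status", call. = FALSE)
  }
  if (!"passage" %in% names(df)) df$passage <- NA_integer_
  df$passage <- as.integer(df$passage)
  if (any(!is.na(df$passage) & df$passage < 0)) stop("negative passage number", call. = FALSE)
  if (!"clone_id" %in% names(df)) df$clone_id <- NA_character_
  df$clone_id <- as.character(df$clone_id)
  if (!"replicate_role" %in% names(df)) df$replicate_role <- "technical"
  bad_rr <- setdiff(unique(df$replicate_role), c("technical", "biological"))
  if (length(bad_rr) > 0) {
    stop(sprintf("unknown replicate_role '%s'", bad_rr[1]), call. = FALSE)
  }
  df
}

#' Read a probe-to-gene annotation table
#'
#' Two columns: \code{probe_id} and \code{gene_symbol}. A probe may map to
#' several symbols separated by \code{;} (kept as given; symbol matching is
#' case-insensitive throughout the package).
#'
#' @param path Path to a tab-separated annotation file.
#' @return data.frame with unique \code{probe_id} and \code{gene_symbol}.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(df))) {
    stop("annotation needs columns probe_id, gene_symbol", call. = FALSE)
  }
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate probe_id in annotation: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name}, \code{description}, then members. Duplicate members within a
#' line are dropped with a warning; empty sets and duplicate names are errors.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file", call. = FALSE)
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                   i, length(fields)), call. = FALSE)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d ('%s'): duplicate members removed", i, fields[1]),
              call. = FALSE)
      members <- unique(members)
    }
    if (length(members) == 0) stop(sprintf("GMT line %d: empty set", i), call. = FALSE)
    nm[i] <- fields[1]
    sets[[i]] <- members
  }
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate set name: %s", nm[duplicated(nm)][1]), call. = FALSE)
  }
  names(sets) <- nm
  message(sprintf("read %d gene sets (sizes %d-%d)",
                  length(sets), min(lengths(sets)), max(lengths(sets))))
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(n) {
    paste(c(n, "na", sets[[n]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction network from a two-column edge list
#'
#' Whitespace- or tab-delimited node pairs, one edge per line; a third column
#' (interaction type) is tolerated and ignored. The result is an undirected
#' simple graph: duplicate edges are merged and self-loops dropped with a
#' warning.
#'
#' @param path Path to the edge-list file.
#' @return An undirected [igraph::igraph] object.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty network file", call. = FALSE)
  parts <- strsplit(trimws(lines), "[ \t]+")
  short <- which(lengths(parts) < 2)
  if (length(short) > 0) {
    stop(sprintf("network line %d has fewer than 2 columns", short[1]), call. = FALSE)
  }
  el <- cbind(vapply(parts, `[[`, character(1), 1L),
              vapply(parts, `[[`, character(1), 2L))
  loops <- el[, 1] == el[, 2]
  if (any(loops)) {
    warning(sprintf("%d self-loop(s) dropped", sum(loops)), call. = FALSE)
    el <- el[!loops, , drop = FALSE]
  }
  if (nrow(el) == 0) stop("network has no non-loop edges", call. = FALSE)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write an interaction network as a two-column edge list
#'
#' @param network An igraph object.
#' @param path Output path.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Tab-separated with header, columns in the order given, floating-point
#' columns formatted at a fixed significant-digit precision so that rewrites
#' of the same table are byte-identical.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @param digits Significant digits for numeric (non-integer) columns.
#' @export
write_results_table <- function(records, path, digits = 10) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         formatC(out[[j]], digits = digits, format = "g"))
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a probe x sample matrix in the package's TSV dialect
#'
#' First column \code{probe_id}, then one column per sample; \code{NA} for
#' missing values. Full double precision so a write/read round trip is exact.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  body <- data.table::as.data.table(mat)
  # 17 significant digits round-trip an IEEE double exactly
  for (j in names(body)) {
    v <- body[[j]]
    data.table::set(body, j = j,
                    value = ifelse(is.na(v), NA_character_, sprintf("%.17g", v)))
  }
  out <- cbind(data.table::data.table(probe_id = rownames(mat)), body)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
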