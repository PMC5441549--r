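#' Build a directional methylation-expression concordance network
#'
#' Restricts an interactome to the genes that are differentially methylated
#' (DM) and/or differentially expressed (DE), then filters edges by a
#' direction-concordance rule: an edge joining a DM-only gene to a DE-only
#' gene is kept only when it is consistent with activation (hypomethylation
#' with up-regulated expression) or inhibition (hypermethylation with
#' down-regulated expression). Edges between two genes differential in the
#' same assay, or involving a gene differential in both, are kept on the
#' both-differential-and-adjacent rule. Every adjacent differential pair is
#' classified; rejected edges carry a reason.
#'
#' @param de data.frame of differentially expressed genes: columns
#'   \code{gene_symbol}, \code{direction} (\code{"up"}/\code{"down"}),
#'   \code{effect}.
#' @param dm data.frame of differentially methylated genes: columns
#'   \code{gene_symbol}, \code{direction} (\code{"hyper"}/\code{"hypo"}),
#'   \code{effect}.
#' @param interactome Undirected igraph with named vertices.
#' @return List of class \code{concordance_network}: \code{nodes} (gene,
#'   source DM/DE/both, direction(s), magnitude = |effect|), \code{edges}
#'   (from, to, status kept/rejected, reason), \code{graph} (igraph of kept
#'   edges plus isolated differential genes present in the interactome).
#' @export
build_concordance_network <- function(de, dm, interactome) {
  if (igraph::ecount(interactome) == 0 && igraph::vcount(interactome) == 0) {
    stop("empty interactome", call. = FALSE)
  }
  de_dir <- stats::setNames(as.character(de$direction), toupper(de$gene_symbol))
  dm_dir <- stats::setNames(as.character(dm$direction), toupper(dm$gene_symbol))
  de_mag <- stats::setNames(abs(de$effect), toupper(de$gene_symbol))
  dm_mag <- stats::setNames(abs(dm$effect), toupper(dm$gene_symbol))
  diff_genes <- union(names(de_dir), names(dm_dir))

  vn <- igraph::V(interactome)$name
  present <- vn[toupper(vn) %in% diff_genes]
  sub <- igraph::induced_subgraph(interactome, present)
  el <- igraph::as_edgelist(sub)

  src <- function(g) {
    in_de <- g %in% names(de_dir); in_dm <- g %in% names(dm_dir)
    if (in_de && in_dm) "both" else if (in_de) "DE" else "DM"
  }
  concordant <- function(meth_dir, expr_dir) {
    (meth_dir == "hypo" && expr_dir == "up") ||
      (meth_dir == "hyper" && expr_dir == "down")
  }

  status <- character(nrow(el)); reason <- character(nrow(el))
  for (i in seq_len(nrow(el))) {
    a <- toupper(el[i, 1]); b <- toupper(el[i, 2])
    sa <- src(a); sb <- src(b)
    if (sa == "DM" && sb == "DE") {
      ok <- concordant(dm_dir[[a]], de_dir[[b]])
    } else if (sa == "DE" && sb == "DM") {
      ok <- concordant(dm_dir[[b]], de_dir[[a]])
    } else {
      ok <- TRUE   # DE-DE, DM-DM, or a 'both' endpoint: both differential and adjacent
    }
    status[i] <- if (ok) "kept" else "rejected"
    reason[i] <- if (ok) "" else "discordant"
  }
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      status = status, reason = reason,
                      stringsAsFactors = FALSE)

  nodes <- data.frame(
    gene = present,
    source = vapply(toupper(present), src, character(1)),
    meth_direction = unname(dm_dir[toupper(present)]),
    expr_direction = unname(de_dir[toupper(present)]),
    magnitude = pmax(dm_mag[toupper(present)], de_mag[toupper(present)], na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)

  kept <- edges[edges$status == "kept", c("from", "to"), drop = FALSE]
  g <- igraph::graph_from_data_frame(kept, directed = FALSE,
                                     vertices = data.frame(name = present))
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "concordance_network")
}

#' Node-degree statistics of a network
#'
#' Reports per-node incident-edge counts plus two distinct summaries: the
#' edges-per-node ratio E/V and the mean degree 2E/V (for a simple graph the
#' mean degree is twice the edge/node ratio; both are reported because the
#' field's figure legends sometimes quote the former).
#'
#' @param network igraph object or \code{concordance_network}.
#' @return List: \code{per_node} (data.frame gene, degree), \code{n_nodes},
#'   \code{n_edges}, \code{min}, \code{max}, \code{edges_per_node},
#'   \code{mean_degree}.
#' @export
degree_stats <- function(network) {
  g <- if (inherits(network, "concordance_network")) network$graph else network
  if (igraph::vcount(g) == 0) stop("network has no nodes", call. = FALSE)
  deg <- igraph::degree(g)
  list(per_node = data.frame(gene = names(deg), degree = unname(deg),
                             row.names = NULL, stringsAsFactors = FALSE),
       n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       min = min(deg), max = max(deg),
       edges_per_node = igraph::ecount(g) / igraph::vcount(g),
       mean_degree = 2 * igraph::ecount(g) / igraph::vcount(g))
}

# Uncentered-correlation distance between columns (Cluster 3.0 convention):
# d(x, y) = 1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2)).
# A zero-norm (constant-zero) column has distance 1 to everything, with warning.
.uncentered_cor_dist <- function(mat) {
  norms <- sqrt(colSums(mat^2))
  if (any(norms == 0)) {
    warning("zero-norm column(s); distance to them defined as 1", call. = FALSE)
  }
  cp <- crossprod(mat)
  denom <- outer(norms, norms)
  r <- ifelse(denom > 0, cp / denom, 0)
  d <- 1 - r
  diag(d) <- 0
  stats::as.dist(d)
}

#' Hierarchical clustering of a significant-probe matrix
#'
#' Agglomerative clustering with average linkage on an uncentered-correlation
#' distance for both columns (samples) and, optionally, rows (probes) --- the
#' convention of the Cluster 3.0 / Java TreeView toolchain. Leaf order is
#' deterministic given the input order. Cutting the column tree at
#' \code{k_columns} groups yields the sample partition (e.g. three clusters
#' separating three cell types).
#'
#' @param mat Numeric matrix (typically restricted to significant probes).
#' @param k_columns Number of groups for the column-tree cut (default 3).
#' @param cluster_rows Also cluster rows (default TRUE when \code{nrow(mat)}
#'   <= \code{max_rows}, else rows are ordered by decreasing variance).
#' @param max_rows Row-count cap above which row clustering is skipped.
#' @return List: \code{col_tree} (hclust), \code{col_order}, \code{col_clusters}
#'   (named cut membership), \code{row_tree} (hclust or NULL), \code{row_order}.
#' @export
hierarchical_cluster <- function(mat, k_columns = 3, cluster_rows = NULL,
                                 max_rows = 2000) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2) stop("need >=2 columns to cluster", call. = FALSE)
  col_tree <- stats::hclust(.uncentered_cor_dist(mat), method = "average")
  k_columns <- min(k_columns, ncol(mat))
  col_clusters <- stats::cutree(col_tree, k = k_columns)
  names(col_clusters) <- colnames(mat)
  if (is.null(cluster_rows)) cluster_rows <- nrow(mat) <= max_rows
  if (cluster_rows && nrow(mat) >= 2) {
    row_tree <- stats::hclust(.uncentered_cor_dist(t(mat)), method = "average")
    row_order <- row_tree$order
  } else {
    row_tree <- NULL
    row_order <- order(apply(mat, 1, stats::var), decreasing = TRUE)
  }
  list(col_tree = col_tree, col_order = col_tree$order,
       col_clusters = col_clusters, row_tree = row_tree, row_order = row_order)
}

#' Export a clustered matrix in CDT-like layout
#'
#' Writes the matrix reordered by the clustering result as TSV (first column
#' probe_id), usable by tree-viewer tools.
#'
#' @param mat Matrix that was clustered.
#' @param clust Result of [hierarchical_cluster()].
#' @param path Output path.
#' @export
write_clustered_matrix <- function(mat, clust, path) {
  ordered <- mat[clust$row_order, clust$col_order, drop = FALSE]
  write_matrix(ordered, path)
}
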