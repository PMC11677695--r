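rel_table_matrix <- function(table) {
  need <- c("gene", "tissue", "log2_fc")
  if (!all(need %in% names(table))) {
    abort_fmt("expression table needs columns %s.",
              paste(need, collapse = ", "), class = "semarkr_format_error")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(table, "gene", "tissue", "log2_fc"),
    names_from = "tissue", values_from = "log2_fc")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    abort_fmt("missing log2 fold change for: %s",
              paste(sprintf("(%s, %s)", rownames(m)[bad[, 1]],
                            colnames(m)[bad[, 2]]), collapse = ", "),
              class = "semarkr_validation_error")
  }
  m
}

new_linkage_tree <- function(hc, metric, method) {
  structure(list(hclust = hc, leaves = hc$labels, merges = hc$merge,
                 heights = hc$height, metric = metric, method = method),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d leaves, %s linkage on %s distance\n",
              length(x$leaves), x$method, x$metric))
  invisible(x)
}

#' @export
as.hclust.linkage_tree <- function(x, ...) x$hclust

#' Hierarchical clustering of tissues
#'
#' Clusters tissue samples by their gene expression profiles (log2 fold
#' changes versus the calibrator): pairwise Euclidean distances, Ward
#' agglomeration (`hclust` method `ward.D2`, the Lance-Williams update on
#' squared Euclidean distances with merge heights reported on the distance
#' scale).
#'
#' @param table a relative-expression tibble with columns `gene`, `tissue`,
#'   `log2_fc` (e.g. from [relative_expression_table()]); every tissue must
#'   have a complete gene profile.
#' @return a `linkage_tree` (wraps the `hclust` object; see
#'   [as.hclust()]).
#' @export
tissue_clustering <- function(table) {
  m <- t(rel_table_matrix(table)) # tissues x genes
  if (nrow(m) < 2) {
    abort_fmt("need >= 2 tissues to cluster (got %d).", nrow(m),
              class = "semarkr_validation_error")
  }
  m <- m[order(rownames(m)), , drop = FALSE] # label-order invariance
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2")
  new_linkage_tree(hc, "euclidean", "ward")
}

#' Hierarchical clustering of genes
#'
#' Clusters genes by the similarity of their expression profiles across
#' tissues: distance is 1 - Pearson correlation, agglomeration is complete
#' linkage (the furthest-neighbour criterion). Gene profiles with zero
#' variance have no defined correlation and are an error.
#'
#' @inheritParams tissue_clustering
#' @return a `linkage_tree`.
#' @export
gene_clustering <- function(table) {
  m <- rel_table_matrix(table) # genes x tissues
  if (nrow(m) < 2) {
    abort_fmt("need >= 2 genes to cluster (got %d).", nrow(m),
              class = "semarkr_validation_error")
  }
  vars <- apply(m, 1, stats::var)
  if (any(vars == 0)) {
    abort_fmt("zero-variance gene profile(s): %s",
              paste(rownames(m)[vars == 0], collapse = ", "),
              class = "semarkr_validation_error")
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(m), method = "pearson"))
  hc <- stats::hclust(d, method = "complete")
  new_linkage_tree(hc, "one_minus_pearson", "complete")
}

#' Cut a linkage tree into k groups
#'
#' @param tree a `linkage_tree`.
#' @param k number of groups.
#' @return named integer vector of group assignments.
#' @export
cut_linkage <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  stats::cutree(tree$hclust, k = k)
}

#' Render the expression heatmap with dendrograms
#'
#' Draws a gene-by-tissue heatmap of log2 fold changes, rows and columns
#' ordered by the given dendrograms, on a diverging palette anchored at 0
#' with red for decreased and blue for increased expression relative to the
#' calibrator (so the all-zero calibrator column sits at the palette
#' midpoint). Alongside the image it writes the plotted matrix as TSV (in
#' dendrogram leaf order) and both dendrograms in Newick format.
#'
#' @param table a relative-expression tibble (`gene`, `tissue`, `log2_fc`).
#' @param tissue_tree a `linkage_tree` over the table's tissues.
#' @param gene_tree a `linkage_tree` over the table's genes.
#' @param out_dir output directory (created if needed).
#' @return named list of written file paths, invisibly.
#' @export
render_heatmap <- function(table, tissue_tree, gene_tree, out_dir) {
  m <- rel_table_matrix(table)
  bad_genes <- c(setdiff(gene_tree$leaves, rownames(m)),
                 setdiff(rownames(m), gene_tree$leaves))
  bad_tissues <- c(setdiff(tissue_tree$leaves, colnames(m)),
                   setdiff(colnames(m), tissue_tree$leaves))
  if (length(bad_genes) || length(bad_tissues)) {
    abort_fmt("tree/table label mismatch; offending gene(s): %s; tissue(s): %s",
              if (length(bad_genes)) paste(bad_genes, collapse = ", ") else "none",
              if (length(bad_tissues)) paste(bad_tissues, collapse = ", ") else "none",
              class = "semarkr_validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  gene_hc <- gene_tree$hclust
  tissue_hc <- tissue_tree$hclust
  lim <- max(abs(m), 1e-9)
  breaks <- seq(-lim, lim, length.out = 101)
  pal <- grDevices::colorRampPalette(c("red", "white", "blue"))(100)

  img <- file.path(out_dir, "heatmap.png")
  pheatmap::pheatmap(
    m,
    cluster_rows = gene_hc, cluster_cols = tissue_hc,
    color = pal, breaks = breaks,
    border_color = NA, filename = img, silent = TRUE)

  ordered <- m[gene_hc$labels[gene_hc$order],
               tissue_hc$labels[tissue_hc$order], drop = FALSE]
  mat_path <- file.path(out_dir, "heatmap_matrix.tsv")
  utils::write.table(
    data.frame(gene = rownames(ordered), ordered, check.names = FALSE),
    mat_path, sep = "\t", quote = FALSE, row.names = FALSE)

  tissue_nwk <- file.path(out_dir, "tissue_dendrogram.nwk")
  gene_nwk <- file.path(out_dir, "gene_dendrogram.nwk")
  ape::write.tree(ape::as.phylo(tissue_hc), tissue_nwk)
  ape::write.tree(ape::as.phylo(gene_hc), gene_nwk)

  invisible(list(image = img, matrix = mat_path,
                 tissue_dendrogram = tissue_nwk, gene_dendrogram = gene_nwk))
}
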