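#' Single-nuclei QC filter
#'
#' Applies the stated single-nuclei quality filters to a cell-level count
#' matrix, in a fixed single pass: (1) mitochondrial genes (symbol prefix)
#' are removed, (2) genes detected (count > 0) in fewer than
#' `min_cells_per_gene` cells are dropped, (3) cells with fewer than
#' `min_genes_per_cell` detected genes are dropped. Before/after dimensions
#' are logged.
#'
#' @param x a [count_matrix()] whose samples are cells.
#' @param min_cells_per_gene minimum number of cells a gene must be detected
#'   in (default 200).
#' @param min_genes_per_cell minimum number of detected genes per cell
#'   (default 333).
#' @param drop_mito remove mitochondrial genes first.
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes
#'   (default lowercase mouse `"mt-"`).
#' @return Filtered [count_matrix()].
#' @export
snqc_filter <- function(x, min_cells_per_gene = 200, min_genes_per_cell = 333,
                        drop_mito = TRUE, mito_prefix = "mt-") {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  n_genes0 <- nrow(m); n_cells0 <- ncol(m)

  if (drop_mito) {
    mito <- startsWith(rownames(m), mito_prefix)
    m <- m[!mito, , drop = FALSE]
    message(sprintf("snqc_filter: removed %d mitochondrial genes", sum(mito)))
  }
  keep_genes <- rowSums(m > 0) >= min_cells_per_gene
  m <- m[keep_genes, , drop = FALSE]
  keep_cells <- colSums(m > 0) >= min_genes_per_cell
  m <- m[, keep_cells, drop = FALSE]
  if (ncol(m) == 0) stop("snqc_filter: all cells removed by QC thresholds")

  message(sprintf("snqc_filter: genes %d -> %d, cells %d -> %d",
                  n_genes0, nrow(m), n_cells0, ncol(m)))
  count_matrix(m, as.character(x$conditions[colnames(m)]))
}
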