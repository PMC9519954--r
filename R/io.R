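#' Read a count matrix from TSV or MatrixMarket files
#'
#' TSV layout: genes as rows, a header row of sample IDs, first column gene
#' IDs. MTX layout: a MatrixMarket file plus sidecar gene and sample name
#' files (one name per line), as written by [write_counts()].
#'
#' @param path counts file (`.tsv`/`.txt` or `.mtx`).
#' @param conditions condition label per sample, or the path of a
#'   two-column TSV (sample, condition); `NULL` labels all samples
#'   `"unknown"`.
#' @param genes_path,samples_path sidecar name files for MTX input; default
#'   `<path>.genes.txt` / `<path>.samples.txt`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, conditions = NULL,
                        genes_path = NULL, samples_path = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.txt")
    if (is.null(samples_path)) samples_path <- paste0(path, ".samples.txt")
    m <- as.matrix(Matrix::readMM(path))
    g <- readLines(genes_path); s <- readLines(samples_path)
    if (nrow(m) != length(g) || ncol(m) != length(s))
      stop("MTX dimensions disagree with sidecar name files")
    dimnames(m) <- list(g, s)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
  }
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative count at gene ", rownames(m)[bad[1, 1]],
         ", sample ", colnames(m)[bad[1, 2]])
  if (any(abs(m - round(m)) > 1e-8)) {
    r <- which(apply(abs(m - round(m)) > 1e-8, 1, any))[1]
    stop("non-integer counts at gene ", rownames(m)[r])
  }
  if (is.character(conditions) && length(conditions) == 1 &&
      file.exists(conditions)) {
    ct <- utils::read.delim(conditions, header = FALSE,
                            col.names = c("sample", "condition"))
    conditions <- ct$condition[match(colnames(m), ct$sample)]
    if (anyNA(conditions)) stop("conditions file misses some samples")
  }
  if (is.null(conditions)) conditions <- rep("unknown", ncol(m))
  count_matrix(m, conditions)
}

#' Write a count matrix to TSV or MatrixMarket files
#'
#' @param x a [count_matrix()].
#' @param path output file; extension picks the format (`.tsv` or `.mtx`,
#'   the latter with `<path>.genes.txt` / `<path>.samples.txt` sidecars).
#' @param conditions_path optional path for a two-column sample/condition
#'   TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, conditions_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(rownames(x$counts), paste0(path, ".genes.txt"))
    writeLines(colnames(x$counts), paste0(path, ".samples.txt"))
  } else {
    df <- data.frame(gene = rownames(x$counts), x$counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(conditions_path))
    utils::write.table(
      data.frame(sample = colnames(x$counts),
                 condition = as.character(x$conditions)),
      conditions_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a DEG table as CSV
#'
#' Column order is fixed (gene, logFC, logCPM, PValue, FDR, extras) and the
#' decimal separator is always '.'.
#'
#' @param tab a [deg_table()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(tab, path) {
  first <- intersect(c("gene", "logFC", "logCPM", "PValue", "FDR"),
                     names(tab))
  tab <- tab[, c(first, setdiff(names(tab), first)), drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
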