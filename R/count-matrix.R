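#' Construct a labeled count matrix
#'
#' The universal expression input of the pipeline: an integer gene-by-sample
#' count matrix with a condition label for every sample. Columns are samples.
#'
#' @param counts integer matrix, genes in rows, samples in columns. Must carry
#'   unique rownames (gene IDs) and colnames (sample IDs).
#' @param conditions character or factor of length `ncol(counts)` assigning
#'   each sample to a condition.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `conditions` (factor named by sample).
#' @examples
#' m <- matrix(rpois(12, 10), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cm <- count_matrix(m, rep(c("A", "B"), each = 2))
#' @export
count_matrix <- function(counts, conditions) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs in counts")
  if (length(conditions) != ncol(counts))
    stop("need one condition label per sample")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integral")
  storage.mode(counts) <- "double"   # keeps >2^31 library sums safe
  # levels in order of appearance: the first condition is the reference
  conditions <- as.character(conditions)
  conditions <- factor(conditions, levels = unique(conditions))
  names(conditions) <- colnames(counts)
  structure(list(counts = counts, conditions = conditions),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$conditions)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix
#'
#' @param x a `count_matrix`.
#' @param genes,samples index vectors (logical, integer or names); missing
#'   means keep all.
#' @return A `count_matrix` restricted to the requested rows/columns.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  count_matrix(m, as.character(x$conditions[colnames(m)]))
}

#' Per-sample library sizes (column sums)
#'
#' @param x a `count_matrix` or a plain matrix.
#' @return Named numeric vector of column sums.
#' @export
library_sizes <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  colSums(m)
}

# Derive a reproducible sub-stream seed from one global seed so that streams
# ("counts", "images", ...) stay independent: adding a stream never perturbs
# another. Kept below 2^31 - 1.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 1009)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}
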