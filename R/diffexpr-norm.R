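#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors between samples, computed against
#' a reference sample from gene-wise log2 ratios of depth-normalized counts:
#' genes zero in either sample are excluded, the 30% most extreme log-ratios
#' (M) and 5% most extreme log-abundances (A) on each side are trimmed, the
#' remaining M values are averaged with inverse asymptotic-variance precision
#' weights, and the resulting factors are rescaled to geometric mean 1.
#'
#' @param x a [count_matrix()] or plain count matrix (genes x samples).
#' @param reference_sample optional sample ID or index to use as the TMM
#'   reference; by default the sample whose upper-quartile expression is
#'   closest to the mean upper quartile.
#' @param logratio_trim,abundance_trim two-sided trim fractions on M and A.
#' @return Object of class `norm_factors`: list with `lib_size` (per-sample
#'   library size) and `factors` (TMM factors, geometric mean 1).
#' @examples
#' m <- matrix(rpois(400, 50), 100,
#'             dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
#' tmm_factors(m)
#' @export
tmm_factors <- function(x, reference_sample = NULL,
                        logratio_trim = 0.30, abundance_trim = 0.05) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(m) < 2) stop("need at least two samples")
  lib <- colSums(m)
  if (any(lib == 0)) stop("sample with all-zero counts: ",
                          paste(colnames(m)[lib == 0], collapse = ", "))

  if (is.null(reference_sample)) {
    expressed <- m[rowSums(m > 0) > 0, , drop = FALSE]
    uq <- apply(expressed, 2, stats::quantile, probs = 0.75) / lib
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- if (is.character(reference_sample))
      match(reference_sample, colnames(m)) else reference_sample
    if (is.na(ref) || ref < 1 || ref > ncol(m)) stop("unknown reference sample")
  }

  f <- vapply(seq_len(ncol(m)), function(k) {
    tmm_pair_factor(m[, k], m[, ref], lib[k], lib[ref],
                    logratio_trim, abundance_trim)
  }, numeric(1))

  f <- f / exp(mean(log(f)))          # geometric mean 1
  structure(list(lib_size = lib, factors = stats::setNames(f, colnames(m))),
            class = "norm_factors")
}

# one sample vs reference; returns 2^(weighted trimmed mean of M)
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, lr_trim, ab_trim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  obs <- obs[keep]; ref <- ref[keep]

  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)

  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)

  n <- length(M)
  loM <- floor(n * lr_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * ab_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM &
          rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Counts per million
#'
#' CPM on effective library sizes (library size times TMM factor). The log2
#' variant adds a prior count scaled by each sample's effective library size
#' relative to the mean, so all-zero genes map to a finite common value.
#'
#' @param x a [count_matrix()] or matrix.
#' @param norm a [tmm_factors()] result; `NULL` uses factors of 1.
#' @param log return log2 CPM.
#' @param prior_count average pseudocount for the log variant.
#' @return Numeric matrix of (log2) CPM values.
#' @export
cpm <- function(x, norm = NULL, log = FALSE, prior_count = 0.5) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  eff <- effective_lib_sizes(m, norm)
  if (!log) return(sweep(m, 2, eff / 1e6, "/"))
  pc <- prior_count * eff / mean(eff)
  log2(sweep(sweep(m, 2, pc, "+"), 2, (eff + 2 * pc) / 1e6, "/"))
}

effective_lib_sizes <- function(m, norm = NULL) {
  if (is.null(norm)) return(colSums(m))
  stopifnot(inherits(norm, "norm_factors"))
  norm$lib_size[colnames(m)] * norm$factors[colnames(m)]
}

#' FPKM from counts and gene lengths
#'
#' Fragments per kilobase of transcript per million mapped reads, computed
#' directly from raw counts: `count / ((length/1000) * (libsize/1e6))` with
#' the library size taken as the raw column sum (no TMM).
#'
#' @param x a [count_matrix()] or matrix.
#' @param lengths named numeric vector or two-column data.frame (gene,
#'   length in bases); must cover every gene in `x`.
#' @return Numeric matrix of FPKM values.
#' @examples
#' m <- matrix(10, 1, 1, dimnames = list("g1", "s1"))
#' m[] <- 10
#' @export
fpkm <- function(x, lengths) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (is.data.frame(lengths))
    lengths <- stats::setNames(as.numeric(lengths[[2]]), lengths[[1]])
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing))
    stop("missing gene lengths for: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  lib <- colSums(m)
  sweep(m / (len / 1000), 2, lib / 1e6, "/")
}
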