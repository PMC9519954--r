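# Equalize sequencing depth by scaling each sample's counts to the geometric
# mean of the effective library sizes. The exact conditional test assumes
# exchangeable samples, which holds after this depth equalization.
pseudo_counts <- function(m, norm = NULL, round = TRUE) {
  eff <- effective_lib_sizes(m, norm)
  target <- exp(mean(log(eff)))
  p <- sweep(m, 2, target / eff, "*")
  if (round) p <- round(p)
  p
}

#' Estimate a common negative-binomial dispersion
#'
#' Single dispersion phi shared across genes, maximizing the summed
#' conditional NB log-likelihood (conditioning on each gene's within-group
#' total) on depth-equalized pseudo-counts. Only conditions with replicates
#' contribute; the estimate is clipped to `[0, 10]`.
#'
#' @param x a [count_matrix()], or a matrix plus `conditions`.
#' @param conditions condition label per sample (ignored for `count_matrix`).
#' @param norm optional [tmm_factors()] result used for depth equalization.
#' @return Estimated dispersion (numeric scalar).
#' @export
estimate_common_dispersion <- function(x, conditions = NULL, norm = NULL) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (inherits(x, "count_matrix")) conditions <- x$conditions
  conditions <- factor(conditions)
  replicated <- names(which(table(conditions) >= 2))
  if (length(replicated) == 0)
    stop("no condition has replicates; supply a dispersion explicitly")

  p <- pseudo_counts(m, norm, round = FALSE)
  groups <- lapply(replicated, function(cn) p[, conditions == cn, drop = FALSE])
  groups <- lapply(groups, function(g) g[rowSums(g) > 0, , drop = FALSE])

  nll <- function(phi) -sum(vapply(groups, cond_loglik_sum, numeric(1), phi = phi))
  opt <- stats::optimize(nll, interval = c(1e-6, 10))
  phi <- opt$minimum
  # flat likelihood toward the Poisson boundary: report the boundary
  if (nll(1e-6) <= opt$objective + 1e-8) phi <- 0
  min(max(phi, 0), 10)
}

# summed conditional log-likelihood of one replicated group at dispersion phi
cond_loglik_sum <- function(g, phi) {
  r <- 1 / max(phi, 1e-10)
  n <- ncol(g)
  z <- rowSums(g)
  sum(rowSums(lgamma(g + r)) - n * lgamma(r) + lgamma(n * r) -
        lgamma(z + n * r) + lgamma(z + 1) - rowSums(lgamma(g + 1)))
}

#' Exact conditional NB test for a two-condition contrast
#'
#' For each gene, conditions on the total depth-equalized pseudo-count and
#' computes the two-sided exact probability that the group-A sum is at most
#' as probable as the one observed, under a negative binomial with common
#' mean and dispersion `dispersion` (binomial split when `dispersion = 0`).
#' Two-sidedness sums all outcomes whose conditional probability does not
#' exceed the observed one (it is not a doubled one-sided tail), capped at 1.
#'
#' Log fold-changes `M` (target over reference) and average abundances `A`
#' are computed from normalized condition means with a prior count of 0.5
#' per group so zeros stay finite.
#'
#' @param x a [count_matrix()] with exactly two conditions.
#' @param norm a [tmm_factors()] result; `NULL` recomputes it.
#' @param dispersion common NB dispersion phi >= 0; `NULL` estimates it with
#'   [estimate_common_dispersion()].
#' @param pair optional character length 2 giving `c(reference, target)`;
#'   defaults to the factor-level order of the conditions.
#' @return A DEG table: data.frame with columns `gene`, `logFC` (M),
#'   `logCPM` (A), `PValue`; see [bh_adjust()] / [deg_table()] for FDR.
#' @export
nb_exact_test <- function(x, norm = NULL, dispersion = NULL, pair = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  lev <- levels(x$conditions)
  if (length(lev) != 2) stop("exact test needs exactly two conditions")
  if (is.null(pair)) pair <- lev
  if (!setequal(pair, lev)) stop("pair must name the two conditions")
  if (is.null(norm)) norm <- tmm_factors(x)
  if (is.null(dispersion)) dispersion <- estimate_common_dispersion(x, norm = norm)
  if (dispersion < 0) stop("dispersion must be non-negative")

  m <- x$counts
  ref <- x$conditions == pair[1]
  tgt <- x$conditions == pair[2]
  n1 <- sum(ref); n2 <- sum(tgt)

  p <- pseudo_counts(m, norm, round = TRUE)
  s1 <- rowSums(p[, ref, drop = FALSE])
  s2 <- rowSums(p[, tgt, drop = FALSE])
  pv <- exact_nb_pvalues(s1, s2, n1, n2, dispersion)

  # M and A from effective-library CPM condition means with prior 0.5
  eff <- effective_lib_sizes(m, norm)
  cpm_m <- sweep(m, 2, eff / 1e6, "/")
  mean1 <- rowMeans(cpm_m[, ref, drop = FALSE])
  mean2 <- rowMeans(cpm_m[, tgt, drop = FALSE])
  prior <- 0.5 / mean(eff) * 1e6
  M <- log2(mean2 + prior) - log2(mean1 + prior)
  A <- 0.5 * (log2(mean2 + prior) + log2(mean1 + prior))

  data.frame(gene = rownames(m), logFC = M, logCPM = A, PValue = pv,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Two-sided exact p-values for group sums s1 (n1 samples) vs s2 (n2 samples)
# conditional on s1 + s2, vectorized across genes. The conditional
# distribution of the group-1 sum is proportional to the product of the two
# group-sum NB densities (binomial split when phi = 0), and its normalizer
# has the closed convolution form dnbinom(t, size = (n1+n2)/phi, mu = t).
# Small totals are enumerated in full. For large totals, the contiguous
# "more probable than observed" region around the mode is located by a
# vectorized binary search (the conditional distribution is unimodal) and
# p = 1 - P(region); when that subtraction would lose precision (p below
# ~1e-12) the two extreme tails are summed directly instead.
exact_nb_pvalues <- function(s1, s2, n1, n2, phi,
                             full_range_max = 2000, sd_mult = 12,
                             chunk_values = 4e6, rel_tie_tol = 1e-10) {
  t <- s1 + s2
  pv <- rep(1, length(t))
  N <- n1 + n2
  pr1 <- n1 / N
  dens <- function(s, tt) {
    # joint density of (s, tt - s) under equal per-sample means tt/N
    if (phi == 0) {
      stats::dbinom(s, tt, pr1)   # already the conditional law
    } else {
      mu0 <- tt / N
      stats::dnbinom(s, size = n1 / phi, mu = n1 * mu0) *
        stats::dnbinom(tt - s, size = n2 / phi, mu = n2 * mu0)
    }
  }
  # sum over gene index of dens evaluated on ragged ranges lo..hi, chunked;
  # with thr also accumulates the sum restricted to d <= thr
  ragged_sum <- function(gidx, lo, hi, tt, thr = NULL, n_out) {
    tot <- num <- numeric(n_out)
    keep <- hi >= lo
    gidx <- gidx[keep]; lo <- lo[keep]; hi <- hi[keep]; tt <- tt[keep]
    if (!is.null(thr)) thr <- thr[keep]
    if (!length(gidx)) return(if (is.null(thr)) tot else list(tot, num))
    nv <- hi - lo + 1
    bounds <- c(which(!duplicated(ceiling(cumsum(nv) / chunk_values))),
                length(nv) + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      segs <- bounds[b]:(bounds[b + 1L] - 1L)
      gi <- rep.int(segs, nv[segs])
      d <- dens(sequence(nv[segs], from = lo[segs]), tt[gi])
      tot <- tot + rowsum_vec(d, gidx[gi], n_out)
      if (!is.null(thr))
        num <- num + rowsum_vec(d * (d <= thr[gi]), gidx[gi], n_out)
    }
    if (is.null(thr)) tot else list(tot, num)
  }

  small <- which(t > 0 & t <= full_range_max)
  if (length(small)) {
    ts <- t[small]
    d_obs <- dens(s1[small], ts)
    res <- ragged_sum(seq_along(small), rep(0, length(small)), ts, ts,
                      thr = d_obs * (1 + rel_tie_tol), n_out = length(small))
    pv[small] <- pmin(res[[2]] / res[[1]], 1)
  }

  big <- which(t > full_range_max)
  if (!length(big)) return(pv)
  tb <- t[big]; sb <- s1[big]
  nb <- length(big)
  tot <- if (phi == 0) rep(1, nb)
         else stats::dnbinom(tb, size = N / phi, mu = tb)
  thr <- dens(sb, tb) * (1 + rel_tie_tol)
  half <- ceiling(sd_mult * sqrt(tb * pr1 * (1 - pr1) * (1 + phi * tb / N)))

  # discrete mode of the conditional law (unimodal; refine around t*pr1)
  m0 <- pmin(pmax(floor(tb * pr1), 0), tb)
  cand <- cbind(pmax(m0 - 1, 0), m0, pmin(m0 + 1, tb))
  fc <- matrix(dens(as.vector(cand), rep(tb, 3)), ncol = 3)
  pick <- max.col(fc, ties.method = "first")
  m0 <- cand[cbind(seq_len(nb), pick)]
  f_mode <- fc[cbind(seq_len(nb), pick)]

  at_mode <- f_mode <= thr          # observed as probable as anything: p = 1
  a <- rep(0, nb); b <- tb          # boundaries of the f > thr region

  # left boundary: smallest s in [0, m0] with f(s) > thr
  lo <- rep(0, nb); hi <- m0
  act <- which(!at_mode & lo < hi)
  while (length(act)) {
    mid <- (lo[act] + hi[act]) %/% 2
    g <- dens(mid, tb[act]) > thr[act]
    hi[act[g]] <- mid[g]
    lo[act[!g]] <- mid[!g] + 1
    act <- act[lo[act] < hi[act]]
  }
  a[!at_mode] <- lo[!at_mode]
  # right boundary: largest s in [m0, t] with f(s) > thr
  lo <- m0; hi <- tb
  act <- which(!at_mode & lo < hi)
  while (length(act)) {
    mid <- (lo[act] + hi[act] + 1) %/% 2
    g <- dens(mid, tb[act]) > thr[act]
    lo[act[g]] <- mid[g]
    hi[act[!g]] <- mid[!g] - 1
    act <- act[lo[act] < hi[act]]
  }
  b[!at_mode] <- lo[!at_mode]

  p_big <- rep(1, nb)
  # clearly tail-bound observations skip the (wide) region sum entirely
  direct <- !at_mode & thr < f_mode * 1e-13
  idx <- which(!at_mode & !direct)
  if (length(idx)) {
    region <- ragged_sum(seq_along(idx), a[idx], b[idx], tb[idx],
                         n_out = length(idx))
    p_big[idx] <- pmin(pmax(1 - region / tot[idx], 0), 1)
  }

  # subtraction loses precision for tiny p: sum the two tails directly
  redo <- c(which(direct), idx[p_big[idx] < 1e-12])
  if (length(redo)) {
    lt <- ragged_sum(seq_along(redo), pmax(0, a[redo] - half[redo]),
                     a[redo] - 1, tb[redo], n_out = length(redo))
    rt <- ragged_sum(seq_along(redo), b[redo] + 1,
                     pmin(tb[redo], b[redo] + half[redo]), tb[redo],
                     n_out = length(redo))
    p_big[redo] <- pmin((lt + rt) / tot[redo], 1)
  }
  pv[big] <- p_big
  pv
}

rowsum_vec <- function(v, idx, n) {
  out <- numeric(n)
  r <- rowsum(v, idx)
  out[as.integer(rownames(r))] <- r[, 1]
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR values: with p-values sorted ascending,
#' `q_(k) = min_{j >= k} (m/j) p_(j)` capped at 1, returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`; NA/NaN are rejected.
#' @return Numeric vector of FDR values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("NA/NaN p-values rejected")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  a <- m / seq_len(m) * p[o]
  q <- pmin(rev(cummin(rev(a))), 1)
  q[order(o)]
}

#' Call differentially expressed genes at an FDR cutoff
#'
#' @param table a DEG table with columns `gene` and `FDR`.
#' @param fdr_cutoff strict upper bound on FDR (default 0.01, the
#'   conservative cutoff used throughout).
#' @return Character vector of DEG gene IDs.
#' @export
call_degs <- function(table, fdr_cutoff = 0.01) {
  if (nrow(table) == 0) return(character(0))
  stopifnot(all(c("gene", "FDR") %in% names(table)))
  degs <- table$gene[table$FDR < fdr_cutoff]
  message(sprintf("call_degs: %d of %d genes at FDR < %g",
                  length(degs), nrow(table), fdr_cutoff))
  degs
}

#' Two-condition differential expression, end to end
#'
#' Runs the full DE core on a two-condition count matrix: TMM factors,
#' common-dispersion estimate (unless supplied), exact conditional NB test,
#' and BH adjustment.
#'
#' @inheritParams nb_exact_test
#' @param lengths optional gene-length table; adds per-condition mean FPKM
#'   columns.
#' @return Data.frame with columns `gene`, `logFC`, `logCPM`, `PValue`,
#'   `FDR` (and mean FPKM per condition when `lengths` is given).
#' @examples
#' d <- synthetic_design(300, c(ctrl = 3, trt = 3), dispersion = 0.05,
#'                       offpanel_sd = 0, library_sizes = 1e6, seed = 2)
#' tab <- deg_table(generate_counts(d)$counts)
#' @export
deg_table <- function(x, norm = NULL, dispersion = NULL, pair = NULL,
                      lengths = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(norm)) norm <- tmm_factors(x)
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(x, norm = norm)
  tab <- nb_exact_test(x, norm = norm, dispersion = dispersion, pair = pair)
  tab$FDR <- bh_adjust(tab$PValue)
  if (!is.null(lengths)) {
    fk <- fpkm(x, lengths)
    if (is.null(pair)) pair <- levels(x$conditions)
    for (cn in pair)
      tab[[paste0("FPKM_", cn)]] <-
        rowMeans(fk[, x$conditions == cn, drop = FALSE])
  }
  attr(tab, "dispersion") <- dispersion
  tab
}
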