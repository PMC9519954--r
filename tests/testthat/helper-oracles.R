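# Independent oracles used across tests. These deliberately take different
# computational routes than the package implementation.

# Exact conditional two-sided p-value by exhaustive enumeration of the
# conditional law of the group-1 sum given the total, via the
# negative-hypergeometric closed form in log-gamma space (binomial via
# lchoose when phi = 0). Scalar; only for small totals.
enumerate_exact_pvalue <- function(s1_obs, total, n1, n2, phi,
                                   rel_tie_tol = 1e-10) {
  s <- 0:total
  if (phi == 0) {
    logw <- lchoose(total, s) + s * log(n1 / (n1 + n2)) +
      (total - s) * log(n2 / (n1 + n2))
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    logw <- lgamma(s + r1) - lgamma(s + 1) - lgamma(r1) +
      lgamma(total - s + r2) - lgamma(total - s + 1) - lgamma(r2)
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  w_obs <- w[s1_obs + 1]
  min(sum(w[w <= w_obs * (1 + rel_tie_tol)]), 1)
}

# Literal BH step-up by definition: with p sorted ascending, the adjusted
# value at rank k is min over j >= k of (m/j) p_(j), capped at 1 — computed
# here by an explicit per-rank scan, not the reverse-cummin trick.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) adj[k] <- min(1, m * ps[k:m] / (k:m))
  out <- numeric(m)
  out[o] <- adj
  out
}

# unit-factor normalization object for hand-built toy matrices
unit_norm <- function(m, lib = NULL) {
  if (is.null(lib)) lib <- colSums(m)
  structure(list(lib_size = stats::setNames(lib, colnames(m)),
                 factors = stats::setNames(rep(1, ncol(m)), colnames(m))),
            class = "norm_factors")
}

# small labeled count matrix from a plain matrix
cm_of <- function(m, conditions) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  count_matrix(m, conditions)
}
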