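toy_deg <- function(genes, m, fdr = NULL) {
  tab <- data.frame(gene = genes, logFC = m,
                    logCPM = 5, PValue = 0.5)
  if (!is.null(fdr)) tab$FDR <- fdr
  tab
}

test_that("state changes preserve M values and honor the FDR mask", {
  tab <- toy_deg(c("c", "a", "b"), c(3, -1, 0), fdr = c(0.001, 0.5, 0.2))
  v <- state_change(tab)
  expect_identical(names(v), c("a", "b", "c"))
  expect_equal(as.numeric(v), c(-1, 0, 3))

  masked <- state_change(tab, fdr_mask = 0.01)
  expect_identical(names(masked), "c")
  expect_setequal(names(masked), call_degs(tab, 0.01))

  zero <- state_change(toy_deg(letters[1:4], rep(0, 4)))
  expect_true(all(as.numeric(zero) == 0))
})

test_that("panel restriction is order-stable and composes by intersection", {
  v <- state_change(toy_deg(c("a", "b", "c", "d"), 1:4))
  p <- gene_panel(c("d", "b"), "p")
  r <- restrict_to_panel(v, p)
  expect_identical(names(r), c("b", "d"))
  expect_equal(as.numeric(r), c(2, 4))
  expect_length(restrict_to_panel(v, gene_panel(c("b", "zzz"))), 1)

  nested <- restrict_to_panel(restrict_to_panel(v, c("a", "b", "c")),
                              c("b", "c", "d"))
  direct <- restrict_to_panel(v, c("b", "c"))
  expect_equal(as.numeric(nested), as.numeric(direct))

  expect_error(restrict_to_panel(v, gene_panel("zzz")), "intersect")
})

test_that("median panel DEG summarizes the panel-restricted M values", {
  v <- state_change(toy_deg(c("a", "b", "c", "d"), c(1, 2, 10, -99)))
  expect_equal(median_panel_deg(v, c("a", "b", "c")), 2)
  sym <- state_change(toy_deg(letters[1:4], c(-2, 2, -1, 1)))
  expect_equal(median_panel_deg(sym, letters[1:4]), 0)
})

test_that("top variable DEGs match brute-force variance ranking", {
  va <- state_change(toy_deg(letters[1:5], rep(1, 5)))
  vb <- state_change(toy_deg(letters[1:5], rep(1, 5)))
  expect_identical(top_variable_degs(list(va, vb), k = 3),
                   letters[1:3])   # all-tied: first k by gene ID

  vc <- state_change(toy_deg(letters[1:5], c(1, 1, 9, 1, 1)))
  expect_identical(top_variable_degs(list(va, vc), k = 1), "c")

  set.seed(5)
  genes <- sprintf("g%03d", 1:500)
  vecs <- lapply(1:4, function(i)
    state_change(toy_deg(genes, rnorm(500))))
  got <- top_variable_degs(vecs, k = 50)
  m <- sapply(vecs, as.numeric)
  rownames(m) <- names(vecs[[1]])
  varpop <- apply(m, 1, function(x) mean(x^2) - mean(x)^2)
  want <- rownames(m)[order(-varpop, rownames(m))][1:50]
  expect_identical(got, want)

  expect_error(top_variable_degs(list(va,
    state_change(toy_deg(letters[2:6], 1:5)))), "share")
})

test_that("cosine similarity follows its definition and invariances", {
  v <- c(a = 1, b = 2, c = 2)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(a = 1, b = 0), c(a = 0, b = 3)), 0)
  expect_equal(cosine_similarity(v, c(a = 2, b = 1, c = 2)), 8 / 9)
  # scale and joint-permutation invariance
  expect_equal(cosine_similarity(v, 100 * c(a = 2, b = 1, c = 2)), 8 / 9)
  expect_equal(cosine_similarity(v[c(3, 1, 2)], c(c = 2, b = 1, a = 2)),
               8 / 9)
  expect_error(cosine_similarity(v, c(a = 0, b = 0, c = 0)), "zero-norm")
  expect_error(cosine_similarity(v, c(x = 1)), "shared")
})

test_that("Pearson correlation matches the textbook formula", {
  x <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4, g5 = 5)
  y <- c(g1 = 2, g2 = 1, g3 = 4, g4 = 3, g5 = 5)
  expect_equal(pearson_correlation(x, y), 0.8)   # hand-computed: 8/10
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_error(pearson_correlation(x, c(g1 = 1, g2 = 2)), "3 shared")
  expect_error(pearson_correlation(x, x * 0 + 2), "zero-variance")
})

test_that("PCA matches an eigendecomposition oracle", {
  set.seed(9)
  x <- matrix(rnorm(6 * 20), 6, dimnames = list(paste0("s", 1:6), NULL))
  res <- pca_states(x, n_components = 3)

  # oracle: eigen-decomposition of the covariance of centered data
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  for (j in 1:3) {
    lo <- ev$vectors[, j]
    if (lo[which.max(abs(lo))] < 0) lo <- -lo   # same sign convention
    expect_equal(unname(res$loadings[, j]), lo, tolerance = 1e-8)
    expect_equal(unname(res$scores[, j]), unname(drop(xc %*% lo)),
                 tolerance = 1e-8)
  }
  expect_equal(res$explained,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-8)
  expect_equal(unname(crossprod(res$loadings)), diag(3), tolerance = 1e-8)
  expect_true(all(diff(res$explained) <= 1e-12))

  # 1-D data embedded in 3-D: PC1 explains everything
  line <- outer(c(1, 2, 3, 4), c(1, -2, 0.5))
  rownames(line) <- paste0("s", 1:4)
  expect_equal(pca_states(line, 2)$explained[1], 1, tolerance = 1e-12)
})

test_that("PCA distance is a symmetric metric matching full-space distance
           at full rank", {
  set.seed(4)
  x <- matrix(rnorm(5 * 8), 5, dimnames = list(paste0("s", 1:5), NULL))
  res <- pca_states(x, n_components = 4)   # full rank for 5 samples
  expect_equal(pca_distance(res, "s1", "s1"), 0)
  expect_equal(pca_distance(res, "s1", "s3"), pca_distance(res, "s3", "s1"))
  expect_equal(pca_distance(res, "s2", "s4"),
               sqrt(sum((x["s2", ] - x["s4", ])^2)), tolerance = 1e-8)
  # triangle inequality on random triples
  for (i in 1:10) {
    tri <- sample(rownames(x), 3)
    expect_lte(pca_distance(res, tri[1], tri[3]),
               pca_distance(res, tri[1], tri[2]) +
                 pca_distance(res, tri[2], tri[3]) + 1e-12)
  }
  expect_error(pca_distance(res, "s1", "nope"), "unknown sample")
})

test_that("congruence labels follow the sign/threshold rule", {
  a <- c(g1 = 3, g2 = 3, g3 = -3, g4 = 0.5, g5 = 2)
  b <- c(g1 = 2, g2 = -2, g3 = -2, g4 = 3, g5 = 0.2)
  lab <- congruence_classify(a, b, min_abs_m = 1)
  expect_equal(unname(lab[c("g1", "g2", "g3", "g4", "g5")]),
               c("congruent-up", "divergent", "congruent-down",
                 "null", "null"))
  # negating one vector swaps congruent and divergent labels
  neg <- congruence_classify(a, -b, min_abs_m = 1)
  expect_equal(unname(neg["g1"]), "divergent")
  expect_equal(unname(neg["g2"]), "congruent-up")
  expect_equal(unname(neg["g3"]), "divergent")
})

test_that("cluster composition percentages tally the label pairs", {
  comp <- cluster_composition(rep("c0", 10), rep(c("NPC", "SPONT"), 5))
  expect_equal(comp$percent, c(50, 50))

  set.seed(2)
  cl <- sample(paste0("c", 0:10), 500, replace = TRUE)
  cond <- sample(c("NPC", "SPONT", "CNTF"), 500, replace = TRUE)
  comp <- cluster_composition(cl, cond)
  sums <- tapply(comp$percent, comp$cluster, sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  # brute-force tally
  for (k in 1:5) {
    row <- comp[sample(nrow(comp), 1), ]
    expect_equal(row$n, sum(cl == row$cluster & cond == row$condition))
  }
  expect_error(cluster_composition(cl, cond[-1]), "equal length")
})
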