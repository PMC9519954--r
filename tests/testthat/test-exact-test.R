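test_that("common dispersion is recovered from generated data", {
  d0 <- synthetic_design(2000, c(a = 6, b = 6), dispersion = 0,
                         offpanel_sd = 0, library_sizes = 2e6, seed = 21)
  phi0 <- estimate_common_dispersion(generate_counts(d0)$counts)
  expect_lte(phi0, 0.01)

  d2 <- synthetic_design(2000, c(a = 6, b = 6), dispersion = 0.2,
                         offpanel_sd = 0, library_sizes = 2e6, seed = 22)
  phi2 <- estimate_common_dispersion(generate_counts(d2)$counts)
  expect_gte(phi2, 0.15)
  expect_lte(phi2, 0.25)

  m <- matrix(c(3, 5), 1, dimnames = list("g1", c("s1", "s2")))
  expect_error(estimate_common_dispersion(cm_of(m, c("a", "b"))),
               "replicates")
})

test_that("exact test reproduces closed-form toy cases", {
  # 10 reads vs 0 under equal libraries at phi = 0: p = 2 * (1/2)^10
  m <- matrix(c(5, 5, 0, 0), 1, dimnames = list("g1", paste0("s", 1:4)))
  cm <- cm_of(m, c("A", "A", "B", "B"))
  tab <- nb_exact_test(cm, norm = unit_norm(m, lib = rep(1e6, 4)),
                       dispersion = 0)
  expect_equal(tab$PValue, 2 * 0.5^10, tolerance = 1e-12)

  # identical group sums under a symmetric design: everything is at least
  # as extreme as the observation
  m2 <- matrix(c(7, 3, 3, 7), 1, dimnames = list("g1", paste0("s", 1:4)))
  cm2 <- cm_of(m2, c("A", "A", "B", "B"))
  tab2 <- nb_exact_test(cm2, norm = unit_norm(m2, lib = rep(1e6, 4)),
                        dispersion = 0.1)
  expect_equal(tab2$PValue, 1)
})

test_that("exact test equals exhaustive conditional enumeration at small
           totals", {
  n1 <- 2; n2 <- 2
  for (phi in c(0, 0.1)) {
    for (total in c(1, 5, 17, 30)) {
      for (s1 in 0:total) {
        lib <- rep(1e6, 4)
        pv <- gliastate:::exact_nb_pvalues(s1, total - s1, n1, n2, phi)
        expect_equal(pv, enumerate_exact_pvalue(s1, total, n1, n2, phi),
                     tolerance = 1e-10,
                     label = sprintf("phi=%g total=%d s1=%d", phi, total, s1))
      }
    }
  }
})

test_that("large-total window path agrees with full enumeration", {
  d <- synthetic_design(300, c(a = 4, b = 4), dispersion = 0.05,
                        offpanel_sd = 0, library_sizes = 3e6,
                        baseline_log_mean = c(4, 8), seed = 5,
                        panels = list(list(name = "p", genes = 1:50,
                                           effects = list(b = 2))))
  cm <- generate_counts(d)$counts
  ps <- gliastate:::pseudo_counts(cm$counts, tmm_factors(cm))
  s1 <- rowSums(ps[, 1:4]); s2 <- rowSums(ps[, 5:8])
  pa <- gliastate:::exact_nb_pvalues(s1, s2, 4, 4, 0.05,
                                     full_range_max = 1e9)
  pb <- gliastate:::exact_nb_pvalues(s1, s2, 4, 4, 0.05,
                                     full_range_max = 10)
  expect_lt(max(abs(pa - pb)), 1e-9)
})

test_that("exact test tracks the reference implementation on random data", {
  skip_if_not_installed("edgeR")
  d <- synthetic_design(500, c(a = 4, b = 4), dispersion = 0.1,
                        offpanel_sd = 0, library_sizes = 5e5, seed = 9)
  cm <- generate_counts(d)$counts
  nf <- tmm_factors(cm)
  mine <- nb_exact_test(cm, norm = nf, dispersion = 0.1)
  y <- edgeR::DGEList(cm$counts, group = cm$conditions)
  y$samples$norm.factors <- nf$factors
  ref <- edgeR::exactTest(y, dispersion = 0.1, rejection.region = "smallp")
  expect_gt(stats::cor(mine$PValue, ref$table$PValue), 0.999)
  expect_lt(stats::median(abs(mine$PValue - ref$table$PValue)), 1e-3)
})

test_that("BH adjustment equals the step-up definition and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(3)
  for (i in 1:5) {
    p <- runif(sample(c(10, 100, 500), 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("DEG calling controls errors on nulls and finds planted effects", {
  expect_identical(call_degs(data.frame(gene = character(0),
                                        FDR = numeric(0))),
                   character(0))

  # null: no planted effects
  dn <- synthetic_design(2000, c(a = 4, b = 4), dispersion = 0.2,
                         offpanel_sd = 0, library_sizes = 2e6,
                         baseline_log_mean = c(0, 10), seed = 31)
  tn <- deg_table(generate_counts(dn)$counts)
  expect_lte(length(suppressMessages(call_degs(tn))), 2000 * 0.005)

  # planted 2-fold effects at deep counts, 6 vs 6
  da <- synthetic_design(2000, c(a = 6, b = 6), dispersion = 0.05,
                         panels = list(list(name = "p", genes = 1:200,
                                            effects = list(b = 1))),
                         offpanel_sd = 0, library_sizes = 5e6,
                         baseline_log_mean = c(5, 9), seed = 32)
  sima <- generate_counts(da)
  ta <- deg_table(sima$counts)
  hits <- suppressMessages(call_degs(ta))
  recall <- mean(sprintf("g%05d", 1:200) %in% hits)
  expect_gte(recall, 0.9)
})

test_that("single-nuclei QC drops genes then cells in the stated order", {
  # toy: gene g3 seen in 1 cell only -> dropped; cell c3 then has 1 gene
  m <- cbind(c1 = c(5, 1, 0, 2), c2 = c(4, 2, 0, 1), c3 = c(3, 0, 7, 0))
  rownames(m) <- c("g1", "g2", "g3", "mt-co1")
  cm <- cm_of(m, rep("x", 3))
  out <- suppressMessages(
    snqc_filter(cm, min_cells_per_gene = 2, min_genes_per_cell = 2))
  expect_setequal(rownames(out$counts), c("g1", "g2"))
  expect_setequal(colnames(out$counts), c("c1", "c2"))

  # mitochondrial genes go first regardless of their detection rate
  expect_false("mt-co1" %in% rownames(out$counts))

  expect_error(suppressMessages(
    snqc_filter(cm, min_cells_per_gene = 3, min_genes_per_cell = 4)),
    "all cells")
})

test_that("QC thresholds split a matrix built to straddle them", {
  set.seed(8)
  n_cells <- 400
  # 30 ubiquitous genes, 10 genes in exactly 150 cells (< 200), 5 mito
  ubiq <- matrix(rpois(30 * n_cells, 5) + 1, 30)
  rare <- matrix(0, 10, n_cells)
  for (i in 1:10) rare[i, sample(n_cells, 150)] <- 1
  mito <- matrix(rpois(5 * n_cells, 2) + 1, 5)
  m <- rbind(ubiq, rare, mito)
  rownames(m) <- c(paste0("g", 1:40), paste0("mt-", 1:5))
  colnames(m) <- paste0("c", seq_len(n_cells))
  cm <- cm_of(m, rep("x", n_cells))
  out <- suppressMessages(
    snqc_filter(cm, min_cells_per_gene = 200, min_genes_per_cell = 20))
  expect_equal(nrow(out$counts), 30)   # rare and mito genes gone
  expect_equal(ncol(out$counts), n_cells)
})
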