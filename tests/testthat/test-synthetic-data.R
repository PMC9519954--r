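test_that("identical designs generate bit-identical data", {
  d <- synthetic_design(100, c(a = 3, b = 3),
                        panels = list(list(name = "p", genes = 1:10,
                                           effects = list(b = 2))),
                        seed = 42)
  s1 <- generate_counts(d)
  s2 <- generate_counts(d)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
})

test_that("Poisson limit: per-gene means approach planted means", {
  d <- synthetic_design(200, c(a = 6), dispersion = 0,
                        baseline_log_mean = rep(5, 200),
                        library_sizes = 1e9, offpanel_sd = 0, seed = 1)
  sim <- generate_counts(d)
  planted <- 1e9 / 1e6 * 2^5
  rel <- abs(rowMeans(sim$counts$counts) - planted) / planted
  expect_lt(max(rel), 0.01)
})

test_that("empirical variance follows the NB mean-variance law", {
  phi <- 0.3
  d <- synthetic_design(50, c(a = 1000), dispersion = phi,
                        baseline_log_mean = rep(6, 50),
                        library_sizes = 1e6, offpanel_sd = 0, seed = 3)
  sim <- generate_counts(d)
  mu <- rowMeans(sim$counts$counts)
  v <- apply(sim$counts$counts, 1, stats::var)
  expected <- mu + phi * mu^2
  # median ratio across genes robust to per-gene sampling error
  expect_lt(abs(stats::median(v / expected) - 1), 0.1)
})

test_that("planted log2FC is recovered by estimated M at deep counts", {
  # balanced up/down panels so composition leaves TMM factors unbiased
  d <- synthetic_design(5000, c(pre = 6, post = 6),
                        panels = list(
                          list(name = "up", genes = 1:250,
                               effects = list(post = 2)),
                          list(name = "down", genes = 251:500,
                               effects = list(post = -2))),
                        dispersion = 0.01, baseline_log_mean = c(5, 9),
                        library_sizes = 5e6, offpanel_sd = 0, seed = 11)
  sim <- generate_counts(d)
  tab <- deg_table(sim$counts)
  m_up <- tab$logFC[match(sprintf("g%05d", 1:250), tab$gene)]
  m_dn <- tab$logFC[match(sprintf("g%05d", 251:500), tab$gene)]
  expect_lt(abs(mean(m_up) - 2), 3 * stats::sd(m_up) / sqrt(250) + 0.03)
  expect_lt(abs(mean(m_dn) + 2), 3 * stats::sd(m_dn) / sqrt(250) + 0.03)
})

test_that("truth table covers every gene and condition", {
  d <- synthetic_design(50, c(a = 2, b = 2, c = 2),
                        panels = list(list(name = "p", genes = 5:10,
                                           effects = list(b = 1, c = -1))),
                        seed = 2)
  sim <- generate_counts(d)
  expect_equal(nrow(sim$truth), 50 * 3)
  expect_setequal(unique(sim$truth$condition), c("a", "b", "c"))
  # reference condition has zero planted effect
  expect_true(all(sim$truth$log2fc[sim$truth$condition == "a"] == 0))
  expect_equal(sim$truth$log2fc[sim$truth$gene == "g00005" &
                                  sim$truth$condition == "c"], -1)
})

test_that("designs with unrepresentable means are rejected", {
  d <- synthetic_design(10, c(a = 2, b = 2),
                        baseline_log_mean = rep(60, 10),
                        library_sizes = 1e9, offpanel_sd = 0)
  expect_error(generate_counts(d), "overflow|non-finite")
  expect_error(synthetic_design(10, c(a = 1, b = 2)), ">= 2")
  expect_error(synthetic_design(10, c(a = 2), dispersion = -1))
})

test_that("planted state pairs realize the requested angle exactly", {
  d <- synthetic_design(500, c(pre = 2, post = 2), offpanel_sd = 0, seed = 5)

  conv0 <- planted_convergence(200, theta = 0, seed = 5)
  sp0 <- generate_state_pair(d, conv0, magnitudes = c(3, 7))
  cs0 <- sum(sp0$planted$v1 * sp0$planted$v2) /
    sqrt(sum(sp0$planted$v1^2) * sum(sp0$planted$v2^2))
  expect_equal(cs0, 1, tolerance = 1e-12)

  conv90 <- planted_convergence(200, theta = pi / 2, seed = 5)
  sp90 <- generate_state_pair(d, conv90, magnitudes = c(3, 7))
  cs90 <- sum(sp90$planted$v1 * sp90$planted$v2) /
    sqrt(sum(sp90$planted$v1^2) * sum(sp90$planted$v2^2))
  expect_equal(cs90, 0, tolerance = 1e-12)

  # direction vectors orthonormal
  expect_equal(sum(conv0$u^2), 1, tolerance = 1e-12)
  expect_equal(sum(conv0$w^2), 1, tolerance = 1e-12)
  expect_lt(abs(sum(conv0$u * conv0$w)), 1e-10)
  expect_error(generate_state_pair(d, conv0, magnitudes = c(0, 1)),
               "positive")
})

test_that("voting lists honor sensitivity and the false-positive pool", {
  panel <- paste0("true", 1:30)
  pool <- paste0("fp", 1:100)
  perfect <- generate_voting_lists(panel, 8, sensitivity = 1,
                                   n_false_positives = 0, gene_pool = pool)
  expect_true(all(vapply(perfect, function(l) setequal(l, panel),
                         logical(1))))
  expect_error(
    generate_voting_lists(panel, 3, 0.8, n_false_positives = 200,
                          gene_pool = pool),
    "pool exhausted")
  l1 <- generate_voting_lists(panel, 4, 0.5, 10, pool, seed = 9)
  l2 <- generate_voting_lists(panel, 4, 0.5, 10, pool, seed = 9)
  expect_identical(l1, l2)
})

test_that("lesion images match their configured geometry", {
  flat <- lesion_image_config(size = 64, core_radius = 10, border_width = 5,
                              core_intensity = 7, border_intensity = 7,
                              background_intensity = 7, noise_sd = 0)
  img <- generate_lesion_image(flat)$image
  expect_true(all(img == 7))

  cfg <- lesion_image_config(size = 128, core_radius = 20, border_width = 10,
                             core_intensity = 0, border_intensity = 100,
                             background_intensity = 10, noise_sd = 5,
                             seed = 4)
  g1 <- generate_lesion_image(cfg)
  g2 <- generate_lesion_image(cfg)
  expect_identical(g1$image, g2$image)
  expect_true(all(g1$image >= 0))
  expect_equal(g1$truth$border_radii, c(20, 30))
  expect_error(lesion_image_config(size = 64, core_radius = 40), "core_radius")
})
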