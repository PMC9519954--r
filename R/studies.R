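#' Planted-convergence recovery study
#'
#' The end-to-end benchmark of the state-comparison pipeline: for each seed,
#' two two-condition count data sets are simulated whose panel-restricted
#' planted log2FC vectors meet at a known angle; the full pipeline (TMM,
#' dispersion estimation, exact test, state-change extraction, panel
#' restriction, cosine similarity) is then run and its estimate compared to
#' the planted cosine.
#'
#' Default study conditions: a 2000-gene panel inside 3000 genes, 4
#' replicates per condition, deep counts (5e6 reads/sample, baselines
#' log-uniform 2^5–2^9), dispersion 0.01, planted vector norms 60, and
#' theta = 0.567 rad (cosine 0.843).
#'
#' @param seeds integer vector of simulation seeds.
#' @param theta planted angle in radians.
#' @param n_genes,n_panel total and panel gene counts.
#' @param reps replicates per condition.
#' @param magnitudes planted vector norms (length 2).
#' @param dispersion,library_size,baseline_log_mean NB simulation settings.
#' @return Data.frame with one row per seed: `seed`, `estimated_cs`,
#'   `target_cs`, `abs_error`.
#' @export
cs_recovery_study <- function(seeds, theta = 0.567,
                              n_genes = 3000, n_panel = 2000, reps = 4,
                              magnitudes = c(60, 60), dispersion = 0.01,
                              library_size = 5e6,
                              baseline_log_mean = c(5, 9)) {
  rows <- lapply(seeds, function(seed) {
    design <- synthetic_design(
      n_genes, stats::setNames(c(reps, reps), c("pre", "post")),
      dispersion = dispersion, library_sizes = library_size,
      baseline_log_mean = baseline_log_mean, offpanel_sd = 0.1, seed = seed)
    conv <- planted_convergence(n_panel, theta = theta, seed = seed)
    sp <- generate_state_pair(design, conv, magnitudes = magnitudes)
    v1 <- restrict_to_panel(state_change(deg_table(sp$lineage1$counts)),
                            sp$panel_genes)
    v2 <- restrict_to_panel(state_change(deg_table(sp$lineage2$counts)),
                            sp$panel_genes)
    cs <- cosine_similarity(v1, v2)
    data.frame(seed = seed, estimated_cs = cs, target_cs = cos(theta),
               abs_error = abs(cs - cos(theta)))
  })
  do.call(rbind, rows)
}

#' Null-simulation false-discovery study
#'
#' Runs the full DE core on simulations with no planted effects and reports
#' the fraction of genes called at the FDR cutoff, to verify type-I control
#' of the exact-test pipeline.
#'
#' @param n_sims number of independent null simulations.
#' @param seed base seed (per-simulation seeds derive from it).
#' @param n_genes genes per simulation.
#' @param reps replicates per condition (two conditions).
#' @param dispersion simulated NB dispersion.
#' @param library_size reads per sample.
#' @param fdr_cutoff DEG-calling cutoff.
#' @return Data.frame with `sim`, `n_called`, `fraction`.
#' @export
null_fdr_study <- function(n_sims = 50, seed = 1, n_genes = 5000, reps = 4,
                           dispersion = 0.2, library_size = 2e6,
                           fdr_cutoff = 0.01) {
  rows <- lapply(seq_len(n_sims), function(i) {
    design <- synthetic_design(
      n_genes, c(a = reps, b = reps), dispersion = dispersion,
      library_sizes = library_size, baseline_log_mean = c(0, 10),
      offpanel_sd = 0, seed = stream_seed(seed, paste0("null", i)))
    tab <- deg_table(generate_counts(design)$counts)
    n_called <- sum(tab$FDR < fdr_cutoff)
    data.frame(sim = i, n_called = n_called, fraction = n_called / n_genes)
  })
  do.call(rbind, rows)
}

#' Vote-threshold recovery study
#'
#' Simulates per-dataset enriched-gene lists at a known sensitivity, applies
#' vote thresholding, and compares the recall of the true panel with the
#' binomial prediction P(X >= min_votes; n_datasets, sensitivity).
#'
#' @param seed integer seed.
#' @param n_true true panel size.
#' @param n_datasets number of lists.
#' @param sensitivity per-list detection probability.
#' @param n_false_positives false positives per list.
#' @param pool_size size of the non-panel gene pool.
#' @param min_votes vote threshold.
#' @return List with `recall`, `expected` (binomial closed form), `se`
#'   (binomial standard error over genes) and `n_false_included`.
#' @export
voting_recovery_study <- function(seed = 1, n_true = 400, n_datasets = 8,
                                  sensitivity = 0.8, n_false_positives = 20,
                                  pool_size = 5000, min_votes = 5) {
  truep <- sprintf("true%04d", seq_len(n_true))
  pool <- sprintf("null%05d", seq_len(pool_size))
  lists <- generate_voting_lists(truep, n_datasets, sensitivity,
                                 n_false_positives, pool, seed = seed)
  panel <- vote_panel(lists, min_votes = min_votes, case = "asis")
  expected <- sum(stats::dbinom(min_votes:n_datasets, n_datasets,
                                sensitivity))
  list(recall = mean(truep %in% panel$genes),
       expected = expected,
       se = sqrt(expected * (1 - expected) / n_true),
       n_false_included = sum(!panel$genes %in% truep))
}
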