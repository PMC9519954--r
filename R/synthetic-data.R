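#' Describe a synthetic RNA-seq experiment
#'
#' A design holds everything needed to simulate negative-binomial counts with
#' planted, panel-structured log2 fold-changes: gene number, condition layout,
#' per-gene baseline abundances, a common dispersion and per-sample library
#' sizes. The first condition is the reference state; effects of every other
#' condition are log2 fold-changes relative to it.
#'
#' Counts for gene g in sample s of condition c are drawn as
#' \deqn{y_{gs} \sim NB(\mu_{gs}, \phi), \quad
#'       \mu_{gs} = \frac{L_s}{10^6} \, 2^{b_g + e_{gc}},}
#' with variance \eqn{\mu + \phi \mu^2}. Baselines \eqn{b_g} default to a
#' log-uniform draw over a 2^0–2^12 dynamic range, emulating the spread of
#' bulk RNA-seq abundances.
#'
#' @param n_genes number of genes.
#' @param conditions named integer vector: condition label -> replicate count
#'   (each >= 2). The first entry is the reference condition.
#' @param panels list of panels, each a list with elements `name`, `genes`
#'   (integer indices in 1..n_genes) and `effects` (named list: condition ->
#'   scalar or per-gene log2FC applied to the panel genes).
#' @param baseline_log_mean per-gene baseline on the log2 count scale; a
#'   length-2 numeric is read as a uniform range to draw from (default
#'   `c(0, 12)`), a length-`n_genes` vector is used as-is.
#' @param dispersion common NB dispersion phi >= 0 (0 = Poisson).
#' @param library_sizes per-sample sequencing depths; a scalar is recycled.
#' @param offpanel_sd standard deviation of independent N(0, sd^2) log2FC
#'   noise planted on non-panel genes of every non-reference condition, so
#'   panels dominate the geometry. Set 0 for a clean null.
#' @param seed integer seed; identical designs generate identical data.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_genes,
                             conditions,
                             panels = list(),
                             baseline_log_mean = c(0, 12),
                             dispersion = 0.05,
                             library_sizes = 1e7,
                             offpanel_sd = 0.1,
                             seed = 1L) {
  stopifnot(n_genes >= 1, dispersion >= 0, offpanel_sd >= 0)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("conditions must be a named vector: label -> replicate count")
  if (any(conditions < 2)) stop("replicate counts must be >= 2")
  n_samples <- sum(conditions)
  library_sizes <- rep_len(as.numeric(library_sizes), n_samples)
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  for (p in panels) {
    if (is.null(p$name) || is.null(p$genes) || is.null(p$effects))
      stop("each panel needs name, genes and effects")
    if (any(p$genes < 1L | p$genes > n_genes))
      stop("panel gene indices must lie in 1..n_genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 conditions = conditions,
                 panels = panels,
                 baseline_log_mean = baseline_log_mean,
                 dispersion = dispersion,
                 library_sizes = library_sizes,
                 offpanel_sd = offpanel_sd,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

# per-gene, per-condition planted log2FC matrix (reference column = 0)
planted_effects <- function(design) {
  conds <- names(design$conditions)
  eff <- matrix(0, design$n_genes, length(conds),
                dimnames = list(NULL, conds))
  panel_genes <- integer(0)
  for (p in design$panels) {
    panel_genes <- union(panel_genes, p$genes)
    for (cn in names(p$effects)) {
      if (!cn %in% conds) stop("panel effect names unknown condition: ", cn)
      e <- p$effects[[cn]]
      if (!length(e) %in% c(1L, length(p$genes)))
        stop("panel effect must be scalar or one value per panel gene")
      eff[p$genes, cn] <- eff[p$genes, cn] + e
    }
  }
  if (design$offpanel_sd > 0) {
    off <- setdiff(seq_len(design$n_genes), panel_genes)
    if (length(off) && length(conds) > 1) {
      set.seed(stream_seed(design$seed, "offpanel"))
      for (cn in conds[-1])
        eff[off, cn] <- stats::rnorm(length(off), 0, design$offpanel_sd)
    }
  }
  eff[, conds[1]] <- 0
  eff
}

#' Simulate counts from a synthetic design
#'
#' Draws a negative-binomial count matrix under the design's planted effects
#' and returns it together with a complete truth table of per-gene,
#' per-condition log2 fold-changes (relative to the reference condition), so
#' any downstream estimator can be scored.
#'
#' @param design a [synthetic_design()].
#' @return List with `counts` (a [count_matrix()]), `truth` (data.frame with
#'   columns gene, condition, log2fc) and `design`.
#' @examples
#' d <- synthetic_design(200, c(npc = 3, graft = 3),
#'                       panels = list(list(name = "astro", genes = 1:20,
#'                                          effects = list(graft = 3))),
#'                       offpanel_sd = 0, seed = 7)
#' sim <- generate_counts(d)
#' @export
generate_counts <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  n <- design$n_genes
  conds <- names(design$conditions)

  b <- design$baseline_log_mean
  if (length(b) == 2L && n != 2L) {
    set.seed(stream_seed(design$seed, "baseline"))
    b <- stats::runif(n, b[1], b[2])
  } else if (length(b) != n) {
    stop("baseline_log_mean must be a range or one value per gene")
  }

  eff <- planted_effects(design)
  cond_per_sample <- rep(conds, design$conditions)
  sample_ids <- paste0(cond_per_sample, "_",
                       unlist(lapply(design$conditions, seq_len)))
  genes <- sprintf("g%05d", seq_len(n))

  mu <- outer(2^b, design$library_sizes / 1e6) *
    2^(eff[, cond_per_sample, drop = FALSE])
  if (any(!is.finite(mu))) stop("design rejected: non-finite NB means")
  if (any(mu > 1e12)) stop("design rejected: NB mean overflows representable counts")

  set.seed(stream_seed(design$seed, "counts"))
  counts <- if (design$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / design$dispersion),
           nrow = n)
  } else {
    matrix(stats::rpois(length(mu), mu), nrow = n)
  }
  dimnames(counts) <- list(genes, sample_ids)

  truth <- data.frame(
    gene = rep(genes, times = length(conds)),
    condition = rep(conds, each = n),
    log2fc = as.vector(eff),
    stringsAsFactors = FALSE)

  list(counts = count_matrix(counts, cond_per_sample),
       truth = truth,
       design = design)
}

#' Plant a known angle between two state-change directions
#'
#' Builds two orthonormal direction vectors `u`, `w` over a gene panel so a
#' pair of planted state changes `m1*u` and `m2*(cos(theta)*u + sin(theta)*w)`
#' has cosine similarity exactly `cos(theta)`. This is the ground truth the
#' cosine-similarity pipeline is scored against.
#'
#' @param n_panel_genes number of genes carrying the planted directions.
#' @param theta angle in radians, in `[0, pi/2]`.
#' @param seed integer seed for the random directions.
#' @return Object of class `planted_convergence` with `theta`, `target_cs`,
#'   and orthonormal `u`, `w`.
#' @export
planted_convergence <- function(n_panel_genes, theta, seed = 1L) {
  stopifnot(n_panel_genes >= 2, theta >= 0, theta <= pi / 2)
  set.seed(stream_seed(seed, "convergence"))
  u <- stats::rnorm(n_panel_genes)
  u <- u / sqrt(sum(u^2))
  w <- stats::rnorm(n_panel_genes)
  w <- w - sum(w * u) * u
  w <- w / sqrt(sum(w^2))
  structure(list(theta = theta, target_cs = cos(theta), u = u, w = w),
            class = "planted_convergence")
}

#' Simulate two lineages with a planted state-change angle
#'
#' Generates two independent two-condition count data sets ("lineages", e.g.
#' NPC before/after grafting and astrocytes healthy/reactive) whose
#' panel-restricted planted log2FC vectors are `m1*u` and
#' `m2*(cos(theta)*u + sin(theta)*w)`: their true cosine similarity equals
#' `cos(theta)` exactly. Off-panel genes receive independent N(0, sd^2) noise
#' effects in each lineage.
#'
#' @param design a [synthetic_design()] with exactly two conditions
#'   (reference, target) and no panels; its gene/replicate/depth/dispersion
#'   settings are used for both lineages.
#' @param convergence a [planted_convergence()]; its direction length fixes
#'   the panel size. The panel occupies the first `n_panel_genes` genes.
#' @param magnitudes positive numeric length 2: Euclidean norms `m1`, `m2` of
#'   the two planted panel vectors.
#' @return List with `lineage1`, `lineage2` (each a [generate_counts()]
#'   result), `panel_genes` (gene IDs), `planted` (the two planted panel
#'   vectors) and `target_cs`.
#' @export
generate_state_pair <- function(design, convergence, magnitudes) {
  stopifnot(inherits(design, "synthetic_design"),
            inherits(convergence, "planted_convergence"))
  if (any(magnitudes <= 0)) stop("magnitudes must be positive")
  if (length(design$conditions) != 2L)
    stop("design must have exactly two conditions (reference, target)")
  npanel <- length(convergence$u)
  if (npanel > design$n_genes)
    stop("panel named in convergence does not fit the design")
  target <- names(design$conditions)[2]

  v1 <- magnitudes[1] * convergence$u
  v2 <- magnitudes[2] * (cos(convergence$theta) * convergence$u +
                           sin(convergence$theta) * convergence$w)

  make <- function(v, tag, seed_off) {
    d <- design
    d$panels <- list(list(name = "planted", genes = seq_len(npanel),
                          effects = stats::setNames(list(v), target)))
    d$seed <- stream_seed(design$seed, paste0("lineage_", tag)) + seed_off
    generate_counts(d)
  }
  l1 <- make(v1, "1", 0L)
  l2 <- make(v2, "2", 0L)

  list(lineage1 = l1, lineage2 = l2,
       panel_genes = rownames(l1$counts$counts)[seq_len(npanel)],
       planted = list(v1 = v1, v2 = v2),
       target_cs = convergence$target_cs)
}

#' Simulate per-dataset enriched-gene lists for vote-based curation
#'
#' Emulates the meta-analysis input of panel curation: each of `n_datasets`
#' lists contains every true-panel gene independently with probability
#' `sensitivity`, plus a stated number of false-positive genes drawn without
#' replacement from a non-panel pool.
#'
#' @param true_panel character vector of true panel gene symbols.
#' @param n_datasets number of lists.
#' @param sensitivity per-dataset detection probability (scalar or length
#'   `n_datasets`), in `[0, 1]`.
#' @param n_false_positives false positives per list (scalar or vector).
#' @param gene_pool character vector of non-panel genes the false positives
#'   are drawn from.
#' @param seed integer seed.
#' @return List of character vectors (one gene list per dataset).
#' @export
generate_voting_lists <- function(true_panel, n_datasets,
                                  sensitivity, n_false_positives,
                                  gene_pool, seed = 1L) {
  stopifnot(all(sensitivity >= 0), all(sensitivity <= 1), n_datasets >= 1)
  sensitivity <- rep_len(sensitivity, n_datasets)
  n_false_positives <- rep_len(as.integer(n_false_positives), n_datasets)
  pool <- setdiff(gene_pool, true_panel)
  if (any(n_false_positives > length(pool)))
    stop("false-positive pool exhausted")
  set.seed(stream_seed(seed, "voting"))
  lapply(seq_len(n_datasets), function(i) {
    keep <- stats::runif(length(true_panel)) < sensitivity[i]
    fp <- if (n_false_positives[i] > 0) sample(pool, n_false_positives[i])
          else character(0)
    c(true_panel[keep], fp)
  })
}
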