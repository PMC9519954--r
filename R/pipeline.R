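#' Read a pipeline run configuration
#'
#' YAML key-value configuration for [run_pipeline()]: input paths, an output
#' directory, stage parameters and a seed. Referenced input paths are
#' validated at read time; parameters get documented defaults.
#'
#' @param path YAML file.
#' @return Object of class `run_config` (a named list).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(fdr_cutoff = 0.01, lfc_threshold = 2, min_votes = NULL,
                   k = 2000, space = "logfc", bin_width = 5,
                   min_cells_per_gene = 200, min_genes_per_cell = 333,
                   qc = FALSE, seed = 1L, verbosity = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!cfg$space %in% c("logfc", "fpkm"))
    stop("space must be 'logfc' or 'fpkm'")
  for (nm in c("counts1", "counts2", "conditions1", "conditions2",
               "panel", "lengths")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop("config path does not exist: ", nm, " = ", cfg[[nm]])
  }
  if (is.null(cfg$outdir)) stop("config needs an outdir")
  structure(cfg, class = "run_config")
}

#' Run the state-comparison pipeline
#'
#' Executes the stages in declared order — QC (optional), normalization,
#' differential expression for each of the two contrasts, panel restriction,
#' and state-change geometry (cosine similarity, PCA distance, congruence) —
#' writing each stage's table under `outdir` plus a run manifest with input
#' checksums, so an identical config on identical inputs reproduces
#' identical outputs.
#'
#' @param config a [read_run_config()] result, or the path of one.
#' @return The manifest (named list), invisibly; side effect: files under
#'   `outdir` (`deg_contrast1.csv`, `deg_contrast2.csv`,
#'   `similarity.json`, `congruence.csv`, `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "read"
  res <- tryCatch({
    cm1 <- read_counts(config$counts1, config$conditions1)
    cm2 <- read_counts(config$counts2, config$conditions2)

    if (isTRUE(config$qc)) {
      stage <- "qc"
      cm1 <- snqc_filter(cm1, config$min_cells_per_gene,
                         config$min_genes_per_cell)
      cm2 <- snqc_filter(cm2, config$min_cells_per_gene,
                         config$min_genes_per_cell)
    }

    stage <- "normalize"
    n1 <- tmm_factors(cm1); n2 <- tmm_factors(cm2)

    stage <- "de"
    lengths <- if (!is.null(config$lengths))
      utils::read.delim(config$lengths, header = FALSE,
                        col.names = c("gene", "length"))
    t1 <- deg_table(cm1, norm = n1, lengths = lengths)
    t2 <- deg_table(cm2, norm = n2, lengths = lengths)
    write_deg_table(t1, file.path(config$outdir, "deg_contrast1.csv"))
    write_deg_table(t2, file.path(config$outdir, "deg_contrast2.csv"))

    stage <- "panels"
    panel <- if (!is.null(config$panel)) read_panel(config$panel)
    v1 <- state_change(t1); v2 <- state_change(t2)
    if (!is.null(panel)) {
      v1 <- restrict_to_panel(v1, panel)
      v2 <- restrict_to_panel(v2, panel)
    }

    stage <- "geometry"
    cs <- cosine_similarity(v1, v2)
    shared <- intersect(names(v1), names(v2))
    pca <- pca_states(rbind(contrast1 = as_state_values(v1)[shared],
                            contrast2 = as_state_values(v2)[shared],
                            origin = 0 * seq_along(shared)),
                      n_components = 2)
    sim <- list(panel = if (is.null(panel)) "all genes" else panel$name,
                n_genes = length(shared),
                cosine_similarity = cs,
                pca_distance = pca_distance(pca, "contrast1", "contrast2"))
    jsonlite::write_json(sim, file.path(config$outdir, "similarity.json"),
                         auto_unbox = TRUE, digits = NA)
    cong <- congruence_classify(v1, v2)
    utils::write.csv(data.frame(gene = names(cong), label = cong,
                                row.names = NULL),
                     file.path(config$outdir, "congruence.csv"),
                     row.names = FALSE, quote = FALSE)
    sim
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  inputs <- unlist(config[c("counts1", "counts2", "conditions1",
                            "conditions2", "panel", "lengths")])
  manifest <- list(
    tool_version = as.character(utils::packageVersion("gliastate")),
    seed = config$seed,
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    similarity = res,
    n_degs_contrast1 = nrow(utils::read.csv(
      file.path(config$outdir, "deg_contrast1.csv"))),
    n_degs_contrast2 = nrow(utils::read.csv(
      file.path(config$outdir, "deg_contrast2.csv"))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
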