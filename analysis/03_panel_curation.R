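#!/usr/bin/env Rscript
# Stage 3: curate gene panels by vote thresholding and report distinctness.
#
# Applies the >= 5-of-8 vote rule to the stage-1 enriched-gene lists,
# scores the curated panel against the simulation truth, and writes a
# panel-overlap (uniqueness) report for three panels with the study's
# panel sizes.

suppressPackageStartupMessages(library(gliastate))
datadir <- "results/data"
outdir <- "results/panels"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

lists <- lapply(sprintf("%s/aeg_list_%d.txt", datadir, 1:8), readLines)
panel <- vote_panel(lists, min_votes = 5, name = "healthy_astrocyte",
                    case = "asis")
write_panel(panel, file.path(outdir, "healthy_astrocyte_panel.tsv"))

truth <- readLines(file.path(datadir, "healthy_panel_truth.txt"))
recall <- mean(truth %in% panel$genes)
precision <- mean(panel$genes %in% truth)
cat(sprintf("voted panel: %d genes (truth %d); recall %.3f, precision %.3f\n",
            length(panel$genes), length(truth), recall, precision))
cat(sprintf("binomial prediction for recall: %.3f\n",
            sum(dbinom(5:8, 8, 0.8))))

# distinctness across three synthetic astrocyte-state panels
reactivity <- gene_panel(c(sprintf("react%03d", 1:160),
                           panel$genes[1:10]), "reactivity")
emt <- gene_panel(c(sprintf("emt%03d", 1:190), sprintf("react%03d", 1:7)),
                  "emt")
rep3 <- panel_uniqueness(list(panel, reactivity, emt))
utils::write.csv(
  data.frame(panel = names(rep3$unique_fraction),
             size = rep3$sizes,
             unique_percent = rep3$unique_fraction),
  file.path(outdir, "panel_uniqueness.csv"), row.names = FALSE)
jsonlite::write_json(rep3, file.path(outdir, "panel_overlap.json"),
                     auto_unbox = TRUE, digits = NA)
cat("unique fractions (%):",
    sprintf("%s=%.1f", names(rep3$unique_fraction), rep3$unique_fraction),
    "\n")
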