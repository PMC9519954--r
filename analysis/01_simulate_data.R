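#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs with known ground truth.
#
# Produces, under results/data/:
#   - two two-condition count data sets ("lineages") whose panel-restricted
#     state-change vectors meet at a planted angle (cosine 0.843): a
#     progenitor-to-graft transition and a healthy-to-reactive astrocyte
#     transition;
#   - eight per-dataset enriched-gene lists for vote-based panel curation;
#   - a synthetic lesion image with a bright astroglial border annulus.

suppressPackageStartupMessages(library(gliastate))
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 2026

## planted-convergence state pair -----------------------------------------
design <- synthetic_design(3000, c(pre = 4, post = 4), dispersion = 0.01,
                           library_sizes = 5e6, baseline_log_mean = c(5, 9),
                           offpanel_sd = 0.1, seed = seed)
conv <- planted_convergence(2000, theta = 0.567, seed = seed)
pair <- generate_state_pair(design, conv, magnitudes = c(60, 60))

write_counts(pair$lineage1$counts, file.path(outdir, "npc_graft.tsv"),
             conditions_path = file.path(outdir, "npc_graft.conditions.tsv"))
write_counts(pair$lineage2$counts, file.path(outdir, "astro_sci.tsv"),
             conditions_path = file.path(outdir, "astro_sci.conditions.tsv"))
writeLines(pair$panel_genes, file.path(outdir, "reactivity_panel.txt"))
utils::write.csv(pair$lineage1$truth,
                 file.path(outdir, "npc_graft.truth.csv"), row.names = FALSE)
utils::write.csv(pair$lineage2$truth,
                 file.path(outdir, "astro_sci.truth.csv"), row.names = FALSE)
cat(sprintf("state pair: 2 x %d genes, planted cosine %.3f\n",
            nrow(pair$lineage1$counts$counts), pair$target_cs))

## voting lists for panel curation ----------------------------------------
true_panel <- sprintf("astro%03d", 1:429)      # healthy-astrocyte-sized
pool <- sprintf("other%04d", 1:8000)
lists <- generate_voting_lists(true_panel, n_datasets = 8,
                               sensitivity = 0.8, n_false_positives = 40,
                               gene_pool = pool, seed = seed)
for (i in seq_along(lists))
  writeLines(lists[[i]], file.path(outdir, sprintf("aeg_list_%d.txt", i)))
writeLines(true_panel, file.path(outdir, "healthy_panel_truth.txt"))
cat(sprintf("voting lists: 8 lists, median length %d\n",
            as.integer(median(lengths(lists)))))

## lesion image ------------------------------------------------------------
cfg <- lesion_image_config(size = 220, core_radius = 55, border_width = 12,
                           core_intensity = 20, border_intensity = 120,
                           background_intensity = 20, noise_sd = 10,
                           seed = seed)
les <- generate_lesion_image(cfg)
write_image(les$image, file.path(outdir, "lesion_gfap_synthetic.tif"),
            scale = 255)
cat(sprintf("lesion image: %dx%d px, border radii %g-%g px\n",
            nrow(les$image), ncol(les$image),
            les$truth$border_radii[1], les$truth$border_radii[2]))
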