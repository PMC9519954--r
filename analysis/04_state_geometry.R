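#!/usr/bin/env Rscript
# Stage 4: compare the two transcriptional state changes.
#
# Builds state-change vectors from the stage-2 DEG tables, restricts them
# to the reactivity panel, and measures their geometry: cosine similarity
# (against the planted 0.843), PCA Euclidean distance, congruent/divergent
# regulation, and the top-k most differently regulated genes.

suppressPackageStartupMessages(library(gliastate))
outdir <- "results/geometry"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

t1 <- utils::read.csv("results/de/npc_graft_deg.csv")
t2 <- utils::read.csv("results/de/astro_sci_deg.csv")
panel <- read_panel("results/data/reactivity_panel.txt", case = "asis",
                    name = "reactivity")

v1 <- state_change(t1, labels = c("NPC", "graft 14dpi"))
v2 <- state_change(t2, labels = c("healthy astrocyte", "reactive astrocyte"))
r1 <- restrict_to_panel(v1, panel)
r2 <- restrict_to_panel(v2, panel)

cs_panel <- cosine_similarity(r1, r2)
cs_all <- cosine_similarity(v1, v2)
cat(sprintf("cosine similarity: %.3f on the %d-gene panel, %.3f on all %d genes\n",
            cs_panel, length(r1), cs_all, length(v1)))

shared <- intersect(names(r1), names(r2))
mat <- rbind(graft = as.numeric(r1[shared]),
             host = as.numeric(r2[shared]),
             origin = rep(0, length(shared)))
pca <- pca_states(mat, n_components = 2)
d_graft <- pca_distance(pca, "graft", "origin")
d_host <- pca_distance(pca, "host", "origin")
d_between <- pca_distance(pca, "graft", "host")
cat(sprintf("PCA distances from start state: graft %.1f, host %.1f; between %.1f\n",
            d_graft, d_host, d_between))

cong <- congruence_classify(r1, r2, min_abs_m = 1)
utils::write.csv(data.frame(gene = names(cong), label = unname(cong)),
                 file.path(outdir, "congruence.csv"), row.names = FALSE)
cat("congruence labels:",
    sprintf("%s=%d", names(table(cong)), as.integer(table(cong))), "\n")

topk <- top_variable_degs(list(v1, v2), k = 2000)
writeLines(topk, file.path(outdir, "top2000_variable_degs.txt"))

jsonlite::write_json(
  list(panel = panel$name, n_panel_genes = length(shared),
       cosine_similarity_panel = cs_panel,
       cosine_similarity_all_genes = cs_all,
       pca_distance_graft = d_graft, pca_distance_host = d_host,
       pca_distance_between = d_between,
       median_panel_deg_graft = median_panel_deg(v1, panel),
       median_panel_deg_host = median_panel_deg(v2, panel),
       pearson_r_panel = pearson_correlation(r1, r2)),
  file.path(outdir, "similarity.json"), auto_unbox = TRUE, digits = NA)
cat("wrote", file.path(outdir, "similarity.json"), "\n")
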