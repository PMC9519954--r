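# gliastate

Transcriptome state-change geometry for grafted neural progenitors and
reactive astrocytes.

## What this is for

When neural progenitor cells (NPC) are transplanted into a CNS lesion
(stroke, spinal cord injury), they differentiate mostly into astroglia; at
the same time host astrocytes proliferate into border-forming, wound-repair
cells. `gliastate` is for asking, quantitatively, whether two such
populations **converge**: it compares the *state change* each population
undergoes — the vector of per-gene log2 fold-changes between its reference
and target conditions — restricted to curated gene panels (healthy
astrocyte, reactivity, EMT, progenitor/proliferation), using cosine
similarity and Euclidean distances in PCA space. It is aimed at
transcriptomics analysts working with bulk (ribosome-pulldown style) and
single-nuclei RNA-seq of neural cell populations.

The package implements the full path from counts to geometry:

* **Differential expression core** — TMM normalization, common-dispersion
  negative-binomial estimation, the exact conditional test
  (two-sided by summing all outcomes with probability ≤ the observed one),
  Benjamini–Hochberg adjustment, DEGs at FDR < 0.01, M–A values, FPKM.
  For gene *g*: counts `y ~ NB(mu, phi)` with `Var = mu + phi mu^2`;
  `M = log2(mean_target / mean_ref)` on normalized means with prior 0.5.
* **Panel curation** — enriched genes by strict log2FC > 2, vote
  thresholding across datasets (e.g. ≥ 5 of 8 lists), panel uniqueness
  reports.
* **State geometry** — state-change vectors, panel restriction,
  `CS = v1·v2 / (|v1||v2|)`, PCA (2–3 components, deterministic signs) with
  distances referenced to a start state, congruent/divergent gene
  classification, median panel DEG summaries, top-k most variable DEGs,
  cluster composition tables, and the stated single-nuclei QC filters
  (mitochondrial genes out; genes in < 200 cells out; cells with < 333
  genes out).
* **Image quantification** — radial/line intensity profiles, trapezoidal
  AUC totals, min-combine (RG2B-style) two-channel colocalization.
* **Synthetic data** — NB count matrices with planted, panel-structured
  log2FC and a complete truth table; state pairs with a *planted angle*
  between their panel vectors (true cosine exactly cos θ); voting lists
  with known sensitivity; lesion images with known border geometry.

## Worked example

The numbered scripts under `analysis/` run the whole study on simulated
data (`Rscript analysis/01_simulate_data.R`, then 02–05). Stage 1 plants
two lineages — an NPC→graft transition and a healthy→reactive astrocyte
transition — whose 2000-gene panel vectors meet at cos(0.567) = 0.843;
stages 2–4 recover it blind:

```
$ Rscript analysis/02_differential_expression.R
npc_graft: dispersion 0.0098, 1635/3000 genes at FDR < 0.01, median |M| 0.41
  M vs planted truth: r = 0.994, RMSE = 0.116
astro_sci: dispersion 0.0102, 1660/3000 genes at FDR < 0.01, median |M| 0.43
  M vs planted truth: r = 0.995, RMSE = 0.114

$ Rscript analysis/04_state_geometry.R
cosine similarity: 0.838 on the 2000-gene panel, 0.833 on all 3000 genes
PCA distances from start state: graft 60.3, host 60.1; between 34.2
congruence labels: congruent-down=305 congruent-up=320 divergent=2 null=1373
```

Reading: both simulated populations moved a comparable distance from their
start states (60.3 vs 60.1 in PCA space) and in nearly the same direction —
panel cosine 0.838 against the planted 0.843, the small shortfall being the
expected noise attenuation of the cosine. Most panel genes with |M| > 1 are
congruently regulated, as constructed. Stage 3 likewise recovers a
429-gene panel by 5-of-8 voting with recall 0.942 against the binomial
prediction 0.944, and stage 5 finds the lesion border peak at r = 58 px
inside the planted 55–67 px annulus.

The same machinery is exposed as functions:

```r
library(gliastate)
design <- synthetic_design(3000, c(pre = 4, post = 4), dispersion = 0.01,
                           library_sizes = 5e6, baseline_log_mean = c(5, 9),
                           seed = 1)
pair <- generate_state_pair(design, planted_convergence(2000, 0.567, seed = 1),
                            magnitudes = c(60, 60))
v1 <- state_change(deg_table(pair$lineage1$counts))
v2 <- state_change(deg_table(pair$lineage2$counts))
cosine_similarity(restrict_to_panel(v1, pair$panel_genes),
                  restrict_to_panel(v2, pair$panel_genes))
#> [1] 0.8374788
```

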