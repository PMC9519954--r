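---
title: "Comparing transcriptional state changes of grafted progenitors and reactive astrocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing transcriptional state changes of grafted progenitors and reactive astrocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliastate)
```

## The scientific question

Neural progenitor cells (NPC) transplanted into central nervous system
lesions — after stroke or spinal cord injury — differentiate mostly into
astroglia, while nearby host astrocytes proliferate and form borders that
wall off the fibrotic lesion core. A natural way to ask whether these two
very different starting populations end up in the *same* transcriptional
place is to compare not their absolute expression profiles but their **state
changes**: the vector of per-gene log2 fold-changes each population
undergoes (NPC before vs after grafting; astrocytes in healthy vs injured
tissue). If both vectors, restricted to a panel of astrocyte-reactivity
genes, point in nearly the same direction, the two populations converged on
a shared wound-repair astroglial program regardless of where they started.

`gliastate` implements that comparison end to end — gene-panel curation,
a two-condition differential-expression core, state-change geometry, the
stated single-nuclei QC filters, and radial-profile image quantification —
together with a synthetic-data generator that plants known fold-changes and
a known angle between two state changes, so every stage can be scored
against ground truth without any external download.

## The model

### Counts

Gene counts are modeled as negative binomial. For gene $g$ in sample $s$ of
condition $c$,

$$ y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi), \qquad
   \mu_{gs} = \frac{L_s}{10^6}\, 2^{\,b_g + e_{gc}}, \qquad
   \mathrm{Var}(y) = \mu + \phi\mu^2 , $$

with library size $L_s$, per-gene baseline $b_g$ (log2 CPM scale),
condition effect $e_{gc}$ (log2 fold-change against the reference
condition) and a **common dispersion** $\phi$ shared across genes. The
common-dispersion parameterization was chosen because it matches the
classic exact-test route the DE core implements; per-gene (tagwise) or
quasi-likelihood dispersion is deliberately out of scope.

### Normalization

Between-sample scaling uses TMM (trimmed mean of M-values): against a
reference sample (the one whose upper-quartile expression is closest to the
mean upper quartile, computed over genes expressed somewhere), gene-wise
log2 ratios of depth-normalized counts are trimmed 30% on M and 5% on A on
each side, averaged with inverse asymptotic-variance weights, and the
resulting factors rescaled to geometric mean 1. FPKM is computed directly
from raw counts and column-sum library sizes, *without* TMM — matching a
spreadsheet-style direct calculation — so `fpkm()` and `cpm()` answer
different questions and are kept separate.

### The exact conditional test

For a two-condition contrast the per-gene p-value is the classic exact
conditional NB test: counts are depth-equalized to the geometric-mean
effective library size ("pseudo-counts", here by direct scaling and
rounding rather than full iterative quantile adjustment — a deliberate
simplification documented here because the two differ slightly at very
small counts), group sums $S_1, S_2$ are formed, and conditional on
$S_1 + S_2 = t$ the two-sided p-value is

$$ p = \sum_{s\,:\,f(s) \le f(S_1)} f(s), $$

where $f$ is the conditional law of the group-1 sum (negative
hypergeometric; binomial when $\phi = 0$). Two-sidedness **sums all
outcomes at most as probable as the one observed** rather than doubling a
one-sided tail; the two conventions differ in ties, and the summation form
is the one whose closed-form toy values are asserted in the tests (e.g.
totals 10 vs 0 under equal libraries at $\phi=0$ give exactly
$2 \cdot 2^{-10}$).

Numerics: the normalizer of $f$ has the closed convolution form
$\mathrm{dnbinom}(t;\, (n_1{+}n_2)/\phi,\, t)$, so full enumeration is only
used for totals up to 2000. For larger totals the contiguous "more probable
than observed" region around the (unimodal) conditional mode is located by
a vectorized binary search and $p = 1 - P(\text{region})$; when that
subtraction would lose precision ($p < 10^{-12}$) the two extreme tails are
summed directly over a window of 12 conditional standard deviations, beyond
which the omitted mass is negligible at double precision. Ties are matched
with a relative tolerance of $10^{-10}$. Dispersion is estimated by
maximizing the summed conditional log-likelihood on the pseudo-counts,
clipped to $[0, 10]$, with a flat-likelihood boundary reported as 0
(Poisson).

Fold-changes are reported as $M = \log_2$ of the ratio of normalized
condition means with a prior count of 0.5 per group (so zeros stay finite),
and abundances as $A$, the average log2 CPM. Multiple testing uses
Benjamini–Hochberg step-up, implemented explicitly because it is part of
the specified core and cross-checked in the tests against both a literal
step-up scan and `p.adjust`. DEGs are genes at **FDR < 0.01**, strictly.

### Gene panels

Panels are curated by **vote thresholding** over per-dataset enriched-gene
lists: a gene enters the panel iff it appears in at least `min_votes` of
the lists (5-of-8 for the healthy-astrocyte panel, 3-of-6 for reactivity in
routine use). Enriched genes are defined by a **strict** log2FC > 2 rule —
a gene at exactly 2 is excluded, a boundary case the tests pin down.
Symbols are whitespace-trimmed and case-normalized (default lowercase)
before matching because source lists mix symbol cases; whether aliases
should additionally be unified is left to the user, and matching is on the
exact normalized symbol. Panel distinctness is summarized as the percentage
of each panel's genes found in no other panel, plus pairwise and triple
intersection counts.

### State-change geometry

A `state_change` is the gene-ordered M vector of one transition. Geometry
operations — cosine similarity, Pearson correlation, PCA, congruence
classification — operate on the **intersection of genes** in a shared
sorted order. Cosine similarity is reported raw in $[-1, 1]$; displays
that describe similarity "on a 0–1 scale" are a presentation convention and
the stored value is never clipped. Because it is genuinely ambiguous
whether such comparisons are best made on fold-change vectors or on
FPKM profiles, both spaces are supported (`space = "logfc"` in the
pipeline default, FPKM columns available from `deg_table()`); neither is
asserted as canonical.

PCA is a column-centered SVD with a deterministic sign convention (the
largest-magnitude loading of each component is positive), 2 or 3 retained
components in routine use, and Euclidean distances measured between sample
scores with one sample as the explicit initial point. Congruence
classification labels each shared gene `congruent-up`, `congruent-down`,
`divergent`, or `null` at a magnitude threshold `min_abs_m` whose default
of 1 (2-fold) is an invented, configurable convention — the qualitative
congruent/divergent contrast (e.g. shared reactivity genes up in both
populations, proliferation genes up in host but down in graft) is robust
to it, and the tests assert the antisymmetry of the rule rather than any
particular threshold.

### Single-nuclei QC and composition

`snqc_filter()` applies, in a fixed single pass: mitochondrial-gene removal
(symbol prefix, default mouse `"mt-"`), then genes detected in fewer than
200 cells, then cells with fewer than 333 detected genes. The order
matters (a cell's detected-gene count is taken *after* gene filtering) and
is fixed, not configurable. Clustering itself (UMAP/Louvain) is published
single-cell tool territory and out of scope; `cluster_composition()`
summarizes, for externally supplied cluster labels, the per-cluster
percentage of cells from each condition.

### Image quantification

`radial_profile()` bins pixels into half-open annuli $[r, r+w)$ by
Euclidean distance from a center, using pixel-center coordinates; empty
annuli are recorded as missing, never zero. Totals are trapezoidal AUCs
with missing bins bridged linearly (and logged). No background subtraction
is applied by default, matching quantification on raw, uncorrected
intensities; colocalization is the min-combine rule — where both channels
exceed their thresholds the colocalized intensity is $\min(a, b)$ — with
thresholds defaulting to 0 and configurable because plugin defaults vary.
The bin width and the definition of the lesion center are explicit
parameters: neither has a canonical value, and the tests show the border
peak is recovered to within one bin for noise up to 10% of contrast.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
study conditions used throughout:

* negative-binomial counts with panel-structured planted log2 fold-changes
  and a complete truth table, so any estimator downstream can be scored;
* baselines drawn log-uniformly over a 2^0–2^12 dynamic range (the data it
  emulates do not report their abundance distribution, so this is a stated
  choice, not an inference);
* off-panel genes receive small independent N(0, 0.1²) log2FC noise so the
  planted panels dominate the geometry; set `offpanel_sd = 0` for clean
  nulls;
* `generate_state_pair()` plants two panel vectors $m_1 u$ and
  $m_2(\cos\theta\, u + \sin\theta\, w)$ with $u \perp w$ orthonormal, so
  the true cosine is exactly $\cos\theta$;
* one global seed feeds named sub-streams (baselines, counts, off-panel
  noise, images), so adding one component does not perturb the others and
  identical designs are bit-identical.

What it does **not** emulate: read-level artifacts (adapter content,
mapping ambiguity), UMI chemistry, ambient RNA, batch structure,
gene-length–dependent biases within a sample, or per-gene dispersion
heterogeneity. Passing the recovery benchmarks therefore shows the
pipeline's statistics are implemented correctly and are mutually
consistent — not that real tissue data are free of those artifacts.

### Benchmark conditions

The planted-convergence benchmark simulates a 2000-gene panel inside 3000
genes, two conditions with 4 replicates each, library size $5\times10^6$,
baselines log-uniform over $2^5$–$2^9$, dispersion 0.01, and planted vector
norms of 60 (per-gene panel |log2FC| around 1.3), with
$\theta = 0.567$ rad so the planted cosine is 0.843. At these depths the
noise-attenuation of the cosine (estimation noise inflates vector norms)
is below 0.01, which is why the recovered value sits just under the
planted one; a ±0.05 recovery tolerance over 20 seeds absorbs it with a
wide margin. Null-control simulations use 5000 genes, 4 vs 4 replicates and
dispersion 0.2 over 50 replicate simulations; vote-recovery uses 8 lists at
sensitivity 0.8 over a 400-gene truth. These problem sizes are the
package's own benchmark choices and are stated here so they can be
reproduced or scaled.

## Degenerate inputs and tie-breaks

* all-zero samples are rejected by TMM; all-zero genes get $p = 1$;
* `top_variable_degs()` breaks variance ties by gene ID, so the all-tied
  case returns the first *k* genes alphabetically — deterministic, not
  meaningful;
* panel restriction errors on an empty intersection rather than returning
  a zero-length vector;
* cosine similarity and Pearson correlation refuse zero-norm and
  zero-variance inputs rather than returning NaN;
* p-values below roughly $10^{-290}$ underflow to 0; FDR calling is
  unaffected.

## Known limitations

The DE core implements exactly one test — the common-dispersion exact
conditional test for two groups — and none of the GLM/quasi-likelihood
machinery needed for covariates or batch terms. The depth equalization is
a scaling approximation to quantile adjustment. The cosine comparison
weights every shared panel gene equally; strongly expressed genes
contribute no more than barely detectable ones beyond their larger M
precision. And the congruence threshold, radial bin width and
colocalization thresholds are conventions with sensible defaults, not
estimated quantities.
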