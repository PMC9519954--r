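#' State-change vector from a DEG table
#'
#' The object compared by all state geometry: the ordered per-gene log2
#' fold-change (M) vector of one transition (reference condition -> target
#' condition), e.g. NPC before vs after grafting. Optionally masked to
#' significant genes only.
#'
#' @param deg_table a two-condition DEG table (see [deg_table()]).
#' @param labels character length 2, `c(reference, target)` display labels.
#' @param fdr_mask optional strict FDR bound; genes at or above it are
#'   dropped.
#' @param source provenance tag (`"bulk"` or a single-nuclei cluster
#'   contrast).
#' @return Object of class `state_change`: named numeric vector of M values
#'   ordered by gene ID, with `labels` and `source` attributes.
#' @export
state_change <- function(deg_table, labels = c("reference", "target"),
                         fdr_mask = NULL, source = "bulk") {
  stopifnot(all(c("gene", "logFC") %in% names(deg_table)))
  tab <- deg_table
  if (!is.null(fdr_mask)) {
    stopifnot("FDR" %in% names(tab))
    tab <- tab[tab$FDR < fdr_mask, , drop = FALSE]
  }
  if (anyDuplicated(tab$gene)) stop("duplicate genes in DEG table")
  v <- stats::setNames(tab$logFC, tab$gene)[order(tab$gene)]
  if (any(!is.finite(v))) stop("non-finite M values in state change")
  structure(v, class = "state_change", labels = labels, source = source)
}

#' @export
print.state_change <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("state_change %s -> %s: %d genes, median M = %.3f\n",
              lab[1], lab[2], length(x), stats::median(unclass(x))))
  invisible(x)
}

as_state_values <- function(v) {
  if (inherits(v, "state_change")) stats::setNames(as.numeric(v), names(v))
  else stats::setNames(as.numeric(v), names(v))
}

#' Restrict a state-change vector to a gene panel
#'
#' @param v a [state_change()] vector (or named numeric).
#' @param panel a `gene_panel` or character vector of symbols.
#' @return The subvector over the panel/vector gene intersection, in panel
#'   order (sorted panel symbols); errors if the intersection is empty.
#' @export
restrict_to_panel <- function(v, panel) {
  genes <- if (inherits(panel, "gene_panel")) panel$genes
           else sort(normalize_symbols(panel))
  vals <- as_state_values(v)
  common <- genes[genes %in% names(vals)]
  if (length(common) == 0) stop("panel does not intersect the vector's genes")
  out <- vals[common]
  attributes(out) <- c(attributes(out),
                       list(class = "state_change",
                            labels = attr(v, "labels") %||% c("?", "?"),
                            source = attr(v, "source") %||% "bulk"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median panel DEG
#'
#' The violin-plot summary statistic: the median log2 fold-change of a
#' state-change vector over a gene panel.
#'
#' @inheritParams restrict_to_panel
#' @return Numeric scalar.
#' @export
median_panel_deg <- function(v, panel) {
  stats::median(as.numeric(restrict_to_panel(v, panel)))
}

#' Top-k most differently regulated genes
#'
#' The k genes whose M values vary most across a set of state-change vectors
#' (population variance across vectors), ties broken by gene ID; k is capped
#' at the shared gene count.
#'
#' @param vectors list of state-change vectors over a common gene set.
#' @param k number of genes (default 2000).
#' @return Character vector of gene IDs, by decreasing variance.
#' @export
top_variable_degs <- function(vectors, k = 2000) {
  stopifnot(length(vectors) >= 2)
  vals <- lapply(vectors, as_state_values)
  genes <- names(vals[[1]])
  for (v in vals[-1])
    if (!identical(sort(names(v)), sort(genes)))
      stop("vectors must share one gene set; intersect first")
  m <- vapply(vals, function(v) v[genes], numeric(length(genes)))
  n <- ncol(m)
  varpop <- rowMeans(m^2) - rowMeans(m)^2   # population variance
  k <- min(k, length(genes))
  genes[order(-varpop, genes)][seq_len(k)]
}

#' Cosine similarity of two state-change vectors
#'
#' `v1 . v2 / (|v1| |v2|)`, computed over the gene intersection in a shared
#' sorted order. The raw signed value in `[-1, 1]` is returned (1 = parallel
#' state changes, 0 = orthogonal).
#'
#' @param v1,v2 state-change vectors (named numeric).
#' @return Numeric scalar in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(a = 1, b = 2, c = 2), c(a = 2, b = 1, c = 2)) # 8/9
#' @export
cosine_similarity <- function(v1, v2) {
  a <- as_state_values(v1); b <- as_state_values(v2)
  common <- sort(intersect(names(a), names(b)))
  if (length(common) == 0) stop("no shared genes")
  a <- a[common]; b <- b[common]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm state-change vector")
  sum(a * b) / (na * nb)
}

#' Pearson correlation of two state-change vectors
#'
#' Sample correlation of M values over the shared genes, e.g. between a
#' single-nuclei cluster contrast and the matching bulk contrast.
#'
#' @param v1,v2 state-change vectors (named numeric).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(v1, v2) {
  a <- as_state_values(v1); b <- as_state_values(v2)
  common <- sort(intersect(names(a), names(b)))
  if (length(common) < 3) stop("need at least 3 shared genes")
  a <- a[common]; b <- b[common]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance state-change vector")
  stats::cor(a, b)
}

#' Principal component analysis of sample profiles
#'
#' Column-centered SVD (via [stats::prcomp()]) with a deterministic sign
#' convention: within each component the loading of largest magnitude is
#' made positive.
#'
#' @param x samples-by-features numeric matrix (e.g. samples x genes of
#'   FPKM or log2FC values).
#' @param n_components number of components to retain (2 or 3 in routine
#'   use).
#' @return Object of class `pca_result`: `scores` (samples x k), `loadings`
#'   (features x k, orthonormal), `explained` (variance fractions,
#'   non-increasing), `center`.
#' @export
pca_states <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two samples")
  if (any(!is.finite(x))) stop("features must be finite")
  k <- min(n_components, nrow(x) - 1, ncol(x))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    l <- pr$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pr$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pr$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained = expl[seq_len(k)], center = pr$center),
            class = "pca_result")
}

#' Euclidean distance between two samples in PCA space
#'
#' The vector magnitude in PCA space of one sample referenced to another as
#' the initial point, over the retained components.
#'
#' @param result a [pca_states()] result.
#' @param sample_a,sample_b row names (or indices) of the two samples;
#'   `sample_b` is the initial point.
#' @return Non-negative numeric scalar.
#' @export
pca_distance <- function(result, sample_a, sample_b) {
  stopifnot(inherits(result, "pca_result"))
  s <- result$scores
  for (id in list(sample_a, sample_b))
    if (is.character(id) && !id %in% rownames(s))
      stop("unknown sample ID: ", id)
  sqrt(sum((s[sample_a, ] - s[sample_b, ])^2))
}

#' Classify congruent vs divergent regulation
#'
#' Per-gene comparison of two state changes (e.g. grafted NPC vs host
#' astrocytes): `congruent-up` if both M exceed `min_abs_m`,
#' `congruent-down` if both fall below `-min_abs_m`, `divergent` if the
#' signs differ and both magnitudes exceed the threshold, otherwise `null`.
#'
#' @param v_npc,v_host state-change vectors (named numeric).
#' @param min_abs_m magnitude threshold on M (default 1, i.e. 2-fold).
#' @return Named character vector of labels over the shared genes.
#' @export
congruence_classify <- function(v_npc, v_host, min_abs_m = 1) {
  a <- as_state_values(v_npc); b <- as_state_values(v_host)
  common <- sort(intersect(names(a), names(b)))
  if (length(common) == 0) stop("no shared genes")
  a <- a[common]; b <- b[common]
  lab <- rep("null", length(common))
  lab[a > min_abs_m & b > min_abs_m] <- "congruent-up"
  lab[a < -min_abs_m & b < -min_abs_m] <- "congruent-down"
  lab[abs(a) > min_abs_m & abs(b) > min_abs_m & sign(a) != sign(b)] <-
    "divergent"
  stats::setNames(lab, common)
}

#' Cluster composition by condition
#'
#' Counts and within-cluster percentages of cells from each condition, as
#' used to summarize which conditions populate each single-nuclei cluster.
#'
#' @param cluster_labels cluster ID per cell.
#' @param condition_labels condition per cell (same length).
#' @return Data.frame with columns `cluster`, `condition`, `n`, `percent`;
#'   percentages sum to 100 within each cluster.
#' @export
cluster_composition <- function(cluster_labels, condition_labels) {
  if (length(cluster_labels) != length(condition_labels))
    stop("label vectors must have equal length")
  tab <- table(cluster = cluster_labels, condition = condition_labels)
  df <- as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  tot <- rowSums(tab)
  df$percent <- 100 * df$n / tot[df$cluster]
  df[order(df$cluster, df$condition), , drop = FALSE]
}
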