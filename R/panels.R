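#' Enriched genes from a DEG table
#'
#' The enrichment rule of gene-panel curation: genes whose log2 fold-change
#' strictly exceeds `lfc_threshold` (default 2), optionally also requiring a
#' strict FDR bound. Output is order-stable: descending M, ties by symbol.
#'
#' @param deg_table data.frame with columns `gene` and `logFC` (and `FDR`
#'   when `fdr_cutoff` is used).
#' @param lfc_threshold strict lower bound on log2FC (default 2; a gene at
#'   exactly the threshold is excluded).
#' @param fdr_cutoff optional strict FDR bound applied on top.
#' @return Character vector of enriched gene symbols.
#' @examples
#' tab <- data.frame(gene = c("a", "b", "c"), logFC = c(2.5, 2, 1.9))
#' derive_enriched_genes(tab)   # only "a": strict inequality
#' @export
derive_enriched_genes <- function(deg_table, lfc_threshold = 2,
                                  fdr_cutoff = NULL) {
  if (nrow(deg_table) == 0) stop("empty DEG table")
  stopifnot(all(c("gene", "logFC") %in% names(deg_table)))
  keep <- deg_table$logFC > lfc_threshold
  if (!is.null(fdr_cutoff)) {
    stopifnot("FDR" %in% names(deg_table))
    keep <- keep & deg_table$FDR < fdr_cutoff
  }
  hits <- deg_table[keep, , drop = FALSE]
  hits$gene[order(-hits$logFC, hits$gene)]
}

normalize_symbols <- function(genes, case = c("lower", "upper", "asis")) {
  case <- match.arg(case)
  g <- trimws(genes)
  switch(case, lower = tolower(g), upper = toupper(g), asis = g)
}

#' Curate a gene panel by vote thresholding
#'
#' A gene enters the panel iff it appears in at least `min_votes` of the
#' source lists (set semantics: duplicates within one list count once).
#' Symbols are whitespace-trimmed and case-normalized before matching, since
#' lists from heterogeneous sources mix symbol cases.
#'
#' @param lists list of character vectors, one enriched-gene list per source
#'   dataset.
#' @param min_votes minimum number of source lists (in `[1, length(lists)]`),
#'   e.g. 5 of 8 for the healthy-astrocyte panel or 3 of 6 for reactivity.
#' @param name panel name.
#' @param case symbol case normalization (`"lower"`, `"upper"`, `"asis"`).
#' @return Object of class `gene_panel`: `name`, sorted `genes`, per-gene
#'   `votes`, `n_sources`, `min_votes`.
#' @examples
#' vote_panel(list(c("A", "B"), c("B", "C"), "B"), min_votes = 2)
#' @export
vote_panel <- function(lists, min_votes, name = "panel", case = "lower") {
  if (length(lists) == 0) stop("empty list collection")
  if (min_votes < 1 || min_votes > length(lists))
    stop("min_votes must lie in [1, number of lists]")
  sets <- lapply(lists, function(l) unique(normalize_symbols(l, case)))
  votes <- table(unlist(sets))
  keep <- votes[votes >= min_votes]
  genes <- sort(names(keep))
  structure(list(name = name,
                 genes = genes,
                 votes = stats::setNames(as.integer(keep[genes]), genes),
                 n_sources = length(lists),
                 min_votes = as.integer(min_votes)),
            class = "gene_panel")
}

#' Build a gene panel directly from symbols
#'
#' For panels adopted from external curation (e.g. an EMT signature) rather
#' than derived by voting here.
#'
#' @param genes character vector of symbols.
#' @param name panel name.
#' @param votes optional named integer vote counts.
#' @param case symbol case normalization.
#' @return A `gene_panel`.
#' @export
gene_panel <- function(genes, name = "panel", votes = NULL, case = "lower") {
  g <- unique(normalize_symbols(genes, case))
  if (length(g) < length(genes))
    warning("duplicate symbols collapsed in panel '", name, "'")
  g <- sort(g)
  if (is.null(votes)) votes <- stats::setNames(rep(1L, length(g)), g)
  else votes <- stats::setNames(as.integer(votes[g]), g)
  structure(list(name = name, genes = g, votes = votes,
                 n_sources = max(votes, 1L), min_votes = 1L),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel '%s': %d genes (>= %d of %d lists)\n",
              x$name, length(x$genes), x$min_votes, x$n_sources))
  invisible(x)
}

#' @export
length.gene_panel <- function(x) length(x$genes)

#' Panel distinctness report
#'
#' For each panel, the percentage of its genes found in no other panel, plus
#' all pairwise intersection counts (and the triple intersection for three
#' panels) — the bookkeeping behind "each gene panel having at least 85%
#' unique genes".
#'
#' @param panels list of `gene_panel` objects (>= 2).
#' @return List with `unique_fraction` (named percentages), `sizes`,
#'   `pairwise` (symmetric intersection-count matrix) and `triple`
#'   (intersection count across all panels, `NA` unless >= 3 panels).
#' @export
panel_uniqueness <- function(panels) {
  if (length(panels) < 2) stop("need at least two panels")
  sets <- lapply(panels, function(p) {
    stopifnot(inherits(p, "gene_panel"))
    if (length(p$genes) == 0) stop("empty panel: ", p$name)
    p$genes
  })
  names(sets) <- vapply(panels, `[[`, character(1), "name")
  k <- length(sets)
  uniq <- vapply(seq_len(k), function(i) {
    others <- unique(unlist(sets[-i]))
    100 * length(setdiff(sets[[i]], others)) / length(sets[[i]])
  }, numeric(1))
  pw <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  triple <- if (k >= 3) length(Reduce(intersect, sets)) else NA_integer_
  list(unique_fraction = stats::setNames(uniq, names(sets)),
       sizes = vapply(sets, length, integer(1)),
       pairwise = pw, triple = triple)
}

#' Read / write gene panels
#'
#' Panels are stored as newline-delimited symbols or as two-column TSV
#' (symbol, votes). Reading trims whitespace, case-normalizes, collapses
#' duplicates with a warning, and reports malformed lines by number;
#' write-then-read round-trips to an identical panel.
#'
#' @param path file path.
#' @param name panel name (defaults to the file name).
#' @param case symbol case normalization.
#' @return `read_panel` returns a `gene_panel`; `write_panel` its path,
#'   invisibly.
#' @export
read_panel <- function(path, name = NULL, case = "lower") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty panel file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf > 2))
    stop("malformed panel lines (more than 2 fields): ",
         paste(which(nf > 2), collapse = ", "))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  syms <- vapply(parts, `[[`, character(1), 1)
  if (all(nf == 2)) {
    v <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2)))
    if (anyNA(v))
      stop("malformed vote counts on lines: ",
           paste(which(is.na(v)), collapse = ", "))
    syms <- normalize_symbols(syms, case)
    if (anyDuplicated(syms)) {
      warning("duplicate symbols in ", path, "; keeping first votes")
      v <- v[!duplicated(syms)]; syms <- unique(syms)
    }
    gene_panel(syms, name = name, votes = stats::setNames(v, syms),
               case = "asis")
  } else {
    gene_panel(syms, name = name, case = case)
  }
}

#' @rdname read_panel
#' @param panel a `gene_panel`.
#' @param with_votes write the two-column TSV form.
#' @export
write_panel <- function(panel, path, with_votes = TRUE) {
  stopifnot(inherits(panel, "gene_panel"))
  if (with_votes) {
    utils::write.table(
      data.frame(gene = panel$genes, votes = panel$votes[panel$genes]),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(panel$genes, path)
  }
  invisible(path)
}
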