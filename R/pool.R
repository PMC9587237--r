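#' Annotation-term overlap between a gene and a target set
#'
#' Measures biological similarity as the number of annotation terms (e.g.
#' GO identifiers) that a gene shares with the union of the target set's
#' terms, and that count as a fraction of the target term union. Genes
#' absent from the annotation have an empty term set and overlap 0.
#'
#' @param gene A single gene identifier.
#' @param target A [gene_set] (or character vector): the target signature.
#' @param annotation Named list of term vectors, as from
#'   [read_annotation()].
#' @return Named numeric vector with elements `count` and `fraction`
#'   (`fraction` is 0 when the target has no annotated terms).
#' @examples
#' ann <- list(g1 = c("GO:1", "GO:2"), t1 = c("GO:2", "GO:3"))
#' go_overlap("g1", gene_set("t1"), ann)
#' @export
go_overlap <- function(gene, target, annotation) {
  stopifnot(is.character(gene), length(gene) == 1L)
  target_terms <- annotation_terms(annotation, target)
  gene_terms <- annotation_terms(annotation, gene)
  count <- length(intersect(gene_terms, target_terms))
  fraction <- if (length(target_terms)) count / length(target_terms) else 0
  c(count = count, fraction = fraction)
}

# Vectorized shared-term counts against a fixed target term union.
overlap_counts <- function(genes, target_terms, annotation) {
  if (!length(target_terms)) return(setNames(integer(length(genes)), genes))
  counts <- integer(length(genes))
  hit <- match(genes, names(annotation))
  ok <- !is.na(hit)
  counts[ok] <- vapply(annotation[hit[ok]],
                       function(tt) sum(tt %in% target_terms), integer(1L))
  setNames(counts, genes)
}

#' Build the stratified surrogate gene-pool ladder
#'
#' Constructs nested gene pools of increasing stringency from which
#' surrogate signatures are drawn. Level 0 removes the proliferation genes
#' `G_p` and the target genes `G_t` from the gene universe `G`
#' (`G_L0 = G \ (G_p U G_t)`); each subsequent level additionally removes
#' the stratum of genes whose annotation-term overlap with the target
#' exceeds that level's threshold, so level `i` holds
#' `G_Li = G \ (G_p U G_t U G_1 U ... U G_i)`. A final threshold of 0
#' leaves only genes with no shared terms at all — the most stringent
#' pool, supporting the severest test.
#'
#' Genes belonging to both `G_p` and `G_t` are removed once and attributed
#' to `G_t` in the provenance. Target genes absent from the universe are
#' ignored with a warning (they carry no expression information).
#'
#' @param universe [gene_set] or character vector: all genes for which data
#'   are available (typically `rownames()` of the expression matrix).
#' @param proliferation [gene_set] or character vector of proliferation
#'   genes to filter out, or `NULL` for none.
#' @param target [gene_set]: the target signature.
#' @param annotation Named list of term vectors; may be empty, in which
#'   case all overlaps are 0.
#' @param thresholds Strictly decreasing integer vector of maximum allowed
#'   shared-term counts, one per stringency level beyond level 0. Use
#'   `numeric(0)` for the unstratified pool only.
#' @return An object of class `"gene_pool"`: a list of levels, each of
#'   class `"gene_pool_level"` with fields `level`, `genes`, `threshold`
#'   (`NA` for level 0), and `removed` (provenance: `G_p`, `G_t`, then one
#'   stratum per level).
#' @examples
#' ann <- list(t1 = "GO:1", g3 = "GO:1")
#' build_pool_levels(paste0("g", 1:6), proliferation = "g1",
#'                   target = gene_set("t1"), annotation = ann,
#'                   thresholds = 0)
#' @export
build_pool_levels <- function(universe, proliferation = NULL, target,
                              annotation = list(), thresholds = c(1, 0)) {
  universe <- as_gene_ids(universe)
  target_ids <- as_gene_ids(target)
  prolif_ids <- if (is.null(proliferation)) character(0)
                else as_gene_ids(proliferation)
  if (length(thresholds) > 1L && any(diff(thresholds) >= 0))
    stop("'thresholds' must be strictly decreasing")
  if (any(thresholds < 0)) stop("'thresholds' must be non-negative")

  missing_t <- setdiff(target_ids, universe)
  if (length(missing_t))
    warning(sprintf("%d target gene(s) absent from the universe are ignored: %s",
                    length(missing_t),
                    paste(utils::head(missing_t, 5L), collapse = ", ")))

  removed <- list(G_t = intersect(universe, target_ids),
                  G_p = setdiff(intersect(universe, prolif_ids), target_ids))
  level0 <- setdiff(universe, union(target_ids, prolif_ids))
  if (!length(level0))
    stop("gene pool is empty at level 0 after removing proliferation and target genes")

  levels <- list(structure(
    list(level = 0L, genes = level0, threshold = NA_real_, removed = removed),
    class = "gene_pool_level"))

  if (length(thresholds)) {
    target_terms <- annotation_terms(annotation, target_ids)
    counts <- overlap_counts(level0, target_terms, annotation)
    current <- level0
    for (i in seq_along(thresholds)) {
      stratum <- current[counts[current] > thresholds[i]]
      current <- setdiff(current, stratum)
      if (!length(current))
        stop(sprintf("gene pool is empty at level %d (threshold %g)",
                     i, thresholds[i]))
      removed[[sprintf("G_%d", i)]] <- stratum
      levels[[i + 1L]] <- structure(
        list(level = i, genes = current, threshold = thresholds[i],
             removed = removed),
        class = "gene_pool_level")
    }
  }
  structure(levels, class = "gene_pool")
}

#' @export
print.gene_pool_level <- function(x, ...) {
  thr <- if (is.na(x$threshold)) "none (proliferation/target removal only)"
         else sprintf("shared-term count <= %g", x$threshold)
  cat(sprintf("Gene pool level %d: %d genes (constraint: %s)\n",
              x$level, length(x$genes), thr))
  rem <- vapply(x$removed, length, integer(1L))
  cat("  removed so far:",
      paste(sprintf("%s=%d", names(rem), rem), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.gene_pool <- function(x, ...) {
  cat(sprintf("Stratified surrogate gene pool (%d level%s)\n",
              length(x), if (length(x) == 1L) "" else "s"))
  for (lv in x) print(lv)
  invisible(x)
}

#' Number of possible surrogate signatures, on the log10 scale
#'
#' Computes `log10(choose(n, k))` through log-gamma, so genome-scale pools
#' pose no overflow problem. For realistic pools the count is
#' astronomically large, which is why surrogate draws are treated as
#' independent samples rather than enumerated.
#'
#' @param pool_size Pool size `n` (non-negative integer).
#' @param signature_size Signature size `k`, with `0 <= k <= n`.
#' @return `log10` of the binomial coefficient `C(n, k)`.
#' @examples
#' log10_surrogate_count(20000, 50)
#' @export
log10_surrogate_count <- function(pool_size, signature_size) {
  n <- pool_size
  k <- signature_size
  if (any(n < 0) || any(k < 0)) stop("sizes must be non-negative")
  if (any(k > n))
    stop("signature size exceeds pool size (k > n)")
  (lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)) / log(10)
}
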