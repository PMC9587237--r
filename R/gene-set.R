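#' Construct a gene set
#'
#' A gene set is a named, ordered collection of unique gene identifiers.
#' Identifiers are opaque, case-sensitive strings; no symbol or accession
#' mapping is attempted. Duplicates are removed, keeping the first
#' occurrence.
#'
#' @param genes Character vector of gene identifiers (at least one).
#' @param name Non-empty label for the set.
#' @return An object of class `"gene_set"`: a list with elements `name`
#'   and `genes`.
#' @examples
#' gene_set(c("TP53", "BRCA1"), name = "example")
#' @export
gene_set <- function(genes, name = "gene_set") {
  if (!is.character(genes)) genes <- as.character(genes)
  genes <- genes[!is.na(genes) & nzchar(genes)]
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0L)
    stop("a gene set must contain at least one gene identifier")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d genes\n", x$name, length(x$genes)))
  shown <- utils::head(x$genes, 8L)
  cat(" ", paste(shown, collapse = ", "),
      if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' @export
as.character.gene_set <- function(x, ...) x$genes

# Accept either a gene_set or a bare character vector of identifiers.
as_gene_ids <- function(x) {
  if (inherits(x, "gene_set")) x$genes
  else if (is.character(x)) unique(x)
  else stop("expected a gene_set or a character vector of gene identifiers")
}
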