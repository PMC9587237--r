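#' Read a gene-by-sample expression matrix
#'
#' Expects a delimited text file with a header row of sample identifiers and
#' gene identifiers in the first column. Expression values are assumed to be
#' already normalized; no transformation is applied on load.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (tab-separated, default) or `"csv"`.
#' @return A numeric matrix (genes in rows, samples in columns) with unique
#'   row and column names.
#' @seealso [write_expression()], [read_survival()], [align_samples()]
#' @export
read_expression <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 3L || nrow(df) < 2L)
    stop("expression file needs >= 2 genes and >= 2 samples: ", path)
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "))
  samples <- colnames(df)[-1L]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup))
    stop("duplicate sample identifiers in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric or non-finite expression value at gene '%s', sample '%s' in %s",
      ids[bad[1L, 1L]], samples[bad[1L, 2L]], path))
  }
  dimnames(vals) <- list(ids, samples)
  validate_expression(vals)
}

#' Validate an expression matrix
#'
#' Checks the container invariants: numeric matrix, unique non-empty row and
#' column names, all values finite, at least 2 genes and 2 samples.
#'
#' @param x Candidate matrix.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene row names and sample column names")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers in expression matrix")
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values")
  x
}

#' Write an expression matrix
#'
#' @param x Numeric gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_expression(x)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample survival table
#'
#' Expects a header plus three columns: sample identifier, non-negative
#' follow-up time (any consistent unit), and event indicator (1 = event
#' observed, 0 = censored).
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with columns `sample`, `time`, `event`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("survival file needs columns sample, time, event: ", path)
  out <- data.frame(sample = as.character(df[[1L]]),
                    time = as.numeric(df[[2L]]),
                    event = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  validate_survival(out)
}

#' Validate a survival table
#'
#' @param x Candidate `data.frame` with columns `sample`, `time`, `event`.
#' @return `x` if valid, else an error. Requires unique sample identifiers,
#'   `time >= 0`, `event` in \{0, 1\}, and at least one observed event.
#' @export
validate_survival <- function(x) {
  if (!is.data.frame(x) || !all(c("sample", "time", "event") %in% names(x)))
    stop("survival table needs columns sample, time, event")
  if (anyDuplicated(x$sample))
    stop("duplicate sample identifiers in survival table")
  if (anyNA(x$time) || any(x$time < 0))
    stop("survival times must be non-negative and non-missing")
  if (anyNA(x$event) || !all(x$event %in% c(0L, 1L)))
    stop("event indicator must be 0 (censored) or 1 (event)")
  if (sum(x$event) < 1L)
    stop("survival table contains no observed events")
  x
}

#' Write a survival table
#'
#' @param x Survival `data.frame` (columns `sample`, `time`, `event`).
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_survival <- function(x, path) {
  validate_survival(x)
  utils::write.table(x[c("sample", "time", "event")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' The description field is discarded. Duplicate genes within a line are
#' removed with a warning.
#'
#' @param path Path to the GMT file.
#' @return A list of [gene_set] objects, in file order. An empty file gives
#'   an empty list.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d of %s: expected >= 3 tab-separated fields",
                   i, path))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes))
      warning(sprintf("duplicate genes in GMT set '%s' (line %d) removed",
                      fields[1L], i))
    out[[i]] <- gene_set(genes, name = fields[1L])
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set] or a list of them.
#' @param path Output path.
#' @param description Description field written for every set (GMT column 2).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-to-term annotation map
#'
#' Expects two tab-separated columns, gene and term, one pair per line
#' (a reduction of GAF-style annotation files). Repeated gene rows
#' accumulate terms; repeated identical pairs are collapsed.
#'
#' @param path Path to the file.
#' @return A named list mapping each annotated gene to a character vector of
#'   term identifiers. Look up unannotated genes with [annotation_terms()],
#'   which returns an empty vector for them.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop(sprintf("annotation parse error at line %d of %s: expected 2 tab-separated fields",
                 which(keep)[which(nf != 2L)[1L]], path))
  gene <- vapply(parts, `[[`, character(1L), 1L)
  term <- vapply(parts, `[[`, character(1L), 2L)
  lapply(split(term, factor(gene, levels = unique(gene))), unique)
}

#' Write an annotation map
#'
#' @param annotation Named list of term vectors, as from [read_annotation()].
#' @param path Output path (two-column TSV).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  gene <- rep(names(annotation), lengths(annotation))
  term <- unlist(annotation, use.names = FALSE)
  writeLines(if (length(gene)) paste(gene, term, sep = "\t") else character(0),
             path)
  invisible(path)
}

#' Look up annotation terms for genes
#'
#' @param annotation Named list of term vectors.
#' @param genes Character vector of gene identifiers (or a [gene_set]).
#' @return Character vector: the union of terms annotated to `genes`.
#'   Unannotated genes contribute nothing; the result may be empty.
#' @export
annotation_terms <- function(annotation, genes) {
  genes <- as_gene_ids(genes)
  found <- intersect(genes, names(annotation))
  if (!length(found)) return(character(0))
  unique(unlist(annotation[found], use.names = FALSE))
}

#' Align an expression matrix and a survival table on shared samples
#'
#' Samples present in one input but not the other are dropped with a
#' message; the intersection keeps the expression matrix's column order.
#'
#' @param expression Gene-by-sample numeric matrix.
#' @param survival Survival `data.frame` (columns `sample`, `time`, `event`).
#' @return A list with the aligned `expression` and `survival`, columns of
#'   the former matching rows of the latter one-to-one.
#' @export
align_samples <- function(expression, survival) {
  validate_expression(expression)
  validate_survival(survival)
  shared <- intersect(colnames(expression), survival$sample)
  if (length(shared) < 2L)
    stop("fewer than 2 samples shared between expression and survival data")
  d_expr <- ncol(expression) - length(shared)
  d_surv <- nrow(survival) - length(shared)
  if (d_expr || d_surv)
    message(sprintf("align_samples: dropped %d expression-only and %d survival-only samples",
                    d_expr, d_surv))
  surv <- survival[match(shared, survival$sample), , drop = FALSE]
  rownames(surv) <- NULL
  if (sum(surv$event) < 1L)
    stop("no observed events remain after sample alignment")
  list(expression = expression[, shared, drop = FALSE],
       survival = validate_survival(surv))
}
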