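#' Draw surrogate gene sets from a pool
#'
#' Each draw is a uniform sample of `k` genes from the pool, without
#' replacement within a draw and independently across draws (a set may
#' recur; with genome-scale pools the number of possible sets is
#' astronomical, so collisions are negligible and independence keeps the
#' surrogate null exact). Fully reproducible from `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param pool A `"gene_pool_level"` (from [build_pool_levels()]) or a
#'   character vector of pool genes.
#' @param k Signature size; every surrogate has exactly `k` genes, matching
#'   the target signature's size.
#' @param n_draws Number of surrogate sets to draw.
#' @param seed Integer RNG seed.
#' @return An object of class `"surrogate_draws"`: list with `pool_level`,
#'   `k`, `n_draws`, `seed`, and `sets` (a list of [gene_set] objects).
#' @export
sample_surrogates <- function(pool, k, n_draws, seed = 1L) {
  genes <- pool_genes(pool)
  level <- pool_level_of(pool)
  if (n_draws < 1L) stop("'n_draws' must be at least 1")
  if (k < 1L) stop("'k' must be at least 1")
  if (k > length(genes))
    stop(sprintf("signature size k = %d exceeds the %d genes of pool level %s",
                 k, length(genes), format(level)))
  sets <- with_seed(seed, {
    lapply(seq_len(n_draws), function(b) {
      gene_set(sample(genes, k), name = sprintf("surrogate_%05d", b))
    })
  })
  structure(list(pool_level = level, k = k, n_draws = n_draws,
                 seed = seed, sets = sets),
            class = "surrogate_draws")
}

#' @export
print.surrogate_draws <- function(x, ...) {
  cat(sprintf("%d surrogate draws of %d genes from pool level %s (seed %d)\n",
              x$n_draws, x$k, format(x$pool_level), x$seed))
  invisible(x)
}

pool_genes <- function(pool) {
  if (inherits(pool, "gene_pool")) pool[[length(pool)]]$genes
  else if (inherits(pool, "gene_pool_level")) pool$genes
  else as_gene_ids(pool)
}

pool_level_of <- function(pool) {
  if (inherits(pool, "gene_pool")) pool[[length(pool)]]$level
  else if (inherits(pool, "gene_pool_level")) pool$level
  else NA_integer_
}

#' Severe test of a gene signature by surrogate resampling
#'
#' Challenges the claim that a target signature's predictive results are
#' specific to its genes. The identical evaluation method is applied to
#' the target set and to `n_draws` same-size surrogate sets drawn
#' uniformly from a stratified gene pool (which contains neither the
#' target genes, proliferation genes, nor — at stringent levels — genes
#' sharing annotation terms with the target). The hypothesis under test,
#' ST, states that target results and surrogate results are *not* the
#' same.
#'
#' The target's standing among the surrogates is summarized by an
#' empirical p-value with the add-one correction,
#' `(1 + #surrogates at least as good) / (1 + n_draws)`, so certainty is
#' never claimed from a finite number of draws. "At least as good" is
#' metric-aware: smaller-or-equal for `logrank_p`, greater-or-equal for
#' `logrank_stat` and `concordance`. If the empirical p-value exceeds
#' `alpha`, ST is rejected: random same-size sets with no designed
#' biological relation to the target reproduce its results, the surrogate
#' sets are interchangeable with the signature, and the signature's
#' biological interpretation is falsified. If the empirical p-value is at
#' most `alpha`, ST is retained: the target outperforms what the pool
#' offers by chance.
#'
#' @param expression Gene-by-sample numeric matrix.
#' @param survival Survival `data.frame` (columns `sample`, `time`,
#'   `event`); aligned with the expression columns by identifier.
#' @param target [gene_set]: the signature under scrutiny. Must be
#'   disjoint from the pool.
#' @param pool `"gene_pool_level"`, `"gene_pool"` (its most stringent
#'   level is used), or character vector of pool genes.
#' @param metric Evaluation metric, as in [evaluate_signature()].
#' @param n_draws Number of surrogate draws `B` (default 999).
#' @param alpha Decision threshold for the empirical p-value.
#' @param seed Integer seed governing the surrogate draws.
#' @return An object of class `"severe_test"`; see Details. Key fields:
#'   `target_result` (a `"signature_eval"`), `surrogate_values` (numeric
#'   vector of length `n_draws`), `empirical_p`, `matching_fraction`,
#'   `decision` (`"ST_rejected"` or `"ST_retained"`), `interpretation`,
#'   and `provenance`.
#' @examples
#' d <- generate_dataset(stf_scenario("specific", n_genes = 300,
#'                                    n_samples = 80, target_size = 10,
#'                                    seed = 7))
#' pool <- build_pool_levels(rownames(d$expression), d$proliferation,
#'                           d$target, d$annotation, thresholds = 0)
#' severe_test(d$expression, d$survival, d$target, pool,
#'             n_draws = 99, seed = 7)
#' @export
severe_test <- function(expression, survival, target, pool,
                        metric = c("logrank_p", "logrank_stat",
                                   "concordance"),
                        n_draws = 999L, alpha = 0.05, seed = 1L) {
  metric <- match.arg(metric)
  if (!inherits(target, "gene_set")) target <- gene_set(target, "target")
  p_genes <- pool_genes(pool)
  clash <- intersect(target$genes, p_genes)
  if (length(clash))
    stop(sprintf("target and pool are not disjoint (%d shared genes, e.g. %s)",
                 length(clash), clash[1L]))
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")

  aligned <- suppressMessages(align_samples(expression, survival))
  expr <- aligned$expression
  surv <- aligned$survival
  p_genes <- intersect(p_genes, rownames(expr))
  if (length(p_genes) < length(target$genes))
    stop("pool has fewer genes with expression data than the target size")

  # The engine evaluates target and surrogates through this single closure:
  # no branch may know which kind of set it is scoring.
  o <- order(surv$time)
  time_s <- surv$time[o]; event_s <- surv$event[o]
  Z <- standardize_rows(expr)
  pairs <- if (metric == "concordance")
    comparable_pairs(surv$time, surv$event) else NULL
  eval_one <- function(ids) {
    score <- colMeans(Z[ids, , drop = FALSE])
    if (metric == "concordance") {
      if (!length(pairs$i)) stop("no comparable sample pairs")
      return(concordance_from_pairs(score, pairs))
    }
    grp <- dichotomize(score)
    core <- logrank_core((grp == "high")[o], time_s, event_s)
    if (core[["variance"]] <= 0) stop("log-rank variance is zero")
    stat <- core[["o_minus_e"]]^2 / core[["variance"]]
    if (metric == "logrank_p")
      stats::pchisq(stat, df = 1L, lower.tail = FALSE) else stat
  }

  target_value <- eval_one(intersect(target$genes, rownames(expr)))
  target_result <- evaluate_signature(expr, surv, target, metric)
  stopifnot(isTRUE(all.equal(target_value, target_result$value)))

  draws <- sample_surrogates(pool, k = length(target$genes),
                             n_draws = n_draws, seed = seed)
  surrogate_values <- numeric(n_draws)
  for (b in seq_len(n_draws)) {
    surrogate_values[b] <- tryCatch(
      eval_one(draws$sets[[b]]$genes),
      error = function(e) {
        stop(sprintf("surrogate draw %d (seed %d) failed: %s",
                     b, seed, conditionMessage(e)), call. = FALSE)
      })
  }

  n_good <- sum(at_least_as_good(metric, surrogate_values, target_value))
  empirical_p <- (1 + n_good) / (1 + n_draws)
  matching_fraction <- n_good / n_draws
  decision <- if (empirical_p <= alpha) "ST_retained" else "ST_rejected"
  interpretation <- if (decision == "ST_rejected") {
    paste0("Hypothesis ST is rejected: random surrogate gene sets from the ",
           "pool reproduce the target signature's results (empirical p = ",
           signif(empirical_p, 3), " > alpha = ", alpha, "). The surrogate ",
           "sets are interchangeable with the signature, so its claimed ",
           "biological specificity is falsified.")
  } else {
    paste0("Hypothesis ST is retained: the target signature outperforms ",
           "random surrogate gene sets (empirical p = ",
           signif(empirical_p, 3), " <= alpha = ", alpha, "). Its results ",
           "are not reproduced by chance draws from the pool.")
  }

  structure(list(
    target_result = target_result,
    surrogate_values = surrogate_values,
    empirical_p = empirical_p,
    matching_fraction = matching_fraction,
    decision = decision,
    alpha = alpha,
    comparison = if (metric == "logrank_p") "surrogate <= target"
                 else "surrogate >= target",
    interpretation = interpretation,
    provenance = list(pool_level = pool_level_of(pool),
                      pool_size = length(p_genes),
                      k = length(target$genes),
                      n_draws = n_draws, seed = seed, metric = metric,
                      n_samples = nrow(surv), n_events = sum(surv$event),
                      package_version =
                        as.character(utils::packageVersion("severetest")))),
    class = "severe_test")
}

#' @export
print.severe_test <- function(x, ...) {
  pv <- x$provenance
  cat("Severe test of gene signature '", x$target_result$gene_set_name,
      "'\n", sep = "")
  cat(sprintf("  method: mean-z score, %s; %d surrogate draws of %d genes from pool level %s (seed %d)\n",
              pv$metric, pv$n_draws, pv$k, format(pv$pool_level), pv$seed))
  cat(sprintf("  target %s = %.4g; surrogates at least as good: %d/%d\n",
              pv$metric, x$target_result$value,
              round(x$matching_fraction * pv$n_draws), pv$n_draws))
  cat(sprintf("  empirical p = %.4g (alpha = %g) -> %s\n",
              x$empirical_p, x$alpha, x$decision))
  cat("  ", strwrap(x$interpretation, width = 70, exdent = 2)[1L], "...\n",
      sep = "")
  invisible(x)
}

#' @export
summary.severe_test <- function(object, ...) {
  qs <- stats::quantile(object$surrogate_values,
                        c(0.025, 0.25, 0.5, 0.75, 0.975))
  out <- list(test = object, surrogate_quantiles = qs)
  class(out) <- "summary.severe_test"
  out
}

#' @export
print.summary.severe_test <- function(x, ...) {
  print(x$test)
  cat("  surrogate metric distribution:\n")
  print(signif(x$surrogate_quantiles, 4))
  cat("\n")
  cat(strwrap(x$test$interpretation, width = 78, prefix = "  "), sep = "\n")
  invisible(x)
}

#' Plot the surrogate null distribution of a severe test
#'
#' Histogram of the surrogate metric values with the target's value marked
#' by a vertical line. For `logrank_p` the axis is `-log10(p)`.
#'
#' @param x A `"severe_test"` object.
#' @param ... Further arguments passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.severe_test <- function(x, ...) {
  metric <- x$provenance$metric
  sv <- x$surrogate_values
  tv <- x$target_result$value
  lab <- metric
  if (metric == "logrank_p") {
    sv <- -log10(sv); tv <- -log10(tv); lab <- "-log10(log-rank p)"
  }
  graphics::hist(sv, breaks = 30, col = "grey85", border = "grey40",
                 main = sprintf("Surrogate null (%d draws): %s",
                                length(sv), x$decision),
                 xlab = lab,
                 xlim = range(c(sv, tv)), ...)
  graphics::abline(v = tv, col = "firebrick", lwd = 2)
  graphics::mtext(sprintf("target (empirical p = %.3g)", x$empirical_p),
                  at = tv, col = "firebrick", cex = 0.8)
  invisible(x)
}
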