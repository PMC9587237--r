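#' Per-sample risk score for a gene set
#'
#' The evaluation method scores each sample by the mean of the set's
#' z-standardized expression rows (zero mean, unit variance across
#' samples). The mean-z score involves no per-set fitting, so target and
#' surrogate sets are evaluated on strictly equal footing. Rows with zero
#' variance contribute 0. Genes absent from the matrix are dropped; the
#' fraction present is attached as an attribute.
#'
#' @param expression Gene-by-sample numeric matrix.
#' @param genes [gene_set] (or character vector) to score.
#' @return Named numeric vector of per-sample scores, with attribute
#'   `fraction_present`.
#' @export
signature_score <- function(expression, genes) {
  ids <- as_gene_ids(genes)
  name <- if (inherits(genes, "gene_set")) genes$name else "gene set"
  present <- intersect(ids, rownames(expression))
  if (!length(present))
    stop(sprintf("none of the %d genes of '%s' are present in the expression matrix",
                 length(ids), name))
  z <- standardize_rows(expression[present, , drop = FALSE])
  score <- colMeans(z)
  attr(score, "fraction_present") <- length(present) / length(ids)
  score
}

# Row-wise z-standardization; constant rows become all-zero.
standardize_rows <- function(x) {
  m <- rowMeans(x)
  centered <- x - m
  s <- sqrt(rowSums(centered^2) / (ncol(x) - 1L))
  z <- centered / s
  z[s == 0, ] <- 0
  z
}

#' Split samples into high- and low-score risk groups at the median
#'
#' Samples strictly above the median score form the high-risk group; ties
#' at the median go to the low group, a deterministic rule that keeps
#' group assignment seed-free.
#'
#' @param scores Numeric vector of per-sample scores (length >= 2).
#' @return Factor with levels `c("low", "high")`, named like `scores`.
#' @export
dichotomize <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 samples to dichotomize")
  if (length(unique(scores)) == 1L)
    stop("all scores identical; no median split possible")
  med <- stats::median(scores)
  grp <- factor(ifelse(scores > med, "high", "low"),
                levels = c("low", "high"))
  names(grp) <- names(scores)
  grp
}

# Log-rank O-E and hypergeometric variance on time-sorted inputs.
# g1: logical, membership of group 1, sorted by time.
logrank_core <- function(g1, time, event) {
  n <- length(time)
  first <- !duplicated(time)
  idx <- which(first)
  tid <- cumsum(first)
  n_at <- n - idx + 1L
  n1_at <- rev(cumsum(rev(g1)))[idx]
  d <- rowsum(event, tid)[, 1L]
  d1 <- rowsum(event * g1, tid)[, 1L]
  keep <- d > 0
  d <- d[keep]; d1 <- d1[keep]
  nt <- n_at[keep]; n1t <- n1_at[keep]
  o_minus_e <- sum(d1 - d * n1t / nt)
  ok <- nt > 1L
  v <- sum(d[ok] * (n1t[ok] / nt[ok]) * (1 - n1t[ok] / nt[ok]) *
             (nt[ok] - d[ok]) / (nt[ok] - 1L))
  c(o_minus_e = o_minus_e, variance = v)
}

#' Two-sample log-rank test
#'
#' Compares the survival experience of two groups with the standard
#' log-rank chi-square: at each distinct event time the observed minus
#' expected number of events in group one is accumulated together with the
#' hypergeometric variance, and the statistic `(O-E)^2 / V` is referred to
#' a chi-square distribution with 1 degree of freedom.
#'
#' @param groups Two-level factor (or vector coercible to one) of group
#'   labels, one per sample.
#' @param survival Survival `data.frame` (columns `sample`, `time`,
#'   `event`), rows matching `groups` positionally.
#' @return An object of class `"logrank_test"`: list with `statistic`,
#'   `p.value`, `n`, `n_events`, and `group_sizes`.
#' @examples
#' surv <- data.frame(sample = paste0("s", 1:6),
#'                    time = c(1, 2, 3, 4, 5, 6),
#'                    event = c(1, 1, 1, 1, 0, 1))
#' logrank_test(rep(c("a", "b"), 3), surv)
#' @export
logrank_test <- function(groups, survival) {
  survival <- validate_survival(survival)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("log-rank test needs exactly 2 group levels, got ", nlevels(groups))
  if (length(groups) != nrow(survival))
    stop("'groups' length must match the number of survival rows")
  sizes <- table(groups)
  if (any(sizes == 0L)) stop("both groups must be non-empty")
  o <- order(survival$time)
  core <- logrank_core(groups[o] == levels(groups)[2L],
                       survival$time[o], survival$event[o])
  if (core[["variance"]] <= 0)
    stop("log-rank variance is zero; groups cannot be compared")
  stat <- core[["o_minus_e"]]^2 / core[["variance"]]
  structure(list(statistic = stat,
                 p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
                 n = nrow(survival),
                 n_events = sum(survival$event),
                 group_sizes = as.integer(sizes)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Two-sample log-rank test: chisq = %.4g (1 df), p = %.4g\n",
              x$statistic, x$p.value))
  cat(sprintf("  n = %d (%d events), group sizes %d / %d\n",
              x$n, x$n_events, x$group_sizes[1L], x$group_sizes[2L]))
  invisible(x)
}

# Index pairs (i, j) admissible for Harrell's C: time_i < time_j and
# sample i experienced the event.
comparable_pairs <- function(time, event) {
  idx <- which(event == 1L)
  i <- rep(idx, each = length(time))
  j <- rep(seq_along(time), times = length(idx))
  keep <- time[i] < time[j]
  list(i = i[keep], j = j[keep])
}

concordance_from_pairs <- function(scores, pairs) {
  si <- scores[pairs$i]
  sj <- scores[pairs$j]
  (sum(si > sj) + 0.5 * sum(si == sj)) / length(si)
}

#' Harrell's concordance index
#'
#' Probability that, of two comparable samples, the one with the higher
#' risk score experiences the event earlier. A pair is comparable when the
#' earlier time is an observed event; score ties count 1/2.
#'
#' @param scores Numeric per-sample risk scores (higher = higher risk),
#'   rows matching `survival` positionally.
#' @param survival Survival `data.frame` (columns `sample`, `time`,
#'   `event`).
#' @return The concordance index, a number in `[0, 1]`.
#' @export
concordance_index <- function(scores, survival) {
  survival <- validate_survival(survival)
  if (length(scores) != nrow(survival))
    stop("'scores' length must match the number of survival rows")
  pairs <- comparable_pairs(survival$time, survival$event)
  if (!length(pairs$i))
    stop("no comparable sample pairs; concordance is undefined")
  concordance_from_pairs(scores, pairs)
}

#' Evaluate a gene set against survival outcome
#'
#' The full evaluation method: score samples by the mean-z signature
#' score, then either split at the median and run the log-rank test
#' (metrics `"logrank_p"` and `"logrank_stat"`) or compute Harrell's
#' concordance on the continuous score (metric `"concordance"`). The code
#' path is identical whichever gene set is supplied — nothing in the
#' evaluation may know whether it is scoring a target or a surrogate.
#'
#' @param expression Gene-by-sample numeric matrix.
#' @param survival Survival `data.frame`; samples are aligned with the
#'   expression columns by identifier.
#' @param genes [gene_set] (or character vector) to evaluate.
#' @param metric `"logrank_p"`, `"logrank_stat"`, or `"concordance"`.
#' @return An object of class `"signature_eval"`: list with
#'   `gene_set_name`, `metric`, `value`, `statistic`, `p.value` (the last
#'   two `NA` for concordance), `group_sizes`, `n_events`, `n`, and
#'   `fraction_present`.
#' @export
evaluate_signature <- function(expression, survival, genes,
                               metric = c("logrank_p", "logrank_stat",
                                          "concordance")) {
  metric <- match.arg(metric)
  aligned <- suppressMessages(align_samples(expression, survival))
  score <- signature_score(aligned$expression, genes)
  name <- if (inherits(genes, "gene_set")) genes$name else "gene set"
  if (metric == "concordance") {
    value <- concordance_index(score, aligned$survival)
    stat <- NA_real_; p <- NA_real_; sizes <- c(NA_integer_, NA_integer_)
  } else {
    grp <- dichotomize(score)
    lr <- logrank_test(grp, aligned$survival)
    stat <- lr$statistic; p <- lr$p.value; sizes <- lr$group_sizes
    value <- if (metric == "logrank_p") p else stat
  }
  structure(list(gene_set_name = name, metric = metric, value = value,
                 statistic = stat, p.value = p, group_sizes = sizes,
                 n_events = sum(aligned$survival$event),
                 n = nrow(aligned$survival),
                 fraction_present = attr(score, "fraction_present")),
            class = "signature_eval")
}

#' @export
print.signature_eval <- function(x, ...) {
  cat(sprintf("Evaluation of '%s' (metric: %s)\n", x$gene_set_name, x$metric))
  cat(sprintf("  value = %.4g", x$value))
  if (x$metric != "concordance")
    cat(sprintf("  (chisq = %.4g, p = %.4g; groups %d/%d)",
                x$statistic, x$p.value, x$group_sizes[1L], x$group_sizes[2L]))
  cat(sprintf("\n  n = %d samples, %d events, %.0f%% of set genes present\n",
              x$n, x$n_events, 100 * x$fraction_present))
  invisible(x)
}

# Direction of "performs at least as well": smaller is better for p-values,
# larger for performance metrics.
at_least_as_good <- function(metric, candidate, reference) {
  if (metric == "logrank_p") candidate <= reference else candidate >= reference
}
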