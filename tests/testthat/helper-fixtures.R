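# Small in-code fixtures shared across test files.

tiny_expression <- function() {
  x <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(4, 3, 2, 1),
             g3 = c(2, 2, 2, 2))
  colnames(x) <- paste0("s", 1:4)
  x
}

tiny_expression_lines <- function(sep = "\t") {
  x <- tiny_expression()
  c(paste(c("gene", colnames(x)), collapse = sep),
    vapply(rownames(x),
           function(g) paste(c(g, x[g, ]), collapse = sep),
           character(1)))
}

make_survival <- function(time, event, samples = paste0("s", seq_along(time))) {
  data.frame(sample = samples, time = time, event = as.integer(event),
             stringsAsFactors = FALSE)
}

random_survival <- function(n, censor = 0.3, seed = 1) {
  set.seed(seed)
  time <- round(rexp(n), 4)
  event <- as.integer(runif(n) > censor)
  if (!sum(event)) event[1] <- 1L
  make_survival(time, event)
}

# Independent log-rank route for cross-checks.
survdiff_chisq <- function(groups, surv) {
  fit <- survival::survdiff(
    survival::Surv(surv$time, surv$event) ~ g,
    data = data.frame(g = groups, surv))
  unname(fit$chisq)
}
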