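test_that("signature scores are means of z-standardized rows", {
  x <- tiny_expression()
  # single gene: score equals the standardized row
  s1 <- signature_score(x, gene_set("g1"))
  expect_equal(as.vector(s1), (c(1, 2, 3, 4) - 2.5) / sd(1:4), tolerance = 1e-12)
  # mirror-image pair cancels exactly
  s12 <- signature_score(x, gene_set(c("g1", "g2")))
  expect_equal(as.vector(s12), rep(0, 4), tolerance = 1e-12)
  # constant rows contribute zero
  s13 <- signature_score(x, gene_set(c("g1", "g3")))
  expect_equal(as.vector(s13), (c(1, 2, 3, 4) - 2.5) / sd(1:4) / 2,
               tolerance = 1e-12)
  expect_identical(attr(s13, "fraction_present"), 1)

  half <- signature_score(x, gene_set(c("g1", "nope")))
  expect_identical(attr(half, "fraction_present"), 0.5)
  expect_error(signature_score(x, gene_set(c("no1", "no2"), "ghost")),
               "ghost")
})

test_that("median dichotomization sends ties to the low group", {
  expect_identical(as.character(dichotomize(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(dichotomize(c(1, 2, 2, 4))),
                   c("low", "low", "low", "high"))
  expect_error(dichotomize(rep(1, 5)), "identical")

  set.seed(9)
  sc <- rnorm(200)
  grp <- dichotomize(sc)
  expect_identical(length(grp), 200L)
  expect_true(min(sc[grp == "high"]) > median(sc))
  expect_identical(sum(grp == "high") + sum(grp == "low"), 200L)
})

test_that("log-rank statistic agrees with the survival package across random datasets", {
  for (seed in 1:25) {
    surv <- random_survival(30, censor = 0.4, seed = seed)
    set.seed(seed + 100)
    grp <- factor(sample(c("low", "high"), 30, TRUE),
                  levels = c("low", "high"))
    ours <- logrank_test(grp, surv)
    expect_equal(ours$statistic, survdiff_chisq(grp, surv),
                 tolerance = 1e-8)
    expect_equal(ours$p.value,
                 pchisq(ours$statistic, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("log-rank matches the independent oracle on every small label assignment", {
  # exhaustive: all 2-group assignments of n uncensored, distinct-time samples
  for (n in c(5, 6)) {
    surv <- make_survival(seq_len(n), rep(1, n))
    for (code in 1:(2^n - 2)) {
      g <- as.integer(intToBits(code))[1:n]
      if (length(unique(g)) < 2) next
      grp <- factor(ifelse(g == 1, "high", "low"), levels = c("low", "high"))
      expect_equal(logrank_test(grp, surv)$statistic,
                   survdiff_chisq(grp, surv), tolerance = 1e-8)
    }
  }
})

test_that("log-rank is invariant under group relabeling and errors on zero variance", {
  surv <- random_survival(40, seed = 5)
  set.seed(6)
  grp <- factor(sample(c("a", "b"), 40, TRUE))
  swapped <- factor(ifelse(grp == "a", "b", "a"))
  expect_equal(logrank_test(grp, surv)$statistic,
               logrank_test(swapped, surv)$statistic, tolerance = 1e-12)

  # all events at one shared time: hypergeometric variance vanishes
  tied <- make_survival(rep(1, 4), rep(1, 4))
  expect_error(logrank_test(c("a", "a", "b", "b"), tied), "variance")
  expect_error(logrank_test(rep("a", 4), random_survival(4)), "2 group")
})

test_that("log-rank detects a threefold hazard ratio at n = 200", {
  hits <- vapply(1:40, function(seed) {
    set.seed(seed)
    time <- c(rexp(100, 1), rexp(100, 3))
    surv <- make_survival(round(time, 6), rep(1, 200))
    grp <- rep(c("low", "high"), each = 100)
    logrank_test(grp, surv)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("concordance matches hand enumeration, direction flips, and the null level", {
  surv <- make_survival(1:5, c(1, 1, 0, 1, 1))
  scores <- c(5, 4, 3, 1, 2)
  # 8 comparable pairs, 7 concordant (enumerated by hand)
  expect_equal(concordance_index(scores, surv), 7 / 8, tolerance = 1e-12)
  # perfect risk ordering of uncensored times
  surv2 <- make_survival(1:6, rep(1, 6))
  expect_identical(concordance_index(6:1, surv2), 1)
  expect_equal(concordance_index(1:6, surv2), 0,
               tolerance = 1e-12)
  # C(s) = 1 - C(-s) on tie-free data
  surv3 <- random_survival(60, seed = 11)
  set.seed(12)
  sc <- rnorm(60)
  expect_equal(concordance_index(sc, surv3),
               1 - concordance_index(-sc, surv3), tolerance = 1e-12)
  # random scores sit at 1/2
  surv4 <- random_survival(500, seed = 13)
  set.seed(14)
  expect_equal(concordance_index(rnorm(500), surv4), 0.5, tolerance = 0.05)
  expect_error(concordance_index(1:2, make_survival(c(1, 2), c(0, 1))),
               "comparable")
})

test_that("concordance agrees with the survival package on tie-free data", {
  for (seed in 1:10) {
    surv <- random_survival(80, censor = 0.35, seed = seed)
    set.seed(seed + 200)
    sc <- rnorm(80)
    ours <- concordance_index(sc, surv)
    ref <- survival::concordance(
      survival::Surv(surv$time, surv$event) ~ sc, reverse = TRUE)$concordance
    expect_equal(ours, unname(ref), tolerance = 1e-10)
  }
})

test_that("evaluation is deterministic and blind to gene-set identity", {
  d <- generate_dataset(stf_scenario("specific", n_genes = 300,
                                     n_samples = 60, target_size = 15,
                                     seed = 21))
  r1 <- evaluate_signature(d$expression, d$survival, d$target)
  r2 <- evaluate_signature(d$expression, d$survival, d$target)
  expect_identical(r1$value, r2$value)

  relabeled <- gene_set(sample(d$target$genes), "surrogate_fake")
  r3 <- evaluate_signature(d$expression, d$survival, relabeled)
  expect_identical(r3$value, r1$value)
  expect_identical(r3$statistic, r1$statistic)
  expect_identical(r3$group_sizes, r1$group_sizes)

  expect_identical(sum(r1$group_sizes), r1$n)
  expect_true(r1$p.value > 0 && r1$p.value <= 1)

  rc <- evaluate_signature(d$expression, d$survival, d$target, "concordance")
  expect_true(rc$value >= 0 && rc$value <= 1)
  expect_identical(rc$value,
                   concordance_index(signature_score(d$expression, d$target),
                                     d$survival))
})

test_that("a specific-scenario target is strongly prognostic through the full method", {
  d <- generate_dataset(stf_scenario("specific", n_genes = 500,
                                     n_samples = 300, target_size = 30,
                                     seed = 33))
  r <- evaluate_signature(d$expression, d$survival, d$target, "logrank_p")
  expect_lt(r$value, 0.01)
})
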