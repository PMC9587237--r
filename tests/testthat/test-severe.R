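# Deterministic construction: one gene perfectly orders the (uncensored)
# survival times, the pool is all-constant rows, so with the concordance
# metric the target scores exactly 1 and every surrogate exactly 0.5.
perfect_vs_flat <- function(n = 10, n_pool = 60) {
  times <- seq_len(n)
  flat <- matrix(1, n_pool, n)
  rownames(flat) <- sprintf("p%02d", seq_len(n_pool))
  expr <- rbind(tg = rev(times), flat)
  colnames(expr) <- paste0("s", seq_len(n))
  list(expr = expr, surv = make_survival(times, rep(1, n)))
}

test_that("extreme target ranks give the add-one empirical p exactly", {
  fx <- perfect_vs_flat()
  best <- severe_test(fx$expr, fx$surv, gene_set("tg", "perfect"),
                      sprintf("p%02d", 1:60), metric = "concordance",
                      n_draws = 99, alpha = 0.05, seed = 1)
  expect_identical(best$target_result$value, 1)
  expect_true(all(best$surrogate_values == 0.5))
  expect_identical(best$empirical_p, 1 / 100)
  expect_identical(best$matching_fraction, 0)
  expect_identical(best$decision, "ST_retained")

  # flat target against perfect surrogates: worse than every draw
  ramps <- matrix(rep(rev(1:10), 30), 30, 10, byrow = TRUE)
  rownames(ramps) <- sprintf("q%02d", 1:30)
  expr2 <- rbind(flat = rep(1, 10), ramps)
  colnames(expr2) <- paste0("s", 1:10)
  worst <- severe_test(expr2, fx$surv, gene_set("flat"),
                       sprintf("q%02d", 1:30), metric = "concordance",
                       n_draws = 99, seed = 1)
  expect_identical(worst$empirical_p, 1)
  expect_identical(worst$matching_fraction, 1)
  expect_identical(worst$decision, "ST_rejected")
  expect_match(worst$interpretation, "falsified")
})

test_that("surrogate draws are uniform k-subsets, reproducible, and RNG-clean", {
  draws <- sample_surrogates(letters[1:10], k = 4, n_draws = 25, seed = 7)
  expect_length(draws$sets, 25L)
  for (s in draws$sets) {
    expect_length(s$genes, 4L)
    expect_true(all(s$genes %in% letters[1:10]))
  }
  again <- sample_surrogates(letters[1:10], k = 4, n_draws = 25, seed = 7)
  expect_identical(draws, again)
  expect_false(identical(
    draws, sample_surrogates(letters[1:10], 4, 25, seed = 8)))

  # forced outcome: pool of exactly k genes
  forced <- sample_surrogates(letters[1:3], k = 3, n_draws = 5, seed = 1)
  for (s in forced$sets) expect_setequal(s$genes, letters[1:3])

  # the caller's RNG stream is not consumed
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(runif(1))
  sample_surrogates(letters[1:10], 2, 10, seed = 99)
  expect_identical(c(runif(1), runif(1)), before[2:3])

  expect_error(sample_surrogates(letters[1:3], k = 5, n_draws = 2),
               "exceeds")
})

test_that("severe test validates its contract and reports failing draws", {
  fx <- perfect_vs_flat()
  expect_error(severe_test(fx$expr, fx$surv, gene_set(c("tg", "p01")),
                           sprintf("p%02d", 1:60), n_draws = 9),
               "not disjoint")
  expect_error(severe_test(fx$expr, fx$surv, gene_set("tg"),
                           sprintf("p%02d", 1:60), n_draws = 9, alpha = 1.2),
               "alpha")
  # constant pool rows make the median split impossible: the offending
  # draw index and seed are reported
  expect_error(severe_test(fx$expr, fx$surv, gene_set("tg"),
                           sprintf("p%02d", 1:60), metric = "logrank_p",
                           n_draws = 9, seed = 4),
               "surrogate draw 1 \\(seed 4\\)")
})

test_that("severe test is reproducible and its empirical p lies on the grid", {
  d <- generate_dataset(stf_scenario("latent_redundant", n_genes = 600,
                                     n_samples = 120, target_size = 25,
                                     seed = 5))
  pool <- build_pool_levels(rownames(d$expression), d$proliferation,
                            d$target, d$annotation, c(1, 0))
  st <- severe_test(d$expression, d$survival, d$target, pool,
                    n_draws = 99, seed = 17)
  st2 <- severe_test(d$expression, d$survival, d$target, pool,
                     n_draws = 99, seed = 17)
  expect_identical(st$surrogate_values, st2$surrogate_values)
  expect_identical(st$empirical_p, st2$empirical_p)

  grid <- seq_len(100) / 100
  expect_true(st$empirical_p %in% grid)
  expect_gt(st$empirical_p, 0)
  expect_equal(st$empirical_p, (1 + st$matching_fraction * 99) / 100,
               tolerance = 1e-12)
  expect_identical(st$provenance$pool_level, 2L)
  expect_identical(st$provenance$k, 25L)
})

test_that("a specific target is retained at the grid minimum across seeds", {
  hits <- vapply(1:10, function(seed) {
    d <- generate_dataset(stf_scenario("specific", n_genes = 500,
                                       n_samples = 150, target_size = 25,
                                       seed = seed))
    pool <- build_pool_levels(rownames(d$expression), d$proliferation,
                              d$target, d$annotation, c(1, 0))
    st <- severe_test(d$expression, d$survival, d$target, pool,
                      n_draws = 99, seed = seed)
    st$decision == "ST_retained" && st$empirical_p == 1 / 100
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("latent redundancy makes surrogates match the target", {
  d <- generate_dataset(stf_scenario("latent_redundant", seed = 71))
  pool <- build_pool_levels(rownames(d$expression), d$proliferation,
                            d$target, d$annotation, c(1, 0))
  st <- severe_test(d$expression, d$survival, d$target, pool,
                    n_draws = 199, seed = 71)
  expect_identical(st$decision, "ST_rejected")
  expect_gte(st$matching_fraction, 0.5)
  expect_match(st$interpretation, "interchangeable")
})

test_that("null-scenario empirical p-values are close to uniform", {
  ps <- vapply(1:60, function(rep) {
    d <- generate_dataset(stf_scenario("null", n_genes = 600,
                                       n_samples = 120, target_size = 25,
                                       seed = 400 + rep))
    pool <- build_pool_levels(rownames(d$expression), d$proliferation,
                              d$target, d$annotation, c(0))
    lvl <- pool[[length(pool)]]
    tgt <- sample(lvl$genes, 25)
    severe_test(d$expression, d$survival, gene_set(tgt, "null_target"),
                setdiff(lvl$genes, tgt), n_draws = 99,
                seed = 400 + rep)$empirical_p
  }, numeric(1))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
  # superuniformity with Monte-Carlo slack
  for (q in c(0.1, 0.25, 0.5))
    expect_lte(mean(ps <= q), q + 0.13)
})

test_that("severe test report methods print and plot without error", {
  fx <- perfect_vs_flat()
  st <- severe_test(fx$expr, fx$surv, gene_set("tg"), sprintf("p%02d", 1:60),
                    metric = "concordance", n_draws = 19, seed = 2)
  expect_output(print(st), "empirical p")
  expect_output(print(summary(st)), "surrogate metric distribution")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(st))
})
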