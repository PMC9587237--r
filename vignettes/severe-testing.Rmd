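---
title: "Severe testing of gene signatures: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severe testing of gene signatures: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure

A small gene signature `G_t` claims biological importance for a complex
phenotype, typically backed by its ability to predict a macroscopic
outcome such as overall survival. Biomarker reasoning treats biological
importance and predictability as associated in both directions, so the
claim is refutable by substitution: draw same-size gene sets `G_s` that by
construction carry no designed biological relation to `G_t`, apply the
*identical* evaluation method `M` to the *identical* data `D`, and compare
results. The package decides the hypothesis

> **ST**: the results with `G_t` and the results with `G_s` are not the
> same,

and frames the decision as the rank of the target within the surrogate
null:

```
empirical_p = (1 + #{b : surrogate_b at least as good as target}) / (1 + B).
```

`empirical_p > alpha` rejects ST (surrogates indistinguishable from the
target; the signature's biological interpretation is falsified);
`empirical_p <= alpha` retains ST.

Three design choices deserve justification because the framework itself
only prescribes "compare R and R'":

* **Rank-based comparison with the add-one correction.** "Results are not
  the same" needs an operational meaning. We use the permutation-test
  convention: the target's rank among exchangeable surrogate re-analyses.
  It makes the decision's type-I behaviour testable (under a null in which
  the target is itself a pool draw, `empirical_p` is uniform on the grid
  `{1/(B+1), ..., 1}`), and the `+1` keeps the p-value away from 0 — a
  finite number of draws can never establish certainty. An alternative —
  declaring results "the same" when they differ by less than an
  effect-size margin — would need a margin the framework does not supply.
* **Metric-aware direction.** "At least as good" means `<=` for
  `logrank_p` and `>=` for `logrank_stat` and `concordance`; the report
  records the direction used.
* **Wording of the decision.** Rejecting ST *falsifies* the signature's
  specificity claim. Because the double negative invites misreading, every
  report carries a plain-language interpretation string.

## The evaluation method M

`M` must depend on the gene set only through its members and must not be
trained per set — otherwise the target could be privileged (or penalized)
relative to surrogates. The default is deliberately the least
parameterized choice in common use:

1. **Score**: mean of the set's z-standardized expression rows (zero mean,
   unit variance per gene across samples). Constant rows contribute 0.
   No weights are fitted, so target and surrogate sets are strictly
   exchangeable under the null.
2. **Dichotomization**: median split; samples strictly above the median
   are "high risk", ties at the median go to the low group. The rule is
   deterministic and seed-free, which the surrogate comparison requires.
3. **Test**: two-sample log-rank chi-square, `(O - E)^2 / V` with the
   hypergeometric variance at each distinct event time, referred to a
   1-df chi-square. Alternatively, Harrell's concordance on the
   continuous score (comparable pairs require the earlier time to be an
   event; score ties count 1/2).

A Cox-model-based `M` was considered and rejected as the default: fitted
coefficients would make `M` partially trained on each set. The
`evaluate_signature()` surface is a fixed contract, and `severe_test()`
evaluates the target and every surrogate through one closure — no code
path can inspect whether a set is the target.

The log-rank statistic and the concordance index are implemented in the
package rather than delegated, for two reasons: the resampling loop needs
them cheap (a severe test at `B = 999` performs a thousand evaluations on
a shared pre-standardized matrix), and the implementations are pinned in
the test suite against the survival package and against exhaustive
small-sample oracles, giving a dual-route check instead of a single
library call.

Degenerate inputs are errors, not silent results: a gene set with no
expressed member, identical scores (no median split), a group with zero
log-rank variance, no comparable concordance pairs, and any surrogate
evaluation failure aborts with the draw index and seed.

## The gene pool ladder

Level 0 removes the proliferation genes and the target
(`G_L0 = G \ (G_p U G_t)`); level `i` additionally removes every gene
whose annotation-term overlap with the target exceeds `thresholds[i]`.
Similarity is the *shared-term count* against the union of the target's
terms (the fraction of that union is also reported). Many biological
similarity measures exist; the count is the only one whose endpoint the
framework fixes — the most stringent pool of the case it models contains
genes with *no* shared terms, i.e. threshold 0 — and integer thresholds
interpolate the intermediate levels. Semantic-similarity measures and
ontology-graph traversal are out of scope; annotations are used as given,
so users who want ancestor propagation should pre-expand the annotation
file. No proliferation gene list ships with the package: any fixed list
would freeze a database snapshot, and the choice is scientific, not
technical. Genes in both `G_p` and `G_t` are removed once and attributed
to `G_t` in the provenance (a deterministic reporting rule; the set union
makes attribution arbitrary).

Surrogate draws are independent across draws (repeats permitted). With
genome-scale pools the number of `k`-subsets is astronomical —
`log10_surrogate_count(1665, 50)` is about 88 — so collisions are
negligible and independence keeps the null exact.

## The synthetic scenarios

The generator emulates the statistical situation the framework addresses,
not any particular platform: a single latent per-sample factor
`L ~ N(0,1)` drives both expression (`x_g = lambda_g * L + N(0,1)`) and
outcome (exponential survival with hazard `exp(beta * L)`, independent
uniform censoring calibrated by root-finding so the realized censored
fraction matches `censor_rate`). Defaults: 2000 genes, 200 samples,
target size 50, `beta = 1`, censoring 0.3, 5% proliferation genes, a
similar block of 10% of the pool sharing two or one annotation terms with
the target, 30% redundant fraction.

* `null`: all loadings 0. Expression carries no outcome information;
  used for calibration.
* `specific`: only the target loads (`lambda = 1`). With 50 genes the
  target score correlates with `L` at about 0.99, so the signature is
  strongly prognostic while every pool draw is noise.
* `latent_redundant`: 30% of the level-0 pool loads at `lambda = 1`
  (the similar block first, so stringent filtering visibly thins the
  loaded genes), while the target loads weakly at `lambda = 0.1`. This
  is the redundancy situation: the prognostic factor pervades the
  transcriptome, the published signature tags it imperfectly, and random
  pool sets predict at least as well.

The target loading of 0.1 in the redundant scenario is a package choice,
fixed by a design-stage power analysis before the test suite was written:
with equal loadings the target (100% loaded genes) would systematically
outrank surrogates (~30% loaded genes), which contradicts the phenomenon
being emulated — published signatures that random sets match or beat. At
loading 0.1 the target's score–factor correlation (~0.58) sits clearly
below the surrogate range (~0.75–0.9) while remaining prognostic, so the
matching fraction exceeds 1/2 robustly across seeds. The redundant
fraction default of 0.3 is likewise a package choice, not an empirical
estimate.

What the generator does *not* emulate: count distributions, platform
noise, batch structure, correlated gene modules beyond the single factor,
non-proportional hazards, informative censoring. Passing tests therefore
demonstrate the framework's statistical behaviour under its own
assumptions, not performance on any real cohort.

## Numerical and interface choices

* Expression values and survival times are quantized to 6 decimals
  through their decimal representation, so TSV fixtures parse back
  bit-identically and bundles from one seed are byte-identical.
* Surrogate sampling and data generation run under a local RNG seed and
  restore the caller's RNG state.
* `log10_surrogate_count()` uses log-gamma, exact to ~1e-12 against
  integer binomials for `n <= 30` and stable at genome scale.
* Sample alignment keeps the intersection of expression and survival
  samples in expression column order, dropping the rest with a message —
  mismatched cohorts are routine, not exceptional.
* Gene identifiers are opaque case-sensitive strings; harmonization
  (symbol/Ensembl mapping) is upstream of the framework.
* Expression is assumed pre-normalized; the package performs no
  normalization, mirroring the framework's "data already generated"
  stance. Which normalization is appropriate is left to the user.
* The five-layer study screen evaluates its checklist strictly top-down
  (phenotype, outcome, timescale, data scale, testing intent), so the
  reported failing layer is deterministic. Studies failing a layer are
  reported `not_prime` with an advisory that they are not ultimately
  excluded; the screen does not model the replacement arguments such
  studies would need.
* Neighborhood expansion counts are the no-overlap upper bound ("up to"),
  with no graph deduplication — the bound itself is the argument.

## Problem sizes in the test suite

The statistical guarantees are verified at the generator's default
conditions: calibration with 500 replicate severe tests at `B = 199`
(retained rate 5% ± 2%), redundancy detection over 50 seeds at the
default `B = 999` (matching fraction ≥ 0.5 and ST rejected in ≥ 90% of
seeds), exhaustive log-rank oracle checks for all label assignments at
`n ≤ 8`, and draw-frequency checks over 10,000 draws from a 4-gene pool.
Smaller configurations (a few hundred genes) are used where only
structural invariants are at stake.

## Known limitations

* One target per run; multiplicity across many tested signatures is the
  user's responsibility.
* Uniform sampling is the only surrogate selection procedure; searching
  for an optimal surrogate set is problem-specific and out of scope.
* The dichotomized log-rank default discards within-group score
  information; use the concordance metric when a continuous comparison
  is wanted.
* No clinical covariate adjustment, time-dependent accuracy, or
  competing risks.
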