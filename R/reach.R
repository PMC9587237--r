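#' Interaction-neighborhood expansion bound
#'
#' Upper bound on the number of genes reached by expanding an interaction
#' neighborhood: starting from `seed_count` genes, each round connects
#' every frontier gene to `partners_per_gene` new genes, which form the
#' next frontier. Neighborhoods are assumed non-overlapping, so the count
#' is the "up to" bound `s * (k^(d+1) - 1) / (k - 1)` for `k > 1` (and
#' `s * (d + 1)` for `k = 1`). With 3 seed genes and 5 partners each, one
#' round reaches 18 genes and a second round 93 — a handful of rounds
#' spans all active genes of a cell, which is why claims about the
#' isolated importance of a few genes unravel on the network level.
#'
#' @param seed_count Number of starting genes `s >= 1`.
#' @param partners_per_gene Interaction partners per gene `k >= 1`.
#' @param rounds Number of expansion rounds `d >= 0`.
#' @return Total gene count (seeds plus all newly reached genes).
#' @examples
#' expansion_count(3, 5, 1) # 18
#' expansion_count(3, 5, 2) # 93
#' @export
expansion_count <- function(seed_count, partners_per_gene, rounds) {
  stopifnot(seed_count >= 1, partners_per_gene >= 1, rounds >= 0,
            seed_count == round(seed_count),
            partners_per_gene == round(partners_per_gene),
            rounds == round(rounds))
  total <- as.numeric(seed_count)
  frontier <- as.numeric(seed_count)
  for (i in seq_len(rounds)) {
    frontier <- frontier * partners_per_gene
    total <- total + frontier
  }
  total
}

#' Rounds needed for an expanding neighborhood to span a gene universe
#'
#' Smallest number of expansion rounds after which the
#' [expansion_count()] bound reaches `universe_size`. Grows
#' logarithmically in the universe size for `partners_per_gene > 1`.
#'
#' @inheritParams expansion_count
#' @param universe_size Number of genes to span (at least `seed_count`).
#' @param max_rounds Safety cap on the iteration.
#' @return The minimal number of rounds `d`.
#' @examples
#' reach_saturation(3, 5, 18)      # 1
#' reach_saturation(1, 5, 20000)   # 6
#' @export
reach_saturation <- function(seed_count, partners_per_gene, universe_size,
                             max_rounds = 10000L) {
  stopifnot(universe_size >= seed_count)
  d <- 0L
  while (expansion_count(seed_count, partners_per_gene, d) < universe_size) {
    d <- d + 1L
    if (d > max_rounds)
      stop(sprintf("universe of %g genes not reached within %d rounds",
                   universe_size, max_rounds))
  }
  d
}
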