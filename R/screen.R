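#' Screen a study for severe-testing suitability
#'
#' Runs a five-layer checklist that classifies an omics study as a prime
#' candidate for a surrogate-resampling severe test. The layers are
#' evaluated strictly top-down — phenotype, outcome, time scale, data,
#' testing intent — so the first failing layer is well defined:
#'
#' 1. **phenotype** — complex phenotypes (emerging from interactions among
#'    many genes and environment) qualify; Mendelian ones, explained by a
#'    few genes, do not.
#' 2. **outcome** — a macroscopic outcome (overall survival, mortality,
#'    symptoms) qualifies; microscopic outcomes (expression, binding,
#'    mutation calls) do not.
#' 3. **timescale** — short (within-lifetime) processes qualify;
#'    evolutionary timescales do not.
#' 4. **data_scale** — genome-scale data qualify, since only a large gene
#'    universe offers enough candidate surrogates; targeted panels do not.
#' 5. **testing_intent** — the investigators must intend a severe test; a
#'    study clearing the first four layers whose authors opt for
#'    incremental corroboration instead is recorded as a declined
#'    candidate.
#'
#' Studies failing an early layer are not ultimately excluded from severe
#' testing, but would need replacement arguments this screen does not
#' model; the verdict carries an advisory note to that effect.
#'
#' @param phenotype `"complex"` or `"mendelian"`.
#' @param outcome `"macroscopic"` or `"microscopic"`.
#' @param timescale `"short"` or `"evolutionary"`.
#' @param data_scale `"genome_scale"` or `"targeted"`.
#' @param testing_intent `"severe"` or `"incremental"`.
#' @return An object of class `"study_screen"`: a list with `verdict`
#'   (`"prime_candidate"`, `"candidate_but_declined"`, or `"not_prime"`),
#'   `failing_layer` (`NA` when no layer fails), `advisory`, and the
#'   resolved `profile`.
#' @examples
#' classify_study("complex", "macroscopic", "short", "genome_scale", "severe")
#' @export
classify_study <- function(phenotype = c("complex", "mendelian"),
                           outcome = c("macroscopic", "microscopic"),
                           timescale = c("short", "evolutionary"),
                           data_scale = c("genome_scale", "targeted"),
                           testing_intent = c("severe", "incremental")) {
  profile <- list(phenotype = match.arg(phenotype),
                  outcome = match.arg(outcome),
                  timescale = match.arg(timescale),
                  data_scale = match.arg(data_scale),
                  testing_intent = match.arg(testing_intent))
  wanted <- c(phenotype = "complex", outcome = "macroscopic",
              timescale = "short", data_scale = "genome_scale")
  failing <- NA_character_
  for (layer in names(wanted)) {
    if (profile[[layer]] != wanted[[layer]]) {
      failing <- layer
      break
    }
  }
  if (!is.na(failing)) {
    verdict <- "not_prime"
    advisory <- paste0(
      "Fails the '", failing, "' layer. Such studies are not ultimately ",
      "excluded from severe testing, but would require replacement ",
      "arguments that this screen does not evaluate.")
  } else if (profile$testing_intent == "incremental") {
    verdict <- "candidate_but_declined"
    failing <- "testing_intent"
    advisory <- paste0(
      "Clears all structural layers but the investigators opt for ",
      "incremental corroboration rather than a severe test.")
  } else {
    verdict <- "prime_candidate"
    advisory <- "Prime candidate for severe testing."
  }
  structure(list(verdict = verdict, failing_layer = failing,
                 advisory = advisory, profile = profile),
            class = "study_screen")
}

#' @export
print.study_screen <- function(x, ...) {
  cat("Study screen for severe testing\n")
  cat(sprintf("  profile: %s\n",
              paste(unlist(x$profile), collapse = " / ")))
  cat(sprintf("  verdict: %s\n", x$verdict))
  if (!is.na(x$failing_layer))
    cat(sprintf("  deciding layer: %s\n", x$failing_layer))
  cat("  ", x$advisory, "\n", sep = "")
  invisible(x)
}
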