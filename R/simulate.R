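#' Configure a synthetic severe-testing scenario
#'
#' Defines the statistical structure of a simulated omics study with a
#' latent prognostic factor. A per-sample factor `L ~ N(0, 1)` drives
#' both expression (gene `g` is `lambda_g * L` plus unit-variance noise)
#' and outcome (exponential survival with hazard `exp(effect_size * L)`,
#' independent uniform censoring calibrated to `censor_rate`). Three
#' scenarios set the loading pattern `lambda_g`:
#'
#' * `"null"` — no gene loads on `L`; expression is pure noise and
#'   carries no outcome information. Used for calibration checks.
#' * `"specific"` — only the target genes load (at `loading`); the
#'   signature's predictive power is genuinely specific to its genes.
#' * `"latent_redundant"` — `redundant_fraction` of the pool genes load
#'   at `loading`, while the target genes load only weakly (default
#'   `0.1 * loading`). Outcome information pervades the transcriptome
#'   through `L`, so random pool sets predict at least as well as the
#'   target — the redundancy phenomenon that severe testing exposes.
#'
#' The annotation generator shares terms within the target set and in a
#' graded "similar block" of pool genes (two shared terms in the first
#' half, one in the second), with disjoint background terms elsewhere,
#' so pool stratification by term overlap has non-trivial levels.
#'
#' @param scenario `"null"`, `"specific"`, or `"latent_redundant"`.
#' @param n_genes Number of genes (default 2000).
#' @param n_samples Number of samples (default 200).
#' @param target_size Target signature size `k`; at most `n_genes / 10`,
#'   since the framework requires the target to be small against the
#'   gene universe.
#' @param effect_size Log-hazard coefficient `beta >= 0` of the latent
#'   factor (default 1).
#' @param loading Expression loading of latent-associated genes
#'   (default 1, against unit-variance noise).
#' @param target_loading Loading of the target genes; `NULL` resolves by
#'   scenario (`null`: 0; `specific`: `loading`;
#'   `latent_redundant`: `0.1 * loading`).
#' @param redundant_fraction Fraction of level-0 pool genes loading on
#'   `L` (`latent_redundant` only, default 0.3).
#' @param censor_rate Target fraction of censored samples, in `[0, 1)`.
#' @param prolif_size Number of proliferation genes; default 5% of
#'   `n_genes` (at least 10).
#' @param similar_fraction Fraction of pool genes in the term-sharing
#'   similar block (default 0.1).
#' @param n_terms Number of background annotation terms (default 60).
#' @param terms_per_gene Terms per annotated gene (default 3, minimum 2).
#' @param unannotated_fraction Fraction of background genes left without
#'   annotation (default 0.1).
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return An object of class `"stf_scenario"` (a validated list of the
#'   above fields with defaults resolved).
#' @seealso [generate_dataset()], [write_fixture_bundle()]
#' @export
stf_scenario <- function(scenario = c("null", "specific", "latent_redundant"),
                         n_genes = 2000L, n_samples = 200L,
                         target_size = 50L, effect_size = 1,
                         loading = 1, target_loading = NULL,
                         redundant_fraction = 0.3, censor_rate = 0.3,
                         prolif_size = NULL, similar_fraction = 0.1,
                         n_terms = 60L, terms_per_gene = 3L,
                         unannotated_fraction = 0.1, seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(prolif_size)) prolif_size <- max(10L, round(0.05 * n_genes))
  if (is.null(target_loading)) {
    target_loading <- switch(scenario,
                             null = 0,
                             specific = loading,
                             latent_redundant = 0.1 * loading)
  }
  cfg <- list(scenario = scenario, n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              target_size = as.integer(target_size),
              effect_size = effect_size, loading = loading,
              target_loading = target_loading,
              redundant_fraction = redundant_fraction,
              censor_rate = censor_rate,
              prolif_size = as.integer(prolif_size),
              similar_fraction = similar_fraction,
              n_terms = as.integer(n_terms),
              terms_per_gene = as.integer(terms_per_gene),
              unannotated_fraction = unannotated_fraction,
              seed = as.integer(seed))
  if (cfg$n_genes < 20L) stop("'n_genes' must be at least 20")
  if (cfg$n_samples < 10L) stop("'n_samples' must be at least 10")
  if (cfg$target_size < 1L) stop("'target_size' must be positive")
  if (cfg$target_size > cfg$n_genes / 10)
    stop("'target_size' must not exceed n_genes / 10: the target must be ",
         "small against the gene universe")
  if (cfg$effect_size < 0) stop("'effect_size' must be non-negative")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("'censor_rate' must be in [0, 1)")
  for (f in c("redundant_fraction", "similar_fraction",
              "unannotated_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must be in [0, 1]")
  }
  if (cfg$terms_per_gene < 2L) stop("'terms_per_gene' must be at least 2")
  if (cfg$target_size + cfg$prolif_size >= cfg$n_genes - cfg$target_size)
    stop("too few genes left for the pool; decrease target/proliferation sizes")
  structure(cfg, class = "stf_scenario")
}

#' @export
print.stf_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario '%s': %d genes x %d samples, target %d, seed %d\n",
              x$scenario, x$n_genes, x$n_samples, x$target_size, x$seed))
  cat(sprintf("  loadings: target %.3g, pool %.3g (redundant fraction %.2g); beta = %.3g, censoring %.2g\n",
              x$target_loading, x$loading, x$redundant_fraction,
              x$effect_size, x$censor_rate))
  invisible(x)
}

#' Generate a synthetic severe-testing dataset
#'
#' Draws expression, survival, gene lists, and annotation according to an
#' [stf_scenario()] configuration. Expression values and survival times
#' are quantized to 6 decimals so that plain-text fixtures written by
#' [write_fixture_bundle()] round-trip exactly.
#'
#' @param config An `"stf_scenario"` object.
#' @return An object of class `"stf_dataset"`: list with `expression`
#'   (matrix), `survival` (`data.frame`), `target` and `proliferation`
#'   ([gene_set]s), `annotation` (named list), `loadings` (named numeric,
#'   diagnostic), `latent` (the per-sample factor, diagnostic), and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "stf_scenario"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  samples <- sprintf("s%04d", seq_len(cfg$n_samples))
  k <- cfg$target_size
  tgt <- genes[seq_len(k)]
  prolif <- genes[k + seq_len(cfg$prolif_size)]
  pool0 <- setdiff(genes, c(tgt, prolif))
  n_sim <- round(cfg$similar_fraction * length(pool0))
  similar <- pool0[seq_len(n_sim)]

  lambda <- setNames(numeric(cfg$n_genes), genes)
  lambda[tgt] <- cfg$target_loading
  if (cfg$scenario == "latent_redundant") {
    n_red <- round(cfg$redundant_fraction * length(pool0))
    redundant <- pool0[seq_len(max(n_red, 0L))]  # similar block first, then beyond
    lambda[redundant] <- cfg$loading
  }
  if (cfg$scenario == "null") lambda[] <- 0

  L <- stats::rnorm(cfg$n_samples)
  X <- outer(lambda, L) +
    matrix(stats::rnorm(cfg$n_genes * cfg$n_samples), cfg$n_genes)
  # quantize through the decimal representation so TSV output parses back
  # to bit-identical values
  X[] <- as.numeric(sprintf("%.6f", X))
  dimnames(X) <- list(genes, samples)

  T_event <- stats::rexp(cfg$n_samples, rate = exp(cfg$effect_size * L))
  if (cfg$censor_rate > 0) {
    f <- function(cm) mean(pmin(T_event / cm, 1)) - cfg$censor_rate
    cal <- tryCatch(stats::uniroot(f, c(1e-12, 1e12), tol = 1e-10),
                    error = function(e)
                      stop("censoring calibration infeasible for censor_rate = ",
                           cfg$censor_rate))
    C_cens <- stats::runif(cfg$n_samples, 0, cal$root)
    time <- pmin(T_event, C_cens)
    event <- as.integer(T_event <= C_cens)
  } else {
    time <- T_event
    event <- rep(1L, cfg$n_samples)
  }
  survival <- data.frame(sample = samples,
                         time = as.numeric(sprintf("%.6f", time)),
                         event = event, stringsAsFactors = FALSE)

  annotation <- generate_annotation(cfg, tgt, prolif, pool0, similar)

  structure(list(expression = validate_expression(X),
                 survival = validate_survival(survival),
                 target = gene_set(tgt, "target_signature"),
                 proliferation = gene_set(prolif, "proliferation"),
                 annotation = annotation,
                 loadings = lambda, latent = L, config = cfg),
            class = "stf_dataset")
}

# Term-sharing structure: targets draw from a small shared term pool;
# the similar block shares 2 (first half) or 1 (second half) target-pool
# terms; everything else uses disjoint background terms.
generate_annotation <- function(cfg, tgt, prolif, pool0, similar) {
  tp <- sprintf("GO:T%03d", seq_len(cfg$terms_per_gene + 2L))
  bg <- sprintf("GO:B%03d", seq_len(cfg$n_terms))
  ann <- list()
  for (g in tgt) ann[[g]] <- sample(tp, cfg$terms_per_gene)
  n_sim <- length(similar)
  tier_a <- similar[seq_len(n_sim %/% 2L)]
  tier_b <- setdiff(similar, tier_a)
  for (g in tier_a)
    ann[[g]] <- c(sample(tp, 2L), sample(bg, cfg$terms_per_gene - 2L))
  for (g in tier_b)
    ann[[g]] <- c(sample(tp, 1L), sample(bg, cfg$terms_per_gene - 1L))
  background_genes <- c(prolif, setdiff(pool0, similar))
  n_unannot <- round(cfg$unannotated_fraction * length(background_genes))
  if (n_unannot > 0)
    background_genes <-
      background_genes[seq_len(length(background_genes) - n_unannot)]
  for (g in background_genes) ann[[g]] <- sample(bg, cfg$terms_per_gene)
  ann
}

#' @export
print.stf_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset ('%s', seed %d): %d genes x %d samples, %d events\n",
              x$config$scenario, x$config$seed, nrow(x$expression),
              ncol(x$expression), sum(x$survival$event)))
  cat(sprintf("  target %d genes, proliferation %d genes, %d annotated genes\n",
              length(x$target), length(x$proliferation), length(x$annotation)))
  invisible(x)
}

#' Write a synthetic dataset as a plain-text fixture bundle
#'
#' Writes the expression matrix (TSV), survival table (TSV), target and
#' proliferation sets (one GMT), annotation map (two-column TSV), and the
#' scenario configuration (YAML) into a directory. Re-reading the files
#' with the package's readers reproduces the in-memory objects exactly;
#' two bundles generated from the same seed are byte-identical.
#'
#' @param dataset An `"stf_dataset"` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the file paths written.
#' @export
write_fixture_bundle <- function(dataset, dir) {
  stopifnot(inherits(dataset, "stf_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             survival = file.path(dir, "survival.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             annotation = file.path(dir, "annotation.tsv"),
             scenario = file.path(dir, "scenario.yaml"))
  write_expression(dataset$expression, paths[["expression"]])
  write_survival(dataset$survival, paths[["survival"]])
  write_gmt(list(dataset$target, dataset$proliferation), paths[["gene_sets"]])
  write_annotation(dataset$annotation, paths[["annotation"]])
  yaml::write_yaml(unclass(dataset$config), paths[["scenario"]])
  paths
}

#' Read a scenario configuration from YAML
#'
#' @param path Path to a YAML file of [stf_scenario()] fields (missing
#'   fields take their defaults).
#' @return An `"stf_scenario"` object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  fields <- yaml::read_yaml(path)
  known <- names(formals(stf_scenario))
  unknown <- setdiff(names(fields), known)
  if (length(unknown))
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  do.call(stf_scenario, fields)
}
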