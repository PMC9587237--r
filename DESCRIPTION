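Package: severetest
Title: Severe Testing of Prognostic Omics Signatures by Surrogate Gene
    Resampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scrutinizes the biological specificity of small gene signatures
    in high-dimensional omics studies. A published target signature is
    challenged by drawing same-size surrogate gene sets from a stratified
    gene pool from which proliferation genes, the target genes, and genes
    sharing annotation terms with the target have been removed, and by
    re-running the identical evaluation method (risk-score dichotomization
    with log-rank survival comparison, or concordance) on every draw. The
    target's rank within the surrogate null yields an empirical p-value for
    the hypothesis that target and surrogate results differ; rejection marks
    the surrogates as interchangeable with the signature and falsifies its
    biological interpretation. Includes a five-layer study-suitability
    screen, interaction-neighborhood expansion bounds, a synthetic-data
    generator with a latent prognostic factor, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
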