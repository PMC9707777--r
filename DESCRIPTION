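Package: coopgi
Title: Group-Versus-Individual Performance Trade-Offs in Plant Competition
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cooperation among plants from focal-by-tester
    competition experiments. Per-genotype performance in mixtures and
    monocultures is condensed into two orthogonal axes: position along a
    fitted quadratic vigor curve (general vigor) and signed orthogonal
    distance from it (the group-versus-individual, G-I, trade-off value,
    positive for cooperative genotypes). Includes a single-marker
    association scan with minor-allele-frequency filtering, a
    density-gradient mixed-model analysis of monoculture productivity,
    payoff-matrix estimation and game classification for near-isogenic
    line competition, an ordinal model for root disease scores, and a
    synthetic-data generator that emulates the experimental designs with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    MASS,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
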