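Package: zygotrace
Title: Single-Cell Expression, Morphokinetics and Ploidy Prediction in
    Early Human Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis workflow for joint single-cell RT-qPCR, time-lapse
    morphokinetics and ploidy status of cleavage-stage human embryos.
    Provides a synthetic cohort generator (division trees, kinetic timings,
    fragmentation, per-blastomere Ct matrices with ploidy-dependent shifts),
    Ct-to-expression preprocessing with quantile normalization, per-gene
    quadratic trajectory fitting with rule-based cluster and
    gametic-versus-embryonic origin classification and activation-time
    estimation, morphokinetic parameter derivation and group comparison,
    30-hour-stratified differential expression with an empirical-Bayes
    moderated t-test, and a k-nearest-neighbour transcriptomic-signature
    classifier of embryo ploidy with repeated stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
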