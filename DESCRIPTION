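Package: carrierprev
Title: Carrier Frequency and Genetic Prevalence of Recessive Disorders
    from Population Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates the carrier frequency and genetic prevalence of
    autosomal recessive disorders from population-stratified allele
    frequencies of curated pathogenic and likely pathogenic variants,
    under Hardy-Weinberg equilibrium. Pools per-variant allele
    frequencies within each reference population, computes exact and
    first-order point estimates, and propagates Wilson score confidence
    intervals from the allele scale to the carrier and prevalence scales.
    Includes readers for tab-separated variant tables and gnomAD-style
    VCF slices, the standard pathogenicity and quality-flag filtering
    rules, a stratified population report, and a synthetic cohort
    generator with known truth for validation. Ships a fixture of
    TMPRSS6 missense variants underlying iron-refractory iron deficiency
    anaemia (IRIDA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    yaml
Config/testthat/edition: 3
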