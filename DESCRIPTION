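Package: alphacor
Title: Correlation of QTL Substitution Effects Across Populations and Generations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts the correlation of quantitative trait locus (QTL) allele
    substitution effects between two populations, breeds, or generations under
    nonadditive gene action. The correlation is expressed through genetic
    distance (Nei minimum distance or Fst), the additive, dominance and
    additive-by-additive variance components of the focal population, and
    moments of heterozygosity under an assumed allele-frequency spectrum
    (uniform, truncated 1/(pq), or symmetric Beta). Includes Kojima
    derivative-based statistical effects for three analytically tractable
    epistatic architectures (complete dominance, complementary epistasis,
    multiplicative epistasis), a folded-normal transform between random-allele
    and mutant-allele effect correlations, and a Wright-Fisher divergence
    simulator that validates the estimators against true substitution effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
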