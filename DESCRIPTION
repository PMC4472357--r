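Package: bdmseed
Title: Multilocus Bateson-Dobzhansky-Muller Models of Hybrid Seed Lethality
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact genetic modelling of parent-of-origin dependent hybrid
    seed abortion in crosses between a selfing and an outcrossing plant
    species. Provides Mendelian gamete enumeration with exact rational
    arithmetic, offspring genotype distributions under seed-stage viability
    selection, predicted seed-abortion rates for backcross pollen donors and
    their theoretical distribution across an F2 panel, chi-square
    goodness-of-fit comparison of locus-number models against per-plant seed
    counts, recombinant-inbred-line propagation by single-seed descent with
    purging of incompatible allele combinations, and a reproducible
    synthetic crossing-experiment simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
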