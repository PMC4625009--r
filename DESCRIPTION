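Package: fourwayqtl
Title: QTL Mapping and Linkage Analysis for Four-Way Cross Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trait locus (QTL) analysis in four-way
    (double) cross populations of the form (A x B) x (C x D). Provides a
    population simulator with the five marker-information categories that
    arise when founder alleles are partially confounded, maximum-likelihood
    estimation of pairwise recombination fractions from partially
    informative markers, linkage-map construction by nearest-neighbor plus
    2-opt ordering, inclusive composite interval mapping (ICIM) with two
    additive effects and one dominance effect fitted by a four-component
    normal-mixture EM algorithm, genome-wide LOD thresholds by an
    effective-test-count formula or by permutation, and multi-environment
    variance-component and heritability estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
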