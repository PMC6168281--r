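Package: larvaqtl
Title: QTL Mapping of Maternal and Zygotic Larval Traits in Structured Outbred Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetics of larval life-history traits in
    outbred intercrosses with half-sib family structure, as in crosses between
    planktotrophic and lecithotrophic populations of the polychaete Streblospio
    benedicti. Provides a synthetic-cross simulator with known truth; SNP quality
    control, sex-linkage testing and composite-likelihood inference of segregation
    patterns without parental genotypes; multi-SNP contig recoding into intercross
    markers and pedigree-error screening; de novo linkage-map construction
    (two-point recombination fractions, grouping, ordering with ripple search,
    error-LOD cleaning, genotyping-error-rate estimation, HMM genotype
    probabilities); founder-of-origin assignment from pooled population
    sequencing; and family-structured QTL mapping (Haley-Knott and logistic
    scans summed over families, within-family permutation thresholds, multi-QTL
    model fits with epistasis, multivariate Pillai-Bartlett scans, and
    mixed-model backcross penetrance tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
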