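Package: trioexpr
Title: Inheritance-Mode, Allele-Specific Expression, and Cis/Trans
    Regulatory Analysis for Parent-Parent-F1 Expression Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis cascade for RNA-seq read counts from an F1 hybrid and
    its two inbred parents across developmental stages. Classifies per-gene
    inheritance modes (additive, high- and low-parent dominance, over- and
    underdominance) against the midparent value, calls allele-specific
    expression from SNP-level allele counts with exact binomial tests and
    Benjamini-Hochberg correction, decomposes regulatory divergence into
    cis and trans components (P, H, T = P - H) with Fisher exact testing,
    and computes trait-level mid-parent and better-parent heterosis
    indices. Ships a negative-binomial/binomial simulator with known
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
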