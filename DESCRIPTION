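Package: estdigex
Title: Digital Differential Expression Screening of EST Pools with
    RNA-Seq Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies genes preferentially expressed in a focal tissue
    from expressed sequence tag (EST) counts across cDNA libraries, using
    a binomial sampling-probability statistic applied pool-by-pool at two
    homology tiers. Cross-validates candidates with RNA-seq profiles via
    FPKM normalization, a relative expression specificity (RES) statistic
    and Pearson chi-square tests, classifies genes into expression groups,
    and summarizes subgenome/copy structure of a polyploid gene catalog.
    Ships a seeded synthetic-data generator (multinomial EST libraries,
    Poisson RNA-seq counts) so every stage is testable end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
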