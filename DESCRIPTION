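Package: bcrclone
Title: Clonality and Segment-Usage Analysis of B Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for analysing B cell receptor (BCR) repertoires from
    AIRR rearrangement tables or TRUST4 report tables. Implements clone tables
    keyed on CDR3 amino-acid sequence with a replicated-sequence classification
    at a configurable pooled-frequency threshold, exact small-sample
    Mann-Whitney rank-sum tests, Pearson chi-squared association tests on
    replicated-by-genotype contingency tables, isotype and V/D/J segment-usage
    summaries, V-J pairing matrices, kappa/lambda ratios, and multi-set CDR3
    overlap reports. A seeded V(D)J recombination simulator generates
    AIRR-format repertoires with known ground truth, including a study design
    of wild-type and knockout B-1a/B-1b samples, so every analysis stage is
    verifiable without external data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
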