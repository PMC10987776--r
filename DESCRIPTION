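Package: kgtrait
Title: Knowledge-Graph Link Prediction of Trait-Regulating and Polyphenotype Genes in Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and queries a heterogeneous knowledge graph linking genes,
    proteins, traits and functional annotations across Arabidopsis, rice, maize
    and wheat, and scores gene pairs by the product of their shared-neighborhood
    size, shared-category diversity and protein sequence similarity. Provides
    F1-calibrated thresholding on a time-sliced split of literature gene-trait
    associations, multi-trait link prediction for unannotated genes, mining and
    mean-rank prioritization of polyphenotype genes (genes predicted to regulate
    two or more agronomic traits), and validation of mined genes against
    differentially-expressed-gene sets. Includes a synthetic fixture generator
    with planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
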