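Package: glycodia
Title: Glycopeptide Ion Libraries and Quantification for SWATH/DIA
    Glycoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds SWATH/DIA transition libraries from glycopeptide
    identifications and quantifies site-specific glycosylation.  Provides
    monoisotopic mass arithmetic for peptides and glycan compositions,
    theoretical fragment-ion enumeration with library slot allocation
    (Y0/Y1/Y2 and glycan-retaining b/y ions repurposed into the a/c slots
    of a PeakView-style transition list), a deterministic rule engine
    encoding oxonium- and Y-ion validation criteria for glycopeptide
    spectrum matches, transition-level extracted-ion quantification with
    top-k peptide and protein rollup, reference-protein normalization,
    site-specific glycoform relative abundances, differential tests and
    principal component analysis, and a seeded synthetic-data generator
    emulating yeast and grape wine glycoproteomes so the whole pipeline
    is testable without instrument data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
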