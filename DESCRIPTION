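Package: g4snv
Title: Spatial Association of G-Quadruplexes with Somatic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the spatial relationship between
    G-quadruplex (G4) loci and single-nucleotide variants in cancer
    cohorts. Provides native genomic-interval arithmetic (signed
    nearest-feature distances, overlap counting, window tiling, masked
    random intervals), consensus PQS motif scanning and GC counting,
    cohort preprocessing (germline filtering, cancer-type exclusion,
    G4-capped genomic windows), distance-density metaprofiles with
    parametric Gaussian fitting, G4-stratified window enrichment with
    GC-controlled partial correlation, incomplete categorical
    bootstrapping with linear-regression sweeps, patient-level
    G4-average statistics and Cox proportional-hazards survival
    modelling, plus a synthetic-study generator with planted spatial,
    linear and survival structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    withr,
    survival,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    GenomicRanges,
    stringi,
    optparse
Config/testthat/edition: 3
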