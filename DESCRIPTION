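Package: memochip
Title: Chromatin Binding and Transcriptional Memory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for stimulus-dependent kinase chromatin binding
    and T-cell transcriptional memory studies. Provides interval arithmetic and
    genomic/chromatin-state annotation of ChIP-seq peaks, non-log minus-average
    (MA) normalization of peak counts between conditions, classification of
    genes into stimulation-response expression groups, Fisher-exact
    binding-by-group enrichment, binned tag-density matrices and PWM
    motif-proximity scanning around binding-site centers, kinase
    peptide-microarray substrate profiling, per-cell nuclear-translocation and
    colocalization quantification, and seeded synthetic-data generators with
    planted ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
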