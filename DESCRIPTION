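Package: procescape
Title: Processing-Escape Analysis of Tumour Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying immune escape through altered proteasomal
    epitope processing in tumour cohorts. Reads somatic variant calls, applies
    depth and allele-frequency evidence filters, projects retained single
    nucleotide variants onto transcript models as missense protein changes,
    enumerates wildtype/mutant epitope windows with flanking context, scores
    proteasomal cleavage with pluggable matrix backends and calls processing
    mutations by a 50-percent cleavage-probability difference, classifies
    altered epitopes by MHC class I supertype binding and immunogenicity,
    aggregates per-patient processing-mutation burden, and correlates burden
    with clinical covariates and overall survival (Fisher's exact comparison,
    Kaplan-Meier, Cox proportional hazards with FDR adjustment). Includes a
    synthetic cohort generator with planted ground truth and a transcribed
    cohort-count fixture for desk-scale reproduction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
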