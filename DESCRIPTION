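Package: tcrpmhc
Title: Template Curation, Confidence Scoring and Docking Assessment for
    TCR-pMHC Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scaffolding for T cell receptor (TCR) - peptide-MHC complex
    structure prediction with the deep-learning folding engine abstracted
    behind a pluggable predictor interface. Provides peptide-MHC template
    library curation (resolution and date filters, Class II peptide
    trimming, redundancy capping), BLOSUM62 similarity-ranked template
    selection, single-sequence TCR template search, focused sequence
    database assembly, confidence scoring from predicted-aligned-error
    matrices (pTM, ipTM, TCR-pMHC group ipTM, model confidence, CDR3
    pLDDT), CAPRI/DockQ docking assessment including peptide-MHC interface
    classification and unbound-TCR CDR loop RMSD, benchmark redundancy
    filtering, and an end-to-end job pipeline with a deterministic mock
    predictor plus synthetic fixture generators for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
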