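Package: p53scan
Title: Scanning and Functional Grading of p53 Response Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies canonical full-site, non-canonical three-quarter
    (3Q) and half-site p53 response elements in DNA sequences and grades
    every hit on a five-level transactivation-potential scale using a
    declarative, position-aware penalty rule system. Supporting analyses
    include GC-preserving local-permutation and GC-matched random null
    models with exact binomial enrichment tests, TSS-centered positional
    metaprofiles, log2 probability-ratio position weight matrix scoring
    for cross-method comparison, distal open-chromatin interval filtering,
    and a synthetic fixture generator that plants response elements of
    known class and grade for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
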