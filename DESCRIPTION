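Package: crossvar
Title: Cross-Platform Somatic Variant Consolidation and Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable tumor/normal variant-interpretation pipeline for
    matched exome (WES) and whole-genome (WGS) sequencing. Consolidates
    per-caller call sets across platforms with mutant-allele-fraction
    support, extracts somatic variants, estimates tumor cellularity from
    the somatic allele-fraction distribution, computes six-class and
    96-context mutational spectra with reference trinucleotide
    normalization, detects localized hypermutation (kataegis) by a sliding
    window, extracts and refits mutational signatures, scores per-gene
    exonic conservation against a population panel, flags GO-term variant
    burdens exceeding the panel maximum, and filters structural variants
    including a coverage-based germline exclusion for de novo insertions.
    A synthetic-data generator with recorded ground truth emulates every
    input so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
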