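Package: cnvscore
Title: Semiautomated Evidence Scoring and Classification of Copy-Number Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates constitutional copy-number variants (deletions and
    duplications) against locally supplied genome annotation tables (gene
    models, ClinGen-style dosage-sensitivity curations, established benign
    regions, population CNV frequencies, known variants and curated critical
    regions), automatically scores the automatable criteria of the 2019
    ACMG/ClinGen CNV interpretation scoring metric (18 criteria for
    copy-number loss, 16 for copy-number gain), validates and merges manual
    evidence for the remaining criteria, and maps the summed point total to
    the five-tier clinical classification. Includes an intragenic
    loss-of-function (PVS1-style) evaluator with reading-frame and
    nonsense-mediated-decay prediction, a deterministic synthetic-database
    generator so every scoring branch is testable offline, and JSON/TSV/text
    reporting for single and batch queries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
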