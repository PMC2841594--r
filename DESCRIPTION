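Package: imprintmarks
Title: Combinatorial Histone-Mark Profiles at Imprinted and Developmentally
    Regulated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to distinguish histone-modification profiles associated
    with genomic-imprinting control from those associated with developmental
    regulation. Reads enrichment-region call sets (BED-like), resolves gene
    identifiers through aliases, scores mark enrichment in windows around
    transcription start sites, classifies combinatorial mark profiles
    (including bivalent H3K4me3/H3K27me3 domains and the H3K4me3/H3K9me3/
    H4K20me3 tri-mark signature of imprinting control regions), integrates
    expression and differential-methylation status, tracks bivalency
    resolution across cell types, and runs condition-checked chi-square
    comparisons with Yates' correction. A parameterized synthetic-data
    generator with retained ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
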