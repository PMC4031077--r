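Package: methtrace
Title: Developmental Tracing of Aberrant CpG Island Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects aberrant CpG-island de novo methylation in embryonic
    stem cells by developmental tracing against a normal-tissue panel.
    Scores methylated-DNA immunoprecipitation (mDIP) two-channel microarray
    data as Island Methylation Scores (IMS) via melting-temperature
    stratified Z-normalization, aggregates per-CpG bisulfite counts to
    island-level percents with coverage filters, defines a constitutively
    unmethylated background set and calls excess methylation against it,
    couples methylation gain to H3K27me3/H3K4me3 chromatin density, and
    ships a fully seeded synthetic-data generator with planted truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
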