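Package: omistack
Title: Single-File Storage and Retrieval of Multi-Omic Data Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified store/retrieve/annotate/extend interface for tabular
    multi-omic datasets ("layers") kept together in one embedded,
    single-file SQL database (a "stack"). Two interchangeable storage
    engines are provided behind the same API: a row-oriented layout for
    frequent small transactions and a column-oriented layout for fast
    whole-column scans. Includes chunked ingestion of (gzip-compressed)
    VCF files with genotype-column extraction and position queries, a
    synthetic multi-omic data generator (cohort characteristics,
    metabolomics, bulk RNA-seq, gut microbiome, and VCF layers), and a
    benchmark harness that summarises storage and retrieval scaling with
    a regression through the origin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    dplyr,
    parallel,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
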