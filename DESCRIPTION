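Package: tumorgem
Title: Multi-Biopsy Tumor Variant Database and Allele-Frequency Filtering Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a searchable relational database from an annotated
    multi-sample VCF and a tumor sample manifest (patient, sampling time,
    optional purity), and provides allele-frequency-pattern filtering tools
    for prioritizing variants across longitudinal and multi-region tumor
    biopsies: bottleneck (rising variant allele frequency over time), loh
    (loss of heterozygosity), truncal (present in all tumors, absent from
    normals), unique (private to a set of samples), and set_somatic
    (depth/frequency-based somatic flagging). Includes an SQL query
    interface over annotation columns, purity correction of allele
    frequencies, a synthetic-cohort generator with planted variant classes
    for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    DBI,
    RSQLite,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
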