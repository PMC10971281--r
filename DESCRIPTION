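Package: svtriangulate
Title: Integration of Structural Variant Calls from Short-Read Sequencing,
    Optical Genome Mapping and RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tumor-only somatic structural variant (SV) detection by
    triangulating three technologies. Builds a high-confidence whole-genome
    sequencing (WGS) call set by dual-caller consensus (LUMPY-style and
    DELLY-style VCF dialects), removes likely germline polymorphisms against a
    control database, matches the consensus set against optical genome mapping
    (OGM) calls with type-specific overlap and window rules, reclassifies
    repeat-driven translocation artifacts as insertions, partitions WGS
    breakpoints unsupported by OGM into explanation categories, and
    triangulates DNA-derived gene-fusion candidates with RNA-Seq read support.
    Includes a seeded call-set simulator so the whole pipeline is testable
    without external data, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
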