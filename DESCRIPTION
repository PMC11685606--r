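Package: orimut
Title: Origin-Centric Analysis of Somatic Mutagenesis in Cancer Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies somatic mutagenesis focused at DNA replication
    origins. Provides origin geometry (domains, flanks, isolation and
    cluster filters), per-window mutation density and burden-ratio
    statistics, background- and composition-adjusted 96-context
    mutational signatures with cosine clustering and non-negative
    exposure refitting, G4Hunter G-quadruplex propensity scoring and
    motif discovery, strand-resolved excision-repair profiling with
    reactive-dinucleotide correction, structural-variant and copy-number
    signature classes with origin-boundary permutation tests,
    expression-derived replicative-stress covariates, and a fully seeded
    synthetic-cohort generator with planted, recoverable effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    glmnet,
    ape,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
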