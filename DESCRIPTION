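Package: hotspotter
Title: Mutational Hotspot Discovery from Tumor/Normal Variant Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A five-phase pipeline for identifying significantly mutated
    genomic regions (mutational hotspots) across cohorts of tumor/normal
    sample pairs. Imports per-sample variant calls and sample metadata,
    extracts cancer-exclusive (putative somatic) variants by filtering
    against matched normals, a panel of normals and known-polymorphism
    sets, annotates variants against interval-indexed annotation sets and
    gene models (synonymous / non-synonymous / non-coding), clusters
    variants by genomic proximity and by shared annotated region,
    re-validates putative somatic calls from tumor and matched-normal
    read pileups (somatic / germline / artifact triage), scores regions
    with a binomial test against the background mutation rate with
    Benjamini-Hochberg correction and per-cohort Fisher enrichment, and
    emits ranked HTML reports with UCSC custom tracks. Includes a
    deterministic cohort simulator producing reference, gene models,
    VCFs, SAM alignments and a machine-readable truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    xml2,
    jsonlite
Config/testthat/edition: 3
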