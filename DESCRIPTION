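Package: msykit
Title: Male-Specific Y Region Classification, Haplotyping and Dating
Version: 0.1.0
Authors@R:
    person("MSY", "Toolkit Authors", email = "msykit@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and dating male-specific Y chromosome
    (MSY) haplotype genealogies from short-read resequencing summaries.
    Classifies assembly windows into single-copy Y, multi-copy Y and
    non-Y-specific regions with a Poisson likelihood-ratio model of male
    versus female mapping coverage; applies haploid-aware variant quality
    filters and phylogenetic imputation; constructs the perfect phylogeny
    implied by the infinite-sites model with per-branch mutation counts;
    tests branch-length equality with simulated p-values; estimates
    de novo mutation rates from pedigree-calibrated generation intervals;
    and performs closed-form Poisson molecular-clock dating. Includes
    synthetic-data generators for coverage tables, infinite-sites
    genealogies and patriline pedigrees so every stage can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    ape,
    phangorn,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
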