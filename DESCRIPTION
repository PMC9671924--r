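Package: seismic
Title: Driver Detection from Cohort Mutational Skew in Cancer Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects signals of positive selection in somatic mutation data
    by testing, for each gene or genomic region, whether the identity of the
    mutated tumours across a cohort deviates from the pattern expected under
    neutral mutagenesis, given each tumour's mutational burden and
    trinucleotide signature. Mutation recurrence is deliberately ignored:
    per-tumour mutation probabilities are rescaled so that the expected
    number of mutated tumours matches the observed number, and the observed
    combination of mutated tumours is compared against Monte-Carlo simulated
    cohorts through a gamma-tail likelihood test. Includes trinucleotide
    territory accounting, coding-effect annotation, per-tumour (WGS) and
    burden-scaled per-cohort (WXS) mutation models, cohort quality filters,
    Benjamini-Hochberg correction, cumulative mutated-tumour (CMT) plot
    series, an exact small-cohort enumeration oracle, and a synthetic-cohort
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    MASS
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
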