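Package: divedit
Title: Windowed Divergence Scans and CRISPR/Cas9 Editing Design for Butterfly Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nominating and functionally testing candidate
    diversification genes in closely related butterfly species. Implements a
    three-way windowed fixed-difference divergence scan with smoothed
    empirical-quantile cutoffs and tri-pair intersection into divergent
    regions; integration of divergence with positive-selection and
    stage-resolved differential-expression evidence into ranked candidate
    genes; CRISPR/Cas9 sgRNA target enumeration with 5' dinucleotide and
    12-nt seed-uniqueness filters plus synthesis-ready oligo construction;
    mismatch-tolerant genome-wide off-target enumeration; global-alignment
    based mutation typing of Sanger-sequenced amplicon clones with
    mutagenesis-efficiency accounting; and seeded synthetic-data generators
    with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
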