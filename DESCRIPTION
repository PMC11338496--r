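Package: metadetect
Title: Genome Presence Detection from Read-Mapping Evenness in Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides which genomes of a reference catalog are truly present
    in a shotgun metagenomic sample from the genome-wide distribution of
    mapped reads. Computes two per-genome coverage-evenness statistics from
    a coordinate-sorted SAM/BAM file: the breadth to expected-breadth ratio
    (BER), which compares observed sequencing breadth with the breadth
    predicted from average coverage, and the fraction of unexpected gaps
    (FUG), which scores inter-read distances against a homogeneous Poisson
    placement model. A thresholded caller combines the two metrics with a
    mapped-read detection limit, a normalized read-count statistic (Rcn)
    summarises abundance, and a seeded simulator writes valid sorted SAM
    alignments with uniform, region-restricted, or bimodal placement
    patterns for end-to-end testing. Evaluation helpers score calls against
    truth labels, including coverage-binned true positive and true negative
    rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    Biostrings,
    Rsamtools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
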