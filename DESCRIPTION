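Package: timexr
Title: Allele-Specific Replication Timing Profiles and Asynchrony Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building replication-timing profiles from S-phase/G1-phase
    sequencing read depths at phased heterozygous SNPs (the TimEX S/G1 ratio
    approach), detecting asynchronously replicated domains (ARDs) between the
    maternal and paternal homologs with a gap-tolerant island finder followed by
    chi-square tests and Benjamini-Hochberg FDR control, and quantifying timing
    delays. Includes a synthetic-data generator with binomial spike-in
    resampling for power and false-discovery benchmarking, dual-scale smoothing
    to call sub-domain timing ripples and nascent-strand clusters, S-phase
    quintile partitioning, interval association and bootstrap enrichment
    statistics, and a randomization test for the effect of structural variants
    on allelic timing. All user-facing functions take and return tidy data
    frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
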