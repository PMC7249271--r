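Package: ssrskim
Title: Microsatellite Marker Development and Diversity Statistics from
    Genome-Skim Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing simple sequence repeat (SSR) markers from
    shallow whole-genome ("genome skim") assemblies of non-model plants and
    for characterising the resulting genotypes.  The pipeline scans contigs
    for perfect di-, tri- and tetranucleotide tandem repeats, enumerates and
    scores candidate primer pairs in the repeat flanks with nearest-neighbor
    melting temperatures, applies a published retention filter (pair penalty,
    per-primer penalty, melting-temperature difference, primer-to-repeat
    distance and product size), screens markers for in-silico repeat-count
    polymorphism across individuals via flank-anchored local alignment, and
    computes per-population diversity panels: allele counts, private alleles,
    observed heterozygosity, unbiased expected heterozygosity, exact
    Hardy-Weinberg tests and the pairwise index of association with a
    permutation null.  Seeded simulators generate reference contigs,
    individual assemblies and genotype matrices with known truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
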