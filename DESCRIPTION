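Package: spodotype
Title: Diagnostic-SNP Strain Typing and Population Genetics of Invasive Fall Armyworm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-based strain typing and population-genetic analysis of fall
    armyworm (Spodoptera frugiperda) survey data. Classifies nuclear Tpi and
    mitochondrial COI amplicon sequences into corn-strain (C) and rice-strain (R)
    classes from diagnostic single-nucleotide sites, resolves Tpi corn-strain
    subgroups (Ca1a, Ca2a, Ca2b and the Ca1/Ca2 heterozygote) from exon and intron
    polymorphisms with IUPAC ambiguity handling, collapses aligned sequences into
    haplotypes, computes DnaSP-style diversity statistics (segregating sites,
    haplotype diversity, nucleotide diversity, Watterson's theta per site, and
    Tajima's D with its beta-approximation significance bands), and builds a
    minimum spanning haplotype network with mutational-step edge weights.
    Includes a seeded synthetic-data generator that reproduces the haplotype
    structure of a 27-specimen, two-marker African/Asian invasion survey so the
    whole pipeline is testable without sequence downloads.
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
    igraph,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
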