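Package: mitocomp
Title: Comparative Mitogenomics of Gene Order, Composition, tRNA
    Compensatory Changes and Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated animal
    mitochondrial genomes: strand- and codon-position-partitioned
    nucleotide composition (A+T content, AT- and GC-skews), codon-usage
    statistics (effective number of codons, MILC, GC3 at fourfold
    degenerate sites), circular signed gene-order comparison with
    rearrangement scenario search (reversals, transpositions, reverse
    transpositions, tandem duplication-random loss), Fitch parsimony
    ancestral reconstruction on a fixed rooted topology, classification
    of compensatory base changes in tRNA cloverleaf stems, congruence of
    compensatory-change clusterings with a reference phylogeny (Baker's
    gamma, tanglegrams), physicochemical-property selection scans with a
    counting-method dN/dS, and a seeded synthetic-data generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
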