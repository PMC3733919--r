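Package: cosmap
Title: Chromosome Assignment and Comparative Synteny Mapping of COS Markers
    in Aegilops U and M Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns gene-based conserved orthologous set (COS) marker loci to
    Aegilops U- and M-genome chromosomes from wheat-Aegilops introgression-line
    genotyping and from flow-sorted subgenomic DNA fractions, detects
    intragenomic duplications, and builds comparative physical maps against
    model grass genomes (Brachypodium, rice) to call synteny blocks and
    evolutionary rearrangements relative to wheat. Includes a synthetic-data
    generator with planted ground truth so every stage of the pipeline can be
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
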