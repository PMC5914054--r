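Package: karyoshuffle
Title: Synteny Blocks, Genome Rearrangements, and Karyotype Evolution in
    Malaria Mosquitoes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chromosome-level comparative genomics of Anopheles
    mosquitoes and similar systems: anchoring of assembly scaffolds to
    chromosome arms via a physical map (AGP), inference of gap-free scaffold
    adjacencies from ortholog contiguity in reference genomes, construction of
    conserved synteny blocks from one-to-one ortholog anchors with a gap
    threshold, exact multichromosomal rearrangement distances and minimal
    sorting scenarios over inversions, translocations, fusions and fissions
    (signed permutations, breakpoint-graph theory), median-of-three ancestral
    karyotype reconstruction, a random-breakage null model for synteny block
    lengths, per-element inversion counts and rearrangement rates per Mb per
    million years, and a fully seeded synthetic-data generator that emulates a
    scaffold-level assembly with a known rearrangement history.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    generics,
    igraph,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
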