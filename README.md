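# karyoshuffle

Chromosome-level comparative genomics for malaria mosquitoes and similar
systems: physical-map anchoring of assembly scaffolds, conserved synteny
blocks, exact multichromosomal rearrangement distances and scenarios,
ancestral-karyotype (median) reconstruction, a random-breakage null model
for block lengths, and rearrangement-rate summaries — with a fully seeded
synthetic-data generator so the whole pipeline is testable without any
external download.

## The scientific problem

*Anopheles* mosquitoes have kept 2n = 6 chromosomes for ~100 My, and their
five chromosome arms ("elements" e1–e5, e1 = X) were long thought to evolve
as intact units, reshuffled internally by paracentric inversions and
re-associated only by whole-arm translocations. High-coverage physical maps
(FISH of probes onto polytene chromosomes, giving the order and orientation
of genomic scaffolds along arms) make it possible to test that picture:
ortholog coordinates lifted to chromosome space are chained into conserved
synteny blocks, the blocks' signed orders per arm become multichromosomal
signed permutations, and minimal rearrangement scenarios between species
reveal whether partial-arm exchanges — breakpoints near the centromeres —
have broken element integrity.

At the core is the genome rearrangement model of breakpoint-graph theory:
a genome is a set of linear chromosomes of signed blocks, and the distance
between two genomes is the minimum number of operations from
{paracentric inversion, reciprocal translocation, fusion, fission}
transforming one into the other. karyoshuffle computes this distance
*exactly* by iterative-deepening A* with the DCJ distance as an admissible
lower bound, enumerates the operation-type decompositions achievable by
minimal scenarios, and reconstructs a median genome `m` minimising
`d(a,m) + d(b,m) + d(c,m)` as a proxy for the ancestral karyotype,
reporting all co-optimal medians it finds.

## Worked example

The canonical in-package fixture is the set of nine major pericentromeric
synteny blocks of *An. gambiae*, *An. atroparvus* and *An. albimanus*,
encoded over four chromosome elements in the `$` dialect:

```r
library(karyoshuffle)
gs <- anopheles_genomes()
gs$atroparvus
#> >An_atroparvus
#> -1 $ -9 $ 6 -4 -5 $ -2 -3 -8 7 $

genome_distance(gs$gambiae, gs$atroparvus)
#> [1] 5
```

Five operations separate the two species. Minimal scenarios are not unique
in their operation types, so we ask for one with the classical
decomposition — three paracentric inversions and two translocations:

```r
sc <- find_scenario(gs$gambiae, gs$atroparvus,
                    n_inversions = 3, n_translocations = 2)
tidy(sc)[, c("step", "kind", "subtype", "genome_after")]
#>    step kind          subtype                   genome_after
#> 1     1 inversion     inversion                 1 $ 2 3 4 -6 -5 $ 7 8 $ 9 $
#> 2     2 inversion     inversion                 1 $ 6 -4 -3 -2 -5 $ 7 8 $ 9 $
#> 3     3 inversion     inversion                 1 $ 6 -4 -3 -2 -5 $ -7 8 $ 9 $
#> 4     4 translocation whole_arm_translocation   1 $ 6 -4 -3 -8 7 $ 5 2 $ 9 $
#> 5     5 translocation partial_arm_translocation 1 $ 6 -4 -5 $ -7 8 3 2 $ 9 $
```

Each step is a genome one operation further from *gambiae* and one closer
to *atroparvus*; the two translocations exchange (pericentromeric) material
between elements, which is precisely the signature that breaks whole-arm
synteny. `median_genome(gs$gambiae, gs$atroparvus, gs$albimanus)` then
reconstructs putative ancestral karyotypes: the best achievable total tree
length is 10, and among the co-optimal medians is one that differs from
*gambiae* by inversions alone.

Physical-map accounting is exact arithmetic — anchoring 200,912,972 bp of a
224,290,125 bp assembly:

```r
pm <- physical_map(tibble::tibble(scaffold = "anchored", arm = "all",
                                  orientation = "+", length_bp = 200912972))
mapped_fraction(pm, 224290125)
#> [1] 89.6
```

meaning 89.6% of the assembly is chromosome-anchored (the remaining 10.4%
sits in unplaced scaffolds, tracked rather than dropped).

The rest of the toolkit follows the same tibble-in/tibble-out style:
`lift_anchors()` converts ortholog coordinates from scaffold to chromosome
space through an AGP physical map; `infer_adjacency()`/`glue_scaffolds()`
call gap-free scaffold adjacencies from ortholog contiguity in reference
genomes; `build_blocks()` produces conserved synteny blocks and their
per-genome signed orders; `simulate_block_lengths()` and
`compare_largest_blocks()` implement the random-breakage null;
`inversion_counts()`, `rate_per_mb_my()`, `classify_block_positions()` and
`largest_blocks()` provide the per-element and positional summaries; and
`sim_config()`/`generate_truth()`/`fragment_to_scaffolds()`/`emit_tables()`
generate fully known synthetic datasets. `autoplot()` methods draw block
maps and null-model comparisons; `tidy()`/`glance()` methods summarise
scenarios, medians and block sets.

## Vignette

`vignettes/karyotype-rearrangements.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale, the
numerical conventions, what the synthetic-data generator does and does not
emulate, and known limitations.
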