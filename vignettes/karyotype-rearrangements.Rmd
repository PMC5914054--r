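---
title: "Models and methods: synteny blocks, rearrangement distances and the random-breakage null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: synteny blocks, rearrangement distances and the random-breakage null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoshuffle)
```

karyoshuffle analyses karyotype evolution at the resolution of chromosome
arms and conserved synteny blocks, in the setting typified by the malaria
mosquitoes: three chromosomes (2n = 6), five arms homologous across species
("chromosome elements" e1–e5, e1 being the X), gene orders reshuffled mostly
by paracentric inversions, plus occasional partial-arm translocations that
exchange pericentromeric material between autosomal arms. This vignette
records the models implemented, the parameters that matter, the numerical
choices, and what the synthetic-data tests do and do not demonstrate.

## Signed genomes and the rearrangement distance

A genome is a set of linear chromosomes, each a sequence of signed block
identifiers; the sign encodes relative orientation. A chromosome read
backwards with all signs flipped is the same chromosome, and chromosome
order is immaterial (flip equivalence). Text I/O uses the `$` dialect
(`1 2 $ -3 $`), with typographic minus signs and en-dashes normalised on
parsing because published gene orders often carry them.

`genome_distance()` returns the minimum number of operations from the set
{paracentric inversion, reciprocal translocation, fusion, fission}
separating two genomes — the classical multichromosomal rearrangement
distance of breakpoint-graph theory. Rather than implementing the closed
formula with its delicate corrections (hurdles, fortresses and their
multichromosomal analogues), the package computes the distance by
iterative-deepening A* over the actual operation set, using the
double-cut-and-join (DCJ) distance as the admissible, consistent lower
bound: every operation in the set is a single DCJ, so one step reduces the
bound by at most one. The search is exact by construction — no special-case
analysis to get wrong — and instantaneous at the chromosome-arm block
counts this analysis works at (≤ ~20 blocks; the worked nine-block example
sorts in milliseconds). The trade-off is that the approach is not meant for
hundreds of markers. An independent check is built in:
`bfs_genome_distance()` is a plain breadth-first search with its own move
generation, used in the tests to certify the solver on every random small
instance.

Minimal scenarios (`sorting_scenario()`) are assembled step by step from
operations that provably reduce the remaining distance by one. Because the
operation-type decomposition of a minimal scenario is not unique, the
package can enumerate all achievable decompositions
(`scenario_decompositions()`) by memoised search over the minimal-scenario
DAG and materialise a scenario with a prescribed composition
(`find_scenario()`). Tests against published operation counts are phrased
as existence of a minimal scenario with the published decomposition, never
as uniqueness.

Operations are classified against the genome they apply to: reciprocal
exchanges of two proper sub-arm segments are partial-arm translocations;
moves that relocate an entire chromosome intact are whole-arm; merges and
splits are fusions and fissions. A one-sided move of a proper internal tail
also counts as partial-arm, since it breaks element integrity.

## Median (ancestral karyotype) reconstruction

`median_genome()` seeks a genome minimising the summed distance to three
input genomes. The search is greedy in the manner of the classical
multiple-genome-rearrangement heuristic: repeatedly apply, to one of the
three working genomes, an operation that brings it closer to both other
genomes (these "good" operations are preferred; any strictly improving
operation is accepted otherwise), until the three meet. Restarts permute
which genome is offered operations first and shuffle candidate order.
The design deviates from an exact branch-and-bound: exactness is instead
*certified* whenever the result attains the perfect-median lower bound
⌈(d(a,b)+d(a,c)+d(b,c))/2⌉, and flagged heuristic otherwise. For the
nine-block worked example the bound is 9 and the best achievable total is
10, so the result carries the heuristic flag even though it reproduces the
published tree length.

Medians are rarely unique. After the greedy phase the package walks the
plateau of equal-total genomes reachable by single operations (budgeted,
default 60) and reports all co-optimal medians found — the honest answer to
"which ancestor?" is the whole set, and downstream consumers can select
among them by biological criteria (e.g. which co-optimal median is within
inversions-only reach of a given genome).

## Coordinate lifting and scaffold gluing

The physical map is a tibble of scaffold placements (arm, rank from the
telomere, orientation, length, offset), read and written as AGP v2.1;
coordinates are 0-based half-open internally and converted at the AGP
boundary (1-based inclusive). Lifting is exact arithmetic: forward
placements add the offset; reverse placements reflect within the scaffold
and flip strand. Unplaced scaffolds are never silently dropped — the count
is warned about and recorded, because the unmapped fraction is part of the
accounting a physical map must report.

Scaffold gluing emulates the synteny-based adjacency test: `k` boundary
genes (default 5; the choice is exposed because published procedures say
only "several" to "several dozen") from the facing ends of two candidate
scaffolds must have orthologs that are contiguous in rank, on a single
sequence, and consistently ordered in *every* reference genome. Unanimity
is required; a missing ortholog or an under-populated scaffold end yields
`undetermined` rather than a call in either direction. This is
deliberately conservative: a false junction corrupts every downstream
rearrangement count, whereas an undetermined pair merely leaves a
cytogenetic gap.

## Synteny blocks

`build_blocks()` chains one-to-one ortholog anchors shared by all genomes:
two anchors are linked when their gene-end-to-gene-start gap is at most
`gap_bp` in every genome (115 kb by default, applied per genome — the
GRIMM-Synteny convention); connected components become blocks; components
whose members interleave with foreign anchors in some genome are split at
that genome's largest rank discontinuity, recursively (a deterministic
simplification of the published tools' overlap repair, which is not fully
specified in print); components with fewer than `min_anchors` genes
(default 2, which deliberately excludes single-gene transpositions) are
dropped. Signs are majority votes of consecutive-pair orientations against
the reference genome, ties resolved toward the longer-spanning run.

Two consequences matter for interpretation. First, a rearranged segment
whose span is below the gap threshold is absorbed into its surrounding
block and becomes invisible — the method has a hard resolution floor of
`gap_bp`. Second, a gene stranded alone between two nearby breakpoints is
discarded by the anchor floor and takes its two breakpoints with it, so
block-level distances can slightly undercount very dense histories. Both
effects are properties of the block model itself, not implementation
accidents, and both are exercised deliberately in the tests.

## The random-breakage null model

To ask whether observed large blocks are compatible with uniformly placed
breakpoints, `simulate_block_lengths()` draws `(N−1)·2` break positions
uniformly on `[0, M]` (`N` = number of blocks, `M` = genome length; integer
positions by default, continuous available), cuts the genome into the
`2N−1` intervals delimited by the breaks plus the endpoints 0 and `M`, and
keeps a uniform half — `N` intervals sampled without replacement — as block
lengths, the discarded half playing the role of inter-block gaps. Including
both endpoints is the convention that makes "remove one half" leave exactly
`N` of `2N−1` intervals; the removal is uniform subsampling, not
alternation. Interval lengths before subsampling sum to `M` exactly in
every replicate, a conservation law the acceptance tests assert.

`compare_largest_blocks()` compares a chosen percentile (default 99th,
linear interpolation between order statistics, ties inclusive) of observed
block lengths against the same percentile of the pooled null sample, and
reports the mean and standard error of the observed above-percentile
blocks. The planted-block test runs in a regime chosen so that the planted
length is genuinely anomalous: 150 blocks on a 60 Mb genome give a null
99th percentile near 0.9 Mb, so three planted 1.5 Mb conserved blocks must
lift the observed percentile above it; with a 224 Mb genome and 440 blocks
a 1.5 Mb block sits at the null's own 99th percentile and no method could
flag it.

## Rates and positional summaries

Per-element fixed-inversion counts are unichromosomal reversal distances
(the same solver restricted to inversions), computed on the blocks shared
by the two copies of an element; elements absent from a genome are `NA`.
Rates are the plain normalisation `n / (L/10^6) / T` with `L` the
pair-averaged assembly (or mapped) length and `T` the divergence time in
MY; the length convention is the caller's choice and is echoed in the
output, because published genome-average rates computed from printed
columns under this formula do not reproduce exactly and the undocumented
factor is not worth guessing. Block positions along an arm are classified
into four quadrants by midpoint (`1 + floor(4·mid/L)`, clamped; quadrants 1
and 4 = terminal); an any-overlap variant is available, midpoint being the
unambiguous default.

## The synthetic-data generator

`generate_truth()` builds an ancestor of `n_genes` genes laid on
`n_chromosomes` arms with uniform-integer gene lengths (2–8 kb) and
intergenic gaps (20–60 kb), then applies per-lineage histories: interior
(paracentric) inversions and translocations whose cut points are drawn with
probability mass concentrated near chromosome ends, mimicking
pericentromeric partial-arm exchanges. Gene lengths travel with genes;
intergenic gaps are redrawn per lineage. `fragment_to_scaffolds()` cuts
chromosomes at intergenic midpoints into approximately exponential scaffold
lengths targeting a configured N50 (500 kb default), flips each scaffold
with probability ½, and returns the true AGP. `emit_tables()` writes the
anchor TSV, AGP, `$`-dialect genomes and a JSON manifest with MD5 checksums;
identical seeds reproduce identical bytes.

Scale choices are deliberate and fixed: every rearranged segment contains
at least `min_segment_genes = 5` genes (~185 kb at the default spacing, at
minimum ~90 kb), because simulated events must exceed the 115 kb gap
threshold to be recoverable at all — real fixed inversions span megabases,
far above the threshold, and a generator emitting sub-threshold events
would test nothing but the resolution floor. Likewise the default 240
genes against ≤18 junctions (a 13:1 gene:junction ratio) is conservative
relative to real data (~12,000 orthologs against hundreds of junctions,
~30:1); at much lower ratios genes get stranded between breakpoints and
the anchor floor discards them, which is method behaviour, not noise. The
X-enrichment preset gives the first chromosome three times the autosomal
inversion count (6 vs 2 per lineage) on equal-sized chromosomes, so the
expected X/autosome rate ratio is exactly 3.

What the generator does *not* emulate: nucleotide sequence, repeats and
heterochromatin, unequal gene content, duplications, transpositions,
assembly errors, and the empirical size distribution of real scaffolds.
Passing the end-to-end tests therefore shows the pipeline's logic is sound
under its own model assumptions, not that real VectorBase extracts would
be recovered with the same fidelity.

## Problem sizes and numerical conventions

The shipped tests run the oracle comparison on 500 random genomes of 2–6
blocks, metric properties on 100 random triples of up to 8 blocks,
end-to-end recovery on 50 seeded replicates of the default configuration,
planted-block detection on 100 runs, and gluing on 100+ simulated adjacent
pairs — sizes chosen to exercise every property at comfortable margins
while keeping the whole suite in minutes on one CPU. All randomness flows
from explicit integer seeds; percentiles use R's type-7 quantile; the
anchors exchange format is 0-based half-open TSV with header
`gene_id genome seq start end strand`.

## Known limitations

- The distance solver targets block-scale inputs; it is exponential in the
  worst case and not suitable for hundreds of markers.
- The median is heuristic above the certified lower bound; co-optimal
  enumeration is budgeted, so the reported set can be incomplete.
- Interleaving repair in block construction is a declared simplification of
  the published tools' behaviour; block sets need not match GRIMM-Synteny
  bit-for-bit.
- Non-1:1 ortholog families must be filtered before block construction.
- Circular chromosomes are unsupported (mosquito chromosomes are linear).
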