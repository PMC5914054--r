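test_that("collinear anchors chain into a single block with the right signs", {
  a <- toy_anchors(3)
  bl <- build_blocks(a, gap_bp = 115e3, min_anchors = 2)
  expect_equal(length(unique(bl$blocks$block_id)), 1L)
  expect_true(all(bl$blocks$sign == "+"))
  expect_equal(format_mgr(bl$genomes$A), "1 $")
  # reversed order in genome B flips the sign
  b <- a
  rows <- b$genome == "B"
  b$start[rows] <- rev(b$start[rows]); b$end[rows] <- rev(b$end[rows])
  bl2 <- build_blocks(b, gap_bp = 115e3, min_anchors = 2)
  expect_equal(bl2$blocks$sign[bl2$blocks$genome == "B"], "-")
  expect_equal(format_mgr(bl2$genomes$B), "-1 $")
})

test_that("anchors beyond the gap threshold start a new block", {
  a <- toy_anchors(4, spacing = 10e3)
  a$start[a$gene_id %in% c("g3", "g4")] <- a$start[a$gene_id %in% c("g3", "g4")] + 3e5
  a$end[a$gene_id %in% c("g3", "g4")] <- a$end[a$gene_id %in% c("g3", "g4")] + 3e5
  bl <- build_blocks(a, gap_bp = 115e3, min_anchors = 2)
  expect_equal(length(unique(bl$blocks$block_id)), 2L)
})

test_that("non one-to-one orthologs are rejected; unshared genes are excluded", {
  a <- toy_anchors(3)
  expect_error(build_blocks(dplyr::bind_rows(a, a[1, ])), "one-to-one")
  a2 <- toy_anchors(4)
  a2 <- a2[!(a2$genome == "B" & a2$gene_id == "g4"), ]
  expect_message(bl <- build_blocks(a2, gap_bp = 115e3, min_anchors = 2),
                 "absent")
  expect_false("g4" %in% bl$anchors$gene_id)
})

test_that("known inversion histories are reconstructed block-for-breakpoint", {
  # ten hand-placed interior inversions, five per lineage; all junctions are
  # at least two genes apart, so no breakpoint reuse and no stranded genes
  anc <- signed_genome(list(1:30, 31:60, 61:90))
  invs1 <- list(c(1, 2, 6), c(1, 9, 13), c(2, 3, 8), c(2, 12, 16), c(3, 4, 9))
  invs2 <- list(c(1, 16, 20), c(1, 23, 27), c(2, 19, 24),
                c(3, 12, 17), c(3, 20, 25))
  apply_invs <- function(g, invs) {
    for (v in invs) g <- apply_op(g, op_row("inversion", v[1],
                                            i = v[2] - 1, j = v[3]))
    g
  }
  g1 <- apply_invs(anc, invs1)
  g2 <- apply_invs(anc, invs2)
  anchors <- dplyr::bind_rows(anchors_from_genome(g1, "L1"),
                              anchors_from_genome(g2, "L2"))
  bl <- build_blocks(anchors, gap_bp = 115e3, min_anchors = 2)
  n_chrom <- n_chromosomes(g1)
  bp <- breakpoint_count(g1, g2)
  n_blocks_found <- length(unique(bl$blocks$block_id))
  expect_lte(abs(n_blocks_found - (bp + n_chrom)), 1L)
  # induced signed genomes reproduce the true gene-level distance (10 inversions)
  expect_equal(genome_distance(g1, g2), 10L)
  expect_equal(genome_distance(bl$genomes$L1, bl$genomes$L2), 10L)
})

test_that("gap threshold and anchor floor act monotonically on block counts", {
  sim <- generate_truth(sim_config(n_genes = 120, seed = 59))
  # gaps all above the gene spacing, where the anchor floor does not interact
  counts <- vapply(c(115e3, 250e3, 500e3), function(gap) {
    bl <- suppressMessages(suppressWarnings(
      build_blocks(sim$anchors, gap_bp = gap, min_anchors = 2)))
    length(unique(bl$blocks$block_id))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))   # larger gap, never more blocks
  n2 <- counts[2]
  bl3 <- suppressMessages(suppressWarnings(
    build_blocks(sim$anchors, gap_bp = 115e3, min_anchors = 3)))
  expect_lte(length(unique(bl3$blocks$block_id)), n2)
})

test_that("blocks never overlap within a genome and anchors belong to one block", {
  sim <- generate_truth(sim_config(n_genes = 120, seed = 61))
  bl <- suppressMessages(build_blocks(sim$anchors))
  expect_false(any(duplicated(paste(bl$anchors$genome, bl$anchors$gene_id))))
  overlaps <- bl$blocks |>
    dplyr::group_by(genome, seq) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(ok = all(dplyr::lead(start)[-dplyr::n()] >= end[-dplyr::n()]),
                     .groups = "drop")
  expect_true(all(overlaps$ok))
})

test_that("pairwise per-element counts are consistent and need labels", {
  sim <- generate_truth(sim_config(n_genes = 120, seed = 67))
  labels <- tidyr::expand_grid(genome = names(sim$lineages),
                               seq = paste0("chr", 1:3)) |>
    dplyr::mutate(element = sub("chr", "e", seq))
  counts <- suppressMessages(count_blocks_by_element(sim$anchors, labels))
  per_pair <- counts |>
    dplyr::filter(element != "total") |>
    dplyr::group_by(genome_a, genome_b) |>
    dplyr::summarise(n = sum(n_blocks), .groups = "drop")
  totals <- dplyr::filter(counts, element == "total")
  expect_equal(per_pair$n, totals$n_blocks)
  expect_error(
    suppressMessages(count_blocks_by_element(sim$anchors, labels[-1, ])),
    "element label")
})
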