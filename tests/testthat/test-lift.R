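test_that("forward and reverse placements lift as offset and reflection", {
  pm <- physical_map(tibble::tibble(
    scaffold = c("sF", "sR"), arm = c("2R", "2R"),
    orientation = c("+", "-"), length_bp = c(100L, 100L)
  ))
  a <- tibble::tibble(gene_id = c("f", "r"), genome = "q",
                      seq = c("sF", "sR"), start = 10L, end = 20L,
                      strand = "+")
  # place each on its own arm for clean offsets
  pm$offset_bp <- c(1000L, 1000L)
  pm$arm <- c("A1", "A2")
  lifted <- lift_anchors(a, pm)
  f <- lifted[lifted$gene_id == "f", ]
  r <- lifted[lifted$gene_id == "r", ]
  expect_equal(c(f$start, f$end, f$strand), c("1010", "1020", "+"),
               ignore_attr = TRUE)
  expect_equal(c(r$start, r$end, r$strand), c("1080", "1090", "-"),
               ignore_attr = TRUE)
})

test_that("lift and unlift are inverse on a fragmented synthetic genome", {
  sim <- generate_truth(sim_config(n_genes = 60, seed = 5))
  fr <- fragment_to_scaffolds(sim$lineages$lineage1$anchors, 3e5, seed = 9)
  lifted <- lift_anchors(fr$anchors, fr$map)
  orig <- dplyr::arrange(sim$lineages$lineage1$anchors, gene_id)
  got <- dplyr::arrange(lifted, gene_id)
  expect_equal(got$start, orig$start)
  expect_equal(got$end, orig$end)
  expect_equal(got$strand, orig$strand)
  expect_equal(got$seq, orig$seq)
  back <- dplyr::arrange(unlift_anchors(lifted, fr$map), gene_id)
  fra <- dplyr::arrange(fr$anchors, gene_id)
  expect_equal(back$start, fra$start)
  expect_equal(back$seq, fra$seq)
  expect_equal(back$strand, fra$strand)
  # anchors of one scaffold occupy a contiguous arm interval within it
  joined <- dplyr::inner_join(fr$anchors, fr$map, by = c(seq = "scaffold"))
  expect_true(all(joined$start >= 0 & joined$end <= joined$length_bp))
})

test_that("anchors on unplaced scaffolds are dropped with a logged count", {
  pm <- physical_map(tibble::tibble(scaffold = "s1", arm = "X",
                                    orientation = "+", length_bp = 50L))
  a <- tibble::tibble(gene_id = c("a", "b"), genome = "q",
                      seq = c("s1", "s_unplaced"), start = 0L, end = 10L,
                      strand = "+")
  expect_warning(out <- lift_anchors(a, pm), "1 anchor")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_unmapped"), 1L)
})

test_that("mapped fraction arithmetic and consistency guard", {
  pm <- physical_map(tibble::tibble(scaffold = "s", arm = "X",
                                    orientation = "+", length_bp = 0))
  expect_equal(mapped_fraction(pm, 100), 0)
  pm2 <- physical_map(tibble::tibble(scaffold = "s", arm = "X",
                                     orientation = "+", length_bp = 150))
  expect_error(mapped_fraction(pm2, 100), "exceeds")
})

test_that("AGP round-trips placements including declared gaps", {
  pm <- physical_map(tibble::tibble(
    scaffold = c("s1", "s2", "s3"), arm = c("3R", "3R", "3L"),
    orientation = c("+", "-", "+"), length_bp = c(100L, 200L, 50L),
    gap_before_bp = c(0L, 500L, 0L)
  ))
  path <- withr::local_tempfile(fileext = ".agp")
  write_agp(pm, path)
  back <- read_agp(path)
  expect_equal(back$scaffold, pm$scaffold)
  expect_equal(back$offset_bp, pm$offset_bp)
  expect_equal(back$length_bp, pm$length_bp)
  expect_equal(back$orientation, pm$orientation)
  expect_equal(back$gap_before_bp, pm$gap_before_bp)
})

test_that("a physical map rejects duplicate or overlapping placements", {
  expect_error(physical_map(tibble::tibble(
    scaffold = c("s", "s"), arm = "X", orientation = "+", length_bp = 10L
  )), "more than once")
  expect_error(physical_map(tibble::tibble(
    scaffold = c("a", "b"), arm = "X", orientation = "+",
    length_bp = c(100L, 10L), rank = c(0L, 1L), offset_bp = c(0L, 50L)
  )), "overlap")
})
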