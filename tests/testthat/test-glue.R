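# tiny hand-built query/reference anchor sets for adjacency verdicts:
# reference genome R carries genes g1..g8 in order on one chromosome;
# the query has them split across two scaffolds (sA: g1..g4, sB: g5..g8)
glue_fixture <- function() {
  ref <- tibble::tibble(
    gene_id = paste0("g", 1:8), genome = "R", seq = "chr1",
    start = (0:7) * 10e3, end = (0:7) * 10e3 + 1e3, strand = "+"
  )
  qry <- dplyr::bind_rows(
    tibble::tibble(gene_id = paste0("g", 1:4), genome = "Q", seq = "sA",
                   start = (0:3) * 10e3, end = (0:3) * 10e3 + 1e3, strand = "+"),
    tibble::tibble(gene_id = paste0("g", 5:8), genome = "Q", seq = "sB",
                   start = (0:3) * 10e3, end = (0:3) * 10e3 + 1e3, strand = "+")
  )
  list(ref = ref, qry = qry)
}

test_that("contiguous boundary orthologs in one reference give 'adjacent'", {
  fx <- glue_fixture()
  v <- infer_adjacency("sA", "sB", fx$qry, fx$ref, k = 2)
  expect_equal(v$verdict, "adjacent")
  expect_equal(c(v$orientation_a, v$orientation_b), c("+", "+"))
  # orientation is recovered when the second scaffold is stored flipped
  qry2 <- fx$qry
  flip <- qry2$seq == "sB"
  L <- 31e3                       # scaffold sB length
  s_old <- qry2$start[flip]; e_old <- qry2$end[flip]
  qry2$start[flip] <- L - e_old
  qry2$end[flip] <- L - s_old
  qry2$strand[flip] <- "-"
  v2 <- infer_adjacency("sA", "sB", qry2, fx$ref, k = 2)
  expect_equal(v2$verdict, "adjacent")
  expect_equal(v2$orientation_b, "-")
})

test_that("orthologs split across reference sequences give 'not_adjacent'", {
  fx <- glue_fixture()
  ref2 <- fx$ref
  ref2$seq[5:8] <- "chr2"   # the two scaffold ends map to different sequences
  v <- infer_adjacency("sA", "sB", fx$qry, ref2, k = 2)
  expect_equal(v$verdict, "not_adjacent")
})

test_that("a single dissenting reference vetoes the adjacency", {
  fx <- glue_fixture()
  ref_bad <- fx$ref
  ref_bad$genome <- "R2"
  ref_bad$seq[5:8] <- "chr2"
  both <- dplyr::bind_rows(fx$ref, ref_bad)
  v <- infer_adjacency("sA", "sB", fx$qry, both, k = 2)
  expect_equal(v$verdict, "not_adjacent")
  expect_equal(v$n_refs, 2L)
})

test_that("missing orthologs or short scaffold ends give 'undetermined'", {
  fx <- glue_fixture()
  ref_missing <- dplyr::filter(fx$ref, gene_id != "g4")
  v <- infer_adjacency("sA", "sB", fx$qry, ref_missing, k = 2)
  expect_equal(v$verdict, "undetermined")
  v2 <- infer_adjacency("sA", "sB", fx$qry, fx$ref, k = 5)  # only 4 genes per scaffold
  expect_equal(v2$verdict, "undetermined")
})

test_that("gluing calls no false adjacency on a small simulated fragmentation", {
  sim <- generate_truth(sim_config(n_genes = 120, seed = 77,
                                   inversions_per_lineage = 1,
                                   translocations_per_lineage = 0))
  fr <- fragment_to_scaffolds(sim$lineages$lineage1$anchors, 2e5, seed = 78)
  refs <- dplyr::bind_rows(sim$lineages$lineage2$anchors,
                           sim$lineages$lineage3$anchors)
  map <- dplyr::arrange(fr$map, arm, rank)
  true_adjacent <- dplyr::bind_rows(purrr::map_dfr(split(map, map$arm), function(m) {
    if (nrow(m) < 2) return(NULL)
    tibble::tibble(scaffold_a = utils::head(m$scaffold, -1),
                   scaffold_b = utils::tail(m$scaffold, -1))
  }))
  set.seed(79)
  fake <- tibble::tibble(
    scaffold_a = sample(map$scaffold, 15, replace = TRUE),
    scaffold_b = sample(map$scaffold, 15, replace = TRUE)
  )
  fake <- dplyr::anti_join(
    dplyr::filter(fake, scaffold_a != scaffold_b),
    dplyr::bind_rows(true_adjacent,
                     dplyr::rename(true_adjacent, scaffold_a = scaffold_b,
                                   scaffold_b = scaffold_a)),
    by = c("scaffold_a", "scaffold_b"))
  verdicts <- glue_scaffolds(dplyr::bind_rows(true_adjacent, fake),
                             fr$anchors, refs, k = 3)
  called <- verdicts[verdicts$verdict == "adjacent", ]
  truth_keys <- c(paste(true_adjacent$scaffold_a, true_adjacent$scaffold_b),
                  paste(true_adjacent$scaffold_b, true_adjacent$scaffold_a))
  expect_gt(nrow(called), 0)
  expect_true(all(paste(called$scaffold_a, called$scaffold_b) %in% truth_keys))
})
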