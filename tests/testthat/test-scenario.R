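test_that("identity pair gives the empty scenario", {
  g <- signed_genome(list(c(1L, 2L), c(3L, 4L)))
  sc <- sorting_scenario(g, g)
  expect_equal(sc$distance, 0L)
  expect_equal(nrow(sc$steps), 0L)
  expect_equal(glance(sc)$n_ops, 0L)
})

test_that("scenarios are minimal and every prefix reduces the distance by one", {
  set.seed(31)
  for (trial in 1:8) {
    a <- random_genome(6)
    b <- apply_random_ops(a, 3)
    d <- genome_distance(a, b)
    for (policy in c("first-found", "min-translocations")) {
      sc <- sorting_scenario(a, b, policy)
      expect_equal(nrow(sc$steps), d)
      if (d > 0) {
        along <- vapply(sc$steps$genome_after, function(s) {
          genome_distance(parse_mgr(s)[[1]], b)
        }, integer(1))
        expect_equal(unname(along), d - seq_len(d))
        expect_true(genomes_equal(parse_mgr(sc$steps$genome_after[d])[[1]], b))
      }
    }
  }
})

test_that("operation classification distinguishes arm exchanges", {
  g <- signed_genome(list(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  # exchange of non-empty tails of two 3-block chromosomes
  expect_equal(classify_op(g, op_row("translocation", 1, 2, 1, 1, 1)),
               "partial_arm_translocation")
  # an entire chromosome moves intact
  expect_equal(classify_op(g, op_row("translocation", 1, 2, 0, 1, 1)),
               "whole_arm_translocation")
  # merging the two chromosomes
  expect_equal(classify_op(g, op_row("translocation", 1, 2, 3, 0, 1)), "fusion")
  expect_equal(classify_op(g, op_row("inversion", 1, i = 0, j = 2)), "inversion")
  expect_equal(classify_op(g, op_row("fission", 1, i = 1)), "fission")
})

test_that("glance counts equal an independent recount of the steps", {
  set.seed(37)
  a <- random_genome(7)
  b <- apply_random_ops(a, 4)
  sc <- sorting_scenario(a, b, "min-translocations")
  g <- glance(sc)
  expect_equal(g$n_ops, nrow(sc$steps))
  expect_equal(g$n_inversions, sum(sc$steps$kind == "inversion"))
  expect_equal(g$n_inversions + g$n_translocations + g$n_fusions + g$n_fissions,
               g$n_ops)
})

test_that("decomposition search finds a planted inversion/translocation mix", {
  a <- signed_genome(list(c(1L, 2L, 3L, 4L), c(5L, 6L, 7L, 8L)))
  b <- a
  b <- apply_op(b, op_row("translocation", 1, 2, 2, 2, 1))
  b <- apply_op(b, op_row("inversion", 1, i = 1, j = 3))
  b <- apply_op(b, op_row("translocation", 1, 2, 1, 3, 2))
  d <- genome_distance(a, b)
  expect_equal(d, 3L)
  dec <- scenario_decompositions(a, b)
  expect_true(any(dec$n_inversions == 1 & dec$n_translocations == 2 &
                    dec$n_other == 0))
  sc <- find_scenario(a, b, n_inversions = 1, n_translocations = 2)
  g <- glance(sc)
  expect_equal(g$n_inversions, 1L)
  expect_equal(g$n_translocations, 2L)
  expect_error(find_scenario(a, b, n_inversions = d + 5, n_translocations = 0),
               "sums to")
})
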