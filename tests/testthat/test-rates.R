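test_that("per-element inversion counts: identity, single inversion, missing element", {
  anc <- signed_genome(list(c(1L, 2L, 3L), c(4L, 5L)), elements = c("e1", "e2"))
  same <- signed_genome(list(c(1L, 2L, 3L), c(4L, 5L)), elements = c("e1", "e2"))
  inv <- signed_genome(list(c(1L, -2L, 3L), c(4L, 5L)), elements = c("e1", "e2"))
  partial <- signed_genome(list(c(1L, 2L, 3L)), elements = "e1")
  out <- inversion_counts(list(anc = anc, s = same, i = inv, p = partial),
                          reference = "anc")
  expect_equal(out$n_inversions[out$genome == "s"], c(0L, 0L))
  expect_equal(out$n_inversions[out$genome == "i" & out$element == "e1"], 1L)
  expect_true(is.na(out$n_inversions[out$genome == "p" & out$element == "e2"]))
  # totals are row sums
  tot <- dplyr::summarise(dplyr::group_by(out, genome),
                          total = sum(n_inversions, na.rm = TRUE))
  expect_equal(tot$total[tot$genome == "i"], 1L)
})

test_that("per-element counts track applied inversions on simulated histories", {
  set.seed(71)
  ok <- 0; n_rep <- 50
  for (r in 1:n_rep) {
    cfg <- sim_config(n_genes = 90, n_lineages = 1,
                      inversions_per_lineage = c(3L, 0L, 0L),
                      translocations_per_lineage = 0, seed = 7000 + r)
    sim <- generate_truth(cfg)
    out <- inversion_counts(list(ancestor = sim$ancestor$genome,
                                 l1 = sim$lineages$lineage1$genome),
                            reference = "ancestor")
    n1 <- out$n_inversions[out$element == "e1"]
    expect_lte(n1, 3L)                       # never exceeds the applied ops
    expect_equal(sum(out$n_inversions[out$element != "e1"]), 0L)
    if (n1 == 3L) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.9)                # equality for short histories
})

test_that("rate formula, unit proportionality and guards", {
  expect_equal(rate_per_mb_my(100, 1e8, 10), 0.1)
  expect_equal(rate_per_mb_my(100, 1e8, 20), 0.05)  # doubling T halves the rate
  expect_equal(rate_per_mb_my(50, 5e7, 10), rate_per_mb_my(100, 1e8, 10))
  expect_error(rate_per_mb_my(10, 1e6, 0), "positive")
  df <- tibble::tibble(n_rearrangements = c(309, 465),
                       assembly_len_bp = c(248699585, 198814682),
                       divergence_my = c(58, 100))
  out <- rearrangement_rates(df)
  expect_equal(out$rate_per_mb_my,
               df$n_rearrangements / (df$assembly_len_bp / 1e6) / df$divergence_my)
})

test_that("quadrant classification follows the floor-of-midpoint convention", {
  out <- classify_block_positions(
    tibble::tibble(start = c(5, 45, 95), end = c(15, 55, 100),
                   arm_length = 100))
  expect_equal(out$quadrant, c(1L, 3L, 4L))
  expect_equal(out$position_class, c("terminal", "middle", "terminal"))
  expect_error(classify_block_positions(
    tibble::tibble(start = -5, end = 10, arm_length = 100)), "outside")
})

test_that("uniformly placed blocks are terminal about half the time", {
  set.seed(73)
  mid <- runif(1000, 0, 1)
  df <- tibble::tibble(start = mid, end = mid, arm_length = 1)
  frac <- mean(classify_block_positions(df)$position_class == "terminal")
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("largest-block thresholding keeps ties and is monotone in the percentile", {
  equal <- tibble::tibble(genome = "g", length = rep(1e5, 100))
  out <- largest_blocks(equal)
  expect_equal(nrow(out$blocks), 100L)       # all tie at the threshold
  one_big <- tibble::tibble(genome = "g", length = c(rep(1e5, 99), 1e6))
  out2 <- largest_blocks(one_big, percentile = 99)
  expect_equal(nrow(out2$blocks), 1L)
  expect_equal(out2$blocks$length, 1e6)
  set.seed(79)
  rnd <- tibble::tibble(genome = "g", length = rexp(500, 1e-5))
  s <- largest_blocks(rnd)$summary
  expect_true(s$min_length <= s$mean_length && s$mean_length <= s$max_length)
  n99 <- nrow(largest_blocks(rnd, 99)$blocks)
  n95 <- nrow(largest_blocks(rnd, 95)$blocks)
  expect_lte(n99, n95)
})
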