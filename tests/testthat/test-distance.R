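test_that("distance basics: identity, single inversion, block-set mismatch", {
  set.seed(2)
  for (i in 1:5) {
    g <- random_genome(sample(2:7, 1))
    expect_equal(genome_distance(g, g), 0L)
  }
  expect_equal(genome_distance(signed_genome(list(c(1L, 2L, 3L))),
                               signed_genome(list(c(1L, -2L, 3L)))), 1L)
  expect_error(genome_distance(signed_genome(list(c(1L, 2L))),
                               signed_genome(list(c(1L, 3L)))), "3")
})

test_that("distance agrees with the BFS oracle near a random 5-block genome", {
  set.seed(7)
  for (trial in 1:50) {
    a <- random_genome(5)
    b <- apply_random_ops(a, sample(0:3, 1))
    expect_equal(genome_distance(a, b), bfs_genome_distance(a, b))
  }
})

test_that("distance is a metric on flip-equivalence classes", {
  set.seed(13)
  for (trial in 1:25) {
    n <- sample(3:8, 1)
    a <- random_genome(n); b <- random_genome(n); c <- random_genome(n)
    dab <- genome_distance(a, b)
    dba <- genome_distance(b, a)
    expect_equal(dab, dba)                      # symmetry
    expect_equal(dab == 0, genomes_equal(a, b)) # identity of indiscernibles
    dac <- genome_distance(a, c); dbc <- genome_distance(b, c)
    expect_lte(dab, dac + dbc)                  # triangle inequality
  }
})

test_that("whole-chromosome flips leave all distances unchanged", {
  set.seed(19)
  for (trial in 1:10) {
    n <- sample(4:8, 1)
    a <- random_genome(n); b <- random_genome(n)
    af <- a
    for (k in seq_along(af$chromosomes)) {
      if (stats::runif(1) < 0.5) af$chromosomes[[k]] <- -rev(af$chromosomes[[k]])
    }
    af$chromosomes <- rev(af$chromosomes)
    expect_equal(genome_distance(af, b), genome_distance(a, b))
  }
})

test_that("distance is bounded below by breakpoints/2 and above by ops applied", {
  set.seed(23)
  for (trial in 1:20) {
    n <- sample(4:8, 1)
    a <- random_genome(n)
    k <- sample(0:4, 1)
    b <- apply_random_ops(a, k)
    d <- genome_distance(a, b)
    expect_lte(d, k)
    expect_gte(d, breakpoint_count(a, b) / 2)
    expect_gte(d, dcj_distance(a, b))
  }
})

test_that("inversion-only distance sorts single chromosomes and matches full search", {
  expect_equal(genome_distance(signed_genome(list(c(1L, 2L, 3L))),
                               signed_genome(list(c(1L, -2L, 3L))),
                               inversions_only = TRUE), 1L)
  set.seed(29)
  for (trial in 1:15) {
    n <- sample(3:7, 1)
    a <- signed_genome(list(sample(n) * sample(c(-1L, 1L), n, replace = TRUE)))
    b <- signed_genome(list(sample(n) * sample(c(-1L, 1L), n, replace = TRUE)))
    drev <- genome_distance(a, b, inversions_only = TRUE)
    expect_gte(drev, genome_distance(a, b))  # more moves can only help
  }
})
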