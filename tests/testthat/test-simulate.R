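test_that("zero operations leave descendants identical to the ancestor", {
  sim <- generate_truth(sim_config(n_genes = 40, inversions_per_lineage = 0,
                                   translocations_per_lineage = 0, seed = 2))
  for (l in sim$lineages) {
    expect_true(genomes_equal(l$genome, sim$ancestor$genome))
    expect_equal(nrow(l$ops), 0L)
  }
})

test_that("one inversion changes exactly two gene adjacencies", {
  sim <- generate_truth(sim_config(n_genes = 40, n_lineages = 2,
                                   inversions_per_lineage = 1,
                                   translocations_per_lineage = 0, seed = 3))
  for (l in sim$lineages) {
    expect_equal(breakpoint_count(sim$ancestor$genome, l$genome), 2L)
    expect_equal(genome_distance(sim$ancestor$genome, l$genome), 1L)
  }
})

test_that("distance to the ancestor is bounded by, and usually equals, the ops applied", {
  set.seed(83)
  eq <- 0; n_rep <- 100
  for (r in 1:n_rep) {
    n_inv <- sample(0:2, 1); n_tr <- sample(0:1, 1)
    sim <- generate_truth(sim_config(n_genes = 90, n_lineages = 1,
                                     inversions_per_lineage = n_inv,
                                     translocations_per_lineage = n_tr,
                                     seed = 8000 + r))
    d <- genome_distance(sim$ancestor$genome, sim$lineages$lineage1$genome)
    expect_lte(d, n_inv + n_tr)
    if (d == n_inv + n_tr) eq <- eq + 1
  }
  expect_gte(eq / n_rep, 0.95)
})

test_that("infeasible configurations are rejected", {
  expect_error(generate_truth(sim_config(n_genes = 24, n_chromosomes = 3,
                                         min_segment_genes = 5)),
               "too small")
})

test_that("fragmentation respects the N50 target and degenerates gracefully", {
  sim <- generate_truth(sim_config(n_genes = 40, seed = 5,
                                   inversions_per_lineage = 0,
                                   translocations_per_lineage = 0))
  a <- sim$lineages$lineage1$anchors
  whole <- fragment_to_scaffolds(a, scaffold_n50_bp = 1e9, seed = 6)
  expect_equal(nrow(whole$map), length(unique(a$seq)))  # one scaffold per chromosome
  # empirical N50 near the target once there are many scaffolds
  big <- generate_truth(sim_config(n_genes = 600, seed = 7,
                                   inversions_per_lineage = 0,
                                   translocations_per_lineage = 0))
  fr <- fragment_to_scaffolds(big$lineages$lineage1$anchors,
                              scaffold_n50_bp = 1e5, seed = 8)
  expect_gte(nrow(fr$map), 100)
  expect_lt(abs(fr$n50_bp - 1e5) / 1e5, 0.25)
})

test_that("emitted tables round-trip and are reproducible bit-for-bit", {
  sim <- generate_truth(sim_config(n_genes = 60, seed = 13))
  fr <- fragment_to_scaffolds(sim$lineages$lineage1$anchors, 3e5, seed = 14)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- emit_tables(sim, d1, fragmentations = list(lineage1 = fr))
  back <- read_anchors(f1[["anchors"]])
  expect_equal(nrow(back), nrow(sim$anchors))
  expect_true(all(back$start < back$end))
  expect_true(all(back$strand %in% c("+", "-")))
  gm <- read_mgr(f1[["genomes"]])
  expect_true(genomes_equal(gm$ancestor, sim$ancestor$genome))
  expect_true(genomes_equal(gm$lineage2, sim$lineages$lineage2$genome))
  pm <- read_agp(f1[["agp_lineage1"]])
  expect_equal(sort(pm$scaffold), sort(fr$map$scaffold))
  # lifting the emitted scaffold-space anchors recovers chromosome space
  lifted <- lift_anchors(dplyr::filter(back, genome == "lineage1"), pm)
  orig <- dplyr::arrange(sim$lineages$lineage1$anchors, gene_id)
  expect_equal(dplyr::arrange(lifted, gene_id)$start, orig$start)
  # same seed, same bytes
  sim2 <- generate_truth(sim_config(n_genes = 60, seed = 13))
  fr2 <- fragment_to_scaffolds(sim2$lineages$lineage1$anchors, 3e5, seed = 14)
  f2 <- emit_tables(sim2, d2, fragmentations = list(lineage1 = fr2))
  for (nm in setdiff(names(f1), "manifest")) {
    expect_identical(unname(tools::md5sum(f1[[nm]])),
                     unname(tools::md5sum(f2[[nm]])))
  }
  man <- jsonlite::read_json(f1[["manifest"]])
  expect_equal(man$seed, 13L)
  expect_equal(man$config$n_genes, 60L)
})
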