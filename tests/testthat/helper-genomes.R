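# random signed multichromosomal genome on blocks 1..n
random_genome <- function(n, max_chroms = 3) {
  perm <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
  k <- sample(seq_len(min(max_chroms, n)), 1)
  if (k == 1) return(signed_genome(list(perm)))
  splits <- sort(sample(seq_len(n - 1), k - 1))
  signed_genome(unname(split(perm, findInterval(seq_len(n), splits + 1))))
}

# apply n_ops uniformly chosen operations, returning the resulting genome
apply_random_ops <- function(g, n_ops) {
  for (i in seq_len(n_ops)) {
    ops <- enumerate_ops(g)
    g <- apply_op(g, ops[sample(nrow(ops), 1), ])
  }
  g
}

# collinear two-genome anchor table: one gene every `spacing` bp
toy_anchors <- function(n_genes = 3, genomes = c("A", "B"), spacing = 10e3,
                        gene_len = 1e3, seq = "chr1") {
  starts <- (seq_len(n_genes) - 1) * spacing
  purrr::map_dfr(genomes, function(g) {
    tibble::tibble(gene_id = paste0("g", seq_len(n_genes)), genome = g,
                   seq = seq, start = starts, end = starts + gene_len,
                   strand = "+")
  })
}

# lay a signed gene-level genome out with one gene every `spacing` bp
anchors_from_genome <- function(g, genome_id, spacing = 100e3, gene_len = 5e3) {
  purrr::imap_dfr(g$chromosomes, function(genes, ci) {
    starts <- (seq_along(genes) - 1) * spacing
    tibble::tibble(gene_id = sprintf("g%03d", abs(genes)), genome = genome_id,
                   seq = paste0("chr", ci), start = starts,
                   end = starts + gene_len,
                   strand = ifelse(genes > 0, "+", "-"))
  })
}
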