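#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure of anopheline karyotype
#' evolution observed at chromosome scale: an ancestor genome of genes laid
#' out on a few chromosome arms, descendant lineages accumulating mostly
#' paracentric inversions plus occasional partial-arm translocations whose
#' breakpoints concentrate near chromosome ends (pericentromeric exchanges),
#' and a scaffold-level assembly obtained by fragmenting one descendant into
#' oriented scaffolds of a target N50.
#'
#' Inversion segments and translocated tails always contain at least
#' `min_segment_genes` genes (default 5, spanning ~185 kb on average and
#' at least ~90 kb at the default gene spacing): fixed rearrangements
#' observed cytologically in
#' anophelines span many genes and far exceed the 115 kb block gap
#' threshold, and the block-construction filter deliberately discards
#' single-gene events (as single-gene transpositions). Inversions are drawn
#' strictly interior to the arm (paracentric, interstitial breakpoints).
#'
#' @param n_genes Total number of one-to-one ortholog genes.
#' @param n_chromosomes Number of chromosomes (arms) in the ancestor.
#' @param n_lineages Number of descendant lineages.
#' @param inversions_per_lineage Either a single count per lineage or a
#'   vector of per-chromosome counts (length `n_chromosomes`).
#' @param translocations_per_lineage Translocations per lineage.
#' @param frac_partial_arm Probability a translocation is partial-arm
#'   (reciprocal sub-arm exchange) rather than whole-arm.
#' @param scaffold_n50_bp Target scaffold N50 for [fragment_to_scaffolds()].
#' @param gene_len_range,intergenic_range Uniform integer ranges (bp) for
#'   gene lengths and intergenic gaps.
#' @param min_segment_genes Minimum genes per rearranged segment (>= 2).
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 240, n_chromosomes = 3, n_lineages = 3,
                       inversions_per_lineage = 2,
                       translocations_per_lineage = 1,
                       frac_partial_arm = 1,
                       scaffold_n50_bp = 5e5,
                       gene_len_range = c(2e3, 8e3),
                       intergenic_range = c(2e4, 6e4),
                       min_segment_genes = 5,
                       seed = 1) {
  stopifnot(n_genes >= 2 * n_chromosomes, n_chromosomes >= 1, n_lineages >= 1,
            frac_partial_arm >= 0, frac_partial_arm <= 1,
            min_segment_genes >= 2, scaffold_n50_bp > 0)
  if (length(inversions_per_lineage)
      %in% c(1L, n_chromosomes) == FALSE) {
    stop("inversions_per_lineage must be a single count or one per chromosome",
         call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    n_lineages = as.integer(n_lineages),
    inversions_per_lineage = inversions_per_lineage,
    translocations_per_lineage = as.integer(translocations_per_lineage),
    frac_partial_arm = frac_partial_arm,
    scaffold_n50_bp = scaffold_n50_bp,
    gene_len_range = gene_len_range, intergenic_range = intergenic_range,
    min_segment_genes = as.integer(min_segment_genes),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @description `sim_config_x_enrichment()` is a named preset for the
#'   X-chromosome rate-enrichment scenario: equal-sized chromosomes, no
#'   translocations, and the first chromosome (the X, element e1) receiving
#'   `x_factor` times the autosomal inversion count.
#' @param x_factor Fold enrichment of inversions on the X.
#' @param autosome_inversions Inversions per autosome per lineage.
#' @param ... Passed on to [sim_config()].
#' @export
sim_config_x_enrichment <- function(x_factor = 3, autosome_inversions = 2,
                                    n_chromosomes = 3, n_genes = 120,
                                    seed = 1, ...) {
  sim_config(
    n_genes = n_genes, n_chromosomes = n_chromosomes,
    inversions_per_lineage = c(x_factor * autosome_inversions,
                               rep(autosome_inversions, n_chromosomes - 1)),
    translocations_per_lineage = 0, seed = seed, ...
  )
}

runif_int <- function(n, range) {
  as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

# lay genes (with fixed lengths) on chromosomes, drawing fresh intergenic gaps
layout_anchors <- function(chrom_genes, gene_len, genome_id, config) {
  purrr::imap_dfr(chrom_genes, function(genes, ci) {
    gaps <- runif_int(length(genes), config$intergenic_range)
    lens <- gene_len[abs(genes)]
    starts <- cumsum(gaps) + dplyr::lag(cumsum(lens), default = 0)
    tibble::tibble(
      gene_id = sprintf("g%04d", abs(genes)),
      genome = genome_id,
      seq = sprintf("chr%d", ci),
      start = starts, end = starts + lens,
      strand = ifelse(genes > 0, "+", "-")
    )
  })
}

#' Generate a fully known synthetic rearrangement history
#'
#' Builds an ancestor genome (genes on chromosomes, uniform-integer lengths
#' and gaps), applies each lineage's configured inversions and translocations
#' to the gene order, and lays out descendant coordinates. The full truth —
#' ancestor, per-lineage operation list, descendant gene-level signed genomes
#' and anchor tables — is returned for downstream validation.
#'
#' @param config A [sim_config()].
#' @return A `karyo_sim` list: `config`, `ancestor` (list with `genome` and
#'   `anchors`), `lineages` (named list; each with `genome`, `anchors`,
#'   `ops` tibble), and `anchors` (descendant anchor tables bound together,
#'   ready for [build_blocks()]).
#' @examples
#' sim <- generate_truth(sim_config(n_genes = 30, seed = 7))
#' names(sim$lineages)
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  n <- config$n_genes
  k <- config$n_chromosomes
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  min_needed <- 2 * config$min_segment_genes
  if (any(sizes < min_needed + 2)) {
    stop("chromosomes too small for the configured rearrangements; ",
         "increase n_genes or decrease n_chromosomes", call. = FALSE)
  }
  bounds <- cumsum(sizes)
  chrom_genes <- purrr::map2(c(1, utils::head(bounds, -1) + 1), bounds,
                             function(a, b) as.integer(seq(a, b)))
  gene_len <- runif_int(n, config$gene_len_range)
  elements <- paste0("e", seq_len(k))

  anc_genome <- signed_genome(chrom_genes, name = "ancestor",
                              elements = elements)
  anc_anchors <- layout_anchors(chrom_genes, gene_len, "ancestor", config)

  inv_counts <- config$inversions_per_lineage
  lineages <- list()
  for (l in seq_len(config$n_lineages)) {
    nm <- paste0("lineage", l)
    g <- anc_genome
    ops <- list()
    # per-chromosome or pooled inversion counts
    inv_plan <- if (length(inv_counts) == 1) {
      sample(seq_len(k), inv_counts, replace = TRUE)
    } else {
      rep(seq_len(k), inv_counts)
    }
    kinds <- sample(c(rep("inversion", length(inv_plan)),
                      rep("translocation", config$translocations_per_lineage)))
    inv_iter <- sample(inv_plan)
    ii <- 0
    for (kind in kinds) {
      if (kind == "inversion") {
        ii <- ii + 1
        op <- draw_inversion(g, inv_iter[ii], config)
      } else {
        op <- draw_translocation(g, config)
      }
      ops[[length(ops) + 1L]] <- dplyr::mutate(op, subtype = classify_op(g, op))
      g <- apply_op(g, op)
    }
    g$name <- nm
    g$elements <- elements[seq_along(g$chromosomes)]
    lineages[[nm]] <- list(
      genome = g,
      anchors = layout_anchors(g$chromosomes, gene_len, nm, config),
      ops = if (length(ops)) dplyr::bind_rows(ops) else
        op_row("inversion", 1)[0, ]
    )
  }
  structure(list(
    config = config,
    ancestor = list(genome = anc_genome, anchors = anc_anchors),
    lineages = lineages,
    anchors = dplyr::bind_rows(purrr::map(lineages, "anchors"))
  ), class = "karyo_sim")
}

# interior (paracentric, interstitial) inversion of >= min_segment_genes genes
draw_inversion <- function(g, chrom, config) {
  L <- length(g$chromosomes[[chrom]])
  m <- config$min_segment_genes
  if (L < m + 2) stop("chromosome ", chrom, " too small for an inversion",
                      call. = FALSE)
  len <- sample(m:min(L - 2, max(m, L %/% 2)), 1)
  s <- sample(2:(L - len), 1)              # 1-based start, interior
  op_row("inversion", chrom, i = s - 1L, j = s - 1L + len)
}

# translocation with end-weighted cut points; all four resulting pieces keep
# >= min_segment_genes genes so no single-gene block is created
draw_translocation <- function(g, config) {
  K <- length(g$chromosomes)
  if (K < 2) stop("translocation requires at least two chromosomes", call. = FALSE)
  cs <- sample(seq_len(K), 2)
  m <- config$min_segment_genes
  L1 <- length(g$chromosomes[[cs[1]]])
  L2 <- length(g$chromosomes[[cs[2]]])
  if (L1 < 2 * m || L2 < 2 * m) {
    stop("chromosomes too small for a translocation", call. = FALSE)
  }
  end_weighted_cut <- function(L) {
    cand <- m:(L - m)
    d <- pmin(cand, L - cand)               # distance to nearest end
    sample(cand, 1, prob = 1 / (1 + d))
  }
  if (stats::runif(1) <= config$frac_partial_arm) {
    i <- end_weighted_cut(L1)
    j <- end_weighted_cut(L2)
  } else {
    i <- 0L                                 # whole chromosome moves intact
    j <- end_weighted_cut(L2)
  }
  op_row("translocation", cs[1], cs[2], i, j, sample(1:2, 1))
}

#' Fragment a genome into oriented scaffolds with a known physical map
#'
#' Cuts each chromosome at intergenic positions into scaffolds whose lengths
#' are approximately exponential with the configured N50, flips each scaffold
#' with probability 1/2, and returns the genes in scaffold coordinates
#' together with the true [physical_map] (the ground truth an AGP would
#' record). If the N50 exceeds a chromosome's length the chromosome becomes
#' a single scaffold.
#'
#' @param anchors Chromosome-space anchors of one genome (tibble with
#'   `gene_id`, `genome`, `seq`, `start`, `end`, `strand`).
#' @param scaffold_n50_bp Target N50 (bp).
#' @param seed Seed for cut positions and flips.
#' @return A `karyo_fragmentation` list: `anchors` (scaffold space), `map`
#'   (the true [physical_map]), `n50_bp` (empirical N50).
#' @examples
#' sim <- generate_truth(sim_config(n_genes = 30, seed = 7))
#' fr <- fragment_to_scaffolds(sim$lineages$lineage1$anchors, 2e5, seed = 7)
#' fr$n50_bp
#' @export
fragment_to_scaffolds <- function(anchors, scaffold_n50_bp, seed = 1) {
  anchors <- tibble::as_tibble(anchors)
  withr::local_seed(seed)
  mean_len <- scaffold_n50_bp / 1.678    # N50 of exponential lengths ~ 1.678 * mean
  rows <- list()
  out_anchors <- list()
  scf_i <- 0
  for (chrom in unique(anchors$seq)) {
    sub <- dplyr::arrange(dplyr::filter(anchors, .data$seq == chrom), .data$start)
    chrom_len <- max(sub$end) + stats::rexp(1, 2 / mean_len)
    # candidate cut positions: midpoints of intergenic intervals; none when
    # the target N50 already exceeds the chromosome
    cand <- if (nrow(sub) > 1 && scaffold_n50_bp < chrom_len) {
      floor((utils::head(sub$end, -1) + utils::tail(sub$start, -1)) / 2)
    } else numeric(0)
    # target cuts from exponential scaffold lengths, snapped to candidates
    targets <- cumsum(stats::rexp(ceiling(chrom_len / mean_len) + 5, 1 / mean_len))
    targets <- targets[targets < chrom_len]
    cuts <- sort(unique(purrr::map_dbl(targets, function(t) {
      if (length(cand) == 0) return(NA_real_)
      cand[which.min(abs(cand - t))]
    })))
    cuts <- cuts[!is.na(cuts)]
    edges <- c(0, cuts, chrom_len)
    for (s in seq_len(length(edges) - 1)) {
      scf_i <- scf_i + 1
      scf <- sprintf("scf%03d", scf_i)
      lo <- edges[s]; hi <- edges[s + 1]
      len <- hi - lo
      ori <- sample(c("+", "-"), 1)
      rows[[scf_i]] <- tibble::tibble(
        scaffold = scf, arm = chrom, rank = s - 1L, orientation = ori,
        length_bp = len, offset_bp = lo, gap_before_bp = 0)
      inside <- dplyr::filter(sub, .data$start >= lo, .data$end <= hi)
      if (nrow(inside) > 0) {
        out_anchors[[length(out_anchors) + 1L]] <- dplyr::mutate(
          inside,
          seq = scf,
          new_start = if (ori == "+") .data$start - lo else hi - .data$end,
          new_end = if (ori == "+") .data$end - lo else hi - .data$start,
          strand = if (ori == "+") .data$strand else
            ifelse(.data$strand == "+", "-", "+")
        ) |>
          dplyr::transmute(.data$gene_id, .data$genome, .data$seq,
                           start = .data$new_start, end = .data$new_end,
                           .data$strand)
      }
    }
  }
  map <- physical_map(dplyr::bind_rows(rows))
  lens <- sort(map$length_bp, decreasing = TRUE)
  n50 <- lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
  structure(list(anchors = dplyr::bind_rows(out_anchors), map = map,
                 n50_bp = n50),
            class = "karyo_fragmentation")
}

#' Write a synthetic dataset to disk in the pipeline's exchange formats
#'
#' Emits the descendant ortholog anchor table (TSV), per-fragmentation AGP
#' files, the gene-level genomes in MGR `$` dialect, and a JSON manifest
#' recording the seed, the configuration and an MD5 checksum per file, so a
#' rerun with the same seed can be verified bit-for-bit.
#'
#' @param truth A `karyo_sim` from [generate_truth()].
#' @param dir Output directory (created if needed).
#' @param fragmentations Optional named list of `karyo_fragmentation`
#'   objects (name = genome whose anchors they replace); their scaffold-space
#'   anchors are written instead of that genome's chromosome-space anchors.
#' @return Invisibly, a named character vector of the files written.
#' @export
emit_tables <- function(truth, dir, fragmentations = NULL) {
  stopifnot(inherits(truth, "karyo_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anchors <- truth$anchors
  files <- character(0)
  for (nm in names(fragmentations)) {
    fr <- fragmentations[[nm]]
    anchors <- dplyr::bind_rows(dplyr::filter(anchors, .data$genome != nm),
                                fr$anchors)
    agp <- file.path(dir, paste0(nm, ".agp"))
    write_agp(fr$map, agp)
    files[paste0("agp_", nm)] <- agp
  }
  anchors_path <- file.path(dir, "anchors.tsv")
  write_anchors(dplyr::arrange(anchors, .data$genome, .data$seq, .data$start),
                anchors_path)
  files["anchors"] <- anchors_path
  mgr_path <- file.path(dir, "genomes.mgr")
  write_mgr(c(list(ancestor = truth$ancestor$genome),
              purrr::map(truth$lineages, "genome")), mgr_path)
  files["genomes"] <- mgr_path
  manifest <- list(
    seed = truth$config$seed,
    config = unclass(truth$config),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files)))
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files["manifest"] <- manifest_path
  invisible(files)
}
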