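#' Build conserved synteny blocks from one-to-one ortholog anchors
#'
#' Chains ortholog anchors shared by all supplied genomes into conserved
#' synteny blocks: two anchors are linked when the gap between them (end of
#' one gene to start of the next) is at most `gap_bp` in *every* genome;
#' connected components of this graph are candidate blocks; components whose
#' member anchors interleave with other anchors in some genome are split at
#' that genome's largest rank discontinuity (repeatedly, largest gap first);
#' components with fewer than `min_anchors` genes (or spanning less than
#' `min_span_bp` in some genome) are dropped. Each surviving block gets, per
#' genome, a sequence, a span, a rank along the sequence, and a sign: `+`
#' when the anchor order agrees with the first genome, `-` when reversed
#' (majority over consecutive pairs; ties resolved by the longer-spanning
#' orientation run).
#'
#' @param anchors Tibble with columns `gene_id`, `genome`, `seq`, `start`,
#'   `end`, `strand`; each gene at most once per genome. Genes absent from
#'   some genome are excluded (with a message) before chaining.
#' @param gap_bp Maximum within-block gap between consecutive genes, per
#'   genome (bp).
#' @param min_anchors Minimum number of orthologous genes per block.
#' @param min_span_bp Optional minimum block span in bp (applied per genome).
#' @param reference Genome whose order defines signs and block numbering;
#'   default the first genome in the table.
#' @return An object of class `synteny_blocks`: a list with `blocks` (tibble:
#'   `block_id`, `genome`, `seq`, `start`, `end`, `sign`, `n_anchors`,
#'   `rank`), `genomes` (named list of [signed_genome] over block ids),
#'   `anchors` (the anchors used, with their block assignment) and `params`.
#'   [generics::tidy()] returns the block table; [generics::glance()] a
#'   one-row summary.
#' @examples
#' a <- tibble::tibble(
#'   gene_id = rep(paste0("g", 1:3), 2),
#'   genome = rep(c("A", "B"), each = 3),
#'   seq = "chr1", start = rep(c(0, 20e3, 40e3), 2) + 1,
#'   end = rep(c(10e3, 30e3, 50e3), 2), strand = "+"
#' )
#' build_blocks(a, gap_bp = 115e3, min_anchors = 2)
#' @export
build_blocks <- function(anchors, gap_bp = 115000, min_anchors = 2,
                         min_span_bp = 0, reference = NULL) {
  stopifnot(gap_bp > 0, min_anchors >= 2)
  anchors <- tibble::as_tibble(anchors)
  genomes <- unique(anchors$genome)
  if (length(genomes) < 2) stop("need anchors from at least two genomes", call. = FALSE)
  if (is.null(reference)) reference <- genomes[1]
  genomes <- c(reference, setdiff(genomes, reference))
  dup <- anchors |>
    dplyr::count(.data$genome, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("gene(s) appear more than once in a genome (non one-to-one ",
         "orthologs must be pre-filtered): ",
         paste(utils::head(unique(dup$gene_id), 5), collapse = ", "),
         call. = FALSE)
  }
  shared <- anchors |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n == length(genomes)) |>
    dplyr::pull(.data$gene_id)
  n_dropped <- length(unique(anchors$gene_id)) - length(shared)
  if (n_dropped > 0) {
    message(n_dropped, " gene(s) absent from some genome excluded from block construction")
  }
  anchors <- dplyr::filter(anchors, .data$gene_id %in% shared)
  if (length(shared) == 0) {
    warning("no shared anchors; empty block set", call. = FALSE)
    return(empty_blocks(genomes, gap_bp, min_anchors))
  }

  ranked <- anchors |>
    dplyr::group_by(.data$genome, .data$seq) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()

  # pairs of genes within gap_bp in one genome (gene-end to gene-start gap)
  pairs_in <- function(df) {
    out <- character(0)
    for (s in split(df, df$seq)) {
      s <- dplyr::arrange(s, .data$start)
      n <- nrow(s)
      for (i in seq_len(max(n - 1, 0))) {
        for (j in (i + 1):n) {
          if (s$start[j] - s$end[i] > gap_bp) break
          key <- paste(sort(c(s$gene_id[i], s$gene_id[j])), collapse = "\r")
          out <- c(out, key)
        }
      }
    }
    unique(out)
  }
  edge_keys <- Reduce(intersect, lapply(split(ranked, ranked$genome), pairs_in))

  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(shared)
  if (length(edge_keys) > 0) {
    em <- do.call(rbind, strsplit(edge_keys, "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(em)))
  }
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)

  # rank lookup per genome: gene -> (seq, rank)
  rank_tabs <- lapply(split(ranked, ranked$genome), function(df) {
    stats::setNames(df$rank, df$gene_id)
  })
  # split components interleaved by foreign anchors in some genome
  split_group <- function(genes) {
    if (length(genes) <= 1) return(list(genes))
    for (gt in rank_tabs) {
      rk <- sort(unname(gt[genes]))
      if (max(rk) - min(rk) + 1L != length(rk)) {
        gaps <- diff(rk)
        cut <- which.max(gaps)
        left <- genes[gt[genes] <= rk[cut]]
        right <- setdiff(genes, left)
        return(c(split_group(left), split_group(right)))
      }
    }
    list(genes)
  }
  groups <- unlist(lapply(groups, split_group), recursive = FALSE)
  groups <- groups[lengths(groups) >= min_anchors]
  if (length(groups) == 0) {
    warning("no block survived the filters; empty block set", call. = FALSE)
    return(empty_blocks(genomes, gap_bp, min_anchors))
  }

  assign <- tibble::tibble(
    gene_id = unlist(groups),
    component = rep(seq_along(groups), lengths(groups))
  )
  withblock <- dplyr::inner_join(ranked, assign, by = "gene_id")

  per_genome <- withblock |>
    dplyr::group_by(.data$genome, .data$component) |>
    dplyr::summarise(seq = .data$seq[1], start = min(.data$start),
                     end = max(.data$end), n_anchors = dplyr::n(),
                     .groups = "drop")
  if (min_span_bp > 0) {
    keep <- per_genome |>
      dplyr::group_by(.data$component) |>
      dplyr::summarise(ok = min(.data$end - .data$start) >= min_span_bp,
                       .groups = "drop")
    groups_keep <- keep$component[keep$ok]
    per_genome <- dplyr::filter(per_genome, .data$component %in% groups_keep)
    withblock <- dplyr::filter(withblock, .data$component %in% groups_keep)
    if (nrow(per_genome) == 0) {
      warning("no block survived the filters; empty block set", call. = FALSE)
      return(empty_blocks(genomes, gap_bp, min_anchors))
    }
  }

  # block numbering by position in the reference genome
  ref_order <- per_genome |>
    dplyr::filter(.data$genome == reference) |>
    dplyr::arrange(.data$seq, .data$start) |>
    dplyr::mutate(block_id = dplyr::row_number())
  id_of <- stats::setNames(ref_order$block_id, ref_order$component)

  # sign per genome relative to the reference anchor order
  ref_rank <- rank_tabs[[reference]]
  sign_of <- function(genes, gt) {
    ord <- genes[order(ref_rank[genes])]
    rk <- unname(gt[ord])
    if (length(rk) < 2) return("+")
    steps <- diff(rk)
    up <- sum(steps > 0); down <- sum(steps < 0)
    if (up > down) return("+")
    if (down > up) return("-")
    # tie: sign of the longer-spanning run of consistent orientation
    run_sign <- sign(steps)
    r <- rle(run_sign)
    spans <- numeric(length(r$lengths))
    pos <- 1L
    for (k in seq_along(r$lengths)) {
      lo <- pos; hi <- pos + r$lengths[k]
      spans[k] <- abs(rk[hi] - rk[lo])
      pos <- hi
    }
    if (r$values[which.max(spans)] >= 0) "+" else "-"
  }
  signs <- withblock |>
    dplyr::group_by(.data$genome, .data$component) |>
    dplyr::summarise(
      sign = sign_of(.data$gene_id, rank_tabs[[.data$genome[1]]]),
      .groups = "drop")

  blocks <- per_genome |>
    dplyr::inner_join(signs, by = c("genome", "component")) |>
    dplyr::mutate(block_id = unname(id_of[as.character(.data$component)])) |>
    dplyr::group_by(.data$genome, .data$seq) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$genome, .data$seq, .data$start) |>
    dplyr::select("block_id", "genome", "seq", "start", "end", "sign",
                  "n_anchors", "rank")

  signed <- lapply(genomes, function(gn) {
    sub <- dplyr::filter(blocks, .data$genome == gn)
    chroms <- lapply(split(sub, sub$seq), function(s) {
      s <- dplyr::arrange(s, .data$start)
      as.integer(ifelse(s$sign == "+", 1L, -1L) * s$block_id)
    })
    signed_genome(unname(chroms), name = gn, elements = names(chroms))
  })
  names(signed) <- genomes

  structure(list(
    blocks = blocks,
    genomes = signed,
    anchors = dplyr::mutate(withblock,
                            block_id = unname(id_of[as.character(.data$component)])) |>
      dplyr::select(-"component"),
    params = list(gap_bp = gap_bp, min_anchors = min_anchors,
                  min_span_bp = min_span_bp, reference = reference)
  ), class = "synteny_blocks")
}

empty_blocks <- function(genomes, gap_bp, min_anchors) {
  structure(list(
    blocks = tibble::tibble(block_id = integer(), genome = character(),
                            seq = character(), start = numeric(),
                            end = numeric(), sign = character(),
                            n_anchors = integer(), rank = integer()),
    genomes = list(), anchors = tibble::tibble(),
    params = list(gap_bp = gap_bp, min_anchors = min_anchors)
  ), class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  nb <- length(unique(x$blocks$block_id))
  cat("Conserved synteny blocks:", nb, "blocks across",
      length(x$genomes), "genomes (gap", x$params$gap_bp, "bp, >=",
      x$params$min_anchors, "anchors)\n")
  print(x$blocks)
  invisible(x)
}

#' @export
tidy.synteny_blocks <- function(x, ...) x$blocks

#' @export
glance.synteny_blocks <- function(x, ...) {
  tibble::tibble(
    n_blocks = length(unique(x$blocks$block_id)),
    n_genomes = length(x$genomes),
    mean_length_bp = mean(x$blocks$end - x$blocks$start),
    mean_anchors = mean(x$blocks$n_anchors[!duplicated(x$blocks$block_id)]),
    gap_bp = x$params$gap_bp,
    min_anchors = x$params$min_anchors
  )
}

#' Write a block table and the induced signed genomes to disk
#'
#' @param x A `synteny_blocks` object.
#' @param tsv_path,mgr_path Output paths (either may be `NULL` to skip).
#' @export
write_blocks <- function(x, tsv_path = NULL, mgr_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(x$blocks, tsv_path)
  if (!is.null(mgr_path)) write_mgr(x$genomes, mgr_path)
  invisible(x)
}

#' Synteny block counts per chromosome element for genome pairs
#'
#' Counts conserved synteny blocks per chromosome element for every pair of
#' genomes, rebuilding blocks for each pair in isolation (the other genomes
#' are excluded from the construction, so pairwise counts do not depend on a
#' third genome's fragmentation).
#'
#' @inheritParams build_blocks
#' @param element_labels Tibble with columns `genome`, `seq`, `element`
#'   labelling every chromosome that carries anchors.
#' @return A tibble: `genome_a`, `genome_b`, `element`, `n_blocks`, plus a
#'   `total` attribute-free row per pair with `element = "total"`.
#' @export
count_blocks_by_element <- function(anchors, element_labels, gap_bp = 115000,
                                    min_anchors = 2) {
  anchors <- tibble::as_tibble(anchors)
  genomes <- unique(anchors$genome)
  pairs <- utils::combn(genomes, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    sub <- dplyr::filter(anchors, .data$genome %in% c(ga, gb))
    bl <- suppressMessages(build_blocks(sub, gap_bp = gap_bp,
                                        min_anchors = min_anchors,
                                        reference = ga))
    ba <- dplyr::filter(bl$blocks, .data$genome == ga)
    lab <- dplyr::filter(element_labels, .data$genome == ga)
    miss <- setdiff(unique(ba$seq), lab$seq)
    if (length(miss) > 0) {
      stop("chromosome(s) without an element label in genome ", ga, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    counts <- ba |>
      dplyr::inner_join(lab, by = "seq") |>
      dplyr::count(.data$element, name = "n_blocks")
    dplyr::bind_rows(
      dplyr::mutate(counts, genome_a = ga, genome_b = gb, .before = 1),
      tibble::tibble(genome_a = ga, genome_b = gb, element = "total",
                     n_blocks = sum(counts$n_blocks))
    )
  })
}
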