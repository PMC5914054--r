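#' Fixed-inversion counts per chromosome element
#'
#' For every chromosome element shared by a genome and the reference, the
#' minimum number of inversions (unichromosomal signed reversal distance)
#' between the two block orders of that element. Elements are matched by the
#' `elements` labels of the [signed_genome]s; an element missing from either
#' genome is reported as `NA`. When the two copies of an element carry
#' different block sets (inter-arm exchanges), the count is computed on the
#' shared blocks only.
#'
#' @param genomes Named list of [signed_genome] objects with element labels.
#' @param reference Name of the reference genome (e.g. a reconstructed
#'   ancestor) in `genomes`, or a [signed_genome].
#' @return A tibble: `genome`, `element`, `n_inversions`; totals via
#'   `dplyr::summarise()`.
#' @examples
#' a <- signed_genome(list(c(1L, 2L, 3L)), elements = "e1")
#' b <- signed_genome(list(c(1L, -2L, 3L)), elements = "e1")
#' inversion_counts(list(anc = a, x = b), reference = "anc")
#' @export
inversion_counts <- function(genomes, reference) {
  ref <- if (inherits(reference, "signed_genome")) reference else genomes[[reference]]
  ref_name <- if (inherits(reference, "signed_genome")) reference$name else reference
  if (is.null(ref$elements)) stop("reference genome has no element labels", call. = FALSE)
  others <- genomes[setdiff(names(genomes), ref_name)]
  purrr::imap_dfr(others, function(g, nm) {
    purrr::map_dfr(ref$elements, function(el) {
      n <- element_inversions(ref, g, el)
      tibble::tibble(genome = nm, element = el, n_inversions = n)
    })
  })
}

element_inversions <- function(a, b, element) {
  ia <- match(element, a$elements)
  ib <- match(element, b$elements)
  if (is.na(ia) || is.na(ib)) return(NA_integer_)
  ca <- a$chromosomes[[ia]]
  cb <- b$chromosomes[[ib]]
  shared <- intersect(abs(ca), abs(cb))
  if (length(shared) == 0) return(NA_integer_)
  ca <- ca[abs(ca) %in% shared]
  cb <- cb[abs(cb) %in% shared]
  genome_distance(signed_genome(list(ca)), signed_genome(list(cb)),
                  inversions_only = TRUE)
}

#' Rearrangement rate per Mb per million years
#'
#' `rate = n / (L / 1e6) / T` with `n` rearrangements, `L` the (pair-averaged)
#' genome or mapped-assembly length in bp and `T` the divergence time in
#' million years. Vectorised; also accepts a data frame with columns
#' `n_rearrangements`, `assembly_len_bp`, `divergence_my` via
#' [rearrangement_rates()].
#'
#' @param n_rearrangements Number of rearrangements fixed between the pair.
#' @param assembly_len_bp Average assembly (or mapped) length of the pair, bp.
#' @param divergence_my Divergence time, million years.
#' @return Rate(s) in rearrangements per Mb per MY.
#' @examples
#' rate_per_mb_my(100, 1e8, 10)  # 0.1
#' @export
rate_per_mb_my <- function(n_rearrangements, assembly_len_bp, divergence_my) {
  if (any(divergence_my <= 0)) stop("divergence time must be positive", call. = FALSE)
  if (any(assembly_len_bp <= 0)) stop("assembly length must be positive", call. = FALSE)
  n_rearrangements / (assembly_len_bp / 1e6) / divergence_my
}

#' @rdname rate_per_mb_my
#' @param df Data frame with columns `n_rearrangements`, `assembly_len_bp`,
#'   `divergence_my`.
#' @export
rearrangement_rates <- function(df) {
  dplyr::mutate(tibble::as_tibble(df),
                rate_per_mb_my = rate_per_mb_my(.data$n_rearrangements,
                                                .data$assembly_len_bp,
                                                .data$divergence_my))
}

#' Positional class of a block along a chromosome arm
#'
#' Assigns each block to one of four equal quadrants of its arm by the block
#' midpoint: `quadrant = 1 + floor(4 * midpoint / arm_length)`, clamped to 4;
#' quadrants 1 (telomeric) and 4 (centromeric) are `terminal`, 2 and 3
#' `middle`. With `by = "overlap"` a block is terminal if it overlaps a
#' terminal quadrant at all.
#'
#' @param blocks Tibble with columns `start`, `end` and `arm_length`
#'   (bp; block span must lie within `[0, arm_length]`).
#' @param by `"midpoint"` (default) or `"overlap"`.
#' @return The input with `quadrant` and `position_class` columns added.
#' @examples
#' classify_block_positions(
#'   tibble::tibble(start = c(5, 45), end = c(15, 55), arm_length = 100))
#' @export
classify_block_positions <- function(blocks, by = c("midpoint", "overlap")) {
  by <- match.arg(by)
  blocks <- tibble::as_tibble(blocks)
  if (any(blocks$start < 0 | blocks$end > blocks$arm_length)) {
    stop("block span outside its arm", call. = FALSE)
  }
  if (by == "midpoint") {
    mid <- (blocks$start + blocks$end) / 2
    q <- pmin(4L, 1L + floor(4 * mid / blocks$arm_length))
  } else {
    q1 <- pmin(4L, 1L + floor(4 * blocks$start / blocks$arm_length))
    q2 <- pmin(4L, 1L + floor(4 * pmax(blocks$end - 1e-9, 0) / blocks$arm_length))
    q <- ifelse(q1 == 1 | q2 == 4, ifelse(q1 == 1, 1L, 4L), q1)
  }
  dplyr::mutate(blocks, quadrant = as.integer(q),
                position_class = ifelse(q %in% c(1L, 4L), "terminal", "middle"))
}

#' Largest synteny blocks above a per-genome length percentile
#'
#' Thresholds block lengths at the given percentile (linear interpolation
#' between order statistics, ties at the threshold included) separately per
#' genome and returns the surviving blocks plus a per-genome summary of
#' minimum, mean and maximum length among them.
#'
#' @param blocks Tibble with columns `genome` and either `length` or
#'   `start`/`end` (from which lengths are computed).
#' @param percentile Length percentile (default 99).
#' @return A list with `blocks` (rows at or above the threshold) and
#'   `summary` (per genome: `threshold`, `n_large`, `min_length`,
#'   `mean_length`, `max_length`).
#' @export
largest_blocks <- function(blocks, percentile = 99) {
  blocks <- tibble::as_tibble(blocks)
  if (nrow(blocks) == 0) stop("no blocks supplied", call. = FALSE)
  if (!"length" %in% names(blocks)) {
    blocks <- dplyr::mutate(blocks, length = .data$end - .data$start)
  }
  if (!"genome" %in% names(blocks)) blocks$genome <- "all"
  thr <- blocks |>
    dplyr::group_by(.data$genome) |>
    dplyr::summarise(threshold = stats::quantile(.data$length, percentile / 100,
                                                 names = FALSE, type = 7),
                     .groups = "drop")
  big <- blocks |>
    dplyr::inner_join(thr, by = "genome") |>
    dplyr::filter(.data$length >= .data$threshold)
  summary <- big |>
    dplyr::group_by(.data$genome) |>
    dplyr::summarise(threshold = .data$threshold[1],
                     n_large = dplyr::n(),
                     min_length = min(.data$length),
                     mean_length = mean(.data$length),
                     max_length = max(.data$length),
                     .groups = "drop")
  list(blocks = big, summary = summary)
}
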