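#' Random-breakage null model for synteny block lengths
#'
#' Simulates the lengths of `n_blocks` synteny blocks expected if
#' rearrangement breakpoints fell uniformly on a genome of length
#' `genome_bp`: per replicate, `(N-1)*2` break positions are drawn uniformly
#' on `[0, M]`; together with the boundaries 0 and `M` they delimit `2N-1`
#' intervals; a uniform half of the intervals (`N` of them, sampled without
#' replacement) is kept as the simulated block lengths — the removed half
#' plays the role of the inter-block gaps.
#'
#' @param n_blocks `N`, the (mean) number of synteny blocks.
#' @param genome_bp `M`, the (mean) genome length in bp.
#' @param reps Number of replicates.
#' @param seed Seed; identical seed and parameters give identical samples.
#' @param integer_positions Draw break positions as integer bp (default);
#'   set to `FALSE` for continuous positions.
#' @param keep_all Return all `2N-1` intervals with a logical `kept` column
#'   instead of only the retained `N` (exposes the pre-subsampling intervals,
#'   whose lengths sum exactly to `genome_bp` in every replicate).
#' @return A tibble with columns `rep` and `length` (`n_blocks` rows per
#'   replicate), plus `kept` when `keep_all = TRUE`.
#' @examples
#' sim <- simulate_block_lengths(n_blocks = 10, genome_bp = 1e6, reps = 3)
#' dplyr::count(sim, rep)
#' @export
simulate_block_lengths <- function(n_blocks, genome_bp, reps = 1000, seed = 1,
                                   integer_positions = TRUE, keep_all = FALSE) {
  stopifnot(n_blocks >= 1, genome_bp > 0, reps >= 1)
  withr::local_seed(seed)
  purrr::map_dfr(seq_len(reps), function(r) {
    if (n_blocks == 1) {
      out <- tibble::tibble(rep = r, length = genome_bp)
      if (keep_all) out$kept <- TRUE
      return(out)
    }
    n_breaks <- (n_blocks - 1L) * 2L
    pos <- if (integer_positions) {
      sample.int(genome_bp + 1, n_breaks, replace = TRUE) - 1
    } else {
      stats::runif(n_breaks, 0, genome_bp)
    }
    lens <- diff(sort(c(0, pos, genome_bp)))   # 2N-1 intervals summing to M
    keep <- sample.int(length(lens), n_blocks)
    if (keep_all) {
      tibble::tibble(rep = r, length = lens,
                     kept = seq_along(lens) %in% keep)
    } else {
      tibble::tibble(rep = r, length = lens[keep])
    }
  })
}

#' Compare observed largest synteny blocks against the random-breakage null
#'
#' For each observed genome, computes the given percentile of the observed
#' block lengths and of the pooled null sample; the verdict `exceeds_null` is
#' `TRUE` when the observed percentile exceeds the null percentile, the
#' signature of blocks too long to survive under uniform random breakage.
#' The mean and standard error of the mean of the observed blocks above the
#' percentile are reported alongside.
#'
#' @param observed A tibble with columns `genome` and `length` (bp), or a
#'   bare numeric vector of lengths.
#' @param null A tibble from [simulate_block_lengths()] (columns `rep`,
#'   `length`), or a numeric vector.
#' @param percentile Percentile used for the comparison (default 99).
#' @return A tibble of class `breakage_comparison`, one row per observed
#'   genome: `observed_p`, `null_p`, `exceeds_null`, `n_large`,
#'   `mean_large`, `sem_large`.
#' @export
compare_largest_blocks <- function(observed, null, percentile = 99) {
  if (is.numeric(observed)) {
    observed <- tibble::tibble(genome = "observed", length = observed)
  }
  null_lengths <- if (is.numeric(null)) null else null$length
  if (nrow(observed) == 0 || length(null_lengths) == 0) {
    stop("empty observed or null sample", call. = FALSE)
  }
  p <- percentile / 100
  null_p <- stats::quantile(null_lengths, p, names = FALSE, type = 7)
  out <- observed |>
    dplyr::group_by(.data$genome) |>
    dplyr::summarise(
      observed_p = stats::quantile(.data$length, p, names = FALSE, type = 7),
      n_large = sum(.data$length >= .data$observed_p[1]),
      mean_large = mean(.data$length[.data$length >= .data$observed_p[1]]),
      sem_large = stats::sd(.data$length[.data$length >= .data$observed_p[1]]) /
        sqrt(max(sum(.data$length >= .data$observed_p[1]), 1)),
      .groups = "drop") |>
    dplyr::mutate(null_p = null_p,
                  exceeds_null = .data$observed_p > null_p,
                  percentile = percentile, .after = "observed_p")
  class(out) <- c("breakage_comparison", class(out))
  attr(out, "observed") <- observed
  attr(out, "null") <- tibble::tibble(length = null_lengths)
  out
}
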