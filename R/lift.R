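#' Physical maps: ordered, oriented scaffold placements on chromosome arms
#'
#' A physical map assigns assembly scaffolds to positions and orientations on
#' chromosome arms (in mosquito cytogenetics, via FISH of probes to polytene
#' chromosomes). Internally it is a tibble with one row per placed scaffold:
#' `scaffold`, `arm`, `rank` (0-based order along the arm from the telomere),
#' `orientation` (`"+"` or `"-"`), `length_bp`, `offset_bp` (arm coordinate
#' of the scaffold start, 0-based), and `gap_before_bp` (declared cytogenetic
#' gap preceding the scaffold, default 0).
#'
#' @param placements A data frame with at least `scaffold`, `arm`,
#'   `orientation`, `length_bp`; `rank` defaults to input order within arm,
#'   `gap_before_bp` to 0, and `offset_bp` is computed by tiling.
#' @return A tibble of class `physical_map`.
#' @examples
#' pm <- physical_map(tibble::tibble(
#'   scaffold = c("s1", "s2"), arm = "2R",
#'   orientation = c("+", "-"), length_bp = c(100L, 50L)
#' ))
#' pm
#' @export
physical_map <- function(placements) {
  df <- tibble::as_tibble(placements)
  need <- c("scaffold", "arm", "orientation", "length_bp")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("physical map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$scaffold)) {
    stop("scaffold(s) placed more than once: ",
         paste(unique(df$scaffold[duplicated(df$scaffold)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$orientation %in% c("+", "-"))) {
    stop("orientation must be '+' or '-'", call. = FALSE)
  }
  if (any(df$length_bp < 0)) stop("negative scaffold length", call. = FALSE)
  if (!"gap_before_bp" %in% names(df)) df$gap_before_bp <- 0
  df <- df |>
    dplyr::group_by(.data$arm) |>
    dplyr::mutate(rank = if ("rank" %in% names(df)) .data$rank else
      dplyr::row_number() - 1L) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::mutate(offset_bp = if ("offset_bp" %in% names(df)) .data$offset_bp else
      cumsum(.data$gap_before_bp) +
        dplyr::lag(cumsum(.data$length_bp), default = 0)) |>
    dplyr::ungroup()
  bad <- df |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(ok = all(diff(.data$offset_bp) >=
                                (.data$length_bp[-dplyr::n()])),
                     .groups = "drop")
  if (!all(bad$ok)) {
    stop("overlapping scaffold placements on arm(s): ",
         paste(bad$arm[!bad$ok], collapse = ", "), call. = FALSE)
  }
  class(df) <- c("physical_map", class(df))
  df
}

#' Read and write physical maps as AGP v2.1
#'
#' Component (`W`) lines become scaffold placements; gap (`N`/`U`) lines are
#' honoured as declared gaps of the stated size. AGP is 1-based inclusive;
#' the in-memory map is 0-based half-open, converted at this boundary.
#'
#' @param path File path.
#' @return `read_agp()`: a [physical_map]. `write_agp()`: `path`, invisibly.
#' @export
read_agp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::map_dfr(f, function(x) {
    if (length(x) < 8) stop("malformed AGP line: ", paste(x, collapse = "\t"),
                            call. = FALSE)
    if (x[5] %in% c("N", "U")) {
      return(tibble::tibble(arm = x[1], gap = as.numeric(x[6]),
                            scaffold = NA_character_, length_bp = NA_real_,
                            offset_bp = NA_real_, orientation = NA_character_))
    }
    tibble::tibble(arm = x[1], gap = 0,
                   scaffold = x[6],
                   length_bp = as.numeric(x[8]) - as.numeric(x[7]) + 1,
                   offset_bp = as.numeric(x[2]) - 1,
                   orientation = if (length(x) >= 9 && x[9] == "-") "-" else "+")
  })
  comp <- rows |>
    dplyr::filter(!is.na(.data$scaffold)) |>
    dplyr::group_by(.data$arm) |>
    dplyr::mutate(rank = dplyr::row_number() - 1L,
                  gap_before_bp = .data$offset_bp -
                    dplyr::lag(.data$offset_bp + .data$length_bp, default = 0)) |>
    dplyr::ungroup() |>
    dplyr::select("scaffold", "arm", "rank", "orientation", "length_bp",
                  "offset_bp", "gap_before_bp")
  physical_map(comp)
}

#' @rdname read_agp
#' @param map A [physical_map].
#' @export
write_agp <- function(map, path) {
  lines <- character(0)
  part_tracker <- list()
  for (arm in unique(map$arm)) {
    sub <- dplyr::arrange(dplyr::filter(map, .data$arm == !!arm), .data$rank)
    part <- 0L
    for (r in seq_len(nrow(sub))) {
      gap <- sub$gap_before_bp[r]
      if (!is.na(gap) && gap > 0) {
        part <- part + 1L
        lines <- c(lines, paste(arm, sub$offset_bp[r] - gap + 1, sub$offset_bp[r],
                                part, "N", gap, "contig", "no", "na", sep = "\t"))
      }
      part <- part + 1L
      lines <- c(lines, paste(arm, sub$offset_bp[r] + 1,
                              sub$offset_bp[r] + sub$length_bp[r],
                              part, "W", sub$scaffold[r], 1, sub$length_bp[r],
                              sub$orientation[r], sep = "\t"))
    }
  }
  writeLines(c("##agp-version\t2.1", lines), path)
  invisible(path)
}

#' Lift gene anchors from scaffold to chromosome coordinates
#'
#' For a scaffold placed forward at offset `o`, an anchor `[s, e)` lifts to
#' `[o + s, o + e)` with strand preserved; for a reverse placement of a
#' scaffold of length `L` it lifts to `[o + L - e, o + L - s)` with strand
#' flipped. Anchors on scaffolds absent from the map are dropped with a
#' warning; the dropped count is recorded in the `n_unmapped` attribute (the
#' unplaced fraction of an assembly is part of the accounting, never silent).
#'
#' @param anchors A tibble with columns `gene_id`, `genome`, `seq`, `start`,
#'   `end`, `strand` (0-based half-open coordinates).
#' @param map A [physical_map].
#' @return A tibble of lifted anchors (`seq` is now the arm).
#' @examples
#' pm <- physical_map(tibble::tibble(scaffold = "s1", arm = "X",
#'                                   orientation = "-", length_bp = 100L))
#' a <- tibble::tibble(gene_id = "g1", genome = "q", seq = "s1",
#'                     start = 10L, end = 20L, strand = "+")
#' lift_anchors(a, pm)
#' @export
lift_anchors <- function(anchors, map) {
  anchors <- tibble::as_tibble(anchors)
  hit <- dplyr::inner_join(anchors, map, by = c(seq = "scaffold"))
  n_unmapped <- nrow(anchors) - nrow(hit)
  if (n_unmapped > 0) {
    warning(n_unmapped, " anchor(s) on scaffolds absent from the physical map ",
            "were dropped", call. = FALSE)
  }
  out <- hit |>
    dplyr::mutate(
      new_start = ifelse(.data$orientation == "+",
                         .data$offset_bp + .data$start,
                         .data$offset_bp + .data$length_bp - .data$end),
      new_end = ifelse(.data$orientation == "+",
                       .data$offset_bp + .data$end,
                       .data$offset_bp + .data$length_bp - .data$start),
      strand = ifelse(.data$orientation == "+", .data$strand,
                      ifelse(.data$strand == "+", "-", "+"))
    ) |>
    dplyr::transmute(.data$gene_id, .data$genome, seq = .data$arm,
                     start = .data$new_start, end = .data$new_end,
                     .data$strand)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' @rdname lift_anchors
#' @description `unlift_anchors()` is the inverse: chromosome coordinates back
#'   to scaffold coordinates for the mapped portion.
#' @export
unlift_anchors <- function(anchors, map) {
  anchors <- tibble::as_tibble(anchors)
  out <- dplyr::inner_join(anchors, map, by = c(seq = "arm"),
                           relationship = "many-to-many") |>
    dplyr::filter(.data$start >= .data$offset_bp,
                  .data$end <= .data$offset_bp + .data$length_bp) |>
    dplyr::mutate(
      new_start = ifelse(.data$orientation == "+",
                         .data$start - .data$offset_bp,
                         .data$offset_bp + .data$length_bp - .data$end),
      new_end = ifelse(.data$orientation == "+",
                       .data$end - .data$offset_bp,
                       .data$offset_bp + .data$length_bp - .data$start),
      strand = ifelse(.data$orientation == "+", .data$strand,
                      ifelse(.data$strand == "+", "-", "+"))
    ) |>
    dplyr::transmute(.data$gene_id, .data$genome, seq = .data$scaffold,
                     start = .data$new_start, end = .data$new_end,
                     .data$strand)
  if (nrow(out) < nrow(anchors)) {
    warning(nrow(anchors) - nrow(out),
            " anchor(s) fell outside every scaffold placement", call. = FALSE)
  }
  out
}

#' Fraction of an assembly anchored to chromosomes
#'
#' @param map A [physical_map].
#' @param assembly_total_bp Total assembly length in bp.
#' @return Percentage mapped, rounded to one decimal.
#' @examples
#' # the An. atroparvus accounting: 200,912,972 of 224,290,125 bp anchored
#' pm <- physical_map(tibble::tibble(scaffold = "all", arm = "all",
#'                                   orientation = "+",
#'                                   length_bp = 200912972))
#' mapped_fraction(pm, 224290125)
#' @export
mapped_fraction <- function(map, assembly_total_bp) {
  stopifnot(assembly_total_bp > 0)
  mapped <- sum(map$length_bp)
  if (mapped > assembly_total_bp) {
    stop("mapped length (", mapped, " bp) exceeds the assembly total (",
         assembly_total_bp, " bp)", call. = FALSE)
  }
  round(100 * mapped / assembly_total_bp, 1)
}

#' Write anchors as BED6
#'
#' @inheritParams lift_anchors
#' @param path Output path.
#' @export
write_bed <- function(anchors, path) {
  readr::write_tsv(
    dplyr::transmute(tibble::as_tibble(anchors),
                     chrom = .data$seq, chromStart = .data$start,
                     chromEnd = .data$end, name = .data$gene_id,
                     score = 0L, strand = .data$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' Read and write ortholog anchor tables
#'
#' Plain TSV with header `gene_id genome seq start end strand`, the package's
#' exchange format for one-to-one ortholog coordinates (emulating a BioMart
#' ortholog extract).
#'
#' @param path File path.
#' @export
read_anchors <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), genome = readr::col_character(),
    seq = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), strand = readr::col_character()))
}

#' @rdname read_anchors
#' @inheritParams lift_anchors
#' @export
write_anchors <- function(anchors, path) {
  readr::write_tsv(anchors[, c("gene_id", "genome", "seq", "start", "end",
                               "strand")], path)
  invisible(path)
}

#' Infer gap-free scaffold adjacency from ortholog contiguity
#'
#' Tests whether two scaffolds of a query genome are adjacent without a gap:
#' `k` boundary genes are taken from the facing ends of each scaffold (under
#' each of the four possible orientation combinations), and the pair is
#' called `adjacent` only if, in *every* reference genome supplied, the
#' orthologs of all `2k` boundary genes lie on a single reference sequence,
#' occupy a contiguous run of ranks, and appear in an order consistent with
#' one relative orientation of the pair. If any boundary gene lacks an
#' ortholog, or a scaffold end carries fewer than `k` genes, the verdict is
#' `undetermined`; a single dissenting reference gives `not_adjacent`.
#'
#' @param scaffold_a,scaffold_b Scaffold identifiers in `query_anchors$seq`.
#' @param query_anchors Scaffold-space anchors of the query genome.
#' @param ref_anchors Anchors of one or more reference genomes (the `genome`
#'   column distinguishes them), in chromosome or scaffold space.
#' @param k Number of boundary genes taken from each facing end.
#' @return A one-row tibble: `scaffold_a`, `scaffold_b`, `verdict`
#'   (`adjacent` / `not_adjacent` / `undetermined`), `orientation_a`,
#'   `orientation_b` (relative orientations when adjacent), `n_refs`.
#' @export
infer_adjacency <- function(scaffold_a, scaffold_b, query_anchors, ref_anchors,
                            k = 5) {
  stopifnot(k >= 1)
  qa <- dplyr::arrange(dplyr::filter(tibble::as_tibble(query_anchors),
                                     .data$seq == scaffold_a), .data$start)
  qb <- dplyr::arrange(dplyr::filter(tibble::as_tibble(query_anchors),
                                     .data$seq == scaffold_b), .data$start)
  refs <- split(tibble::as_tibble(ref_anchors), ref_anchors$genome)
  result <- function(verdict, oa = NA_character_, ob = NA_character_) {
    tibble::tibble(scaffold_a = scaffold_a, scaffold_b = scaffold_b,
                   verdict = verdict, orientation_a = oa, orientation_b = ob,
                   n_refs = length(refs))
  }
  if (nrow(qa) < k || nrow(qb) < k) return(result("undetermined"))
  undetermined <- FALSE
  for (oa in c("+", "-")) {
    for (ob in c("+", "-")) {
      # boundary genes walking away from the putative junction
      end_a <- if (oa == "+") rev(utils::tail(qa$gene_id, k)) else utils::head(qa$gene_id, k)
      end_b <- if (ob == "+") utils::head(qb$gene_id, k) else rev(utils::tail(qb$gene_id, k))
      expect <- c(rev(end_a), end_b)  # junction-crossing order
      status <- check_run_in_refs(expect, refs)
      if (status == "adjacent") return(result("adjacent", oa, ob))
      if (status == "undetermined") undetermined <- TRUE
    }
  }
  result(if (undetermined) "undetermined" else "not_adjacent")
}

check_run_in_refs <- function(expect, refs) {
  out <- "adjacent"
  for (rf in refs) {
    hit <- rf[match(expect, rf$gene_id), ]
    if (anyNA(hit$gene_id)) return("undetermined")
    if (length(unique(hit$seq)) != 1) { out <- "not_adjacent"; next }
    ranked <- dplyr::mutate(dplyr::arrange(rf[rf$seq == hit$seq[1], ],
                                           .data$start),
                            rank = dplyr::row_number())
    rk <- ranked$rank[match(expect, ranked$gene_id)]
    contiguous <- max(rk) - min(rk) + 1L == length(rk)
    increasing <- all(diff(rk) == 1L)
    decreasing <- all(diff(rk) == -1L)
    if (!(contiguous && (increasing || decreasing))) out <- "not_adjacent"
  }
  out
}

#' Batch scaffold gluing over candidate pairs
#'
#' @param pairs A tibble with columns `scaffold_a`, `scaffold_b`.
#' @inheritParams infer_adjacency
#' @return One verdict row per candidate pair (see [infer_adjacency()]).
#' @export
glue_scaffolds <- function(pairs, query_anchors, ref_anchors, k = 5) {
  purrr::map2_dfr(pairs$scaffold_a, pairs$scaffold_b, infer_adjacency,
                  query_anchors = query_anchors, ref_anchors = ref_anchors,
                  k = k)
}
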