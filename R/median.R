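#' Median-of-three ancestral genome reconstruction
#'
#' Reconstructs a putative ancestral genome `m` minimising (heuristically)
#' the total tree length `d(a,m) + d(b,m) + d(c,m)` under the
#' multichromosomal rearrangement distance. The search is greedy in the
#' style of multiple-genome-rearrangement programs: over all single
#' operations applicable to any of the three working genomes, repeatedly
#' apply one that maximally reduces the sum of distances from that genome to
#' the other two (operations bringing a genome closer to both others are
#' preferred), until the three genomes meet in a common genome, the median.
#' Restarts with permuted genome preference and shuffled candidate order
#' explore the solution space; because the median of three genomes is rarely
#' unique, all co-optimal medians connected to the solutions found (single
#' operations preserving the best total) are then enumerated up to a budget
#' and reported.
#'
#' The result is certified exact when the total attains the perfect-median
#' lower bound `ceiling((dab + dac + dbc)/2)`; otherwise it is flagged as
#' heuristic best.
#'
#' @param a,b,c [signed_genome] objects over identical block sets.
#' @param n_starts Number of greedy restarts (preference orders/shuffles).
#' @param seed Seed for the restart shuffles.
#' @param max_co_optimal Budget for the co-optimal plateau enumeration
#'   (set to 0 to skip it).
#' @param node_cap Safety cap passed to the distance search.
#' @return A `karyo_median` object with components `median` (the inferred
#'   [signed_genome]), `edges` (tibble of per-edge distances and operation
#'   counts from the median to each input, via minimal scenarios),
#'   `co_optimal` (tibble of all co-optimal medians found, with their edge
#'   distances), `total_ops`, `lower_bound`, `optimal`.
#'   [generics::tidy()] returns the edge table; [generics::glance()] a
#'   one-row summary.
#' @examples
#' gs <- anopheles_genomes()
#' med <- median_genome(gs$gambiae, gs$atroparvus, gs$albimanus)
#' glance(med)
#' @export
median_genome <- function(a, b, c, n_starts = 6, seed = 1,
                          max_co_optimal = 60, node_cap = 5e6) {
  genomes0 <- list(as_signed_genome(a), as_signed_genome(b), as_signed_genome(c))
  nms <- purrr::imap_chr(genomes0, function(g, i) {
    if (!is.null(g$name)) g$name else c("a", "b", "c")[i]
  })
  dist_cache <- new.env(parent = emptyenv())
  dd <- function(x, y) {
    kx <- genome_key(x); ky <- genome_key(y)
    key <- if (kx < ky) paste(kx, ky, sep = "|") else paste(ky, kx, sep = "|")
    v <- dist_cache[[key]]
    if (is.null(v)) {
      v <- genome_distance(x, y, node_cap = node_cap)
      dist_cache[[key]] <- v
    }
    v
  }
  d0 <- c(dd(genomes0[[1]], genomes0[[2]]), dd(genomes0[[1]], genomes0[[3]]),
          dd(genomes0[[2]], genomes0[[3]]))
  lower <- as.integer(ceiling(sum(d0) / 2))
  total_of <- function(m) dd(m, genomes0[[1]]) + dd(m, genomes0[[2]]) + dd(m, genomes0[[3]])

  prefs <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
                c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))
  found <- list()   # canonical key -> signed_genome, all with best total
  best_total <- Inf
  withr::local_seed(seed)
  for (start in seq_len(n_starts)) {
    pref <- prefs[[(start - 1L) %% length(prefs) + 1L]]
    m <- greedy_median_once(genomes0, dd, pref, shuffle = start > 1)
    if (is.null(m)) next
    tot <- total_of(m)
    if (tot < best_total) {
      best_total <- tot
      found <- list()
    }
    if (tot == best_total) found[[genome_key(m)]] <- m
  }
  if (length(found) == 0) {
    # degenerate fallback: best of the inputs
    tots <- vapply(genomes0, total_of, integer(1))
    i <- which.min(tots)
    best_total <- tots[i]
    found[[genome_key(genomes0[[i]])]] <- genomes0[[i]]
  }
  if (max_co_optimal > 0) {
    found <- plateau_medians(found, best_total, total_of, genomes0,
                             max_co_optimal)
  }
  keys <- sort(names(found))
  co_optimal <- purrr::map_dfr(keys, function(k) {
    m <- found[[k]]
    tibble::tibble(genome = format_mgr(canonicalize(m)),
                   !!paste0("d_", nms[1]) := dd(m, genomes0[[1]]),
                   !!paste0("d_", nms[2]) := dd(m, genomes0[[2]]),
                   !!paste0("d_", nms[3]) := dd(m, genomes0[[3]]))
  })
  m <- found[[keys[1]]]
  m$name <- "median"
  edges <- purrr::map_dfr(seq_along(genomes0), function(i) {
    sc <- sorting_scenario(m, genomes0[[i]], "min-translocations",
                           node_cap = node_cap)
    dplyr::mutate(scenario_counts(sc$steps$subtype),
                  genome = nms[i], distance = sc$distance, .before = 1)
  })
  structure(list(median = m, edges = edges, co_optimal = co_optimal,
                 total_ops = as.integer(best_total), lower_bound = lower,
                 optimal = best_total == lower,
                 input_names = nms, inputs = genomes0),
            class = "karyo_median")
}

# single greedy descent; pref gives the order in which genomes are offered ops
greedy_median_once <- function(genomes, dd, pref = c(1, 2, 3), shuffle = FALSE,
                               max_steps = 200L) {
  gs <- genomes
  for (step in seq_len(max_steps)) {
    pair_d <- c(dd(gs[[1]], gs[[2]]), dd(gs[[1]], gs[[3]]), dd(gs[[2]], gs[[3]]))
    if (sum(pair_d) == 0L) return(canonicalize(gs[[1]]))
    best_delta <- 0L
    best_move <- NULL
    for (i in pref) {
      others <- setdiff(1:3, i)
      base <- dd(gs[[i]], gs[[others[1]]]) + dd(gs[[i]], gs[[others[2]]])
      if (base == 0L) next
      ops <- enumerate_ops(gs[[i]])
      idx <- seq_len(nrow(ops))
      if (shuffle) idx <- sample(idx)
      for (r in idx) {
        after <- apply_op(gs[[i]], ops[r, ])
        # cheap necessary condition before the exact distances
        lb <- dcj_distance(after, gs[[others[1]]]) +
          dcj_distance(after, gs[[others[2]]])
        if (base - lb < max(best_delta + 1L, 1L)) next
        delta <- base - (dd(after, gs[[others[1]]]) + dd(after, gs[[others[2]]]))
        if (delta > best_delta) {
          best_delta <- delta
          best_move <- list(i = i, after = after)
          if (delta == 2L) break
        }
      }
      if (best_delta == 2L) break
    }
    if (is.null(best_move)) return(NULL)  # greedy got stuck
    gs[[best_move$i]] <- best_move$after
  }
  NULL
}

# breadth-first walk over the plateau of genomes with the same (best) total
plateau_medians <- function(found, best_total, total_of, genomes0, budget) {
  frontier <- unname(found)
  while (length(frontier) > 0 && length(found) < budget) {
    nxt <- list()
    for (g in frontier) {
      ops <- enumerate_ops(g)
      for (r in seq_len(nrow(ops))) {
        h <- apply_op(g, ops[r, ])
        key <- genome_key(h)
        if (!is.null(found[[key]])) next
        lb <- sum(vapply(genomes0, function(x) dcj_distance(h, x), integer(1)))
        if (lb > best_total) next
        if (total_of(h) == best_total) {
          found[[key]] <- h
          nxt[[length(nxt) + 1L]] <- h
          if (length(found) >= budget) break
        }
      }
      if (length(found) >= budget) break
    }
    frontier <- nxt
  }
  found
}

#' @export
print.karyo_median <- function(x, ...) {
  cat("Median (putative ancestral) genome:\n  ", format_mgr(x$median), "\n", sep = "")
  cat("Total tree length: ", x$total_ops, " (lower bound ", x$lower_bound,
      if (x$optimal) ", certified optimal" else ", heuristic best", ")\n", sep = "")
  cat("Co-optimal medians found: ", nrow(x$co_optimal), "\n", sep = "")
  print(x$edges)
  invisible(x)
}

#' @export
tidy.karyo_median <- function(x, ...) x$edges

#' @export
glance.karyo_median <- function(x, ...) {
  tibble::tibble(total_ops = x$total_ops, lower_bound = x$lower_bound,
                 optimal = x$optimal, n_co_optimal = nrow(x$co_optimal),
                 n_inversions = sum(x$edges$n_inversions),
                 n_translocations = sum(x$edges$n_translocations))
}
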