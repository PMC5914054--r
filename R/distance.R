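#' Multichromosomal rearrangement distance
#'
#' The minimum number of operations from the set inversion, (reciprocal)
#' translocation, fusion and fission that transforms `a` into `b`, on
#' flip-equivalence classes of signed multichromosomal genomes. Computed
#' exactly by iterative-deepening A* with the double-cut-and-join (DCJ)
#' distance as an admissible, consistent lower bound: every operation in the
#' set is a single DCJ, so each step can reduce the DCJ distance by at most
#' one. For genomes that differ only by inversions the bound is tight and the
#' search is essentially greedy; unoriented (hurdle-like) configurations cost
#' one extra deepening each.
#'
#' @param a,b [signed_genome] objects over identical block-id sets.
#' @param inversions_only If `TRUE`, restrict the operation set to inversions
#'   (unichromosomal reversal distance; both genomes must have the same
#'   chromosome content).
#' @param node_cap Safety cap on search nodes.
#' @return A non-negative integer distance.
#' @examples
#' gs <- anopheles_genomes()
#' genome_distance(gs$gambiae, gs$atroparvus)
#' @export
genome_distance <- function(a, b, inversions_only = FALSE, node_cap = 5e6) {
  ab <- relabel_pair(as_signed_genome(a), as_signed_genome(b))
  cpp_genome_distance(ab$a$chromosomes, ab$b$chromosomes, ab$n,
                      inversions_only, node_cap)
}

#' Lower-bound DCJ distance (internal bound, exported for diagnostics)
#'
#' @inheritParams genome_distance
#' @return Integer DCJ distance; a lower bound on [genome_distance()].
#' @export
dcj_distance <- function(a, b) {
  ab <- relabel_pair(as_signed_genome(a), as_signed_genome(b))
  cpp_dcj_distance(ab$a$chromosomes, ab$b$chromosomes, ab$n)
}

#' Exhaustive breadth-first-search distance oracle
#'
#' An independent check on [genome_distance()]: plain BFS over all genomes
#' reachable by single operations, with its own move generation and state
#' canonicalisation. Only practical for small genomes (<= ~6 blocks).
#'
#' @inheritParams genome_distance
#' @param max_depth Maximum search depth.
#' @param max_states Cap on stored states.
#' @return Integer distance.
#' @export
bfs_genome_distance <- function(a, b, max_depth = 12, max_states = 2e6) {
  ab <- relabel_pair(as_signed_genome(a), as_signed_genome(b))
  cpp_bfs_distance(ab$a$chromosomes, ab$b$chromosomes, max_depth, max_states)
}

relabel_pair <- function(a, b) {
  ia <- block_ids(a); ib <- block_ids(b)
  if (!identical(ia, ib)) {
    d <- c(setdiff(ia, ib), setdiff(ib, ia))
    stop("genomes are not over the same block set; symmetric difference: ",
         paste(d, collapse = ", "), call. = FALSE)
  }
  map <- integer(max(ia))
  map[ia] <- seq_along(ia)
  rl <- function(g) {
    g$chromosomes <- lapply(g$chromosomes, function(ch) {
      as.integer(sign(ch) * map[abs(ch)])
    })
    g
  }
  list(a = rl(a), b = rl(b), n = length(ia))
}

#' Minimal sorting scenario between two genomes
#'
#' Finds an ordered list of operations of length exactly
#' `genome_distance(a, b)` transforming `a` into `b`; every prefix decreases
#' the distance to the target by one. Several minimal scenarios usually
#' exist; `tie_policy` selects among them:
#' \describe{
#'   \item{`"first-found"`}{greedy, first distance-reducing operation in
#'     enumeration order;}
#'   \item{`"min-translocations"`}{a minimal scenario with the smallest
#'     possible number of inter-chromosomal operations (memoised exhaustive
#'     search over minimal scenarios);}
#'   \item{`"min-inversions"`}{symmetric, fewest inversions.}
#' }
#'
#' @inheritParams genome_distance
#' @param tie_policy Scenario selection policy, see Details.
#' @return A `karyo_scenario` object: a tibble of steps (`step`, `kind`,
#'   `subtype`, cut coordinates, genome after the step) with the source and
#'   target genomes as attributes. [generics::tidy()] returns the step table,
#'   [generics::glance()] the operation counts by type.
#' @examples
#' gs <- anopheles_genomes()
#' sc <- sorting_scenario(gs$gambiae, gs$atroparvus, "min-translocations")
#' glance(sc)
#' @export
sorting_scenario <- function(a, b,
                             tie_policy = c("first-found", "min-translocations",
                                            "min-inversions"),
                             node_cap = 5e6) {
  tie_policy <- match.arg(tie_policy)
  a <- as_signed_genome(a); b <- as_signed_genome(b)
  d <- genome_distance(a, b, node_cap = node_cap)
  steps <- list()
  if (d > 0) {
    cache <- new.env(parent = emptyenv())
    dist_to_b <- function(g) {
      key <- genome_key(g)
      if (!is.null(cache[[key]])) return(cache[[key]])
      v <- genome_distance(g, b, node_cap = node_cap)
      cache[[key]] <- v
      v
    }
    if (tie_policy == "first-found") {
      cur <- a
      for (s in seq_len(d)) {
        cand <- good_moves(cur, b, d - s + 1L, dist_to_b)
        pick <- cand[[1]]
        steps[[s]] <- pick
        cur <- pick$after
      }
    } else {
      costly <- if (tie_policy == "min-translocations") {
        c("partial_arm_translocation", "whole_arm_translocation",
          "fusion", "fission")
      } else {
        "inversion"
      }
      memo <- new.env(parent = emptyenv())
      best_cost <- function(g, rem) {
        if (rem == 0L) return(0L)
        key <- genome_key(g)
        if (!is.null(memo[[key]])) return(memo[[key]])
        cand <- good_moves(g, b, rem, dist_to_b)
        best <- Inf
        for (cd in cand) {
          cost <- as.integer(cd$subtype %in% costly) + best_cost(cd$after, rem - 1L)
          if (cost < best) best <- cost
        }
        memo[[key]] <- best
        best
      }
      total <- best_cost(a, d)
      cur <- a
      for (s in seq_len(d)) {
        rem <- d - s + 1L
        cand <- good_moves(cur, b, rem, dist_to_b)
        ord <- order(vapply(cand, function(cd) cd$subtype %in% costly, logical(1)))
        for (k in ord) {
          cd <- cand[[k]]
          cost <- as.integer(cd$subtype %in% costly) + best_cost(cd$after, rem - 1L)
          if (cost == total) { pick <- cd; break }
        }
        steps[[s]] <- pick
        total <- total - as.integer(pick$subtype %in% costly)
        cur <- pick$after
      }
    }
  }
  tab <- steps_table(steps)
  structure(list(steps = tab, source = a, target = b, distance = d,
                 tie_policy = tie_policy),
            class = "karyo_scenario")
}

# all single operations taking g one step closer to target (distance rem - 1),
# pre-filtered by the cheap DCJ bound
good_moves <- function(g, target, rem, dist_fun) {
  ops <- enumerate_ops(g)
  out <- list()
  for (r in seq_len(nrow(ops))) {
    op <- ops[r, ]
    after <- apply_op(g, op)
    if (dcj_distance(after, target) > rem - 1L) next
    if (dist_fun(after) == rem - 1L) {
      out[[length(out) + 1L]] <- list(op = op, after = after,
                                      subtype = classify_op(g, op))
    }
  }
  if (length(out) == 0) stop("internal error: no distance-reducing operation found")
  out
}

steps_table <- function(steps) {
  if (length(steps) == 0) {
    return(tibble::tibble(step = integer(), kind = character(),
                          subtype = character(), genome_after = character(),
                          c1 = integer(), c2 = integer(), i = integer(),
                          j = integer(), variant = integer()))
  }
  purrr::map2_dfr(steps, seq_along(steps), function(st, s) {
    dplyr::mutate(st$op, step = s, subtype = st$subtype,
                  genome_after = format_mgr(st$after), .before = 1)
  })
}

scenario_counts <- function(subtypes) {
  tibble::tibble(
    n_ops = length(subtypes),
    n_inversions = sum(subtypes == "inversion"),
    n_translocations = sum(subtypes %in% c("partial_arm_translocation",
                                           "whole_arm_translocation")),
    n_partial_arm = sum(subtypes == "partial_arm_translocation"),
    n_whole_arm = sum(subtypes == "whole_arm_translocation"),
    n_fusions = sum(subtypes == "fusion"),
    n_fissions = sum(subtypes == "fission")
  )
}

#' @export
print.karyo_scenario <- function(x, ...) {
  cat("Minimal rearrangement scenario (", x$distance, " ops, policy ",
      x$tie_policy, ")\n", sep = "")
  cat("  from:", format_mgr(x$source), "\n")
  cat("  to:  ", format_mgr(x$target), "\n")
  if (x$distance > 0) print(x$steps[, c("step", "kind", "subtype", "genome_after")])
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.karyo_scenario <- function(x, ...) x$steps

#' @export
glance.karyo_scenario <- function(x, ...) {
  dplyr::mutate(scenario_counts(x$steps$subtype), distance = x$distance)
}

#' Pairwise distance table for a set of genomes
#'
#' @param genomes Named list of [signed_genome] objects.
#' @return A tibble with columns `genome_a`, `genome_b`, `distance`.
#' @export
distance_matrix <- function(genomes) {
  nms <- names(genomes)
  if (is.null(nms)) nms <- paste0("genome_", seq_along(genomes))
  pairs <- utils::combn(seq_along(genomes), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tibble::tibble(genome_a = nms[i], genome_b = nms[j],
                   distance = genome_distance(genomes[[i]], genomes[[j]]))
  })
}

#' Operation-type decompositions achievable by minimal scenarios
#'
#' The operation-type decomposition of a minimal scenario is not unique.
#' This enumerates, by memoised search over all minimal scenarios, every
#' achievable triple (number of inversions, number of translocations
#' counting partial- and whole-arm exchanges, number of fusions+fissions).
#'
#' @inheritParams genome_distance
#' @return A tibble with columns `n_inversions`, `n_translocations`,
#'   `n_other` (fusions + fissions); one row per achievable decomposition.
#' @examples
#' gs <- anopheles_genomes()
#' scenario_decompositions(gs$gambiae, gs$atroparvus)
#' @export
scenario_decompositions <- function(a, b, node_cap = 5e6) {
  a <- as_signed_genome(a); b <- as_signed_genome(b)
  d <- genome_distance(a, b, node_cap = node_cap)
  env <- decomposition_search_env(b, node_cap)
  sets <- env$achievable(a, d)
  tibble::tibble(n_inversions = sets[, 1], n_translocations = sets[, 2],
                 n_other = sets[, 3]) |>
    dplyr::arrange(.data$n_translocations, .data$n_other)
}

decomposition_search_env <- function(target, node_cap) {
  dist_cache <- new.env(parent = emptyenv())
  memo <- new.env(parent = emptyenv())
  dist_to <- function(g) {
    key <- genome_key(g)
    v <- dist_cache[[key]]
    if (is.null(v)) {
      v <- genome_distance(g, target, node_cap = node_cap)
      dist_cache[[key]] <- v
    }
    v
  }
  subtype_axis <- function(subtype) {
    if (subtype == "inversion") 1L
    else if (subtype %in% c("partial_arm_translocation",
                            "whole_arm_translocation")) 2L
    else 3L
  }
  achievable <- function(g, rem) {
    if (rem == 0L) return(matrix(0L, nrow = 1, ncol = 3))
    key <- genome_key(g)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    cand <- good_moves(g, target, rem, dist_to)
    rows <- list()
    for (cd in cand) {
      sub <- achievable(cd$after, rem - 1L)
      ax <- subtype_axis(cd$subtype)
      sub[, ax] <- sub[, ax] + 1L
      rows[[length(rows) + 1L]] <- sub
    }
    m <- unique(do.call(rbind, rows))
    memo[[key]] <- m
    m
  }
  list(achievable = achievable, dist_to = dist_to)
}

#' Find a minimal scenario with a prescribed operation-type decomposition
#'
#' @inheritParams genome_distance
#' @param n_inversions,n_translocations,n_other Required counts; must sum to
#'   the distance and be achievable (see [scenario_decompositions()]).
#' @return A `karyo_scenario` object.
#' @export
find_scenario <- function(a, b, n_inversions, n_translocations, n_other = 0L,
                          node_cap = 5e6) {
  a <- as_signed_genome(a); b <- as_signed_genome(b)
  d <- genome_distance(a, b, node_cap = node_cap)
  want <- c(n_inversions, n_translocations, n_other)
  if (sum(want) != d) {
    stop("requested decomposition sums to ", sum(want),
         " but the distance is ", d, call. = FALSE)
  }
  env <- decomposition_search_env(b, node_cap)
  has_row <- function(m, v) any(m[, 1] == v[1] & m[, 2] == v[2] & m[, 3] == v[3])
  if (!has_row(env$achievable(a, d), want)) {
    stop("no minimal scenario with the requested decomposition exists",
         call. = FALSE)
  }
  subtype_axis <- function(subtype) {
    if (subtype == "inversion") 1L
    else if (subtype %in% c("partial_arm_translocation",
                            "whole_arm_translocation")) 2L
    else 3L
  }
  steps <- list()
  cur <- a
  rem <- d
  left <- as.integer(want)
  while (rem > 0L) {
    cand <- good_moves(cur, b, rem, env$dist_to)
    for (cd in cand) {
      nxt <- left
      ax <- subtype_axis(cd$subtype)
      if (nxt[ax] == 0L) next
      nxt[ax] <- nxt[ax] - 1L
      if (has_row(env$achievable(cd$after, rem - 1L), nxt)) {
        steps[[length(steps) + 1L]] <- cd
        cur <- cd$after
        left <- nxt
        break
      }
    }
    rem <- rem - 1L
  }
  tab <- steps_table(steps)
  structure(list(steps = tab, source = a, target = b, distance = d,
                 tie_policy = "prescribed"),
            class = "karyo_scenario")
}
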