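#' Rearrangement operations on signed genomes
#'
#' Operations are rows of a tibble with columns `kind` (one of `"inversion"`,
#' `"fission"`, `"translocation"`), chromosome indices `c1`, `c2`, cut
#' positions `i`, `j` and, for translocations, `variant` (1: plain tail
#' exchange; 2: tail exchange with the second chromosome flipped). Cut
#' positions follow 0-based "between blocks" convention: for an inversion the
#' reversed segment is `chrom[(i+1):j]` in 1-based R indexing; for a
#' translocation `i`/`j` split the chromosomes into prefix and suffix.
#'
#' @name operations
NULL

#' @rdname operations
#' @param kind Operation kind.
#' @param c1,c2 Chromosome indices (`c2` for translocations only).
#' @param i,j Cut positions (see Details above).
#' @param variant Translocation variant (1 or 2).
#' @return `op_row()`: a one-row operation tibble.
#' @export
op_row <- function(kind, c1, c2 = NA_integer_, i = NA_integer_, j = NA_integer_,
                   variant = NA_integer_) {
  tibble::tibble(kind = kind, c1 = as.integer(c1), c2 = as.integer(c2),
                 i = as.integer(i), j = as.integer(j),
                 variant = as.integer(variant))
}

#' Enumerate all operations applicable to a genome
#'
#' Whole-chromosome inversions (identities under flip equivalence) and no-op
#' translocations are excluded.
#'
#' @param g A [signed_genome].
#' @return A tibble of operations (see [operations]).
#' @export
enumerate_ops <- function(g) {
  g <- as_signed_genome(g)
  lens <- lengths(g$chromosomes)
  K <- length(lens)
  rows <- list()
  for (c1 in seq_len(K)) {
    L <- lens[c1]
    for (i in 0:(L - 1)) {
      for (j in (i + 1):L) {
        if (i == 0 && j == L) next
        rows[[length(rows) + 1L]] <- op_row("inversion", c1, i = i, j = j)
      }
    }
    if (L >= 2) {
      for (i in 1:(L - 1)) {
        rows[[length(rows) + 1L]] <- op_row("fission", c1, i = i)
      }
    }
  }
  if (K >= 2) {
    for (c1 in 1:(K - 1)) {
      for (c2 in (c1 + 1):K) {
        L1 <- lens[c1]; L2 <- lens[c2]
        for (i in 0:L1) {
          for (j in 0:L2) {
            if (!((i == L1 && j == L2) || (i == 0 && j == 0))) {
              rows[[length(rows) + 1L]] <- op_row("translocation", c1, c2, i, j, 1L)
            }
            if (!((i == L1 && j == 0) || (i == 0 && j == L2))) {
              rows[[length(rows) + 1L]] <- op_row("translocation", c1, c2, i, j, 2L)
            }
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Apply a single operation to a genome
#'
#' @param g A [signed_genome].
#' @param op A one-row operation tibble (see [operations]).
#' @return The rearranged [signed_genome]; empty chromosomes are dropped.
#' @export
apply_op <- function(g, op) {
  g <- as_signed_genome(g)
  ch <- g$chromosomes
  kind <- op$kind[1]
  c1 <- op$c1[1]; c2 <- op$c2[1]; i <- op$i[1]; j <- op$j[1]
  if (kind == "inversion") {
    v <- ch[[c1]]
    if (i < 0 || j > length(v) || i >= j) stop("inapplicable inversion", call. = FALSE)
    seg <- v[(i + 1):j]
    v[(i + 1):j] <- -rev(seg)
    ch[[c1]] <- v
  } else if (kind == "fission") {
    v <- ch[[c1]]
    if (i < 1 || i >= length(v)) stop("inapplicable fission", call. = FALSE)
    ch[[c1]] <- v[1:i]
    ch[[length(ch) + 1L]] <- v[(i + 1):length(v)]
  } else if (kind == "translocation") {
    v1 <- ch[[c1]]; v2 <- ch[[c2]]
    if (i < 0 || i > length(v1) || j < 0 || j > length(v2)) {
      stop("inapplicable translocation", call. = FALSE)
    }
    A <- if (i > 0) v1[1:i] else integer(0)
    B <- if (i < length(v1)) v1[(i + 1):length(v1)] else integer(0)
    C <- if (j > 0) v2[1:j] else integer(0)
    D <- if (j < length(v2)) v2[(j + 1):length(v2)] else integer(0)
    if (op$variant[1] == 1L) {
      ch[[c1]] <- c(A, D)
      ch[[c2]] <- c(C, B)
    } else {
      ch[[c1]] <- c(A, -rev(C))
      ch[[c2]] <- c(-rev(B), D)
    }
  } else {
    stop("unknown operation kind: ", kind, call. = FALSE)
  }
  ch <- ch[lengths(ch) > 0]
  signed_genome(ch, name = g$name)
}

#' Classify an operation applied to a given genome state
#'
#' Inversions and fissions classify as themselves. A translocation whose
#' result merges the two chromosomes into one is a `"fusion"`. Otherwise it is
#' a `"whole_arm"` translocation if one of the exchanged segments is an entire
#' source chromosome moving intact, and a `"partial_arm"` translocation when
#' both exchanged segments are proper (neither empty nor a whole chromosome).
#'
#' @param g The [signed_genome] the operation applies to.
#' @param op A one-row operation tibble.
#' @return A string: `"inversion"`, `"fission"`, `"fusion"`,
#'   `"whole_arm_translocation"` or `"partial_arm_translocation"`.
#' @export
classify_op <- function(g, op) {
  g <- as_signed_genome(g)
  kind <- op$kind[1]
  if (kind == "inversion") return("inversion")
  if (kind == "fission") return("fission")
  if (kind != "translocation") stop("unknown operation kind: ", kind, call. = FALSE)
  L1 <- length(g$chromosomes[[op$c1[1]]])
  L2 <- length(g$chromosomes[[op$c2[1]]])
  i <- op$i[1]; j <- op$j[1]
  # exchanged segments under variant 1 are (B, D); under variant 2 are (B, C)
  if (op$variant[1] == 1L) {
    s1 <- L1 - i; s2 <- L2 - j
  } else {
    s1 <- L1 - i; s2 <- j
  }
  if (s1 == 0 && s2 == 0) stop("inapplicable operation (identity)", call. = FALSE)
  n1 <- i + s2; n2 <- (L2 - s2) + s1   # resulting chromosome sizes
  if (n1 == 0 || n2 == 0) return("fusion")
  if (s1 == L1 || s2 == L2) return("whole_arm_translocation")
  # both segments are sub-arm; a one-sided move of a proper tail still breaks
  # element integrity, so it counts as partial-arm as well
  "partial_arm_translocation"
}
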