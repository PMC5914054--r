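#' Signed multichromosomal genomes
#'
#' A signed genome is a set of linear chromosomes, each a non-empty sequence
#' of signed block (or gene) identifiers; every identifier appears exactly
#' once in absolute value. A chromosome and its full reversal with all signs
#' flipped denote the same chromosome (flip equivalence), and chromosome
#' order within a genome carries no meaning.
#'
#' @param chromosomes A list of integer vectors of signed, non-zero block ids.
#' @param name Optional genome name.
#' @param elements Optional character vector of chromosome-element labels
#'   (e.g. `"e1"` for the X), one per chromosome.
#' @return An object of class `signed_genome`.
#' @examples
#' g <- signed_genome(list(c(1L, 2L, -3L), 4L), name = "toy")
#' g
#' @export
signed_genome <- function(chromosomes, name = NULL, elements = NULL) {
  stopifnot(is.list(chromosomes), length(chromosomes) > 0)
  chromosomes <- lapply(chromosomes, function(ch) {
    ch <- as.integer(ch)
    if (length(ch) == 0) stop("empty chromosome in signed genome", call. = FALSE)
    if (any(ch == 0L) || anyNA(ch)) stop("block ids must be non-zero integers", call. = FALSE)
    ch
  })
  ids <- abs(unlist(chromosomes))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("block id(s) appear more than once: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(elements) && length(elements) != length(chromosomes)) {
    stop("`elements` must have one label per chromosome", call. = FALSE)
  }
  structure(list(chromosomes = chromosomes, name = name, elements = elements),
            class = "signed_genome")
}

#' @export
print.signed_genome <- function(x, ...) {
  if (!is.null(x$name)) cat(">", x$name, "\n", sep = "")
  cat(format_mgr(x), "\n")
  invisible(x)
}

#' @rdname signed_genome
#' @param x An object to coerce.
#' @export
as_signed_genome <- function(x, name = NULL) {
  if (inherits(x, "signed_genome")) return(x)
  if (is.numeric(x)) return(signed_genome(list(x), name = name))
  if (is.list(x)) return(signed_genome(x, name = name))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to a signed genome", call. = FALSE)
}

#' @rdname signed_genome
#' @export
n_chromosomes <- function(x) length(x$chromosomes)

#' @rdname signed_genome
#' @export
n_blocks <- function(x) length(unlist(x$chromosomes))

#' @rdname signed_genome
#' @export
block_ids <- function(x) sort(abs(unlist(x$chromosomes)))

flip_chrom <- function(ch) -rev(ch)

canonical_chrom <- function(ch) {
  f <- flip_chrom(ch)
  a <- paste(ch, collapse = ",")
  b <- paste(f, collapse = ",")
  if (b < a) f else ch
}

#' Canonical form of a signed genome
#'
#' Flips each chromosome to a deterministic orientation and sorts chromosomes,
#' so that two genomes are equal up to flip equivalence and chromosome order
#' iff their canonical forms are identical.
#'
#' @inheritParams n_chromosomes
#' @return A `signed_genome` in canonical form.
#' @export
canonicalize <- function(x) {
  ch <- lapply(x$chromosomes, canonical_chrom)
  keys <- vapply(ch, function(c) paste(c, collapse = ","), character(1))
  x$chromosomes <- ch[order(keys)]
  if (!is.null(x$elements)) x$elements <- x$elements[order(keys)]
  x
}

genome_key <- function(x) {
  paste(vapply(canonicalize(x)$chromosomes,
               function(c) paste(c, collapse = ","), character(1)),
        collapse = ";")
}

#' Test equality of signed genomes up to flip equivalence
#'
#' @param a,b `signed_genome` objects.
#' @return `TRUE` iff the genomes are identical up to chromosome flips and
#'   chromosome order.
#' @export
genomes_equal <- function(a, b) {
  identical(genome_key(as_signed_genome(a)), genome_key(as_signed_genome(b)))
}

normalize_mgr_text <- function(text) {
  # printed gene orders use typographic minus signs and dashes glued to digits
  text <- gsub("[−–—]", "-", text)
  text <- gsub("(?<=[0-9])-", " -", text, perl = TRUE)
  text <- gsub("-\\s+", "-", text)
  text
}

#' Parse and format genomes in the MGR `$` dialect
#'
#' The dialect encodes a multichromosomal signed genome as whitespace-separated
#' signed integers with a `$` terminating each chromosome; lines starting with
#' `>` name the following genome. Typographic minus signs and en-dashes (as
#' found in printed gene orders) are normalised to ASCII `-` before parsing.
#'
#' @param text Character vector of lines (or a single string with newlines).
#' @return `parse_mgr()`: a named list of [signed_genome] objects.
#'   `format_mgr()`: a single string such as `"1 2 $ -3 $"`.
#' @examples
#' gs <- parse_mgr(c(">a", "1 2 $ 3 $", ">b", "-3 $ 1 -2 $"))
#' format_mgr(gs$a)
#' @export
parse_mgr <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  genomes <- list()
  cur_name <- NULL
  cur_tokens <- character(0)
  finish <- function(genomes, name, tokens) {
    if (length(tokens) == 0) return(genomes)
    g <- tokens_to_genome(tokens, name)
    nm <- if (is.null(name)) paste0("genome_", length(genomes) + 1L) else name
    genomes[[nm]] <- g
    genomes
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      genomes <- finish(genomes, cur_name, cur_tokens)
      cur_name <- gsub("[*]", "", trimws(sub("^>", "", ln)))
      cur_tokens <- character(0)
    } else {
      ln <- normalize_mgr_text(ln)
      cur_tokens <- c(cur_tokens, strsplit(ln, "\\s+")[[1]])
    }
  }
  genomes <- finish(genomes, cur_name, cur_tokens)
  if (length(genomes) == 0) stop("no genomes found in MGR text", call. = FALSE)
  genomes
}

tokens_to_genome <- function(tokens, name) {
  tokens <- tokens[nzchar(tokens)]
  chroms <- list()
  cur <- integer(0)
  for (tk in tokens) {
    if (tk == "$") {
      if (length(cur) > 0) chroms[[length(chroms) + 1L]] <- cur
      cur <- integer(0)
    } else {
      v <- suppressWarnings(as.integer(tk))
      if (is.na(v) || v == 0L) {
        stop("invalid token in MGR text: '", tk, "'", call. = FALSE)
      }
      cur <- c(cur, v)
    }
  }
  if (length(cur) > 0) chroms[[length(chroms) + 1L]] <- cur
  signed_genome(chroms, name = name)
}

#' @rdname parse_mgr
#' @param g A [signed_genome].
#' @export
format_mgr <- function(g) {
  g <- as_signed_genome(g)
  paste(vapply(g$chromosomes,
               function(ch) paste(c(ch, "$"), collapse = " "), character(1)),
        collapse = " ")
}

#' Read and write MGR `$` dialect genome files
#'
#' @param path File path.
#' @return `read_mgr()`: a named list of [signed_genome] objects.
#' @export
read_mgr <- function(path) parse_mgr(readLines(path, warn = FALSE))

#' @rdname read_mgr
#' @param genomes A [signed_genome] or a (named) list of them.
#' @export
write_mgr <- function(genomes, path) {
  if (inherits(genomes, "signed_genome")) genomes <- list(genomes)
  lines <- character(0)
  nms <- names(genomes)
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    nm <- if (!is.null(g$name)) g$name else if (!is.null(nms)) nms[i] else paste0("genome_", i)
    lines <- c(lines, paste0(">", nm), format_mgr(g))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Count breakpoints between two signed genomes
#'
#' A breakpoint is an adjacency (ordered pair of gene extremities) present in
#' `a` but not in `b`. Every single rearrangement operation changes at most
#' two adjacencies, so the distance is bounded below by half this count.
#'
#' @inheritParams genomes_equal
#' @return Integer breakpoint count.
#' @export
breakpoint_count <- function(a, b) {
  adj <- function(g) {
    out <- character(0)
    for (ch in g$chromosomes) {
      ext <- unlist(lapply(ch, function(v) {
        if (v > 0) c(2L * v - 1L, 2L * v) else c(-2L * v, -2L * v - 1L)
      }))
      if (length(ext) > 2) {
        inner <- ext[2:(length(ext) - 1)]
        pr <- matrix(inner, ncol = 2, byrow = TRUE)
        out <- c(out, paste(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2])))
      }
    }
    out
  }
  length(setdiff(adj(as_signed_genome(a)), adj(as_signed_genome(b))))
}

#' The nine-block pericentromeric genomes of three *Anopheles* species
#'
#' Returns the signed orders of the nine major pericentromeric synteny blocks
#' over four chromosome elements, of *An. gambiae*, *An. atroparvus*
#' and *An. albimanus*, in the MGR `$` dialect, as shipped in
#' `inst/extdata/anopheles_9block.mgr`. These orders are the canonical worked
#' example for the rearrangement machinery: the species differ by small
#' numbers of paracentric inversions and partial-arm translocations.
#'
#' @return A named list of three [signed_genome] objects
#'   (`gambiae`, `atroparvus`, `albimanus`).
#' @examples
#' gs <- anopheles_genomes()
#' genome_distance(gs$gambiae, gs$atroparvus)
#' @export
anopheles_genomes <- function() {
  path <- system.file("extdata", "anopheles_9block.mgr",
                      package = "karyoshuffle", mustWork = TRUE)
  gs <- read_mgr(path)
  names(gs) <- c("gambiae", "atroparvus", "albimanus")
  gs
}
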