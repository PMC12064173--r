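#' RNA secondary structure
#'
#' A well-nested (pseudoknot-free) set of base pairs over `n` positions.
#' Pairs are stored as a two-column matrix of 1-based indices `(i, j)` with
#' `i < j`; every position belongs to at most one pair, pairs may not cross,
#' and every hairpin loop encloses at least `min_hairpin` unpaired positions
#' (`j - i - 1 >= min_hairpin`).
#'
#' @param n sequence length.
#' @param pairs two-column integer matrix of pairs (zero rows for the empty
#'   structure), or `NULL`.
#' @param min_hairpin minimum hairpin loop size (default 3).
#' @return object of class `rna_structure`.
#' @export
#' @examples
#' s <- rna_structure(9, cbind(c(1, 2, 3), c(9, 8, 7)))
#' format_dotbracket(s)
rna_structure <- function(n, pairs = NULL, min_hairpin = 3L) {
  n <- as.integer(n)
  if (n < 1) abort("n must be >= 1", class = "psifold_input_error")
  if (is.null(pairs) || length(pairs) == 0)
    pairs <- matrix(integer(0), ncol = 2)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0) {
    if (any(pairs < 1L | pairs > n))
      abort("pair index out of range", class = "psifold_input_error")
    bad <- pairs[, 1] >= pairs[, 2]
    if (any(bad)) {
      pairs[bad, ] <- pairs[bad, c(2, 1)]
    }
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      abort("a position appears in more than one pair",
            class = "psifold_input_error")
    if (any(pairs[, 2] - pairs[, 1] - 1L < min_hairpin))
      abort(paste0("hairpin loop smaller than ", min_hairpin),
            class = "psifold_input_error")
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    # crossing check: i < i' <= j < j' is forbidden
    if (nrow(pairs) > 1) {
      for (r in seq_len(nrow(pairs) - 1)) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        later <- pairs[(r + 1):nrow(pairs), , drop = FALSE]
        inside <- later[, 1] > i & later[, 1] < j
        if (any(inside & later[, 2] > j))
          abort("crossing base pairs (pseudoknot)",
                class = "psifold_input_error")
      }
    }
  }
  structure(list(n = n, pairs = unname(pairs)), class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> n =", x$n, "with", nrow(x$pairs), "pairs\n")
  cat(" ", format_dotbracket(x), "\n")
  invisible(x)
}

#' Dot-bracket notation
#'
#' `parse_dotbracket()` reads a string over `.`, `(` and `)` into an
#' [rna_structure()]; `format_dotbracket()` renders one back. Column position
#' is the only coordinate (1-based by position).
#'
#' @param x dot-bracket string.
#' @param min_hairpin minimum hairpin loop size.
#' @return an [rna_structure()] / a character string.
#' @export
#' @examples
#' parse_dotbracket("(((...)))")
parse_dotbracket <- function(x, min_hairpin = 3L) {
  chars <- strsplit(x, "")[[1]]
  if (!all(chars %in% c(".", "(", ")")))
    abort("dot-bracket may contain only '.', '(' and ')'",
          class = "psifold_input_error")
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") open <- c(open, k)
    else if (chars[k] == ")") {
      if (length(open) == 0)
        abort("unbalanced ')' in dot-bracket", class = "psifold_input_error")
      pairs <- rbind(pairs, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0)
    abort("unbalanced '(' in dot-bracket", class = "psifold_input_error")
  rna_structure(length(chars), pairs, min_hairpin = min_hairpin)
}

#' @rdname parse_dotbracket
#' @param s an [rna_structure()].
#' @export
format_dotbracket <- function(s) {
  out <- rep(".", s$n)
  if (nrow(s$pairs) > 0) {
    out[s$pairs[, 1]] <- "("
    out[s$pairs[, 2]] <- ")"
  }
  paste(out, collapse = "")
}

#' Single-stem hairpin target
#'
#' The canonical toy design target: a single helix of length
#' `floor((n - 3) / 2)` closing a terminal loop.
#'
#' @param n sequence length (>= 5).
#' @return an [rna_structure()].
#' @export
#' @examples
#' format_dotbracket(hairpin_target(11))
hairpin_target <- function(n) {
  stem <- (n - 3L) %/% 2L
  if (stem < 1) abort("n too short for a hairpin", class = "psifold_input_error")
  rna_structure(n, cbind(seq_len(stem), n + 1L - seq_len(stem)))
}

# ---------------------------------------------------------------------------
# Loop decomposition: the bridge between per-loop energies and whole
# structures. Returns a list of loops, each a list with a `type` in
# {hairpin, stack, internal, multiloop, exterior} and the index data needed
# to evaluate its energy for any sequence.
# ---------------------------------------------------------------------------
decompose_loops <- function(s) {
  pairs <- s$pairs
  np <- nrow(pairs)
  loops <- list()
  if (np == 0) {
    return(list(list(type = "exterior", children = matrix(integer(0), ncol = 2))))
  }
  # parent of each pair via a stack sweep (pairs sorted by i)
  parent <- rep(NA_integer_, np)
  open <- integer(0)
  for (r in seq_len(np)) {
    while (length(open) > 0 && pairs[r, 1] > pairs[open[length(open)], 2])
      open <- open[-length(open)]
    if (length(open) > 0) parent[r] <- open[length(open)]
    open <- c(open, r)
  }
  children <- lapply(seq_len(np), function(r) which(parent == r))
  top <- which(is.na(parent))
  for (r in seq_len(np)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    cs <- children[[r]]
    if (length(cs) == 0) {
      loops[[length(loops) + 1]] <-
        list(type = "hairpin", outer = c(i, j), size = j - i - 1L)
    } else if (length(cs) == 1) {
      k <- pairs[cs, 1]; l <- pairs[cs, 2]
      if (k == i + 1L && l == j - 1L) {
        loops[[length(loops) + 1]] <-
          list(type = "stack", outer = c(i, j), inner = c(k, l))
      } else {
        loops[[length(loops) + 1]] <-
          list(type = "internal", outer = c(i, j), inner = c(k, l),
               left = k - i - 1L, right = j - l - 1L)
      }
    } else {
      spans <- pairs[cs, , drop = FALSE]
      unpaired <- (j - i - 1L) - sum(spans[, 2] - spans[, 1] + 1L)
      loops[[length(loops) + 1]] <-
        list(type = "multiloop", outer = c(i, j),
             children = spans, branches = 1L + length(cs),
             unpaired = unpaired)
    }
  }
  loops[[length(loops) + 1]] <-
    list(type = "exterior", children = pairs[top, , drop = FALSE])
  loops
}
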