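#' Nearest-neighbor energy model
#'
#' Holds the loop free-energy parameters (kcal/mol) that the folding core
#' sums over: size-indexed hairpin initiation, directional stacking energies
#' for all ordered pairs of allowed base pairs, size-indexed bulge and
#' internal-loop initiation (capped), an affine multiloop model
#' `a + b * branches + c * unpaired`, a terminal penalty for non-GC closing
#' pairs, and the thermal energy `kT`. Loop initiation tables are extended
#' beyond their largest tabulated size by the Jacobson-Stockmayer form
#' `E(m) = E(m_max) + 1.75 * kT * log(m / m_max)`.
#'
#' Scope: coaxial stacking, dangling ends, terminal mismatches and tetraloop
#' bonuses are deliberately excluded, so a loop's energy depends only on its
#' size(s) and its closing pair identities. Hairpins take the terminal
#' penalty on their closing pair; bulge and internal loops on both closing
#' pairs; multiloop branches and exterior helices take none. Lonely (isolated)
#' pairs are allowed.
#'
#' @param hairpin named numeric, hairpin initiation by loop size.
#' @param stack_increments named numeric of per-pair stack half-energies; the
#'   stack energy of outer pair p on inner pair q is
#'   `stack_increments[p] + stack_increments[q]` unless a full `stack` matrix
#'   is supplied.
#' @param stack optional 6 x 6 numeric matrix (dimnames = allowed pairs) of
#'   directional stack energies; overrides `stack_increments`.
#' @param bulge,internal named numeric initiation tables by loop size.
#' @param multi numeric length 3: closing, per-branch, per-unpaired.
#' @param terminal_au penalty (kcal/mol) for a non-GC/CG closing pair.
#' @param kT thermal energy in kcal/mol; 0.61633 corresponds to 37 C.
#' @param theta minimum hairpin loop size (unpaired nucleotides).
#' @param internal_cap largest total unpaired size of an internal/bulge loop;
#'   larger loops get weight zero.
#' @return object of class `energy_model`.
#' @export
#' @examples
#' m <- energy_model()
#' stack_energy(m, "GC", "GC")
energy_model <- function(hairpin = c("3" = 5.4, "4" = 5.6, "5" = 5.7,
                                     "6" = 5.4, "7" = 6.0, "8" = 5.5,
                                     "9" = 6.4),
                         stack_increments = c(GC = -1.65, CG = -1.65,
                                              AU = -0.55, UA = -0.55,
                                              GU = -0.35, UG = -0.35),
                         stack = NULL,
                         bulge = c("1" = 3.8, "2" = 2.8, "3" = 3.2,
                                   "4" = 3.6, "5" = 4.0, "6" = 4.4),
                         internal = c("2" = 1.5, "3" = 1.6, "4" = 1.7,
                                      "5" = 1.8, "6" = 2.0),
                         multi = c(3.4, 0.4, 0.0),
                         terminal_au = 0.5,
                         kT = 0.61633,
                         theta = 3L,
                         internal_cap = 30L) {
  if (kT <= 0) abort("kT must be positive", class = "psifold_input_error")
  if (is.null(stack)) {
    stack <- outer(stack_increments[ALLOWED_PAIRS],
                   stack_increments[ALLOWED_PAIRS], `+`)
    dimnames(stack) <- list(ALLOWED_PAIRS, ALLOWED_PAIRS)
  }
  stopifnot(identical(dim(stack), c(6L, 6L)),
            identical(rownames(stack), ALLOWED_PAIRS),
            identical(colnames(stack), ALLOWED_PAIRS),
            !anyNA(stack))
  check_size_table <- function(x, min_size, what) {
    sz <- as.integer(names(x))
    if (anyNA(sz) || any(sz < min_size) || anyNA(x))
      abort(paste0("malformed ", what, " table"),
            class = "psifold_input_error")
    x[order(sz)]
  }
  m <- structure(list(
    hairpin = check_size_table(hairpin, theta, "hairpin"),
    stack = stack,
    bulge = check_size_table(bulge, 1L, "bulge"),
    internal = check_size_table(internal, 2L, "internal"),
    multi = setNames(as.numeric(multi), c("a", "b", "c")),
    terminal_au = as.numeric(terminal_au),
    kT = as.numeric(kT),
    theta = as.integer(theta),
    internal_cap = as.integer(internal_cap)
  ), class = "energy_model")
  m
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model>\n")
  cat("  kT:", x$kT, "kcal/mol  theta:", x$theta,
      " internal cap:", x$internal_cap, "\n")
  cat("  hairpin sizes:", paste(names(x$hairpin), collapse = " "),
      " terminal non-GC penalty:", x$terminal_au, "\n")
  cat("  multiloop (a, b, c):", paste(x$multi, collapse = ", "), "\n")
  invisible(x)
}

# size-indexed lookup with Jacobson-Stockmayer tail
size_energy <- function(table, size, kT) {
  key <- as.character(size)
  if (key %in% names(table)) return(unname(table[key]))
  sizes <- as.integer(names(table))
  mx <- max(sizes)
  if (size < min(sizes)) abort("loop size below table range",
                               class = "psifold_domain_error")
  unname(table[as.character(mx)]) + 1.75 * kT * log(size / mx)
}

terminal_penalty <- function(model, pair) {
  if (pair %in% GC_PAIRS) 0 else model$terminal_au
}

check_pair <- function(pair) {
  if (!is_allowed_pair(pair))
    abort(paste0("not an allowed base pair: ", pair),
          class = "psifold_domain_error")
  invisible(pair)
}

#' Loop free energies
#'
#' Accessors evaluating single loop terms of an [energy_model()]:
#' `hairpin_energy()` for a hairpin of given closing pair and loop size,
#' `stack_energy()` for an outer pair stacked on an inner pair,
#' `internal_or_bulge_energy()` for an internal or bulge loop with given
#' unpaired counts on each strand, and `multiloop_energy()` for the affine
#' multiloop term (`branches` counts the closing pair).
#'
#' @param model an [energy_model()].
#' @param pair,outer,inner ordered pair strings, e.g. `"GC"` for G paired
#'   with C reading 5' to 3' on the closing positions.
#' @param size hairpin loop size (unpaired nucleotides).
#' @param left,right unpaired counts on the two strands of an internal or
#'   bulge loop; `left + right >= 1`. Loops above the model's size cap get
#'   `+Inf` (Boltzmann weight zero).
#' @param branches number of branches including the closing pair (>= 3).
#' @param unpaired number of unpaired nucleotides inside the multiloop.
#' @return energy in kcal/mol.
#' @export
#' @examples
#' m <- energy_model()
#' hairpin_energy(m, "GC", 3)
#' hairpin_energy(m, "AU", 3)  # adds the terminal penalty
hairpin_energy <- function(model, pair, size) {
  check_pair(pair)
  if (size < model$theta)
    abort(paste0("hairpin loop size ", size, " below minimum ", model$theta),
          class = "psifold_domain_error")
  size_energy(model$hairpin, size, model$kT) + terminal_penalty(model, pair)
}

#' @rdname hairpin_energy
#' @export
stack_energy <- function(model, outer, inner) {
  check_pair(outer)
  check_pair(inner)
  unname(model$stack[outer, inner])
}

#' @rdname hairpin_energy
#' @export
internal_or_bulge_energy <- function(model, outer, inner, left, right) {
  check_pair(outer)
  check_pair(inner)
  size <- left + right
  if (size < 1) abort("internal/bulge loop needs at least one unpaired base",
                      class = "psifold_domain_error")
  if (size > model$internal_cap) return(Inf)
  init <- if (left == 0L || right == 0L) size_energy(model$bulge, size, model$kT)
          else size_energy(model$internal, size, model$kT)
  init + terminal_penalty(model, outer) + terminal_penalty(model, inner)
}

#' @rdname hairpin_energy
#' @export
multiloop_energy <- function(model, branches, unpaired) {
  if (branches < 3)
    abort("a multiloop has at least 3 branches counting the closing pair",
          class = "psifold_domain_error")
  unname(model$multi["a"] + model$multi["b"] * branches +
           model$multi["c"] * unpaired)
}

#' Boltzmann weight of an energy
#'
#' `exp(-e / kT)`; an infinite energy maps to weight zero.
#'
#' @param model an [energy_model()].
#' @param e energy in kcal/mol.
#' @return dimensionless weight.
#' @export
boltzmann_weight <- function(model, e) exp(-e / model$kT)

# ---------------------------------------------------------------------------
# Parameter file I/O: plain text, one record per line, '#' comments.
#   hairpin <size> <kcal/mol> | stack <pair> <pair> <e> | bulge <size> <e>
#   internal <size> <e> | multi <a> <b> <c> | terminal_au <e> | kT <e>
#   internal_cap <int> | theta <int>
# ---------------------------------------------------------------------------

#' Read and write energy parameter files
#'
#' The format is one whitespace-separated record per line (`hairpin <size>
#' <energy>`, `stack <pair> <pair> <energy>`, `bulge <size> <energy>`,
#' `internal <size> <energy>`, `multi <a> <b> <c>`, `terminal_au <energy>`,
#' `kT <energy>`, `internal_cap <int>`, `theta <int>`), with `#` comments.
#' Entries absent from the file fall back to the package's built-in toy
#' defaults with a warning. A shipped example lives at
#' `system.file("extdata", "params_toy.txt", package = "psifold")`.
#'
#' @param path file path.
#' @param model an [energy_model()] (for `write_energy_params`).
#' @return `read_energy_params` returns an [energy_model()];
#'   `write_energy_params` returns `path` invisibly.
#' @export
read_energy_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  defaults <- energy_model()
  hairpin <- numeric(0); bulge <- numeric(0); internal <- numeric(0)
  stack <- matrix(NA_real_, 6, 6, dimnames = list(ALLOWED_PAIRS, ALLOWED_PAIRS))
  multi <- NULL; terminal_au <- NULL; kT <- NULL
  cap <- NULL; theta <- NULL
  parse_fail <- function(i, why) {
    abort(sprintf("parse error at line %d: %s", i, why),
          class = "psifold_parse_error")
  }
  num <- function(tok, i) {
    x <- suppressWarnings(as.numeric(tok))
    if (anyNA(x)) parse_fail(i, paste0("not a number: ", paste(tok, collapse = " ")))
    x
  }
  for (i in seq_along(lines)) {
    line <- sub("#.*", "", lines[i])
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) == 0) next
    key <- tok[1]
    if (key %in% c("hairpin", "bulge", "internal")) {
      if (length(tok) != 3) parse_fail(i, "expected: <key> <size> <energy>")
      sz <- as.integer(num(tok[2], i))
      val <- setNames(num(tok[3], i), as.character(sz))
      if (key == "hairpin") hairpin <- c(hairpin, val)
      else if (key == "bulge") bulge <- c(bulge, val)
      else internal <- c(internal, val)
    } else if (key == "stack") {
      if (length(tok) != 4) parse_fail(i, "expected: stack <pair> <pair> <energy>")
      p <- toupper(tok[2]); q <- toupper(tok[3])
      if (!is_allowed_pair(p)) parse_fail(i, paste0("not a pair: ", tok[2]))
      if (!is_allowed_pair(q)) parse_fail(i, paste0("not a pair: ", tok[3]))
      stack[p, q] <- num(tok[4], i)
    } else if (key == "multi") {
      if (length(tok) != 4) parse_fail(i, "expected: multi <a> <b> <c>")
      multi <- num(tok[2:4], i)
    } else if (key == "terminal_au") {
      terminal_au <- num(tok[2], i)
    } else if (key == "kT") {
      kT <- num(tok[2], i)
    } else if (key == "internal_cap") {
      cap <- as.integer(num(tok[2], i))
    } else if (key == "theta") {
      theta <- as.integer(num(tok[2], i))
    } else {
      parse_fail(i, paste0("unknown record type: ", key))
    }
  }
  missing <- character(0)
  if (length(hairpin) == 0) { hairpin <- defaults$hairpin; missing <- c(missing, "hairpin") }
  if (length(bulge) == 0) { bulge <- defaults$bulge; missing <- c(missing, "bulge") }
  if (length(internal) == 0) { internal <- defaults$internal; missing <- c(missing, "internal") }
  if (anyNA(stack)) {
    if (all(is.na(stack))) { stack <- defaults$stack; missing <- c(missing, "stack") }
    else {
      # fill individual gaps from defaults
      stack[is.na(stack)] <- defaults$stack[is.na(stack)]
      missing <- c(missing, "stack (partial)")
    }
  }
  if (is.null(multi)) { multi <- defaults$multi; missing <- c(missing, "multi") }
  if (is.null(terminal_au)) { terminal_au <- defaults$terminal_au; missing <- c(missing, "terminal_au") }
  if (is.null(kT)) { kT <- defaults$kT; missing <- c(missing, "kT") }
  if (is.null(cap)) cap <- defaults$internal_cap
  if (is.null(theta)) theta <- defaults$theta
  if (length(missing) > 0)
    warn(paste0("parameter file ", path, " missing entries, using defaults for: ",
                paste(missing, collapse = ", ")),
         class = "psifold_defaults_warning")
  energy_model(hairpin = hairpin, stack = stack, bulge = bulge,
               internal = internal, multi = multi, terminal_au = terminal_au,
               kT = kT, theta = theta, internal_cap = cap)
}

#' @rdname read_energy_params
#' @export
write_energy_params <- function(model, path) {
  fmt <- function(x) sprintf("%.12g", x)
  lines <- c(
    "# nearest-neighbor loop free energies (kcal/mol)",
    paste("kT", fmt(model$kT)),
    paste("theta", model$theta),
    paste("internal_cap", model$internal_cap),
    paste("terminal_au", fmt(model$terminal_au)),
    paste("multi", fmt(model$multi["a"]), fmt(model$multi["b"]),
          fmt(model$multi["c"])),
    paste("hairpin", names(model$hairpin), fmt(model$hairpin)),
    paste("bulge", names(model$bulge), fmt(model$bulge)),
    paste("internal", names(model$internal), fmt(model$internal)),
    as.vector(outer(ALLOWED_PAIRS, ALLOWED_PAIRS, function(p, q)
      paste("stack", p, q, fmt(model$stack[cbind(p, q)]))))
  )
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Precomputed Boltzmann-weight arrays consumed by the C++ kernels.
# ---------------------------------------------------------------------------

# Returns the flat weight list shared by the discrete and expected kernels:
# all energies pre-exponentiated, pairability and terminal penalties as
# multiplicative 4x4 factors, sizes indexed from 0.
fold_weights <- function(model, n, scale = 1) {
  if (scale <= 0) abort("scale constant must be positive",
                        class = "psifold_input_error")
  kT <- model$kT
  theta <- model$theta
  cap <- model$internal_cap
  wh <- numeric(n + 1)
  if (n >= theta + 2) {
    for (sz in theta:(n - 2)) wh[sz + 1] <-
        exp(-size_energy(model$hairpin, sz, kT) / kT)
  }
  pairable <- integer(16)
  au <- rep(1, 16)
  for (p in ALLOWED_PAIRS) {
    pc <- pair_codes(p)
    idx <- pc[1] * 4 + pc[2] + 1
    pairable[idx] <- 1L
    au[idx] <- exp(-terminal_penalty(model, p) / kT)
  }
  ws <- numeric(256)
  for (p in ALLOWED_PAIRS) for (q in ALLOWED_PAIRS) {
    pc <- pair_codes(p); qc <- pair_codes(q)
    idx <- ((pc[1] * 4 + pc[2]) * 4 + qc[1]) * 4 + qc[2] + 1
    ws[idx] <- exp(-model$stack[p, q] / kT)
  }
  wbu <- numeric(cap + 1)
  win <- numeric(cap + 1)
  for (sz in 1:cap) wbu[sz + 1] <- exp(-size_energy(model$bulge, sz, kT) / kT)
  for (sz in 2:cap) win[sz + 1] <- exp(-size_energy(model$internal, sz, kT) / kT)
  list(wh = wh, ws = ws, wbu = wbu, win = win, au = au, pairable = pairable,
       wa = exp(-model$multi[["a"]] / kT),
       wbm = exp(-model$multi[["b"]] / kT),
       wcm = exp(-model$multi[["c"]] / kT),
       theta = as.integer(theta), cap = as.integer(cap),
       scale = as.numeric(scale))
}
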