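# mRNA stability-CAI design over a nucleotide-level sequence distribution.
#
# The partition function operates at the nucleotide level; the coding
# requirement and the codon adaptation index are expressed as smooth
# functionals of the per-codon marginals of Psi, so the whole loss is
# differentiable in Psi.

#' The standard genetic code over RNA codons
#'
#' Codon-to-amino-acid map (one-letter codes, `*` for stop) for all 64 RNA
#' codons, derived from the standard code.
#'
#' @return named character vector of length 64; names are RNA codons.
#' @export
#' @examples
#' genetic_code_rna()[["AUG"]]
genetic_code_rna <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), chartr("T", "U", names(gc)))
}

codon_table <- function() {
  code <- genetic_code_rna()
  codons <- names(code)
  idx <- t(vapply(codons, function(cd) match(strsplit(cd, "")[[1]], NUCS),
                  integer(3)))
  list(code = code, codons = codons, idx = idx,
       sense = codons[code != "*"])
}

# synonymous codon rows (into codon_table order) per amino acid
synonymous_index <- function(tab = codon_table()) {
  split(seq_along(tab$codons), tab$code)
}

#' Translate an RNA sequence
#'
#' @param seq coding nucleotide string, length a multiple of 3.
#' @return amino-acid string.
#' @export
translate_rna <- function(seq) {
  codes <- seq_to_codes(seq)
  if (length(codes) %% 3 != 0)
    abort("sequence length must be a multiple of 3", class = "psifold_input_error")
  code <- genetic_code_rna()
  codons <- vapply(seq_len(length(codes) / 3), function(k)
    codes_to_seq(codes[(3 * k - 2):(3 * k)]), character(1))
  paste(code[codons], collapse = "")
}

check_protein <- function(protein) {
  aas <- strsplit(protein, "")[[1]]
  if (length(aas) == 0 || any(aas == "*"))
    abort("protein must be non-empty and contain no stop symbol",
          class = "psifold_input_error")
  valid <- unique(genetic_code_rna())
  if (!all(aas %in% valid))
    abort("unknown amino-acid letter in protein", class = "psifold_input_error")
  aas
}

# ---------------------------------------------------------------------------
# CAI weights
# ---------------------------------------------------------------------------

#' Relative-adaptiveness (CAI) weight tables
#'
#' A CAI weight table maps each of the 61 sense codons to a relative
#' adaptiveness `w` in (0, 1], with `max w = 1` among the synonymous codons
#' of every amino acid. `read_cai_weights()` reads a two-column TSV
#' (`codon<TAB>weight`, RNA or DNA alphabet), `write_cai_weights()` writes
#' one, `cai_weights_from_usage()` derives `w` from codon-usage counts as
#' the frequency ratio to the most-used synonymous codon, and
#' `toy_cai_weights()` gives the package's deterministic toy table (per
#' amino acid, lexicographically ordered synonymous codons get the weights
#' 1, 0.7, 0.55, 0.45, 0.38, 0.33). A copy of the toy table ships at
#' `system.file("extdata", "cai_weights_toy.tsv", package = "psifold")`.
#'
#' @param path file path.
#' @param w named numeric weight vector.
#' @param counts named numeric codon-usage counts (all 61 sense codons).
#' @return a validated named numeric vector over the 61 sense codons.
#' @export
read_cai_weights <- function(path) {
  df <- readr::read_tsv(path, col_names = c("codon", "weight"),
                        col_types = "cd", comment = "#")
  w <- setNames(df$weight, chartr("T", "U", toupper(df$codon)))
  validate_cai_weights(w)
}

#' @rdname read_cai_weights
#' @export
write_cai_weights <- function(w, path) {
  validate_cai_weights(w)
  readr::write_tsv(tibble(codon = names(w), weight = unname(w)), path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname read_cai_weights
#' @export
validate_cai_weights <- function(w) {
  tab <- codon_table()
  missing <- setdiff(tab$sense, names(w))
  if (length(missing) > 0)
    abort(paste0("CAI weights missing sense codons: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "psifold_input_error")
  w <- w[tab$sense]
  if (any(w <= 0) || any(w > 1))
    abort("CAI weights must lie in (0, 1]", class = "psifold_input_error")
  for (syn in synonymous_index(tab)[setdiff(unique(tab$code), "*")]) {
    cods <- intersect(tab$codons[syn], tab$sense)
    if (abs(max(w[cods]) - 1) > 1e-9)
      abort("every amino acid needs a synonymous codon with weight 1",
            class = "psifold_input_error")
  }
  w
}

#' @rdname read_cai_weights
#' @export
cai_weights_from_usage <- function(counts) {
  tab <- codon_table()
  w <- setNames(numeric(length(tab$sense)), tab$sense)
  for (aa in setdiff(unique(tab$code), "*")) {
    cods <- tab$codons[tab$code == aa]
    cnt <- counts[cods]
    if (anyNA(cnt) || max(cnt) <= 0)
      abort(paste0("usage counts missing for amino acid ", aa),
            class = "psifold_input_error")
    w[cods] <- cnt / max(cnt)
  }
  validate_cai_weights(w)
}

#' @rdname read_cai_weights
#' @export
toy_cai_weights <- function() {
  tab <- codon_table()
  ladder <- c(1, 0.7, 0.55, 0.45, 0.38, 0.33)
  w <- setNames(numeric(length(tab$sense)), tab$sense)
  for (aa in setdiff(unique(tab$code), "*")) {
    cods <- sort(tab$codons[tab$code == aa])
    w[cods] <- ladder[seq_along(cods)]
  }
  validate_cai_weights(w)
}

#' Classical codon adaptation index of a discrete coding sequence
#'
#' Geometric mean of the relative adaptiveness over the sequence's codons.
#'
#' @param seq coding nucleotide string.
#' @param w CAI weight table (see [read_cai_weights()]).
#' @return CAI in (0, 1].
#' @export
classical_cai <- function(seq, w) {
  codes <- seq_to_codes(seq)
  if (length(codes) %% 3 != 0)
    abort("sequence length must be a multiple of 3", class = "psifold_input_error")
  cods <- vapply(seq_len(length(codes) / 3), function(k)
    codes_to_seq(codes[(3 * k - 2):(3 * k)]), character(1))
  if (anyNA(w[cods]))
    abort("sequence contains a stop or unknown codon", class = "psifold_input_error")
  exp(mean(log(w[cods])))
}

# ---------------------------------------------------------------------------
# Distribution-level quantities
# ---------------------------------------------------------------------------

#' Codon marginal of a sequence distribution
#'
#' The distribution over the 64 codons at codon position `k` induced by the
#' product structure of Psi:
#' `p_k(c) = psi_{3k-2}(c1) * psi_{3k-1}(c2) * psi_{3k}(c3)`.
#'
#' @param psi `n x 4` distribution with `n` a multiple of 3.
#' @param k codon index (1-based).
#' @return named probability vector over the 64 codons (sums to 1).
#' @export
codon_marginal <- function(psi, k) {
  n <- nrow(psi)
  if (n %% 3 != 0) abort("psi length must be a multiple of 3",
                         class = "psifold_input_error")
  if (k < 1 || k > n / 3) abort("codon index out of range",
                                class = "psifold_input_error")
  tab <- codon_table()
  r <- 3L * (k - 1L)
  p <- psi[r + 1L, tab$idx[, 1]] * psi[r + 2L, tab$idx[, 2]] *
    psi[r + 3L, tab$idx[, 3]]
  setNames(p, tab$codons)
}

#' Probability that a sampled sequence codes for the target protein
#'
#' `prod over codon positions of the marginal mass on the synonymous codons
#' of the target amino acid`; exact because codon positions are independent
#' under Psi.
#'
#' @param psi `n x 4` distribution, `n = 3 * nchar(protein)`.
#' @param protein target amino-acid string.
#' @return probability in \[0, 1\].
#' @export
#' @examples
#' coding_probability(psi_uniform(3), "M")  # 1/64
coding_probability <- function(psi, protein) {
  aas <- check_protein(protein)
  if (nrow(psi) != 3 * length(aas))
    abort("psi length must be 3 * protein length", class = "psifold_input_error")
  tab <- codon_table()
  syn <- synonymous_index(tab)
  prod(vapply(seq_along(aas), function(k)
    sum(codon_marginal(psi, k)[syn[[aas[k]]]]), numeric(1)))
}

#' Expected codon adaptation index of a sequence distribution
#'
#' Generalizes the classical CAI (undefined for continuous sequences) to a
#' distribution: the product over codon positions of the conditional
#' expectation of `w^(1/L)` given that the codon is synonymous with the
#' target amino acid (the per-position marginal restricted to synonymous
#' codons and renormalized). For a one-hot coding Psi this reduces exactly
#' to the classical CAI, and it factorizes position-wise, giving an
#' `O(64 L)` evaluation.
#'
#' @inheritParams coding_probability
#' @param w CAI weight table.
#' @return expected CAI in (0, 1].
#' @export
expected_cai <- function(psi, protein, w) {
  aas <- check_protein(protein)
  if (nrow(psi) != 3 * length(aas))
    abort("psi length must be 3 * protein length", class = "psifold_input_error")
  w <- w[codon_table()$sense]
  L <- length(aas)
  tab <- codon_table()
  syn <- synonymous_index(tab)
  out <- 1
  for (k in seq_len(L)) {
    p <- codon_marginal(psi, k)[syn[[aas[k]]]]
    B <- sum(p)
    if (B <= 0)
      abort("coding probability is zero; expected CAI undefined",
            class = "psifold_numerical_error")
    out <- out * sum(p * w[names(p)]^(1 / L)) / B
  }
  unname(out)
}

# analytic gradients of expected CAI and log coding probability w.r.t. psi;
# each codon position touches exactly three psi rows
mrna_term_gradients <- function(psi, protein, w) {
  aas <- check_protein(protein)
  tab <- codon_table()
  syn <- synonymous_index(tab)
  L <- length(aas)
  n <- nrow(psi)
  g_ecai <- matrix(0, n, 4)
  g_logcp <- matrix(0, n, 4)
  fk <- numeric(L)
  parts <- vector("list", L)
  for (k in seq_len(L)) {
    rows <- 3L * (k - 1L) + 1:3
    srows <- syn[[aas[k]]]
    idx <- tab$idx[srows, , drop = FALSE]
    wk <- w[tab$codons[srows]]^(1 / L)
    # per-synonymous-codon probability and partials w.r.t. each of the 3 rows
    pcod <- psi[rows[1], idx[, 1]] * psi[rows[2], idx[, 2]] * psi[rows[3], idx[, 3]]
    A <- sum(pcod * wk); B <- sum(pcod)
    if (B <= 0)
      abort("coding probability is zero; gradient undefined",
            class = "psifold_numerical_error")
    dA <- matrix(0, 3, 4); dB <- matrix(0, 3, 4)
    for (pos in 1:3) {
      others <- setdiff(1:3, pos)
      leave_one <- psi[rows[others[1]], idx[, others[1]]] *
        psi[rows[others[2]], idx[, others[2]]]
      for (x in 1:4) {
        sel <- idx[, pos] == x
        dA[pos, x] <- sum(leave_one[sel] * wk[sel])
        dB[pos, x] <- sum(leave_one[sel])
      }
    }
    fk[k] <- A / B
    parts[[k]] <- list(rows = rows, dlogf = dA / A - dB / B, dlogB = dB / B)
  }
  ecai <- prod(fk)
  for (k in seq_len(L)) {
    g_ecai[parts[[k]]$rows, ] <- ecai * parts[[k]]$dlogf
    g_logcp[parts[[k]]$rows, ] <- parts[[k]]$dlogB
  }
  list(ecai = ecai, g_ecai = g_ecai, g_logcp = g_logcp)
}

#' Stability-CAI design loss
#'
#' The continuous mRNA design objective
#' `EFE(Psi) + lambda_cai * max(0, cai_floor - expected_cai)^2
#'  - lambda_code * log(coding_probability)`,
#' where `EFE(Psi) = -kT * log Z_Psi` is the (expected-ensemble) free energy.
#' The CAI hinge is dropped when `cai_floor` is `NULL` (the unconstrained
#' regime). Default penalty weights are `100 kT` and `10 kT`, scale-matched
#' to the free energy term.
#'
#' @param psi `n x 4` distribution, `n = 3 * nchar(protein)`.
#' @param protein target amino-acid string.
#' @param model an [energy_model()].
#' @param w CAI weight table.
#' @param cai_floor target CAI in \[0, 1\] or `NULL`.
#' @param lambda_cai,lambda_code nonnegative loss weights (defaults
#'   `100 * kT` and `10 * kT`).
#' @param scale scaling constant for the partition evaluation.
#' @param grad if `TRUE`, include the gradient w.r.t. Psi.
#' @return list with `loss`, `efe`, `expected_cai`, `coding_probability`,
#'   and (optionally) `grad_psi`.
#' @export
mrna_loss <- function(psi, protein, model, w, cai_floor = NULL,
                      lambda_cai = NULL, lambda_code = NULL, scale = 1,
                      grad = FALSE) {
  lambda_cai <- lambda_cai %||% (100 * model$kT)
  lambda_code <- lambda_code %||% (10 * model$kT)
  fr <- expected_partition(psi, model, scale = scale, grad = grad,
                           validate = FALSE)
  cp <- coding_probability(psi, protein)
  if (cp <= 0)
    abort("coding probability is zero under psi", class = "psifold_numerical_error")
  tg <- mrna_term_gradients(psi, protein, w)
  hinge <- if (is.null(cai_floor)) 0 else max(0, cai_floor - tg$ecai)
  loss <- fr$efe + lambda_cai * hinge^2 - lambda_code * log(cp)
  out <- list(loss = loss, efe = fr$efe, expected_cai = tg$ecai,
              coding_probability = cp)
  if (grad) {
    g <- -model$kT * fr$grad_psi - lambda_code * tg$g_logcp
    if (hinge > 0) g <- g - 2 * lambda_cai * hinge * tg$g_ecai
    out$grad_psi <- g
  }
  out
}

#' Embed a discrete coding sequence as a near-one-hot distribution
#'
#' Warm start for mRNA design: the given coding sequence with `eps`
#' off-sequence mass per nucleotide (keeps gradients finite off the simplex
#' vertex). With `eps = 0` an exact one-hot is returned with a warning that
#' gradients may vanish there.
#'
#' @param seq coding nucleotide string.
#' @param protein target protein the sequence must translate to.
#' @param eps off-sequence mass per nucleotide.
#' @return an `n x 4` distribution with `decode_psi()` equal to `seq`.
#' @export
warm_start <- function(seq, protein, eps = 1e-3) {
  seq <- as_rna(seq)
  if (translate_rna(seq) != protein)
    abort("warm-start sequence does not code for the target protein",
          class = "psifold_input_error")
  if (eps == 0) {
    warn("eps = 0: exact one-hot start; gradients may vanish at the simplex vertex")
    return(psi_one_hot(seq))
  }
  psi_near_one_hot(seq, eps = eps)
}

#' Decode a distribution to a coding sequence
#'
#' Per-codon argmax of the codon marginal restricted to the synonymous
#' codons of the target amino acid, so the output always codes for the
#' protein. Ties break to the lexicographically smallest codon.
#'
#' @inheritParams coding_probability
#' @return coding nucleotide string.
#' @export
decode_coding <- function(psi, protein) {
  aas <- check_protein(protein)
  if (nrow(psi) != 3 * length(aas))
    abort("psi length must be 3 * protein length", class = "psifold_input_error")
  tab <- codon_table()
  syn <- synonymous_index(tab)
  paste(vapply(seq_along(aas), function(k) {
    p <- codon_marginal(psi, k)[syn[[aas[k]]]]
    p <- p[order(names(p))] # lexicographic tie-break
    names(p)[which.max(p)]
  }, character(1)), collapse = "")
}

#' Random coding sequence for a protein
#'
#' Uniformly random synonymous codon at every position; deterministic given
#' the seed. With `min_cai` set, draws are repeated (deterministically) until
#' the sequence's classical CAI under `w` reaches the floor — the natural
#' seed for a CAI-constrained design run, whose warm start is expected to
#' satisfy the constraint (as a constraint-respecting reference solution
#' would).
#'
#' @param protein amino-acid string.
#' @param seed integer seed.
#' @param min_cai optional classical-CAI floor for the drawn sequence.
#' @param w CAI weight table (required with `min_cai`).
#' @param max_tries rejection budget before giving up with an error.
#' @return coding nucleotide string.
#' @export
random_coding_sequence <- function(protein, seed = 1, min_cai = NULL,
                                   w = NULL, max_tries = 1000L) {
  aas <- check_protein(protein)
  tab <- codon_table()
  syn <- synonymous_index(tab)
  draw <- function() paste(vapply(aas, function(aa) {
    cods <- sort(tab$codons[syn[[aa]]])
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
  if (is.null(min_cai)) return(with_local_seed(seed, draw()))
  if (is.null(w)) abort("min_cai requires a CAI weight table",
                        class = "psifold_input_error")
  with_local_seed(seed, {
    for (try in seq_len(max_tries)) {
      sq <- draw()
      if (classical_cai(sq, w) >= min_cai) return(sq)
    }
    abort(paste0("no random coding sequence reached CAI ", min_cai, " in ",
                 max_tries, " draws"), class = "psifold_numerical_error")
  })
}

#' Design an mRNA coding sequence by stability-CAI optimization
#'
#' Adam minimization of [mrna_loss()] over a logits parameterization of
#' Psi, typically warm-started from a known coding sequence. Every iterate
#' is decoded to a discrete coding sequence ([decode_coding()] guarantees
#' the protein) and scored by its discrete ensemble free energy
#' (`-kT log Z` via [partition_discrete()]) and classical CAI; the reported
#' design is the best iterate, selected lexicographically: iterates whose
#' decoded CAI meets `cai_floor` (when set), then lowest decoded EFE, then
#' (among EFE ties within 1e-9, which are iterates decoding to the same
#' sequence) the highest coding probability of Psi. With a warm start whose
#' classical CAI satisfies the floor, the initial iterate is always a
#' candidate, so the reported EFE never exceeds the warm start's; the
#' tie-break favors concentrated late iterates, whose coding probability
#' approaches 1.
#'
#' @param protein target amino-acid string (no stops).
#' @param model an [energy_model()].
#' @param w CAI weight table.
#' @param cai_floor target CAI in \[0, 1\] or `NULL` (unconstrained).
#' @param warm_start_seq optional coding sequence to start from; default
#'   starts at the uniform Psi.
#' @param steps gradient steps (>= 1).
#' @param learning_rate Adam step size.
#' @param seed integer seed (logits jitter symmetry-breaking when starting
#'   uniform).
#' @param lambda_cai,lambda_code loss weights, see [mrna_loss()].
#' @param eps warm-start off-mass.
#' @param scale scaling constant.
#' @return an `mrna_design_result` with the selected `sequence`, its `psi`,
#'   discrete `efe`, classical `cai`, `coding_probability`, the warm-start
#'   reference values, and a per-step trace tibble.
#' @export
design_mrna <- function(protein, model, w, cai_floor = NULL,
                        warm_start_seq = NULL, steps = 300,
                        learning_rate = 0.05, seed = 0,
                        lambda_cai = NULL, lambda_code = NULL,
                        eps = 1e-3, scale = 1) {
  if (steps < 1) abort("steps must be >= 1", class = "psifold_input_error")
  aas <- check_protein(protein)
  n <- 3L * length(aas)
  w <- validate_cai_weights(w)
  psi0 <- if (is.null(warm_start_seq)) psi_uniform(n)
          else warm_start(warm_start_seq, protein, eps = eps)
  logits <- log(pmax(psi0, 1e-12))
  if (is.null(warm_start_seq))
    logits <- logits + with_local_seed(seed, matrix(rnorm(n * 4, sd = 0.01), n, 4))
  state <- adam_init(c(n, 4L))
  rows <- vector("list", steps + 1)
  psis <- vector("list", steps + 1)
  for (t in 0:steps) {
    psi <- softmax_rows(logits)
    ml <- mrna_loss(psi, protein, model, w, cai_floor = cai_floor,
                    lambda_cai = lambda_cai, lambda_code = lambda_code,
                    scale = scale, grad = TRUE)
    if (is.nan(ml$loss))
      abort("objective became NaN during optimization",
            class = "psifold_numerical_error",
            trace_data = dplyr::bind_rows(rows[seq_len(t)]))
    dec <- decode_coding(psi, protein)
    dec_efe <- partition_discrete(dec, model, scale = scale)$efe
    dec_cai <- classical_cai(dec, w)
    g_logits <- softmax_backprop(psi, ml$grad_psi)
    rows[[t + 1]] <- tibble(
      step = t, loss = ml$loss, grad_norm = sqrt(sum(g_logits^2)),
      coding_prob = ml$coding_probability, expected_cai = ml$expected_cai,
      decoded_seq = dec, decoded_efe = dec_efe, decoded_cai = dec_cai)
    psis[[t + 1]] <- psi
    if (t < steps) {
      upd <- adam_step(state, logits, g_logits, learning_rate)
      state <- upd$state
      logits <- upd$par
    }
  }
  trace <- dplyr::bind_rows(rows)
  cai_ok <- if (is.null(cai_floor)) rep(TRUE, nrow(trace))
            else trace$decoded_cai >= cai_floor - 1e-12
  cand <- which(cai_ok)
  if (length(cand) == 0) cand <- seq_len(nrow(trace))
  emin <- min(trace$decoded_efe[cand])
  near <- cand[trace$decoded_efe[cand] <= emin + 1e-9]
  pick <- near[which.max(trace$coding_prob[near])]
  ws_ref <- if (is.null(warm_start_seq)) NULL else list(
    sequence = as_rna(warm_start_seq),
    efe = partition_discrete(warm_start_seq, model, scale = scale)$efe,
    cai = classical_cai(warm_start_seq, w))
  structure(list(
    protein = protein,
    sequence = trace$decoded_seq[pick],
    psi = psis[[pick]],
    efe = trace$decoded_efe[pick],
    cai = trace$decoded_cai[pick],
    coding_probability = trace$coding_prob[pick],
    cai_floor = cai_floor,
    warm_start = ws_ref,
    picked_step = trace$step[pick],
    trace = trace,
    steps = steps, learning_rate = learning_rate, seed = seed
  ), class = "mrna_design_result")
}

#' @export
print.mrna_design_result <- function(x, ...) {
  cat("<mrna_design_result> protein", x$protein, "\n")
  cat("  sequence", x$sequence, "\n")
  cat("  EFE(decoded) =", format(x$efe, digits = 10), "kcal/mol   CAI =",
      format(x$cai, digits = 6), "\n")
  cat("  P(coding | psi) =", format(x$coding_probability, digits = 6),
      "  picked step", x$picked_step, "of", x$steps, "\n")
  if (!is.null(x$warm_start))
    cat("  warm start EFE =", format(x$warm_start$efe, digits = 10),
        " CAI =", format(x$warm_start$cai, digits = 6), "\n")
  invisible(x)
}
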