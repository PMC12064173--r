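#' Free energy of a structure for a discrete sequence
#'
#' Sums the loop free energies of the loop decomposition of `s` given `seq`:
#' hairpins, stacks, internal/bulge loops, affine multiloops and a zero-cost
#' exterior loop. Every paired position must form an allowed pair
#' (AU, UA, CG, GC, GU, UG), otherwise a domain error is raised.
#'
#' @param seq nucleotide string.
#' @param s an [rna_structure()] of matching length.
#' @param model an [energy_model()].
#' @return energy in kcal/mol (possibly `+Inf` for an over-cap loop).
#' @export
#' @examples
#' m <- energy_model()
#' s <- rna_structure(9, cbind(1:3, 9:7))
#' structure_energy("GGGAAACCC", s, m)
structure_energy <- function(seq, s, model) {
  codes <- seq_to_codes(seq)
  if (length(codes) != s$n)
    abort("sequence and structure lengths differ", class = "psifold_input_error")
  loops_energy(codes, decompose_loops(s), model)
}

# evaluate the summed loop energies of a precomputed decomposition
loops_energy <- function(codes, loops, model) {
  pair_of <- function(ij) {
    p <- pair_string(codes[ij[1]], codes[ij[2]])
    check_pair(p)
    p
  }
  total <- 0
  for (loop in loops) {
    total <- total + switch(
      loop$type,
      hairpin = hairpin_energy(model, pair_of(loop$outer), loop$size),
      stack = stack_energy(model, pair_of(loop$outer), pair_of(loop$inner)),
      internal = internal_or_bulge_energy(model, pair_of(loop$outer),
                                          pair_of(loop$inner),
                                          loop$left, loop$right),
      multiloop = {
        for (r in seq_len(nrow(loop$children))) pair_of(loop$children[r, ])
        multiloop_energy(model, loop$branches, loop$unpaired)
      },
      exterior = {
        if (nrow(loop$children) > 0)
          for (r in seq_len(nrow(loop$children))) pair_of(loop$children[r, ])
        0
      }
    )
  }
  total
}

new_fold_result <- function(log_z, model, n, scale, grad_psi = NULL,
                            kind = "expected") {
  structure(list(log_z = log_z,
                 efe = -model$kT * log_z,
                 n = n,
                 scale_log = n * log(scale),
                 grad_psi = grad_psi,
                 kind = kind),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result>", x$kind, " n =", x$n, "\n")
  cat("  log Z =", format(x$log_z, digits = 10),
      "  EFE =", format(x$efe, digits = 10), "kcal/mol\n")
  if (!is.null(x$grad_psi)) cat("  gradient: n x 4 matrix attached\n")
  invisible(x)
}

#' Partition function of a discrete sequence
#'
#' McCaskill's algorithm: `log Z` with
#' `Z = sum over structures of exp(-E(s | seq) / kT)`, the empty structure
#' included with weight 1. Sequences too short for any hairpin give
#' `log Z = 0`.
#'
#' @param seq nucleotide string (T is mapped to U).
#' @param model an [energy_model()].
#' @param scale per-nucleotide scaling constant (> 0); the reported `log_z`
#'   is independent of it.
#' @return a `fold_result` with `log_z` and `efe = -kT * log_z`.
#' @export
#' @examples
#' partition_discrete("GGGGAAACCCC", energy_model())
partition_discrete <- function(seq, model, scale = 1) {
  codes <- seq_to_codes(seq)
  n <- length(codes)
  w <- fold_weights(model, n, scale = scale)
  lz <- .fold_discrete_cpp(codes, w)
  new_fold_result(lz, model, n, scale, kind = "discrete")
}

#' Expected partition function of a sequence distribution
#'
#' Computes `log Z_Psi` with `Z_Psi = E_{pi ~ Psi}[Z_pi]`, the exact
#' expectation over all `4^n` sequences, by a dynamic program whose inside
#' tables condition on the nucleotide identities at interval endpoints.
#' Optionally returns the exact gradient `d log Z_Psi / d Psi` (with respect
#' to the unconstrained matrix entries; Z_Psi is multilinear in the rows of
#' Psi) computed by a reverse-mode adjoint of the dynamic program.
#'
#' `checkpoint_every` controls gradient checkpointing: inside tables are
#' retained only every that-many diagonals and replayed during the backward
#' sweep. Results are identical for every setting; only the memory/time
#' trade-off changes. The default retains every diagonal.
#'
#' @param psi `n x 4` sequence distribution.
#' @param model an [energy_model()].
#' @param scale per-nucleotide scaling constant; pick roughly
#'   `exp(log_z / n)` to keep table entries in floating-point range for long
#'   sequences.
#' @param grad if `TRUE`, also return `d log Z / d Psi`.
#' @param checkpoint_every diagonal checkpoint interval in `1..n`
#'   (`NULL` = retain everything).
#' @param validate check that rows of `psi` lie on the simplex.
#' @param tol row-sum tolerance for validation.
#' @return a `fold_result`; `grad_psi` holds the gradient when requested.
#' @export
#' @examples
#' expected_partition(psi_uniform(8), energy_model())
expected_partition <- function(psi, model, scale = 1, grad = FALSE,
                               checkpoint_every = NULL, validate = TRUE,
                               tol = 1e-9) {
  if (validate) validate_psi(psi, tol = tol)
  n <- nrow(psi)
  k <- as.integer(checkpoint_every %||% n)
  if (k < 1 || k > max(n, 1))
    abort("checkpoint_every must lie in 1..n", class = "psifold_input_error")
  w <- fold_weights(model, n, scale = scale)
  res <- .fold_expected_cpp(psi, w, grad, k)
  new_fold_result(res$log_z, model, n, scale,
                  grad_psi = if (grad) res$grad_psi)
}

# shared tree view of a structure's pairs: parent/children row indices
structure_tree <- function(pairs) {
  np <- nrow(pairs)
  parent <- rep(NA_integer_, np)
  open <- integer(0)
  for (r in seq_len(np)) {
    while (length(open) > 0 && pairs[r, 1] > pairs[open[length(open)], 2])
      open <- open[-length(open)]
    if (length(open) > 0) parent[r] <- open[length(open)]
    open <- c(open, r)
  }
  list(parent = parent,
       children = lapply(seq_len(np), function(r) which(parent == r)),
       top = which(is.na(parent)))
}

#' Expected Boltzmann weight of a fixed structure
#'
#' `E_{pi ~ Psi}[exp(-E(s | pi) / kT)]`, where sequences that cannot form a
#' pair required by `s` contribute zero. Because positions are independent
#' and each loop term sees only the identities of its closing pairs, the
#' expectation factorizes over the structure's loop tree and is computed by
#' bottom-up message passing with 4 x 4 messages per helix.
#'
#' @param psi `n x 4` sequence distribution.
#' @param s an [rna_structure()] on `n` positions.
#' @param model an [energy_model()].
#' @param validate check `psi` rows.
#' @return scalar expected weight (1 for the empty structure).
#' @export
expected_structure_weight <- function(psi, s, model, validate = TRUE) {
  if (validate) validate_psi(psi)
  structure_weight_pass(psi, s, model, grad = FALSE)$value
}

# Up/down message passing over the structure's helix tree.
#
# Up message U_r: 4 x 4 over the closing-pair identities (a, b) of helix r,
# covering r's own loop factor and everything below; strictly-inside
# positions are marginalized under psi. Down message D_r: everything outside
# the subtree of r, as a 4 x 4 coupling to (a, b). For every helix,
#   E[w] = sum_{a,b} psi_i(a) psi_j(b) U_r[a,b] D_r[a,b],
# which yields d E / d psi for all paired rows in a single sweep (E is
# multilinear in the rows of psi; unpaired rows have partials equal to E).
structure_weight_pass <- function(psi, s, model, grad = TRUE) {
  if (nrow(psi) != s$n)
    abort("psi and structure lengths differ", class = "psifold_input_error")
  pairs <- s$pairs
  np <- nrow(pairs)
  n <- s$n
  if (np == 0)
    return(list(value = 1,
                grad_log = if (grad) matrix(0, n, 4)))
  w <- fold_weights(model, n, scale = 1)
  tree <- structure_tree(pairs)
  P16 <- matrix(w$pairable, 4, 4, byrow = TRUE)   # [a, b]
  AU16 <- matrix(w$au, 4, 4, byrow = TRUE)
  WS16 <- matrix(w$ws, 16, 16, byrow = TRUE)      # [ab, cd], row-major vecs

  U <- vector("list", np)
  S <- numeric(np)
  loop_kind <- character(np)
  loop_const <- numeric(np) # internal init weight / multiloop closing factor
  up <- function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    cs <- tree$children[[r]]
    m <- if (length(cs) == 0) {
      loop_kind[r] <<- "hairpin"
      P16 * AU16 * w$wh[j - i]
    } else if (length(cs) == 1) {
      cr <- cs[1]
      up(cr)
      k <- pairs[cr, 1]; l <- pairs[cr, 2]
      weighted <- outer(psi[k, ], psi[l, ]) * U[[cr]]
      if (k == i + 1L && l == j - 1L) {
        loop_kind[r] <<- "stack"
        P16 * matrix(WS16 %*% as.vector(t(weighted)), 4, 4, byrow = TRUE)
      } else {
        sz <- (k - i - 1L) + (j - l - 1L)
        init <- if (sz > w$cap) 0
                else if (k == i + 1L || l == j - 1L) w$wbu[sz + 1]
                else w$win[sz + 1]
        loop_kind[r] <<- "internal"
        loop_const[r] <<- init
        P16 * AU16 * (init * sum(weighted * AU16))
      }
    } else {
      spans <- pairs[cs, , drop = FALSE]
      unpaired <- (j - i - 1L) - sum(spans[, 2] - spans[, 1] + 1L)
      K <- w$wa * w$wbm * w$wcm^unpaired
      loop_kind[r] <<- "multiloop"
      loop_const[r] <<- K
      pb <- 1
      for (cr in cs) { up(cr); pb <- pb * (w$wbm * S[cr]) }
      P16 * (K * pb)
    }
    U[[r]] <<- m
    S[r] <<- sum(outer(psi[i, ], psi[j, ]) * m)
    invisible(NULL)
  }
  for (r in tree$top) up(r)
  value <- prod(S[tree$top])
  if (!grad) return(list(value = value))
  if (value <= 0)
    return(list(value = value, grad_log = NULL))

  D <- vector("list", np)
  for (r in tree$top) D[[r]] <- matrix(value / S[r], 4, 4)
  # rows of positions outside every pair never enter the computation
  # (their simplex normalization is implicit), so their partials vanish --
  # the same convention as the folding DP and its finite-difference oracle
  g <- matrix(0, n, 4)
  # preorder: parents before children (pairs are sorted by opening index)
  for (r in seq_len(np)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    M <- U[[r]] * D[[r]]
    g[i, ] <- as.vector(M %*% psi[j, ])
    g[j, ] <- as.vector(crossprod(M, psi[i, ]))
    cs <- tree$children[[r]]
    if (length(cs) == 0) next
    pp <- outer(psi[i, ], psi[j, ]) * D[[r]] * P16
    if (loop_kind[r] == "stack") {
      D[[cs[1]]] <- matrix(crossprod(WS16, as.vector(t(pp))), 4, 4,
                           byrow = TRUE)
    } else if (loop_kind[r] == "internal") {
      D[[cs[1]]] <- AU16 * (loop_const[r] * sum(pp * AU16))
    } else {
      base <- sum(pp) * loop_const[r] * w$wbm
      for (cr in cs) {
        sib <- 1
        for (cq in cs) if (cq != cr) sib <- sib * (w$wbm * S[cq])
        D[[cr]] <- matrix(base * sib, 4, 4)
      }
    }
  }
  list(value = value, grad_log = g / value)
}

#' Probability-like score of folding into a target structure
#'
#' The ratio of expectations
#' `E[exp(-E(s | pi) / kT)] / E[Z_pi]`, a single scalar in `[0, 1]`. For a
#' one-hot Psi this is exactly the Boltzmann probability of `s` for that
#' discrete sequence.
#'
#' @inheritParams expected_structure_weight
#' @param scale scaling constant passed to [expected_partition()].
#' @return scalar in `[0, 1]`.
#' @export
target_structure_probability <- function(psi, s, model, scale = 1,
                                         validate = TRUE) {
  if (validate) validate_psi(psi)
  num <- expected_structure_weight(psi, s, model, validate = FALSE)
  if (num <= 0) return(0)
  lz <- expected_partition(psi, model, scale = scale, validate = FALSE)$log_z
  exp(log(num) - lz)
}

# gradient of log E[exp(-beta E(s|pi))] w.r.t. psi entries (see
# structure_weight_pass; E is multilinear in the rows of psi)
structure_weight_log_gradient <- function(psi, s, model) {
  pass <- structure_weight_pass(psi, s, model, grad = TRUE)
  if (is.null(pass$grad_log))
    abort("structure weight is zero; gradient undefined",
          class = "psifold_numerical_error")
  pass$grad_log
}

#' Gradient of a folding objective with respect to Psi
#'
#' Exact gradients of scalar objectives of the expected partition function,
#' with respect to every entry of `psi` treated as unconstrained (the
#' caller's logits parameterization handles the simplex). Objectives:
#' `"log_expected_partition"` is `log Z_Psi`;
#' `"target_structure_probability"` is the ratio score of
#' [target_structure_probability()] (requires `target`); `"composite"` is the
#' structure-design loss `-log` of that score.
#'
#' @inheritParams expected_partition
#' @param objective one of `"log_expected_partition"`,
#'   `"target_structure_probability"`, `"composite"`.
#' @param target an [rna_structure()] for the structure-aware objectives.
#' @return `n x 4` gradient matrix.
#' @export
fold_gradient <- function(psi, model,
                          objective = c("log_expected_partition",
                                        "target_structure_probability",
                                        "composite"),
                          target = NULL, scale = 1, checkpoint_every = NULL,
                          validate = TRUE) {
  objective <- match.arg(objective)
  if (validate) validate_psi(psi)
  gz <- expected_partition(psi, model, scale = scale, grad = TRUE,
                           checkpoint_every = checkpoint_every,
                           validate = FALSE)$grad_psi
  if (objective == "log_expected_partition") return(gz)
  if (is.null(target))
    abort("objective requires a target structure", class = "psifold_input_error")
  gw <- structure_weight_log_gradient(psi, target, model)
  if (objective == "composite") return(gz - gw)
  p <- target_structure_probability(psi, target, model, scale = scale,
                                    validate = FALSE)
  p * (gw - gz)
}

#' Fold a set of discrete sequences into a tidy table
#'
#' Vectorized convenience wrapper around [partition_discrete()].
#'
#' @param seqs character vector of sequences (names become ids) or a
#'   `Biostrings::XStringSet`.
#' @param model an [energy_model()].
#' @param scale per-nucleotide scaling constant.
#' @return a tibble with columns `id`, `length`, `log_z`, `efe`.
#' @export
#' @examples
#' fold_sequences(c(a = "AAAA", b = "GGGGAAACCCC"), energy_model())
fold_sequences <- function(seqs, model, scale = 1) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  ids[!nzchar(ids)] <- as.character(which(!nzchar(ids)))
  purrr::map2_dfr(unname(seqs), ids, function(s, id) {
    fr <- partition_discrete(s, model, scale = scale)
    tibble(id = id, length = fr$n, log_z = fr$log_z, efe = fr$efe)
  })
}
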