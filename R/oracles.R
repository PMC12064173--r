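#' Enumerate all secondary structures
#'
#' Every non-crossing pair set on `n` positions whose hairpin loops enclose
#' at least `theta` unpaired positions, each exactly once, including the
#' empty structure. Enumeration recurses on the last position (unpaired, or
#' paired with some k), mirroring the counting recurrence
#' `f(m) = f(m-1) + sum_k f(k-1) f(m-k-1)`, which guarantees completeness.
#' Feasible up to n of about 14.
#'
#' @param n sequence length (>= 0).
#' @param theta minimum hairpin loop size.
#' @return list of two-column pair matrices (1-based indices).
#' @export
#' @examples
#' length(enumerate_structures(7))  # 8
enumerate_structures <- function(n, theta = 3L) {
  memo <- vector("list", n + 1)
  gen <- function(m) {
    if (m >= 0 && !is.null(memo[[m + 1]])) return(memo[[m + 1]])
    if (m <= theta + 1) {
      out <- list(matrix(integer(0), ncol = 2))
    } else {
      out <- gen(m - 1) # position m unpaired
      for (k in seq_len(m - theta - 1)) { # pair (k, m)
        left <- gen(k - 1)
        inner <- gen(m - k - 1)
        for (L in left) for (Iv in inner) {
          shifted <- if (nrow(Iv) > 0) Iv + k else Iv
          out[[length(out) + 1]] <-
            rbind(L, shifted, c(k, m))
        }
      }
    }
    memo[[m + 1]] <<- out
    out
  }
  gen(n)
}

#' Count secondary structures by the standard recurrence
#'
#' Independent of [enumerate_structures()]:
#' `f(m) = f(m-1) + sum over admissible k of f(k-1) * f(m-k-1)`.
#'
#' @inheritParams enumerate_structures
#' @return number of structures.
#' @export
count_structures <- function(n, theta = 3L) {
  f <- numeric(n + 1)
  f[seq_len(min(theta + 2, n + 1))] <- 1 # f(0..theta+1) = 1
  if (n >= theta + 2) {
    for (m in (theta + 2):n) {
      total <- f[m] # m unpaired (f index is value+1)
      for (k in seq_len(m - theta - 1))
        total <- total + f[k] * f[m - k]
      f[m + 1] <- total
    }
  }
  f[n + 1]
}

#' Brute-force partition function of a discrete sequence
#'
#' Enumerates all structures and sums Boltzmann weights, skipping structures
#' demanding a disallowed pair. The test bedrock for the dynamic program;
#' feasible up to n of about 14.
#'
#' @param seq nucleotide string.
#' @param model an [energy_model()].
#' @return `log Z`.
#' @export
brute_partition <- function(seq, model) {
  codes <- seq_to_codes(seq)
  n <- length(codes)
  z <- 0
  for (pairs in enumerate_structures(n, model$theta)) {
    if (nrow(pairs) > 0) {
      ok <- all(apply(pairs, 1, function(ij)
        is_allowed_pair(pair_string(codes[ij[1]], codes[ij[2]]))))
      if (!ok) next
    }
    s <- rna_structure(n, pairs, min_hairpin = model$theta)
    e <- structure_energy(seq, s, model)
    z <- z + exp(-e / model$kT)
  }
  log(z)
}

#' Brute-force expected partition function
#'
#' `log sum over all 4^n sequences of P(pi | Psi) * Z_pi`, with
#' `P(pi | Psi) = prod_i psi_i(pi_i)` and each `Z_pi` summed over the full
#' structure enumeration. The oracle for [expected_partition()]; feasible up
#' to n of about 8.
#'
#' @param psi `n x 4` sequence distribution.
#' @param model an [energy_model()].
#' @return `log Z_Psi`.
#' @export
brute_expected_partition <- function(psi, model) {
  n <- nrow(psi)
  pre <- lapply(enumerate_structures(n, model$theta), function(p) {
    s <- rna_structure(n, p, min_hairpin = model$theta)
    list(pairs = p, loops = decompose_loops(s))
  })
  # all sequences as a 4^n x n matrix of codes
  grid <- as.matrix(expand.grid(rep(list(0:3), n)))
  ztot <- 0
  for (r in seq_len(nrow(grid))) {
    codes <- grid[r, ]
    pprob <- prod(psi[cbind(seq_len(n), codes + 1L)])
    if (pprob == 0) next
    z <- 0
    for (s in pre) {
      if (nrow(s$pairs) > 0) {
        ok <- all(apply(s$pairs, 1, function(ij)
          is_allowed_pair(pair_string(codes[ij[1]], codes[ij[2]]))))
        if (!ok) next
      }
      z <- z + exp(-loops_energy(codes, s$loops, model) / model$kT)
    }
    ztot <- ztot + pprob * z
  }
  log(ztot)
}

#' Central finite-difference gradient
#'
#' Entrywise central differences of a scalar function of an `n x 4` matrix,
#' treating every entry as unconstrained.
#'
#' @param f function taking a matrix and returning a scalar.
#' @param psi base point.
#' @param h step size.
#' @return matrix of the same shape as `psi`.
#' @export
finite_difference_gradient <- function(f, psi, h = 1e-5) {
  g <- matrix(0, nrow(psi), ncol(psi))
  for (i in seq_len(nrow(psi))) for (a in seq_len(ncol(psi))) {
    up <- psi; up[i, a] <- up[i, a] + h
    dn <- psi; dn[i, a] <- dn[i, a] - h
    g[i, a] <- (f(up) - f(dn)) / (2 * h)
  }
  g
}

#' Deterministic synthetic fixtures
#'
#' Reproducible inputs for tests and examples. Kinds:
#' `"random_sequence"` (a uniform random n-mer), `"random_distribution"`
#' (row-normalized uniform draws), `"near_one_hot"` (a random sequence
#' embedded with `eps = 1e-3` off-mass), and `"hairpin_target"` (a
#' single-stem hairpin structure with stem length `floor((n - 3) / 2)`).
#' The same `(kind, n, seed)` always yields the same output.
#'
#' @param kind fixture kind.
#' @param n length.
#' @param seed integer seed.
#' @return a string, an `n x 4` matrix, or (for `hairpin_target`) a list
#'   with the Psi start and the target [rna_structure()].
#' @export
#' @examples
#' make_fixture("random_sequence", 10, seed = 1)
make_fixture <- function(kind = c("random_sequence", "random_distribution",
                                  "near_one_hot", "hairpin_target"),
                         n, seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    random_sequence = with_local_seed(seed,
      paste(sample(NUCS, n, replace = TRUE), collapse = "")),
    random_distribution = with_local_seed(seed, {
      m <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, NUCS))
      m / rowSums(m)
    }),
    near_one_hot = psi_near_one_hot(
      with_local_seed(seed, paste(sample(NUCS, n, replace = TRUE), collapse = "")),
      eps = 1e-3),
    hairpin_target = list(psi = psi_uniform(n), target = hairpin_target(n))
  )
}
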