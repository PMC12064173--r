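#' Sequence distributions
#'
#' A sequence distribution Psi is an `n x 4` row-stochastic matrix: row `i`
#' is the categorical distribution of the nucleotide at position `i` over
#' the ordered alphabet A, C, G, U. Positions are independent, so Psi is a
#' product of categoricals; a one-hot Psi is a discrete sequence.
#'
#' `psi_uniform()` gives the maximum-entropy distribution, `psi_one_hot()`
#' embeds a discrete sequence, and `psi_near_one_hot()` places `1 - 3 * eps`
#' on the sequence nucleotide and `eps` elsewhere (keeping gradients finite
#' at the simplex boundary).
#'
#' @param n sequence length.
#' @param seq a nucleotide string (T accepted, mapped to U).
#' @param eps off-sequence mass per nucleotide.
#' @return an `n x 4` numeric matrix with columns A, C, G, U.
#' @export
#' @examples
#' psi_one_hot("GGAA")
psi_uniform <- function(n) {
  matrix(0.25, nrow = n, ncol = 4, dimnames = list(NULL, NUCS))
}

#' @rdname psi_uniform
#' @export
psi_one_hot <- function(seq) {
  codes <- seq_to_codes(seq)
  psi <- matrix(0, nrow = length(codes), ncol = 4, dimnames = list(NULL, NUCS))
  psi[cbind(seq_along(codes), codes + 1L)] <- 1
  psi
}

#' @rdname psi_uniform
#' @export
psi_near_one_hot <- function(seq, eps = 1e-3) {
  codes <- seq_to_codes(seq)
  psi <- matrix(eps, nrow = length(codes), ncol = 4,
                dimnames = list(NULL, NUCS))
  psi[cbind(seq_along(codes), codes + 1L)] <- 1 - 3 * eps
  psi
}

#' Validate a sequence distribution
#'
#' Checks that `psi` is an `n x 4` numeric matrix with nonnegative entries
#' whose rows sum to 1 within `tol`.
#'
#' @param psi matrix to check.
#' @param tol tolerance on row sums.
#' @return `psi`, invisibly, with columns named A C G U.
#' @export
validate_psi <- function(psi, tol = 1e-9) {
  if (!is.matrix(psi) || ncol(psi) != 4 || !is.numeric(psi))
    abort("psi must be a numeric n x 4 matrix", class = "psifold_input_error")
  if (nrow(psi) < 1) abort("psi needs at least one row",
                           class = "psifold_input_error")
  if (any(psi < 0))
    abort("psi entries must be nonnegative", class = "psifold_input_error")
  rs <- rowSums(psi)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0)
    abort(paste0("psi row ", bad[1], " sums to ", format(rs[bad[1]]),
                 ", not 1"), class = "psifold_input_error")
  colnames(psi) <- NUCS
  invisible(psi)
}

#' Decode a sequence distribution to a discrete sequence
#'
#' Per-position argmax; ties break toward the first nucleotide in the fixed
#' alphabet order A < C < G < U (so the uniform distribution decodes to
#' poly-A).
#'
#' @param psi an `n x 4` sequence distribution.
#' @return a nucleotide string.
#' @export
#' @examples
#' decode_psi(psi_uniform(3))
decode_psi <- function(psi) {
  codes_to_seq(apply(psi, 1, which.max) - 1L)
}

#' Read and write Psi tables
#'
#' Psi is serialized as TSV with one row per position and four probability
#' columns headed `A C G U`.
#'
#' @param path file path.
#' @param psi matrix to write.
#' @param tol row-sum tolerance applied on read.
#' @return `read_psi` returns the validated matrix; `write_psi` returns
#'   `path` invisibly.
#' @export
read_psi <- function(path, tol = 1e-9) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()))
  if (!identical(names(df), NUCS))
    abort("psi TSV must have exactly the columns A, C, G, U",
          class = "psifold_input_error")
  psi <- as.matrix(df)
  validate_psi(psi, tol = tol)
  psi
}

#' @rdname read_psi
#' @export
write_psi <- function(psi, path) {
  validate_psi(psi)
  df <- as.data.frame(psi)
  names(df) <- NUCS
  readr::write_tsv(df, path)
  invisible(path)
}
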