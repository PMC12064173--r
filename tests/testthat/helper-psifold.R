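# shared fixtures and comparison helpers

toy_model <- function(...) energy_model(...)

# relative error with a floor protecting near-zero references
rel_err <- function(x, ref, floor = .Machine$double.eps) {
  max(abs(x - ref) / pmax(abs(ref), floor))
}

# brute-force E[exp(-E(s|pi)/kT)] by enumerating identities of the paired
# positions only (unpaired positions marginalize to 1); independent of the
# message-passing implementation
brute_structure_weight <- function(psi, s, model) {
  pos <- as.vector(t(s$pairs))
  if (length(pos) == 0) return(1)
  grid <- as.matrix(expand.grid(rep(list(0:3), length(pos))))
  loops <- psifold:::decompose_loops(s)
  total <- 0
  for (r in seq_len(nrow(grid))) {
    codes <- integer(s$n) # identities of unpaired positions are irrelevant
    codes[pos] <- grid[r, ]
    p <- prod(psi[cbind(pos, grid[r, ] + 1L)])
    if (p == 0) next
    ok <- all(apply(s$pairs, 1, function(ij)
      psifold:::is_allowed_pair(
        psifold:::pair_string(codes[ij[1]], codes[ij[2]]))))
    if (!ok) next
    e <- psifold:::loops_energy(codes, loops, model)
    total <- total + p * exp(-e / model$kT)
  }
  total
}

# Boltzmann probability of a structure for a discrete sequence, via the
# enumeration oracle rather than the DP
brute_target_probability <- function(seq, s, model) {
  e <- structure_energy(seq, s, model)
  exp(-e / model$kT - brute_partition(seq, model))
}
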