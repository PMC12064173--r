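test_that("degenerate distributions reproduce the discrete partition", {
  m <- toy_model()
  for (sq in c("GGGAAAACCC", "ACGUACGUACGUACGU",
               make_fixture("random_sequence", 40, seed = 2),
               make_fixture("random_sequence", 60, seed = 3))) {
    expect_equal(expected_partition(psi_one_hot(sq), m)$log_z,
                 partition_discrete(sq, m)$log_z,
                 tolerance = 1e-10, info = sq)
  }
})

test_that("too-short distributions give log Z = 0, not an error", {
  m <- toy_model()
  expect_equal(expected_partition(psi_uniform(4), m)$log_z, 0)
  expect_equal(expected_partition(psi_uniform(1), m)$log_z, 0)
})

test_that("the expected DP equals the 4^n brute-force weighted sum", {
  m <- toy_model()
  psi7 <- make_fixture("random_distribution", 7, seed = 7)
  expect_equal(expected_partition(psi7, m)$log_z,
               brute_expected_partition(psi7, m), tolerance = 1e-9)
  psi6 <- make_fixture("random_distribution", 6, seed = 1)
  expect_equal(expected_partition(psi6, m)$log_z,
               brute_expected_partition(psi6, m), tolerance = 1e-9)
  # uniform distribution: the weighted sum is the plain average
  expect_equal(expected_partition(psi_uniform(6), m)$log_z,
               brute_expected_partition(psi_uniform(6), m), tolerance = 1e-9)
})

test_that("Z_Psi is affine in each row of Psi", {
  m <- toy_model()
  zval <- function(psi) exp(expected_partition(psi, m, validate = FALSE)$log_z)
  for (trial in 1:6) {
    psi <- make_fixture("random_distribution", 9, seed = 100 + trial)
    i <- 1 + (trial %% 9)
    u <- as.vector(make_fixture("random_distribution", 1, seed = 200 + trial))
    v <- as.vector(make_fixture("random_distribution", 1, seed = 300 + trial))
    lam <- 0.3 + 0.05 * trial
    at <- function(row) { p <- psi; p[i, ] <- row; zval(p) }
    expect_equal(at(lam * u + (1 - lam) * v),
                 lam * at(u) + (1 - lam) * at(v),
                 tolerance = 1e-9)
  }
})

test_that("ensemble free energy is nonpositive and finite", {
  m <- toy_model()
  for (seed in 1:5) {
    fr <- expected_partition(make_fixture("random_distribution", 25,
                                          seed = seed), m)
    expect_true(is.finite(fr$efe))
    expect_lte(fr$efe, 0) # the empty structure contributes weight 1
    expect_gte(fr$log_z, 0)
  }
})

test_that("expected structure weight matches enumeration over paired sites", {
  m <- toy_model()
  psi <- make_fixture("random_distribution", 9, seed = 5)
  s <- rna_structure(9, cbind(1:3, 9:7))
  expect_equal(expected_structure_weight(psi, s, m),
               brute_structure_weight(psi, s, m), tolerance = 1e-10)
  # empty structure: exterior loop costs nothing
  expect_equal(expected_structure_weight(psi, rna_structure(9), m), 1)
  # one-hot distribution: plain Boltzmann weight
  sq <- "GGGAAACCC"
  expect_equal(expected_structure_weight(psi_one_hot(sq), s, m),
               exp(-structure_energy(sq, s, m) / m$kT), tolerance = 1e-12)
  # structure with an internal loop and a bulge
  s2 <- rna_structure(12, rbind(c(1, 12), c(3, 10)))
  psi2 <- make_fixture("random_distribution", 12, seed = 6)
  expect_equal(expected_structure_weight(psi2, s2, m),
               brute_structure_weight(psi2, s2, m), tolerance = 1e-10)
})

test_that("target probability is a ratio of expectations in [0, 1]", {
  m <- toy_model()
  expect_equal(target_structure_probability(psi_one_hot("AAAA"),
                                            rna_structure(4), m), 1)
  # one-hot case equals the discrete Boltzmann probability from the oracle
  s <- parse_dotbracket("(((....)))")
  expect_equal(
    target_structure_probability(psi_one_hot("GGGAAAACCC"), s, m),
    brute_target_probability("GGGAAAACCC", s, m), tolerance = 1e-10)
  for (seed in 1:5) {
    psi <- make_fixture("random_distribution", 10, seed = seed)
    p <- target_structure_probability(psi, hairpin_target(10), m)
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("distributions off the simplex are rejected with the row named", {
  m <- toy_model()
  bad <- psi_uniform(6)
  bad[3, ] <- c(0.3, 0.3, 0.2, 0.1)
  expect_error(expected_partition(bad, m), regexp = "row 3",
               class = "psifold_input_error")
  neg <- psi_uniform(6)
  neg[2, ] <- c(-0.1, 0.5, 0.3, 0.3)
  expect_error(expected_partition(neg, m), class = "psifold_input_error")
})

test_that("psi TSV round-trips through read/write", {
  psi <- make_fixture("random_distribution", 8, seed = 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psi(psi, f)
  expect_equal(unname(read_psi(f)), unname(psi), tolerance = 1e-12)
})
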