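test_that("codon marginals are products of position marginals", {
  tab <- psifold:::codon_table()
  # one-hot: indicator of the encoded codon
  p <- codon_marginal(psi_one_hot("AUGGCU"), 1)
  expect_equal(unname(p["AUG"]), 1)
  expect_equal(sum(p), 1)
  p2 <- codon_marginal(psi_one_hot("AUGGCU"), 2)
  expect_equal(unname(p2["GCU"]), 1)
  # uniform: 1/64 each
  expect_equal(unname(codon_marginal(psi_uniform(3), 1)),
               rep(1 / 64, 64))
  # half A / half G at the first position concentrates on AUG and GUG
  psi <- psi_one_hot("AUG")
  psi[1, ] <- c(0.5, 0, 0.5, 0)
  p3 <- codon_marginal(psi, 1)
  expect_equal(unname(p3[c("AUG", "GUG")]), c(0.5, 0.5))
  expect_equal(sum(p3), 1)
})

test_that("coding probability multiplies per-codon synonymous masses", {
  expect_equal(coding_probability(psi_uniform(3), "M"), 1 / 64)
  expect_equal(coding_probability(psi_uniform(6), "ML"), (1 / 64) * (6 / 64))
  sq <- "AUGCUGAAA" # M L K
  expect_equal(coding_probability(psi_one_hot(sq), "MLK"), 1)
  expect_error(coding_probability(psi_uniform(6), "M"),
               class = "psifold_input_error") # length mismatch
  expect_error(coding_probability(psi_uniform(3), "M*"),
               class = "psifold_input_error")
})

test_that("expected CAI reduces to the classical CAI at one-hot inputs", {
  w <- toy_cai_weights()
  for (seed in 1:20) {
    sq <- random_coding_sequence("MDKLVRS", seed = seed)
    expect_equal(expected_cai(psi_one_hot(sq), "MDKLVRS", w),
                 classical_cai(sq, w), tolerance = 1e-12, info = sq)
  }
  # all weights 1: expected CAI is 1 for any coding-supported distribution
  w1 <- setNames(rep(1, length(w)), names(w))
  expect_equal(expected_cai(make_fixture("random_distribution", 6, seed = 2),
                            "ML", w1), 1)
})

test_that("expected CAI equals the conditional enumeration for L = 2", {
  w <- toy_cai_weights()
  tab <- psifold:::codon_table()
  protein <- "LS" # 6 x 6 synonymous codons
  psi <- make_fixture("random_distribution", 6, seed = 9)
  # brute force: expectation of prod w^(1/L) over coding sequences,
  # conditioned on coding
  syn1 <- tab$codons[tab$code == "L"]
  syn2 <- tab$codons[tab$code == "S"]
  num <- 0; den <- 0
  for (c1 in syn1) for (c2 in syn2) {
    p <- unname(codon_marginal(psi, 1)[c1] * codon_marginal(psi, 2)[c2])
    num <- num + p * sqrt(w[c1] * w[c2])
    den <- den + p
  }
  expect_equal(expected_cai(psi, protein, w), unname(num / den),
               tolerance = 1e-10)
})

test_that("CAI weight tables are validated and derivable from usage", {
  w <- toy_cai_weights()
  expect_identical(length(w), 61L)
  expect_true(all(w > 0 & w <= 1))
  # every amino acid has a weight-1 codon
  tab <- psifold:::codon_table()
  for (aa in setdiff(unique(tab$code), "*"))
    expect_equal(max(w[tab$codons[tab$code == aa & tab$codons %in% names(w)]]), 1)
  bad <- w; bad["AAA"] <- 1.2
  expect_error(validate_cai_weights(bad), class = "psifold_input_error")
  bad2 <- w[-1]
  expect_error(validate_cai_weights(bad2), class = "psifold_input_error")
  # usage counts: ratio to the most-used synonymous codon
  counts <- setNames(rep(1, 61), names(w))
  counts["AAA"] <- 3; counts["AAG"] <- 1
  wu <- cai_weights_from_usage(counts)
  expect_equal(unname(wu["AAG"]), 1 / 3)
  expect_equal(unname(wu["AAA"]), 1)
  # file round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cai_weights(w, f)
  expect_equal(read_cai_weights(f), w, tolerance = 1e-12)
  shipped <- read_cai_weights(system.file("extdata", "cai_weights_toy.tsv",
                                          package = "psifold"))
  expect_equal(shipped, w)
})

test_that("decode_coding always translates to the target protein", {
  expect_identical(decode_coding(psi_one_hot("AUGCUGAAA"), "MLK"), "AUGCUGAAA")
  expect_identical(decode_coding(psi_uniform(3), "M"), "AUG")
  # uniform ties break to the lexicographically smallest synonymous codon
  expect_identical(decode_coding(psi_uniform(3), "L"), "CUA")
  for (seed in 1:10) {
    set.seed(seed)
    protein <- paste(sample(c("M", "L", "S", "K", "V", "R", "G", "W"),
                            4, replace = TRUE), collapse = "")
    psi <- make_fixture("random_distribution", 12, seed = seed)
    expect_identical(translate_rna(decode_coding(psi, protein)), protein)
  }
})

test_that("warm starts embed coding sequences and reject others", {
  sq <- "AUGCUGAAA"
  psi <- warm_start(sq, "MLK")
  expect_identical(decode_psi(psi), sq)
  expect_equal(max(psi), 1 - 3e-3)
  expect_error(warm_start("AUGCUGAAG", "MLL"), class = "psifold_input_error")
  expect_warning(oh <- warm_start(sq, "MLK", eps = 0))
  expect_identical(unname(oh), unname(psi_one_hot(sq)))
})

test_that("the mRNA loss reduces to the EFE at satisfied one-hot starts", {
  m <- toy_model()
  w <- toy_cai_weights()
  sq <- random_coding_sequence("MKV", seed = 1)
  psi <- psi_one_hot(sq)
  efe <- partition_discrete(sq, m)$efe
  # no floor: penalty terms vanish exactly (log 1 = 0)
  ml <- mrna_loss(psi, "MKV", m, w)
  expect_equal(ml$loss, efe, tolerance = 1e-9)
  expect_equal(ml$coding_probability, 1)
  # floor below the sequence CAI: hinge stays off
  ml2 <- mrna_loss(psi, "MKV", m, w, cai_floor = classical_cai(sq, w) - 0.01)
  expect_equal(ml2$loss, efe, tolerance = 1e-9)
  # zero weights: pure expected-EFE objective
  psir <- make_fixture("random_distribution", 9, seed = 3)
  ml3 <- mrna_loss(psir, "MKV", m, w, lambda_cai = 0, lambda_code = 0,
                   cai_floor = 0.99)
  expect_equal(ml3$loss, ml3$efe)
})

test_that("mRNA loss gradients match finite differences", {
  m <- toy_model()
  w <- toy_cai_weights()
  protein <- "MKL"
  psi <- make_fixture("random_distribution", 9, seed = 4)
  for (fl in list(NULL, 0.95)) { # hinge off and on
    ml <- mrna_loss(psi, protein, m, w, cai_floor = fl, grad = TRUE)
    fd <- finite_difference_gradient(function(p)
      mrna_loss(p, protein, m, w, cai_floor = fl)$loss, psi)
    expect_lt(rel_err(ml$grad_psi, fd, floor = 1e-6), 1e-4)
  }
})

test_that("warm-started design never worsens the decoded free energy", {
  m <- toy_model()
  w <- toy_cai_weights()
  protein <- "MKLV"
  warm <- random_coding_sequence(protein, seed = 5)
  res <- design_mrna(protein, m, w, warm_start_seq = warm, steps = 60,
                     seed = 1)
  expect_lte(res$efe, res$warm_start$efe + 1e-9)
  expect_identical(translate_rna(res$sequence), protein)
  expect_identical(nrow(res$trace), 61L)
  # determinism
  res2 <- design_mrna(protein, m, w, warm_start_seq = warm, steps = 60,
                      seed = 1)
  expect_identical(res$trace, res2$trace)
  expect_s3_class(glance(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
})
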