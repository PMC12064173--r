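test_that("the design loss is a nonnegative log-probability", {
  m <- toy_model()
  expect_equal(structure_design_loss(psi_one_hot("AAAA"), rna_structure(4), m), 0)
  s <- parse_dotbracket("(((....)))")
  expect_equal(structure_design_loss(psi_one_hot("GGGAAAACCC"), s, m),
               -log(brute_target_probability("GGGAAAACCC", s, m)),
               tolerance = 1e-10)
  for (seed in 1:5) {
    psi <- make_fixture("random_distribution", 10, seed = seed)
    expect_gte(structure_design_loss(psi, hairpin_target(10), m), 0)
  }
})

test_that("decode takes the per-position argmax with alphabet-order ties", {
  expect_identical(decode_psi(psi_one_hot("GAUC")), "GAUC")
  expect_identical(decode_psi(psi_uniform(5)), "AAAAA")
  psi <- rbind(c(0.1, 0.2, 0.6, 0.1), c(0.25, 0.25, 0.25, 0.25),
               c(0.4, 0.1, 0.1, 0.4))
  expect_identical(decode_psi(psi), "GAA")
})

test_that("the generator network is deterministic and reduces to logits", {
  net <- generator_network(6, seed = 1)
  expect_identical(generator_forward(net), generator_forward(net))
  net2 <- generator_network(6, seed = 1)
  expect_identical(generator_forward(net), generator_forward(net2))

  # zero weights and offsets emit the uniform distribution
  net0 <- generator_network(6, seed = 2)
  net0$layers <- lapply(net0$layers, function(l)
    list(W = l$W * 0, b = l$b * 0))
  expect_equal(generator_forward(net0), psi_uniform(6), ignore_attr = TRUE)

  # a single linear layer with zero weights and the logits in its offset is
  # exactly the direct parameterization
  logits <- matrix(rnorm(24), 6, 4)
  lin <- generator_network(6, input_dim = 3, hidden = integer(0), seed = 0)
  lin$layers[[1]]$W[] <- 0
  lin$layers[[1]]$b <- as.vector(t(logits))
  expect_equal(generator_forward(lin), psifold:::softmax_rows(logits),
               tolerance = 1e-12, ignore_attr = TRUE)
  m <- toy_model()
  tgt <- hairpin_target(6)
  expect_equal(structure_design_loss(generator_forward(lin), tgt, m),
               structure_design_loss(psifold:::softmax_rows(logits), tgt, m),
               tolerance = 1e-12)
})

test_that("optimization is deterministic and validates its inputs", {
  m <- toy_model()
  tgt <- hairpin_target(8)
  a <- optimize_direct(tgt, m, steps = 10, seed = 3)
  b <- optimize_direct(tgt, m, steps = 10, seed = 3)
  expect_identical(a$trace, b$trace)
  expect_identical(a$psi, b$psi)
  expect_identical(nrow(a$trace), 11L)
  g1 <- optimize_generator(tgt, m, steps = 5, seed = 3)
  g2 <- optimize_generator(tgt, m, steps = 5, seed = 3)
  expect_identical(g1$trace, g2$trace)
  expect_gt(g1$param_count, 8 * 4) # overparameterized
  expect_error(optimize_direct(tgt, m, steps = 0),
               class = "psifold_input_error")
})

test_that("the best iterate improves monotonically with the step budget", {
  m <- toy_model()
  tgt <- hairpin_target(9)
  short <- optimize_direct(tgt, m, steps = 20, seed = 1)
  long <- optimize_direct(tgt, m, steps = 40, seed = 1)
  # identical seed: the longer run revisits the short run's iterates first
  expect_identical(short$trace$loss, long$trace$loss[1:21])
  expect_lte(long$best_loss, short$best_loss)
})

test_that("both paths drive the empty-structure loss to zero", {
  m <- toy_model()
  empty <- rna_structure(8)
  rd <- optimize_direct(empty, m, steps = 200, seed = 0)
  expect_lt(rd$best_loss, 1e-3)
  rg <- optimize_generator(empty, m, steps = 200, seed = 0)
  expect_lt(rg$best_loss, 1e-3)
  # decoded sequences admit (essentially) no structure
  expect_equal(partition_discrete(rd$sequence, m)$log_z, 0, tolerance = 1e-3)
})

test_that("reported probabilities come from the decoded discrete sequence", {
  m <- toy_model()
  res <- optimize_direct(hairpin_target(9), m, steps = 60, seed = 2)
  expect_equal(res$probability,
               brute_target_probability(res$sequence, res$target, m),
               tolerance = 1e-9)
  tt <- tidy(res)
  expect_s3_class(tt, "tbl_df")
  expect_identical(names(tt), c("step", "loss", "grad_norm"))
  gl <- glance(res)
  expect_identical(gl$sequence, res$sequence)
  expect_s3_class(autoplot(res), "ggplot")
})
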