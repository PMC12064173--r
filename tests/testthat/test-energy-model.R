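test_that("hairpin energies combine initiation and the terminal penalty", {
  m <- toy_model()
  expect_equal(hairpin_energy(m, "GC", 3), 5.4)
  expect_equal(hairpin_energy(m, "CG", 3), 5.4)
  expect_equal(hairpin_energy(m, "AU", 3), 5.9)
  expect_equal(hairpin_energy(m, "GU", 4), 5.6 + 0.5)
  expect_error(hairpin_energy(m, "GC", 2), class = "psifold_domain_error")
  expect_error(hairpin_energy(m, "AA", 3), class = "psifold_domain_error")
  # Jacobson-Stockmayer tail beyond the tabulated sizes
  expect_equal(hairpin_energy(m, "GC", 18), 6.4 + 1.75 * m$kT * log(18 / 9))
})

test_that("stack energies are direct table lookups on allowed pairs", {
  m <- toy_model()
  expect_equal(stack_energy(m, "GC", "GC"), -3.3)
  expect_equal(stack_energy(m, "AU", "UA"), -1.1)
  expect_equal(stack_energy(m, "GU", "CG"), -0.35 - 1.65)
  expect_error(stack_energy(m, "GC", "AA"), class = "psifold_domain_error")
  # thermodynamic symmetry of the shipped table: rotating the stack by 180
  # degrees reads the same two pairs in the other order and orientation
  for (p in c("AU", "CG", "GU")) for (q in c("GC", "UA", "UG")) {
    rev_p <- paste0(substr(p, 2, 2), substr(p, 1, 1))
    rev_q <- paste0(substr(q, 2, 2), substr(q, 1, 1))
    expect_equal(stack_energy(m, p, q), stack_energy(m, rev_q, rev_p))
  }
})

test_that("internal and bulge loops add size initiation and both penalties", {
  m <- toy_model()
  expect_equal(internal_or_bulge_energy(m, "GC", "GC", 1, 0), 3.8)
  expect_equal(internal_or_bulge_energy(m, "GC", "GC", 2, 2), 1.7)
  expect_equal(internal_or_bulge_energy(m, "AU", "GU", 1, 1), 1.5 + 0.5 + 0.5)
  expect_identical(internal_or_bulge_energy(m, "GC", "GC", 31, 0), Inf)
  expect_error(internal_or_bulge_energy(m, "GC", "GC", 0, 0),
               class = "psifold_domain_error")
})

test_that("multiloop energy is affine in branches and unpaired count", {
  m <- toy_model()
  expect_equal(multiloop_energy(m, 3, 0), 4.6)
  expect_equal(multiloop_energy(m, 3, 5), 4.6) # default c = 0
  m2 <- toy_model(multi = c(3.4, 0.4, 0.1))
  expect_equal(multiloop_energy(m2, 4, 2), 5.2)
  expect_error(multiloop_energy(m, 2, 0), class = "psifold_domain_error")
})

test_that("Boltzmann weights are positive, decreasing, and vanish at +Inf", {
  m <- toy_model()
  expect_equal(boltzmann_weight(m, 0), 1)
  expect_equal(boltzmann_weight(m, Inf), 0)
  expect_equal(boltzmann_weight(m, -m$kT), exp(1))
  es <- seq(-5, 20, by = 0.5)
  ws <- boltzmann_weight(m, es)
  expect_true(all(ws > 0))
  expect_true(all(diff(ws) < 0))
})

test_that("parameter files round-trip to 1e-12 and fall back to defaults", {
  m <- toy_model(multi = c(3.0, 0.5, 0.1), terminal_au = 0.4)
  f <- withr::local_tempfile(fileext = ".txt")
  write_energy_params(m, f)
  m2 <- read_energy_params(f)
  expect_equal(m2$hairpin, m$hairpin, tolerance = 1e-12)
  expect_equal(m2$stack, m$stack, tolerance = 1e-12)
  expect_equal(m2$bulge, m$bulge, tolerance = 1e-12)
  expect_equal(m2$internal, m$internal, tolerance = 1e-12)
  expect_equal(m2$multi, m$multi, tolerance = 1e-12)
  expect_equal(m2$terminal_au, m$terminal_au, tolerance = 1e-12)
  expect_equal(m2$kT, m$kT, tolerance = 1e-12)

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines("# nothing here", empty)
  expect_warning(md <- read_energy_params(empty),
                 class = "psifold_defaults_warning")
  expect_equal(md$stack, toy_model()$stack)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("kT 0.61633", "stack GC XX -1"), bad)
  expect_error(read_energy_params(bad), regexp = "line 2",
               class = "psifold_parse_error")
})

test_that("the shipped toy parameter file matches the built-in defaults", {
  f <- system.file("extdata", "params_toy.txt", package = "psifold")
  m <- read_energy_params(f)
  expect_equal(stack_energy(m, "GC", "GC"), -3.3)
  expect_equal(m$kT, 0.61633)
  expect_equal(m$hairpin, toy_model()$hairpin)
})
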