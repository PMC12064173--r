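test_that("dot-bracket parsing and formatting round-trip", {
  for (db in c(".........", "(((...)))", "..((...))..",
               "((..(((...)))..((....))..))", ".....")) {
    s <- parse_dotbracket(db)
    expect_identical(format_dotbracket(s), db)
  }
  expect_error(parse_dotbracket("((..x..))"), class = "psifold_input_error")
  expect_error(parse_dotbracket("((...)"), class = "psifold_input_error")
  expect_error(parse_dotbracket("(...)))"), class = "psifold_input_error")
})

test_that("structures reject duplicates, crossings and tight hairpins", {
  expect_error(rna_structure(10, rbind(c(1, 8), c(1, 9))),
               class = "psifold_input_error")
  expect_error(rna_structure(10, rbind(c(1, 6), c(3, 9))),
               class = "psifold_input_error") # pseudoknot
  expect_error(rna_structure(10, cbind(1, 4)),
               class = "psifold_input_error") # loop of 2 < theta
  s <- rna_structure(10, rbind(c(2, 9), c(3, 8)))
  expect_identical(nrow(s$pairs), 2L)
  # index order within a pair is normalized
  s2 <- rna_structure(10, rbind(c(9, 2)))
  expect_identical(s2$pairs, cbind(2L, 9L))
})

test_that("hairpin_target builds the single stem with a minimal loop", {
  s <- hairpin_target(11)
  expect_identical(s$pairs, cbind(1:4, c(11L, 10L, 9L, 8L)))
  expect_identical(format_dotbracket(s), "((((...))))")
  s12 <- hairpin_target(12)
  expect_identical(nrow(s12$pairs), 4L)
  expect_identical(format_dotbracket(s12), "((((....))))")
  expect_error(hairpin_target(4), class = "psifold_input_error")
})

test_that("structure energy decomposes into the hand-computed loop terms", {
  m <- toy_model()
  # exterior only
  expect_equal(structure_energy("ACGUACGUA", rna_structure(9), m), 0)
  # stem of 3 with a GC-closed hairpin
  s <- rna_structure(9, cbind(1:3, 9:7))
  expect_equal(structure_energy("GGGAAACCC", s, m), 5.4 - 2 * 3.3)
  # disallowed pair
  expect_error(structure_energy("AAAAAAAAA", rna_structure(9, cbind(1, 9)), m),
               class = "psifold_domain_error")
  # internal loop: (1,12) over (3,10): 1 unpaired each side
  s2 <- rna_structure(12, rbind(c(1, 12), c(3, 10)))
  expect_equal(structure_energy("GAGAAAAAACAC", s2, m),
               internal_or_bulge_energy(m, "GC", "GC", 1, 1) +
                 hairpin_energy(m, "GC", 6))
  # bulge: (1,12)-(2,10), one unpaired on the right strand
  s3 <- rna_structure(12, rbind(c(1, 12), c(2, 10)))
  expect_equal(structure_energy("GGAAAAAAACAC", s3, m),
               internal_or_bulge_energy(m, "GC", "GC", 0, 1) +
                 hairpin_energy(m, "GC", 7))
  # multiloop: two inner branches plus the closing pair, 3 unpaired inside
  s4 <- rna_structure(18, rbind(c(1, 18), c(2, 7), c(10, 16)))
  expect_equal(structure_energy("GAAAAAUAAGAAAAACAC", s4, m),
               multiloop_energy(m, 3, 3) +
                 hairpin_energy(m, "AU", 4) + hairpin_energy(m, "GC", 5))
  # over-cap internal loop propagates +Inf
  m_small <- toy_model(internal_cap = 3L)
  s5 <- rna_structure(14, rbind(c(1, 14), c(4, 11)))
  expect_identical(structure_energy("GAAGAAAAAACAAC", s5, m_small), Inf)
})
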