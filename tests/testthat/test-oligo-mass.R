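# Mass engine: sequence parsing, elemental composition, neutral mass, m/z.

test_that("bracketed sequence parsing tokenizes and round-trips", {
  o <- parse_sequence("GGACU")
  expect_equal(o$tokens, c("G", "G", "A", "C", "U"))

  m <- parse_sequence("GG[m6A]CU")
  expect_equal(m$tokens, c("G", "G", "m6A", "C", "U"))
  expect_equal(format(m), "GG[m6A]CU")

  expect_error(parse_sequence("GGXCU"), "position 3")
  expect_error(parse_sequence("GGACT"), "position 5")   # T is not RNA
  expect_error(parse_sequence("GG[m6A"), "unterminated")

  # parse -> canonical string -> parse is the identity on tokens
  set.seed(11)
  for (i in 1:20) {
    tokens <- random_rna_tokens(sample(2:30, 1), with_mod = TRUE)
    o <- oligo_spec(tokens)
    expect_identical(parse_sequence(format(o))$tokens, tokens)
  }
})

test_that("elemental composition matches textbook formulas and bookkeeping", {
  # a single 5'-phosphorylated adenosine is AMP
  amp <- elemental_composition(parse_sequence("A", end5 = "phosphate"))
  expect_equal(amp[c("C", "H", "N", "O", "P")],
               c(C = 10L, H = 14L, N = 5L, O = 7L, P = 1L))

  # concatenation: joining a (3'-OH) and b (5'-OH) forms one new
  # phosphodiester, i.e. comp(ab) = comp(a) + comp(b) - H2O + HPO3
  set.seed(21)
  for (i in 1:10) {
    a_tok <- random_rna_tokens(sample(2:8, 1))
    b_tok <- random_rna_tokens(sample(2:8, 1))
    ab <- elemental_composition(oligo_spec(c(a_tok, b_tok)))
    a <- elemental_composition(oligo_spec(a_tok))
    b <- elemental_composition(oligo_spec(b_tok))
    expected <- formula_sum(a, b, formula_multiply(parse_formula("H2O"), -1),
                            parse_formula("HPO3"))
    expect_equal(ab[order(names(ab))], expected[order(names(expected))])
  }

  # methylation difference is exactly CH2
  d <- formula_sum(elemental_composition(parse_sequence("GG[m6A]CU")),
                   formula_multiply(elemental_composition(parse_sequence("GGACU")), -1))
  expect_equal(d[order(names(d))], c(C = 1L, H = 2L))
})

test_that("neutral mass agrees with the brute-force NMP-sum oracle", {
  # 5'-phosphorylated GGACU: value frozen from the independent oracle
  o <- parse_sequence("GGACU", end5 = "phosphate")
  expect_equal(neutral_mass(o), 1648.2245, tolerance = 1e-3)
  expect_equal(neutral_mass(o),
               oracle_mass(o$tokens, end5 = "phosphate"),
               tolerance = 1e-6)

  # 100 random sequences, both mass types, random end chemistry
  set.seed(31)
  for (i in 1:100) {
    tokens <- random_rna_tokens(sample(2:30, 1), with_mod = (i %% 3 == 0))
    e5 <- sample(c("OH", "phosphate"), 1)
    e3 <- sample(c("OH", "phosphate"), 1)
    o <- oligo_spec(tokens, end5 = e5, end3 = e3)
    for (mt in c("mono", "avg")) {
      expect_equal(neutral_mass(o, mt),
                   oracle_mass(tokens, end5 = e5, end3 = e3, mass_type = mt),
                   tolerance = 1e-6)
    }
  }
})

test_that("atomic-mass table reproduces reference masses of known species", {
  # cross-check against masses frozen from an independent dataset
  ref <- c(A = REF_MONO[["AMP"]], C = REF_MONO[["CMP"]],
           G = REF_MONO[["GMP"]], U = REF_MONO[["UMP"]])
  for (b in names(ref)) {
    o <- parse_sequence(b, end5 = "phosphate")
    expect_equal(neutral_mass(o), ref[[b]], tolerance = 1e-4)
  }
  expect_equal(formula_mass(parse_formula("HPO3")), REF_MONO[["HPO3"]],
               tolerance = 1e-4)
})

test_that("5'-phosphate vs 5'-OH gap is the HPO3 mass for any sequence", {
  set.seed(41)
  for (i in 1:10) {
    tokens <- random_rna_tokens(sample(2:20, 1))
    for (mt in c("mono", "avg")) {
      gap <- neutral_mass(oligo_spec(tokens, end5 = "phosphate"), mt) -
        neutral_mass(oligo_spec(tokens, end5 = "OH"), mt)
      expect_equal(gap, formula_mass(parse_formula("HPO3"), mt),
                   tolerance = 1e-9)
    }
  }
})

test_that("modification mass effect is its delta formula, position-independent", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    tokens <- random_rna_tokens(n)
    tokens[sample.int(n, 1)] <- "A"      # guarantee an adenosine
    pos <- sample(rep(which(tokens == "A"), 2), 1)
    mod_tokens <- tokens
    mod_tokens[pos] <- "m6A"
    expect_equal(neutral_mass(oligo_spec(mod_tokens)) -
                   neutral_mass(oligo_spec(tokens)),
                 14.01565, tolerance = 1e-5)
  }
})

test_that("tag mass delta is a pure additive offset", {
  probe <- parse_sequence("AGTCC", strand = "DNA", tag_mass_delta = 250.5)
  bare <- parse_sequence("AGTCC", strand = "DNA")
  expect_equal(neutral_mass(probe) - neutral_mass(bare), 250.5)
  # composition is unaffected by the tag
  expect_identical(elemental_composition(probe),
                   elemental_composition(bare))
  expect_error(oligo_spec("A", tag_mass_delta = -1))
})

test_that("m/z adds proton masses and rejects bad charges", {
  o <- parse_sequence("GGACU", end5 = "phosphate")
  expect_equal(mz(o, 1), neutral_mass(o) + REF_MONO[["proton"]],
               tolerance = 1e-5)
  expect_equal(mz(o, 1), 1649.2318, tolerance = 1e-3)
  expect_equal(mz(o, 2), (neutral_mass(o) + 2 * REF_MONO[["proton"]]) / 2,
               tolerance = 1e-5)
  expect_lt(mz(o, 2), mz(o, 1))
  expect_error(mz(o, 0), "charge")
  expect_error(mz(o, 1.5), "charge")
})

test_that("modification registry accepts new codes and registry files", {
  expect_error(register_modification("m6A", "A", "CH2"), "already")
  def <- register_modification("testMod", parent = "U",
                               delta_formula = "C2H4", overwrite = TRUE)
  expect_equal(def$delta_mono, 2 * 12 + 4 * ATOMIC_MONO[["H"]],
               tolerance = 1e-9)
  o <- parse_sequence("GG[testMod]CU")
  expect_equal(neutral_mass(o) - neutral_mass(parse_sequence("GGUCU")),
               def$delta_mono, tolerance = 1e-9)

  f <- tempfile(fileext = ".csv")
  writeLines(c("code,parent,delta_formula", "dmA,A,C2H4"), f)
  load_modification_registry(f)
  expect_true("dmA" %in% list_modifications()$code)
  expect_error(load_modification_registry(f), "already")
})
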