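# Mass engine: residue/oligomer formulas, monoisotopic masses, m/z.

test_that("free nucleoside masses match the element-summation oracle", {
  # frozen value computed with the independent oracle before the engine
  expect_equal(monoisotopic_mass(residue_formula(nucleotide_spec("C"))),
               243.0855, tolerance = 1e-4 / 243)
  expect_equal(monoisotopic_mass(residue_formula(nucleotide_spec("C"))),
               oracle_formula_mass("C9H13N3O5"), tolerance = 1e-9)
  for (b in c("A", "C", "G", "U")) {
    for (s in c("ribo", "arabino", "threo", "deoxyribo", "dideoxy")) {
      expect_equal(
        monoisotopic_mass(residue_formula(nucleotide_spec(b, s))),
        oracle_nucleoside_mass(b, s), tolerance = 1e-9,
        label = paste(b, s))
    }
  }
})

test_that("ribo and arabino residues are exact isobars; threo is CH2 lighter", {
  ch2 <- oracle_formula_mass("CH2")
  for (b in c("A", "C", "G", "U")) {
    for (lab in c("none", "13C15N_uniform")) {
      m_ribo <- monoisotopic_mass(residue_formula(nucleotide_spec(b, "ribo", lab)))
      m_ara <- monoisotopic_mass(residue_formula(nucleotide_spec(b, "arabino", lab)))
      m_threo <- monoisotopic_mass(residue_formula(nucleotide_spec(b, "threo", lab)))
      expect_identical(m_ribo, m_ara)
      # the threo offset: labeled residues lose a 13C rather than a 12C
      ch2_lab <- if (lab == "none") ch2 else ch2 + 13.00335483507 - 12
      expect_equal(m_ribo - m_threo, ch2_lab, tolerance = 1e-4 / 14)
      if (lab == "none") {
        expect_equal(m_ribo - m_threo, 14.01565, tolerance = 1e-4 / 14)
      }
    }
  }
})

test_that("uniform 13C/15N labeling shifts masses as expected and separates epimers", {
  unlab <- monoisotopic_mass(residue_formula(nucleotide_spec("C")))
  lab <- monoisotopic_mass(residue_formula(
    nucleotide_spec("C", label = "13C15N_uniform")))
  expect_equal(lab - unlab, 12.0213, tolerance = 1e-4)  # 9 C + 3 N
  # labeled-ribo vs unlabeled-arabino separation >= 9 Da for every base:
  # the disambiguation the isotope-labeling strategy achieves
  for (b in c("A", "C", "G", "U")) {
    d <- monoisotopic_mass(residue_formula(
           nucleotide_spec(b, "ribo", "13C15N_uniform"))) -
         monoisotopic_mass(residue_formula(nucleotide_spec(b, "arabino")))
    expect_gte(d, 9)
  }
})

test_that("oligomer assembly reproduces frozen chain masses", {
  rc6 <- oligomer_spec(rep("rC", 6))
  expect_equal(oligomer_mass(rc6), 1768.292, tolerance = 1e-3 / 1768)
  # single residue: nucleoside mass unchanged
  expect_equal(oligomer_mass(oligomer_spec("rC")),
               monoisotopic_mass(residue_formula(nucleotide_spec("C"))))
  # +1 with terminal tC vs terminal rC differs by exactly one CH2
  m_rc7 <- oligomer_mass(extend_oligomer(rc6, "rC"))
  m_tc <- oligomer_mass(extend_oligomer(rc6, "tC"))
  expect_equal(m_rc7 - m_tc, 14.01565, tolerance = 1e-4 / 14)
  # internal-branch addition is isobaric with terminal addition
  m_branch <- oligomer_mass(extend_oligomer(rc6, "rC",
                                            site = "internal_branch"))
  expect_identical(m_rc7, m_branch)
})

test_that("monoisotopic_mass handles edge formulas and unknown elements", {
  expect_identical(monoisotopic_mass(elemental_formula()), 0)
  expect_equal(monoisotopic_mass(c(C = 9, H = 14, N = 3, O = 8, P = 1)),
               323.0519, tolerance = 1e-4 / 323)  # free 5'-CMP
  expect_error(elemental_formula(c(Xx = 1)), "unknown element")
  expect_error(elemental_formula(c(C = -1)), "negative")
})

test_that("negative-mode m/z and sodium-adduct arithmetic are exact", {
  expect_equal(adducted_mz(1768.292, charge = 2), 883.139,
               tolerance = 1e-3 / 883)
  M <- 1500
  expect_equal(adducted_mz(M, 1), M - 1.007276, tolerance = 1e-6)
  expect_equal(adducted_mz(M, 1, n_sodium = 1),
               (M - 1.007276) + 21.98194, tolerance = 1e-4)
  expect_error(adducted_mz(M, charge = 0), "charge")
  lad <- mz_ladder(M, charges = 1:2, max_sodium = 2)
  expect_equal(nrow(lad), 6)
  expect_true(all(diff(lad$mz[lad$charge == 1]) > 0))
})

test_that("oligomer mass is additive over random chain splits", {
  set.seed(101)
  linkage <- oracle_formula_mass("H3PO4") - 2 * oracle_formula_mass("H2O")
  for (i in 1:25) {
    n <- sample(4:12, 1)
    ro <- random_oligomer(n)
    ro$five_prime_end <- "hydroxyl"
    # dideoxy only allowed at a true 3' terminus; keep the split prefix clean
    ro$residues[[n]]$sugar <- sample(c("ribo", "threo", "deoxyribo"), 1)
    cut <- sample(seq_len(n - 1), 1)
    a <- ro; a$residues <- ro$residues[seq_len(cut)]
    b <- ro; b$residues <- ro$residues[(cut + 1):n]
    m_full <- oligomer_mass(as_pkg_oligomer(ro))
    m_a <- oligomer_mass(as_pkg_oligomer(a))
    m_b <- oligomer_mass(as_pkg_oligomer(b))
    expect_equal(m_full, m_a + m_b + linkage, tolerance = 1e-9)
  }
})

test_that("engine agrees with the independent oracle on 100 random oligomers", {
  set.seed(202)
  for (i in 1:100) {
    ro <- random_oligomer()
    expect_equal(oligomer_mass(as_pkg_oligomer(ro)),
                 oracle_oligomer_mass(ro$residues, ro$five_prime_end),
                 tolerance = 1e-6 / 2000)
  }
})

test_that("spec construction enforces its invariants", {
  expect_error(oligomer_spec(list()), "at least one residue")
  expect_error(oligomer_spec("rC", three_prime_end = "dideoxy"), "dideoxy")
  ok <- oligomer_spec(c("rC", "ddC"), three_prime_end = "dideoxy")
  expect_equal(ok$n_linkages, 1L)
  expect_error(parse_residue("xC"), "cannot parse")
  expect_error(nucleotide_spec("T"), "arg")
})

test_that("oligomer specs round-trip through the JSON dialect", {
  spec <- oligomer_spec(c("13C15N-rC", "araC", "tC"),
                        five_prime_end = "hexynyl")
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    residues = lapply(spec$residues, function(r) {
      list(base = r$base, sugar = r$sugar, label = r$label)
    }),
    five_prime_end = "hexynyl", three_prime_end = "diol"
  ), path, auto_unbox = TRUE)
  back <- read_oligomer_json(path)
  expect_equal(oligomer_mass(back), oligomer_mass(spec))
  expect_equal(back$residues[[1]]$label, "13C15N_uniform")
})
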