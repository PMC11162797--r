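# Independent element-summation oracle for monoisotopic masses.
# Deliberately written from scratch (its own atomic-mass table, its own
# nucleoside composition table, string-based formula parsing) so that it
# shares no code path with the package's mass engine.

.ORACLE_ATOMIC <- c(
  H    = 1.00782503207,
  C    = 12.0,
  N    = 14.0030740048,
  O    = 15.9949146196,
  P    = 30.97376199842,
  Na   = 22.9897692809,
  C13  = 13.00335483507,
  N15  = 15.0001088989
)

# parse "C9H13N3O5" style strings (plain light-isotope formulas)
oracle_formula_mass <- function(str) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", str)[[1]]
  toks <- regmatches(str, gregexpr("([A-Z][a-z]?)([0-9]*)", str))[[1]]
  toks <- toks[nzchar(toks)]
  total <- 0
  for (tk in toks) {
    el <- gsub("[0-9]", "", tk)
    n <- gsub("[A-Za-z]", "", tk)
    n <- if (nzchar(n)) as.numeric(n) else 1
    if (!el %in% names(.ORACLE_ATOMIC)) stop("oracle: unknown element ", el)
    total <- total + n * .ORACLE_ATOMIC[[el]]
  }
  total
}

# free-nucleoside element counts, typed independently of the package table
.ORACLE_NUCLEOSIDE <- list(
  A = c(C = 10, H = 13, N = 5, O = 4),
  C = c(C = 9,  H = 13, N = 3, O = 5),
  G = c(C = 10, H = 13, N = 5, O = 5),
  U = c(C = 9,  H = 12, N = 2, O = 6)
)

oracle_nucleoside_mass <- function(base, sugar = "ribo", label = "none") {
  cnt <- .ORACLE_NUCLEOSIDE[[base]]
  cnt <- switch(sugar,
    ribo = cnt, arabino = cnt,
    threo = cnt - c(C = 1, H = 2, N = 0, O = 0),
    deoxyribo = cnt - c(C = 0, H = 0, N = 0, O = 1),
    dideoxy = cnt - c(C = 0, H = 0, N = 0, O = 2))
  mass_C <- if (label == "13C15N_uniform") .ORACLE_ATOMIC[["C13"]] else
    .ORACLE_ATOMIC[["C"]]
  mass_N <- if (label == "13C15N_uniform") .ORACLE_ATOMIC[["N15"]] else
    .ORACLE_ATOMIC[["N"]]
  cnt[["C"]] * mass_C + cnt[["H"]] * .ORACLE_ATOMIC[["H"]] +
    cnt[["N"]] * mass_N + cnt[["O"]] * .ORACLE_ATOMIC[["O"]]
}

.ORACLE_LINKAGE <- function() {
  oracle_formula_mass("H3PO4") - 2 * oracle_formula_mass("H2O")
}

# residues: list of list(base=, sugar=, label=)
oracle_oligomer_mass <- function(residues, five_prime_end = "hydroxyl") {
  total <- sum(vapply(residues, function(r) {
    oracle_nucleoside_mass(r$base, r$sugar, r$label)
  }, numeric(1)))
  total <- total + (length(residues) - 1) * .ORACLE_LINKAGE()
  total + switch(five_prime_end,
                 hydroxyl = 0,
                 hexynyl = oracle_formula_mass("C6H8O"),
                 phosphate = oracle_formula_mass("HPO3"))
}

# random oligomer generator shared by property tests; dideoxy only at the
# 3' terminus (elsewhere it could not carry a 3' linkage)
random_oligomer <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:12, 1)
  sugars <- c("ribo", "arabino", "threo", "deoxyribo")
  res <- lapply(seq_len(n), function(i) {
    list(base = sample(c("A", "C", "G", "U"), 1),
         sugar = if (i == n) sample(c(sugars, "dideoxy"), 1)
                 else sample(sugars, 1),
         label = sample(c("none", "13C15N_uniform"), 1, prob = c(0.8, 0.2)))
  })
  ends <- sample(c("hydroxyl", "hexynyl", "phosphate"), 1)
  list(residues = res, five_prime_end = ends)
}

as_pkg_oligomer <- function(ro) {
  specs <- lapply(ro$residues, function(r) {
    nucleotide_spec(r$base, r$sugar, r$label)
  })
  tp <- if (ro$residues[[length(ro$residues)]]$sugar == "dideoxy")
    "dideoxy" else "diol"
  oligomer_spec(specs, five_prime_end = ro$five_prime_end,
                three_prime_end = tp)
}
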