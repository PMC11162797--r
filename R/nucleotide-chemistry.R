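# Elemental-formula and monoisotopic-mass engine for chimeric oligonucleotides
# (ribo / arabino / threo / deoxyribo / dideoxy residues, uniform 13C/15N
# labels, 5' end groups) plus negative-mode m/z and sodium-adduct arithmetic.

#' Atomic monoisotopic masses used throughout the package
#'
#' Monoisotopic masses in Da for the elements occurring in oligonucleotide
#' chemistry, pinned to IUPAC/CODATA values so that candidate masses are
#' bit-reproducible across platforms. `"13C"` and `"15N"` denote the heavy
#' isotopes used for uniform stable-isotope labeling.
#'
#' @format Named numeric vector (Da).
#' @export
ATOMIC_MASSES <- c(
  "H"   = 1.007825032,
  "C"   = 12.0,
  "13C" = 13.003354838,
  "N"   = 14.003074005,
  "15N" = 15.000108898,
  "O"   = 15.994914620,
  "P"   = 30.973761998,
  "Na"  = 22.989769282
)

#' Mass of a proton (Da), used in m/z arithmetic
#' @export
PROTON_MASS <- 1.007276467

#' Mass shift of one sodium adduct (Na replacing H), Da
#' @export
SODIUM_ADDUCT_SHIFT <- ATOMIC_MASSES[["Na"]] - ATOMIC_MASSES[["H"]]

.BASES  <- c("A", "C", "G", "U")
.SUGARS <- c("ribo", "arabino", "threo", "deoxyribo", "dideoxy")
.LABELS <- c("none", "13C15N_uniform")

# Free ribonucleoside compositions; other sugar families are composition
# offsets from these (arabino is the 2'-epimer, hence identical).
.RIBONUCLEOSIDES <- list(
  A = c(C = 10, H = 13, N = 5, O = 4),
  C = c(C = 9,  H = 13, N = 3, O = 5),
  G = c(C = 10, H = 13, N = 5, O = 5),
  U = c(C = 9,  H = 12, N = 2, O = 6)
)

# ---- ElementalFormula ------------------------------------------------------

#' Construct an elemental formula
#'
#' An `elemental_formula` is a named integer vector of element counts over
#' the supported element set (C, 13C, H, N, 15N, O, P, Na). The empty formula
#' has mass 0.
#'
#' @param counts Named numeric vector of element counts (may be empty).
#' @param allow_negative Permit negative counts (used internally for
#'   composition offsets); final formulas of real species must be
#'   non-negative.
#' @return An object of class `elemental_formula`.
#' @export
elemental_formula <- function(counts = numeric(0), allow_negative = FALSE) {
  if (length(counts)) {
    bad <- setdiff(names(counts), names(ATOMIC_MASSES))
    if (length(bad)) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    }
    if (any(counts != round(counts))) stop("element counts must be integers")
    if (!allow_negative && any(counts < 0)) {
      stop("negative element count in formula")
    }
  }
  full <- stats::setNames(numeric(length(ATOMIC_MASSES)), names(ATOMIC_MASSES))
  full[names(counts)] <- counts
  structure(full, class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  nz <- x[x != 0]
  if (!length(nz)) {
    cat("<empty formula>\n")
  } else {
    cat(paste0(names(nz), ifelse(nz == 1, "", nz), collapse = " "),
        sprintf(" (%.4f Da)\n", monoisotopic_mass(x)))
  }
  invisible(x)
}

formula_add <- function(a, b, scale = 1) {
  out <- unclass(a) + scale * unclass(b)
  structure(out, class = "elemental_formula")
}

formula_check <- function(f, what = "formula") {
  if (any(unclass(f) < 0)) {
    stop("resulting ", what, " has negative element counts (invalid species)")
  }
  f
}

# ---- NucleotideSpec --------------------------------------------------------

#' Define a nucleotide residue
#'
#' @param base One of `"A"`, `"C"`, `"G"`, `"U"`.
#' @param sugar Sugar family: `"ribo"`, `"arabino"` (the 2'-epimer of ribo,
#'   isobaric with it), `"threo"` (lacks the 5'-methylene carbon: one CH2
#'   lighter), `"deoxyribo"`, or `"dideoxy"`.
#' @param label `"none"` or `"13C15N_uniform"` (every carbon becomes 13C and
#'   every nitrogen 15N).
#' @return A `nucleotide_spec` object.
#' @export
nucleotide_spec <- function(base, sugar = "ribo", label = "none") {
  base  <- match.arg(base, .BASES)
  sugar <- match.arg(sugar, .SUGARS)
  label <- match.arg(label, .LABELS)
  structure(list(base = base, sugar = sugar, label = label),
            class = "nucleotide_spec")
}

#' Parse a residue shorthand such as "rC", "araC", "tC", "dC" or "ddC"
#'
#' Sugar prefixes: `r` ribo, `ara` arabino, `t` threo, `d` deoxyribo,
#' `dd` dideoxy. An optional leading `"13C15N-"` marks uniform heavy-isotope
#' labeling (e.g. `"13C15N-rC"`).
#'
#' @param code Character shorthand.
#' @return A `nucleotide_spec`.
#' @export
parse_residue <- function(code) {
  label <- "none"
  if (startsWith(code, "13C15N-")) {
    label <- "13C15N_uniform"
    code <- sub("^13C15N-", "", code)
  }
  m <- regmatches(code, regexec("^(ara|dd|d|r|t)([ACGU])$", code))[[1]]
  if (!length(m)) stop("cannot parse residue shorthand: ", code)
  sugar <- c(r = "ribo", ara = "arabino", t = "threo",
             d = "deoxyribo", dd = "dideoxy")[[m[2]]]
  nucleotide_spec(m[3], sugar, label)
}

#' Elemental formula of a free nucleoside
#'
#' Returns the composition of the free nucleoside for a residue spec. Sugar
#' families are handled as composition offsets from the ribonucleoside:
#' arabino is identical (epimer), threo is one CH2 lighter (no 5'-methylene
#' carbon), deoxyribo one oxygen lighter, dideoxy two oxygens lighter.
#' Uniform labeling converts every C to 13C and every N to 15N.
#'
#' @param spec A `nucleotide_spec`.
#' @return An `elemental_formula`.
#' @export
residue_formula <- function(spec) {
  stopifnot(inherits(spec, "nucleotide_spec"))
  counts <- .RIBONUCLEOSIDES[[spec$base]]
  if (is.null(counts)) stop("unsupported base/sugar combination")
  counts <- switch(spec$sugar,
    ribo      = counts,
    arabino   = counts,
    threo     = counts - c(C = 1, H = 2, N = 0, O = 0),
    deoxyribo = counts - c(C = 0, H = 0, N = 0, O = 1),
    dideoxy   = counts - c(C = 0, H = 0, N = 0, O = 2)
  )
  if (spec$label == "13C15N_uniform") {
    counts <- c(counts, "13C" = unname(counts["C"]),
                "15N" = unname(counts["N"]))
    counts["C"] <- 0
    counts["N"] <- 0
  }
  formula_check(elemental_formula(counts), "nucleoside formula")
}

# ---- OligomerSpec ----------------------------------------------------------

#' Define an oligonucleotide (5' to 3')
#'
#' @param residues List of `nucleotide_spec` objects, or a character vector of
#'   residue shorthands understood by [parse_residue()], ordered 5' to 3'.
#' @param five_prime_end `"hydroxyl"`, `"hexynyl"` (hexynyl ether cap used to
#'   block 5' reactions) or `"phosphate"`.
#' @param three_prime_end `"diol"` (free 2',3'-diol) or `"dideoxy"`; with
#'   `"dideoxy"` the 3'-terminal residue must itself be a dideoxy sugar (the
#'   mass is carried at residue level).
#' @return An `oligomer_spec` with `n_linkages = length(residues) - 1`.
#' @export
oligomer_spec <- function(residues, five_prime_end = "hydroxyl",
                          three_prime_end = "diol") {
  if (is.character(residues)) residues <- lapply(residues, parse_residue)
  if (!length(residues)) stop("oligomer must contain at least one residue")
  ok <- vapply(residues, inherits, logical(1), "nucleotide_spec")
  if (!all(ok)) stop("residues must be nucleotide_spec objects")
  five_prime_end <- match.arg(five_prime_end,
                              c("hydroxyl", "hexynyl", "phosphate"))
  three_prime_end <- match.arg(three_prime_end, c("diol", "dideoxy"))
  last_sugar <- residues[[length(residues)]]$sugar
  if (three_prime_end == "dideoxy" && last_sugar != "dideoxy") {
    stop("three_prime_end = 'dideoxy' requires a dideoxy 3'-terminal residue")
  }
  structure(list(residues = residues,
                 five_prime_end = five_prime_end,
                 three_prime_end = three_prime_end,
                 n_linkages = length(residues) - 1L),
            class = "oligomer_spec")
}

#' @export
print.oligomer_spec <- function(x, ...) {
  codes <- vapply(x$residues, function(r) {
    pre <- c(ribo = "r", arabino = "ara", threo = "t",
             deoxyribo = "d", dideoxy = "dd")[[r$sugar]]
    lab <- if (r$label == "13C15N_uniform") "*" else ""
    paste0(lab, pre, r$base)
  }, character(1))
  cat(sprintf("<oligomer: 5'-%s | %s | 3'-%s>\n", x$five_prime_end,
              paste(codes, collapse = "-"), x$three_prime_end))
  invisible(x)
}

.H3PO4 <- elemental_formula(c(H = 3, P = 1, O = 4))
.H2O   <- elemental_formula(c(H = 2, O = 1))

#' Elemental formula of an oligonucleotide
#'
#' Assembles the chain as the sum of the free-nucleoside formulas plus one
#' phosphoric acid (H3PO4) per internucleotide linkage minus two waters per
#' linkage (condensation), then applies 5'-end adjustments (hexynyl: +C6H8O
#' replacing a 5'-H; phosphate: +HPO3). A branched product (addition at an
#' internal 2'-OH) adds one residue and one linkage exactly as terminal
#' extension does, so branching never changes the mass.
#'
#' @param oligo An `oligomer_spec`.
#' @return An `elemental_formula`.
#' @export
oligomer_formula <- function(oligo) {
  stopifnot(inherits(oligo, "oligomer_spec"))
  f <- elemental_formula()
  for (r in oligo$residues) f <- formula_add(f, residue_formula(r))
  nl <- oligo$n_linkages
  f <- formula_add(f, .H3PO4, nl)
  f <- formula_add(f, .H2O, -2 * nl)
  f <- switch(oligo$five_prime_end,
    hydroxyl  = f,
    hexynyl   = formula_add(f, elemental_formula(c(C = 6, H = 8, O = 1))),
    phosphate = formula_add(f, elemental_formula(c(H = 1, P = 1, O = 3)))
  )
  formula_check(f, "oligomer formula")
}

#' Extend an oligomer by one residue
#'
#' Appends one residue and one internucleotide linkage. `site = "terminal"`
#' grows the 3' end; `site = "internal_branch"` records addition at an
#' internal 2'-OH — the elemental composition (and hence mass) is identical,
#' only the site annotation differs.
#'
#' @param oligo An `oligomer_spec`.
#' @param residue A `nucleotide_spec` (or shorthand string).
#' @param site `"terminal"` or `"internal_branch"`.
#' @return An `oligomer_spec` with one more residue and linkage.
#' @export
extend_oligomer <- function(oligo, residue, site = "terminal") {
  site <- match.arg(site, c("terminal", "internal_branch"))
  if (is.character(residue)) residue <- parse_residue(residue)
  res <- c(oligo$residues, list(residue))
  tp <- if (site == "terminal" && residue$sugar == "dideoxy") "dideoxy"
        else if (site == "internal_branch") oligo$three_prime_end
        else "diol"
  oligomer_spec(res, oligo$five_prime_end, tp)
}

# ---- masses and m/z --------------------------------------------------------

#' Monoisotopic mass of an elemental formula
#'
#' @param f An `elemental_formula` (or named count vector).
#' @return Mass in Da; the empty formula returns 0.
#' @export
monoisotopic_mass <- function(f) {
  if (!inherits(f, "elemental_formula")) f <- elemental_formula(f)
  sum(unclass(f) * ATOMIC_MASSES[names(unclass(f))])
}

#' Monoisotopic mass of an oligomer spec
#' @param oligo An `oligomer_spec`.
#' @return Neutral monoisotopic mass in Da.
#' @export
oligomer_mass <- function(oligo) monoisotopic_mass(oligomer_formula(oligo))

#' Negative-mode m/z of a (possibly sodiated) species
#'
#' `m/z = (M + n_sodium * (Na - H) - z * m_proton) / z`, the deprotonation
#' series observed in negative-mode ESI. The constraint that
#' `n_sodium + z` not exceed the number of exchangeable protons is not
#' checked.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charge Charge-state magnitude `z` (positive integer; the species
#'   carries `z` negative charges).
#' @param n_sodium Number of sodium adducts (H replaced by Na).
#' @return m/z value(s).
#' @export
adducted_mz <- function(neutral_mass, charge = 1, n_sodium = 0) {
  if (any(charge < 1)) stop("charge magnitude must be >= 1")
  if (any(n_sodium < 0)) stop("n_sodium must be >= 0")
  (neutral_mass + n_sodium * SODIUM_ADDUCT_SHIFT - charge * PROTON_MASS) /
    charge
}

#' m/z ladder over charge states and sodium adducts
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charges Integer vector of charge-state magnitudes.
#' @param max_sodium Maximum number of sodium adducts.
#' @return Data frame with columns `charge`, `n_sodium`, `mz`.
#' @export
mz_ladder <- function(neutral_mass, charges = 1:3, max_sodium = 3) {
  grid <- expand.grid(charge = charges, n_sodium = 0:max_sodium)
  grid$mz <- adducted_mz(neutral_mass, grid$charge, grid$n_sodium)
  grid[order(grid$charge, grid$n_sodium), ]
}

#' Read an oligomer definition from JSON
#'
#' Expects `{"residues":[{"base":"C","sugar":"ribo","label":"none"},...],
#' "five_prime_end":"hydroxyl","three_prime_end":"diol"}`.
#'
#' @param path Path to a JSON file.
#' @return An `oligomer_spec`.
#' @export
read_oligomer_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  residues <- lapply(x$residues, function(r) {
    nucleotide_spec(r$base, r$sugar %||% "ribo", r$label %||% "none")
  })
  oligomer_spec(residues,
                x$five_prime_end %||% "hydroxyl",
                x$three_prime_end %||% "diol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
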