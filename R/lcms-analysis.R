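# Matching of deconvoluted LC-MS compound lists to enumerated candidate
# extension products, normalized incorporation percentages across
# replicates, and internal-versus-terminal hydroxyl reactivity
# deconvolution.
#
# Compound records are vendor-style deconvoluted entities: neutral
# monoisotopic mass (Da), retention time (min), abundance, replicate id.
# Retention time is never used for identity — co-eluting or doubled peaks
# assigned to the same compound are summed before normalization.

#' Count free internal 2'-hydroxyls of a primer
#'
#' Internal 2'-OH sites are the ribo/arabino residues upstream of the
#' 3'-terminal residue (the terminal residue's 2'- and 3'-OH together form
#' the terminal diol). DNA and threo residues carry no 2'-OH.
#'
#' @param primer An `oligomer_spec`.
#' @return Integer count of internal 2'-OH sites.
#' @export
n_internal_2oh <- function(primer) {
  res <- primer$residues
  if (length(res) < 2) return(0L)
  internal <- res[seq_len(length(res) - 1)]
  sum(vapply(internal, function(r) r$sugar %in% c("ribo", "arabino"),
             logical(1)))
}

#' Enumerate candidate extension products
#'
#' Generates every sugar sequence of added monomers up to `max_depth` at the
#' chain terminus, plus depth-1 internal-branch candidates (addition at a
#' free internal 2'-OH) when the primer has any — suppressed automatically
#' for primers without internal 2'-OH such as a 5'-hexynyl DNA primer with a
#' single 3'-terminal ribonucleotide. Terminal and internal-branch additions
#' of the same monomer are exact isobars; candidates are annotated with an
#' `isobar_group` (masses within 1e-4 Da) and a `sugar_key` (the added-sugar
#' sequence) that defines compound identity for quantification.
#'
#' @param primer An `oligomer_spec`.
#' @param monomers List of `nucleotide_spec` (or shorthand strings) that can
#'   be added.
#' @param max_depth Maximum extension depth (>= 1).
#' @param include_primer Also emit the unextended primer as a depth-0
#'   candidate.
#' @return Data frame of class `candidate_table`: `candidate_id`, `depth`,
#'   `sugar_key`, `terminal_sugar`, `site_class`, `neutral_mass`,
#'   `isobar_group`.
#' @export
enumerate_candidates <- function(primer, monomers, max_depth = 1,
                                 include_primer = TRUE) {
  stopifnot(inherits(primer, "oligomer_spec"), max_depth >= 0)
  monomers <- lapply(monomers, function(m) {
    if (is.character(m)) parse_residue(m) else m
  })
  m <- length(monomers)
  sugar_of <- vapply(monomers, `[[`, character(1), "sugar")
  linkage_mass <- monoisotopic_mass(.H3PO4) - 2 * monoisotopic_mass(.H2O)
  res_mass <- vapply(monomers, function(x) {
    monoisotopic_mass(residue_formula(x))
  }, numeric(1))
  p_mass <- oligomer_mass(primer)

  rows <- list()
  if (include_primer) {
    rows[[1]] <- data.frame(depth = 0L, sugar_key = "",
                            terminal_sugar = NA_character_,
                            site_class = "primer", neutral_mass = p_mass,
                            stringsAsFactors = FALSE)
  }
  if (max_depth >= 1 && m > 0) {
    for (d in seq_len(max_depth)) {
      idx <- do.call(expand.grid, rep(list(seq_len(m)), d))
      for (i in seq_len(nrow(idx))) {
        path <- as.integer(idx[i, ])
        mass <- p_mass + sum(res_mass[path]) + d * linkage_mass
        rows[[length(rows) + 1]] <- data.frame(
          depth = d, sugar_key = paste(sugar_of[path], collapse = ">"),
          terminal_sugar = sugar_of[path[d]], site_class = "terminal",
          neutral_mass = mass, stringsAsFactors = FALSE)
      }
    }
    if (n_internal_2oh(primer) > 0) {
      for (j in seq_len(m)) {
        rows[[length(rows) + 1]] <- data.frame(
          depth = 1L, sugar_key = sugar_of[j], terminal_sugar = sugar_of[j],
          site_class = "internal_branch",
          neutral_mass = p_mass + res_mass[j] + linkage_mass,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$candidate_id <- paste0("c", seq_len(nrow(out)))
  out$isobar_group <- match(round(out$neutral_mass, 4),
                            unique(round(out$neutral_mass, 4)))
  class(out) <- c("candidate_table", "data.frame")
  out[, c("candidate_id", "depth", "sugar_key", "terminal_sugar",
          "site_class", "neutral_mass", "isobar_group")]
}

#' Match compound records to candidate products
#'
#' Each record's neutral mass is tested against every candidate's neutral
#' mass and its sodium-adduct ladder (0..`max_sodium` Na, each +21.98194 Da);
#' the assignment with the smallest absolute ppm error within `tol_ppm`
#' wins. Records equidistant (identical |ppm|) from two candidates with
#' different compound identities (`sugar_key`) are flagged ambiguous and
#' excluded from quantification; ties between exact isobars of the same
#' identity (terminal versus internal-branch addition of the same monomer)
#' are resolved to the terminal candidate and are not ambiguous.
#'
#' @param records Data frame with columns `replicate`, `neutral_mass_da`,
#'   `abundance` (and optionally `rt_min`).
#' @param candidates A [enumerate_candidates()] table.
#' @param tol_ppm Mass tolerance in ppm (default 10, TOF-class).
#' @param max_sodium Depth of the sodium-adduct ladder searched.
#' @return A `match_table`: list with `matches`, `unmatched`, `ambiguous`
#'   data frames. `matches` carries `replicate`, `neutral_mass_da`,
#'   `abundance`, `candidate_id`, `sugar_key`, `depth`, `site_class`,
#'   `n_sodium`, `ppm_error`.
#' @export
match_compounds <- function(records, candidates, tol_ppm = 10,
                            max_sodium = 3) {
  stopifnot(tol_ppm > 0,
            all(c("replicate", "neutral_mass_da", "abundance") %in%
                  names(records)))
  # candidate x adduct ladder
  ladder <- do.call(rbind, lapply(0:max_sodium, function(na) {
    data.frame(candidate_row = seq_len(nrow(candidates)), n_sodium = na,
               mass = candidates$neutral_mass + na * SODIUM_ADDUCT_SHIFT)
  }))
  # prefer terminal over internal_branch at exactly tied ppm
  site_rank <- match(candidates$site_class,
                     c("terminal", "primer", "internal_branch"))

  n <- nrow(records)
  assigned <- integer(n); na_used <- integer(n); ppm <- rep(NA_real_, n)
  ambiguous <- logical(n)
  for (i in seq_len(n)) {
    err <- (records$neutral_mass_da[i] - ladder$mass) / ladder$mass * 1e6
    ok <- which(abs(err) <= tol_ppm)
    if (!length(ok)) next
    best <- ok[abs(err[ok]) == min(abs(err[ok]))]
    keys <- candidates$sugar_key[ladder$candidate_row[best]]
    if (length(unique(keys)) > 1) {
      ambiguous[i] <- TRUE
      next
    }
    best <- best[order(site_rank[ladder$candidate_row[best]])][1]
    assigned[i] <- ladder$candidate_row[best]
    na_used[i] <- ladder$n_sodium[best]
    ppm[i] <- err[best]
  }
  hit <- assigned > 0
  matches <- cbind(
    records[hit, c("replicate", "neutral_mass_da", "abundance"),
            drop = FALSE],
    candidates[assigned[hit],
               c("candidate_id", "sugar_key", "depth", "site_class"),
               drop = FALSE],
    n_sodium = na_used[hit], ppm_error = ppm[hit])
  rownames(matches) <- NULL
  structure(list(matches = matches,
                 unmatched = records[!hit & !ambiguous, , drop = FALSE],
                 ambiguous = records[ambiguous, , drop = FALSE],
                 tol_ppm = tol_ppm),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat(sprintf("<match_table: %d matched, %d unmatched, %d ambiguous (tol %g ppm)>\n",
              nrow(x$matches), nrow(x$unmatched), nrow(x$ambiguous),
              x$tol_ppm))
  invisible(x)
}

#' Normalized incorporation percentages at a given extension depth
#'
#' Within each replicate, abundances of all records assigned to the same
#' compound identity (`sugar_key`) at the requested depth are summed —
#' this folds sodium adducts and doubled chromatographic peaks into their
#' parent compound — and converted to percentages of the replicate total.
#' Percentages are then averaged across replicates (mean and SD). Equal
#' ionization efficiency across same-length oligomers differing in terminal
#' sugar is assumed unless per-key `response_factors` are supplied, in which
#' case summed abundances are divided by the factor before normalization.
#'
#' @param mt A [match_compounds()] result.
#' @param depth Extension depth to quantify (default 1).
#' @param response_factors Optional named numeric vector of relative
#'   ionization response per `sugar_key` (default: all equal).
#' @return A `composition_result` data frame: `sugar_key`, `mean_percent`,
#'   `sd_percent`, `n_replicates`. Means sum to 100.
#' @export
incorporation_percentages <- function(mt, depth = 1,
                                      response_factors = NULL) {
  stopifnot(inherits(mt, "match_table"))
  m <- mt$matches[mt$matches$depth == depth, , drop = FALSE]
  if (!nrow(m)) stop("no matched products at depth ", depth)
  keys <- sort(unique(m$sugar_key))
  rf <- stats::setNames(rep(1, length(keys)), keys)
  if (!is.null(response_factors)) {
    rf[names(response_factors)] <- response_factors
  }
  reps <- split(m, m$replicate)
  pct <- lapply(reps, function(d) {
    tot <- tapply(d$abundance, factor(d$sugar_key, levels = keys), sum,
                  default = 0)
    tot <- tot / rf
    if (sum(tot) <= 0) return(NULL)
    100 * tot / sum(tot)
  })
  dropped <- vapply(pct, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " replicate(s) with zero total abundance dropped")
    pct <- pct[!dropped]
  }
  if (!length(pct)) stop("no replicate with positive abundance at depth ",
                         depth)
  P <- do.call(rbind, pct)
  out <- data.frame(
    sugar_key = keys,
    mean_percent = colMeans(P),
    sd_percent = if (nrow(P) > 1) apply(P, 2, stats::sd) else rep(0, ncol(P)),
    n_replicates = nrow(P),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("composition_result", "data.frame")
  out
}

#' Per-site internal-versus-terminal hydroxyl reactivity
#'
#' Converts total product fractions at internal versus terminal hydroxyls
#' into an average per-site relative reactivity:
#' `r = (f_internal / n_internal) / (f_terminal / n_terminal)`.
#' For an RNA primer with five internal 2'-OH and one terminal 2',3'-diol
#' (two hydroxyls), a 1:1.6 internal:terminal product ratio gives r = 0.25 —
#' internal hydroxyls are on average four-fold less reactive per site.
#'
#' @param f_internal,f_terminal Total product fractions (any common scale);
#'   `f_terminal` must be positive.
#' @param n_internal,n_terminal Numbers of reactive sites of each class.
#' @return Dimensionless per-site relative reactivity.
#' @export
site_reactivity <- function(f_internal, f_terminal, n_internal = 5,
                            n_terminal = 2) {
  stopifnot(f_internal >= 0, n_internal >= 1, n_terminal >= 1)
  if (f_terminal <= 0) stop("f_terminal must be positive")
  (f_internal / n_internal) / (f_terminal / n_terminal)
}

#' Read a vendor-style compound-list CSV
#'
#' Expects columns `replicate`, `neutral_mass_da`, `rt_min`, `abundance`.
#' @param path CSV path.
#' @return Data frame of compound records.
#' @export
read_compound_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate", "neutral_mass_da", "abundance")
  if (!all(need %in% names(rec))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  }
  rec
}
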