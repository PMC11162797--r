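# Seeded synthetic-data generators emulating the study's three measurement
# types: gel-quantified extension time courses (P/P0), NMR-derived species
# concentration series, and deconvoluted LC-MS compound lists. Every
# generator takes an explicit seed, so outputs are byte-reproducible.

#' Generate gel-band extension time courses
#'
#' Draws `p_frac = clip(exp(-H(t)) * (1 + eps), 0, 1)` per sample, with
#' `eps ~ Normal(0, noise_cv)` multiplicative gel-quantification noise and
#' `H(t)` the cumulative hazard of a (possibly piecewise) first-order decay:
#' `k_true` may be a single rate or a vector of per-segment rates with
#' `breaks` giving the interior segment boundaries (hours) — the piecewise
#' form emulates reactions started from pre-formed bridged dinucleotides,
#' fast before and slower after substrate equilibration.
#'
#' @param k_true Rate constant(s) (h^-1); scalar, or one per segment.
#' @param times Sampling times (hours).
#' @param n_reps Number of replicates.
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param breaks Interior segment boundaries (hours) when `k_true` is a
#'   vector; `length(breaks) == length(k_true) - 1`.
#' @return Data frame `replicate`, `t_hours`, `p_frac`.
#' @export
gen_gel_timecourse <- function(k_true, times = 0:8, n_reps = 3,
                               noise_cv = 0.05, seed, breaks = numeric(0)) {
  stopifnot(noise_cv >= 0, all(k_true >= 0),
            length(breaks) == length(k_true) - 1)
  set.seed(seed)
  bounds <- c(0, breaks, Inf)
  cum_hazard <- function(t) {
    sum(k_true * pmax(pmin(t, bounds[-1]) - bounds[-length(bounds)], 0))
  }
  H <- vapply(times, cum_hazard, numeric(1))
  do.call(rbind, lapply(seq_len(n_reps), function(r) {
    eps <- stats::rnorm(length(times), 0, noise_cv)
    data.frame(replicate = paste0("rep", r), t_hours = times,
               p_frac = pmin(pmax(exp(-H) * (1 + eps), 0), 1))
  }))
}

#' Generate an NMR-like species concentration table
#'
#' Runs [simulate_network()] and applies multiplicative noise per
#' observation, emulating integrated 31P NMR peak areas converted to
#' concentrations. With `renormalize_total` set, the noisy nucleotide-unit
#' total (`mono + 2*bridged + nmp` weighted) is rescaled at every time point
#' to the known total — mimicking the common practice of converting peak
#' integrals to concentrations via a known total nucleotide concentration.
#'
#' @param rc [rate_constants()].
#' @param state0 [species_state()].
#' @param times Time grid (hours), starting at 0.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @param renormalize_total Known total nucleotide-unit concentration (mM),
#'   or `NULL` for no renormalization.
#' @return Tidy data frame `t_hours`, `species`, `conc_mM`.
#' @export
gen_species_timecourse <- function(rc, state0, times, noise_cv = 0.03, seed,
                                   renormalize_total = NULL) {
  stopifnot(noise_cv >= 0)
  set.seed(seed)
  net <- build_network(rc)
  tr <- simulate_network(net, state0, times)
  sp <- setdiff(names(tr), "time")
  M <- as.matrix(tr[, sp])
  M <- M * matrix(1 + stats::rnorm(length(M), 0, noise_cv), nrow = nrow(M))
  M[M < 0] <- 0
  if (!is.null(renormalize_total)) {
    w <- nucleotide_unit_weights(net)[sp]
    tot <- as.vector(M %*% w)
    scale <- ifelse(tot > 0, renormalize_total / tot, 1)
    M <- M * scale
  }
  data.frame(t_hours = rep(tr$time, times = length(sp)),
             species = rep(sp, each = nrow(M)),
             conc_mM = as.vector(M))
}

#' Generate a deconvoluted LC-MS compound list
#'
#' Emulates vendor "extracted compound" exports for a +1 competition
#' experiment. Per replicate, true compound fractions are perturbed with a
#' Dirichlet draw (`concentration = dirichlet_conc * true_fractions`, so
#' replicate SDs scale like `sqrt(p(1-p)/(dirichlet_conc+1))`; the default
#' 200 gives ~3.5 percentage points at p = 0.45, matching gel-to-gel
#' variability of the study's six-replicate LC-MS runs), scaled to a total
#' abundance, split across a sodium-adduct series with fixed proportions
#' `adduct_probs` (for 0, 1, 2, ... Na), and each record's neutral mass is
#' jittered multiplicatively with `delta ~ Normal(0, mass_ppm_sd * 1e-6)`.
#'
#' @param true_fractions Named fractions per added sugar (simplex; names
#'   must match the monomer sugars).
#' @param primer An `oligomer_spec`.
#' @param monomers List of monomer `nucleotide_spec`s (or shorthands); the
#'   candidate +1 masses are computed from these.
#' @param n_reps Number of replicates (default 6).
#' @param mass_ppm_sd SD of the relative mass error, ppm.
#' @param adduct_probs Proportions of abundance carried by the 0-, 1-, ...
#'   sodium forms; normalized internally.
#' @param dirichlet_conc Dirichlet concentration scaling replicate noise
#'   (used when `sd_percent` is `NULL`).
#' @param sd_percent Optional named vector of target per-component replicate
#'   SDs in percentage points. When given, replicate compositions are drawn
#'   as truth plus a zero-sum multivariate-Gaussian deviation whose
#'   per-component SDs equal these targets. The zero-sum constraint is
#'   forced by normalization (compositions sum to 100%) and implies the
#'   strong anticorrelation that measured replicate SDs of normalized data
#'   exhibit; no independent-component noise model (including a Dirichlet)
#'   can reproduce such SD sets.
#' @param total_abundance Total abundance per replicate (arbitrary units).
#' @param seed Integer seed.
#' @return Data frame `replicate`, `neutral_mass_da`, `rt_min`, `abundance`.
#' @export
gen_compound_list <- function(true_fractions, primer, monomers, n_reps = 6,
                              mass_ppm_sd = 5,
                              adduct_probs = c(0.7, 0.2, 0.1),
                              dirichlet_conc = 200, sd_percent = NULL,
                              total_abundance = 1e6,
                              seed) {
  stopifnot(abs(sum(true_fractions) - 1) < 0.02, all(true_fractions >= 0),
            mass_ppm_sd >= 0, dirichlet_conc > 0)
  true_fractions <- true_fractions / sum(true_fractions)
  dev_root <- NULL
  if (!is.null(sd_percent)) {
    sd_frac <- sd_percent[names(true_fractions)] / 100
    if (anyNA(sd_frac)) stop("sd_percent must be named by the sugars")
    dev_root <- .zero_sum_gauss_root(sd_frac)
  }
  set.seed(seed)
  cand <- enumerate_candidates(primer, monomers, max_depth = 1,
                               include_primer = FALSE)
  cand <- cand[cand$site_class == "terminal", ]
  if (!setequal(cand$sugar_key, names(true_fractions))) {
    stop("true_fractions names must match the monomer sugars: ",
         paste(cand$sugar_key, collapse = ", "))
  }
  cand <- cand[match(names(true_fractions), cand$sugar_key), ]
  adduct_probs <- adduct_probs / sum(adduct_probs)
  base_rt <- 8 + seq_along(true_fractions) * 0.5  # arbitrary elution order
  rows <- list()
  for (r in seq_len(n_reps)) {
    if (is.null(dev_root)) {
      g <- stats::rgamma(length(true_fractions),
                         shape = dirichlet_conc * true_fractions, rate = 1)
      frac <- if (sum(g) > 0) g / sum(g) else true_fractions
    } else {
      d <- as.vector(dev_root %*% stats::rnorm(ncol(dev_root)))
      frac <- pmax(true_fractions + d, 1e-4)
      frac <- frac / sum(frac)
    }
    for (j in seq_along(true_fractions)) {
      for (a in seq_along(adduct_probs)) {
        ab <- total_abundance * frac[j] * adduct_probs[a]
        if (ab <= 0) next
        true_mass <- cand$neutral_mass[j] + (a - 1) * SODIUM_ADDUCT_SHIFT
        delta <- stats::rnorm(1, 0, mass_ppm_sd * 1e-6)
        rows[[length(rows) + 1]] <- data.frame(
          replicate = paste0("rep", r),
          neutral_mass_da = true_mass * (1 + delta),
          rt_min = base_rt[j] + stats::rnorm(1, 0, 0.05),
          abundance = ab)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Factor root of the zero-sum Gaussian deviation covariance: diagonal s^2,
# rows summing to zero (s on the fraction scale). Off-diagonals follow from
# the row-sum constraint (law-of-cosines form); feasible iff the largest s
# does not exceed the sum of the others. Tiny negative eigenvalues from the
# near-degenerate geometry are clamped to zero.
.zero_sum_gauss_root <- function(s) {
  K <- length(s)
  if (max(s) > sum(s) - max(s) + 1e-12) {
    stop("infeasible SD set: the largest SD exceeds the sum of the others, ",
         "which zero-sum (normalized) deviations cannot satisfy")
  }
  Sigma <- diag(s^2)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i != j && K == 3) {
        k <- setdiff(seq_len(K), c(i, j))
        Sigma[i, j] <- -(s[i]^2 + s[j]^2 - s[k]^2) / 2
      }
    }
  }
  if (K != 3) {
    # general case: project independent deviations onto the zero-sum plane
    # and rescale the diagonal to the targets
    P <- diag(K) - matrix(1 / K, K, K)
    Sigma <- P %*% diag(s^2) %*% P
    dscale <- s / sqrt(pmax(diag(Sigma), 1e-300))
    Sigma <- Sigma * outer(dscale, dscale)
  }
  eg <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  eg$vectors %*% diag(sqrt(vals), nrow = length(vals))
}

# ---- scenario presets ------------------------------------------------------

.PRIMER_RNA6_HEXYNYL <- function() {
  oligomer_spec(rep("rC", 6), five_prime_end = "hexynyl")
}
.PRIMER_DNA_RC_HEXYNYL <- function() {
  # 5'-hexynyl DNA primer with a single 3'-terminal ribonucleotide: no free
  # internal 2'-OH and a blocked 5' end, so only terminal extension occurs
  oligomer_spec(c(rep("dC", 5), "rC"), five_prime_end = "hexynyl")
}
.MONOMERS_LABELED_RIBO <- function() {
  # the ribo monomer carries a uniform 13C/15N label so that ribo and
  # arabino +1 products (otherwise exact epimeric isobars) are separable
  list(parse_residue("13C15N-rC"), parse_residue("araC"),
       parse_residue("tC"))
}

#' Catalog of measurement scenario presets
#'
#' Each preset bundles the generator, its true parameters and the
#' experimental design (replicates, sampling grid, noise) of one of the
#' study conditions:
#'
#' * `competition_1_1_1` — +1 LC-MS competition at equal *rC:*araC:*tC
#'   input, RNA primer; truth (ribo, arabino, threo) = (30.9, 44.7, 24.4)%.
#' * `competition_10_1_1` — as above at 10:1:1 input; truth
#'   (85.8, 8.4, 5.8)%.
#' * `competition_1_1_1_terminalonly` — terminal-diol-only primer
#'   (hexynyl-DNA with 3'-terminal rC); truth (39.0, 45.0, 16.1)%.
#' * `competition_10_1_1_terminalonly` — truth (89.2, 8.3, 2.6)%.
#' * `hydrolysis_NN` — 20 mM bridged dinucleotide decaying by hydrolysis at
#'   0.105 h^-1 (NMR-like series).
#' * `equilibration_monomer` — 20 mM activated monomer equilibrating into a
#'   monomer/bridged mixture (requires a calibrated `k_rev`).
#' * `monomer_plus_2AI` — 20 mM activated monomer with 100 mM added 2AI
#'   (bridged formation suppressed).
#' * `gel_bridged_rCrC` — gel time course starting from 20 mM bridged
#'   substrate: fast initial rate 2.5e-2 h^-1 (0-8 h) then 5e-3 h^-1.
#' * `gel_mono_rC` — gel time course at 5e-3 h^-1 (monomer start).
#' * `pH_series` — *rG gel series at pH 7/8/9, true rates 1.9e-4, 5.3e-4,
#'   8.1e-4 h^-1.
#'
#' @param name Preset name.
#' @return A list with `name`, `kind` (`"gel"`, `"nmr"`, `"lcms"`) and the
#'   generator arguments (minus the seed).
#' @export
scenario_preset <- function(name) {
  presets <- list(
    competition_1_1_1 = list(
      kind = "lcms",
      true_fractions = c(ribo = 0.309, arabino = 0.447, threo = 0.244),
      sd_percent = c(ribo = 1.1, arabino = 3.5, threo = 2.5),
      primer = .PRIMER_RNA6_HEXYNYL(), monomers = .MONOMERS_LABELED_RIBO(),
      n_reps = 6, mass_ppm_sd = 5),
    competition_10_1_1 = list(
      kind = "lcms",
      true_fractions = c(ribo = 0.858, arabino = 0.084, threo = 0.058),
      sd_percent = c(ribo = 1.3, arabino = 0.4, threo = 1.6),
      primer = .PRIMER_RNA6_HEXYNYL(), monomers = .MONOMERS_LABELED_RIBO(),
      n_reps = 6, mass_ppm_sd = 5),
    competition_1_1_1_terminalonly = list(
      kind = "lcms",
      true_fractions = c(ribo = 0.390, arabino = 0.450, threo = 0.161),
      sd_percent = c(ribo = 1.6, arabino = 2.3, threo = 2.3),
      primer = .PRIMER_DNA_RC_HEXYNYL(),
      monomers = .MONOMERS_LABELED_RIBO(), n_reps = 6, mass_ppm_sd = 5),
    competition_10_1_1_terminalonly = list(
      kind = "lcms",
      true_fractions = c(ribo = 0.892, arabino = 0.083, threo = 0.026),
      sd_percent = c(ribo = 0.2, arabino = 0.5, threo = 0.4),
      primer = .PRIMER_DNA_RC_HEXYNYL(),
      monomers = .MONOMERS_LABELED_RIBO(), n_reps = 6, mass_ppm_sd = 5),
    hydrolysis_NN = list(
      kind = "nmr",
      rc = rate_constants(k_form = 0, k_rev = 0, k_hyd_bridged = 0.105,
                          k_hyd_mono = 1.96e-3),
      state0 = species_state(bridged = 20),
      times = seq(0, 24, by = 2), noise_cv = 0.03),
    equilibration_monomer = list(
      kind = "nmr",
      rc = rate_constants(), state0 = species_state(mono = 20),
      times = seq(0, 8, by = 0.5), noise_cv = 0.03),
    monomer_plus_2AI = list(
      kind = "nmr",
      rc = rate_constants(), state0 = species_state(mono = 20, ai = 100),
      times = seq(0, 8, by = 0.5), noise_cv = 0.03),
    gel_bridged_rCrC = list(
      kind = "gel", k_true = c(2.5e-2, 5e-3), breaks = 8,
      times = c(0, 2, 4, 6, 8, 12, 20, 28, 36, 44, 52),
      n_reps = 3, noise_cv = 0.05),
    gel_mono_rC = list(
      kind = "gel", k_true = 5e-3,
      times = c(0, 2, 4, 6, 8, 12, 20, 28, 36, 44, 52),
      n_reps = 3, noise_cv = 0.05),
    # noise_cv for the slow pH-series rates is calibrated to the printed
    # rate uncertainties (SE ~3-6e-5 h^-1), which imply sub-1% effective
    # quantification noise for those experiments
    pH_series = list(
      kind = "gel_series",
      k_true = c(pH7 = 1.9e-4, pH8 = 5.3e-4, pH9 = 8.1e-4),
      times = seq(0, 52, by = 4), n_reps = 3, noise_cv = 0.005)
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  c(list(name = name), presets[[name]])
}

#' Generate data for a named scenario preset
#'
#' @param name Preset name (see [scenario_preset()]).
#' @param seed Integer seed.
#' @param dir Optional directory: when given, the generated tables are also
#'   written as CSV (`<preset>_<seed>.csv`, one per series).
#' @return The generated data frame (for `gel_series` presets, a named list
#'   of data frames, one per condition).
#' @export
generate_scenario <- function(name, seed, dir = NULL) {
  p <- scenario_preset(name)
  out <- switch(p$kind,
    gel = gen_gel_timecourse(p$k_true, p$times, p$n_reps, p$noise_cv,
                             seed = seed,
                             breaks = p$breaks %||% numeric(0)),
    gel_series = {
      res <- list()
      for (i in seq_along(p$k_true)) {
        res[[names(p$k_true)[i]]] <-
          gen_gel_timecourse(p$k_true[[i]], p$times, p$n_reps, p$noise_cv,
                             seed = seed + i)
      }
      res
    },
    nmr = {
      tidy <- gen_species_timecourse(p$rc, p$state0, p$times, p$noise_cv,
                                     seed = seed)
      tidy
    },
    lcms = gen_compound_list(p$true_fractions, p$primer, p$monomers,
                             p$n_reps, p$mass_ppm_sd,
                             sd_percent = p$sd_percent, seed = seed)
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (is.data.frame(out)) {
      utils::write.csv(out, file.path(dir, paste0(name, "_", seed, ".csv")),
                       row.names = FALSE)
    } else {
      for (nm in names(out)) {
        utils::write.csv(out[[nm]],
                         file.path(dir, paste0(name, "_", nm, "_", seed,
                                               ".csv")),
                         row.names = FALSE)
      }
    }
  }
  out
}

#' Run the full +1 competition pipeline on a synthetic scenario
#'
#' Convenience wrapper chaining [generate_scenario()],
#' [enumerate_candidates()], [match_compounds()] and
#' [incorporation_percentages()] — the end-to-end path from simulated
#' vendor export to normalized incorporation percentages.
#'
#' @param name An `lcms` preset name.
#' @param seed Integer seed.
#' @param tol_ppm Matching tolerance (ppm).
#' @return A `composition_result`.
#' @export
run_competition_pipeline <- function(name, seed, tol_ppm = 10) {
  p <- scenario_preset(name)
  if (p$kind != "lcms") stop("preset '", name, "' is not an LC-MS scenario")
  records <- generate_scenario(name, seed)
  cand <- enumerate_candidates(p$primer, p$monomers, max_depth = 1)
  mt <- match_compounds(records, cand, tol_ppm = tol_ppm)
  incorporation_percentages(mt, depth = 1)
}
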