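# Deterministic mass-action model of 2-aminoimidazole (2AI) activation
# chemistry: imidazolium-bridged dinucleotide formation and reversal,
# hydrolysis of both activated species, and primer extension through both
# the bridged and the mononucleotide pathway.
#
# Units are fixed globally: concentrations in mM, time in hours. Species:
#   mono    *N   2AI-activated mononucleotide
#   bridged N*N  imidazolium-bridged dinucleotide (two nucleotide units)
#   nmp     NMP  unactivated nucleoside monophosphate (hydrolysis product)
#   ai      2AI  free 2-aminoimidazole
#   primer  P    unextended primer (uM-scale in practice, but same units)
#   ext1..k P+k  primer extended by k nucleotides

#' Rate constants of the activation-chemistry network
#'
#' Defaults are the measured ribo-cytidine values where available:
#' bridged-dinucleotide formation 4.5e-3 h^-1 mM^-1, bridged hydrolysis
#' 0.105 h^-1 (half-life ~7 h), monomer hydrolysis 1.96e-3 h^-1 (half-life
#' ~350 h). `k_rev` (reversal of bridge formation by 2AI attack) is not
#' directly measured; calibrate it with [calibrate_k_rev()] against the
#' observation that 100 mM added 2AI keeps bridged species below 0.25 mM.
#' The extension constants are pseudo-first-order observed rates divided by
#' the 20 mM substrate concentration at which they were measured.
#'
#' @param k_form Formation, `2 *N -> N*N + 2AI` (h^-1 mM^-1).
#' @param k_rev Reversal, `N*N + 2AI -> 2 *N` (h^-1 mM^-1).
#' @param k_hyd_bridged Bridged hydrolysis, `N*N -> *N + NMP` (h^-1).
#' @param k_hyd_mono Monomer hydrolysis, `*N -> NMP + 2AI` (h^-1).
#' @param k_ext_bridged Extension via bridged substrate,
#'   `P + N*N -> P+1 + *N` (h^-1 mM^-1).
#' @param k_ext_mono Extension via activated monomer,
#'   `P + *N -> P+1 + 2AI` (h^-1 mM^-1).
#' @return A `rate_constants` object (named list).
#' @export
rate_constants <- function(k_form = 4.5e-3, k_rev = 0,
                           k_hyd_bridged = 0.105, k_hyd_mono = 1.96e-3,
                           k_ext_bridged = 1.25e-3, k_ext_mono = 1e-5) {
  rc <- list(k_form = k_form, k_rev = k_rev,
             k_hyd_bridged = k_hyd_bridged, k_hyd_mono = k_hyd_mono,
             k_ext_bridged = k_ext_bridged, k_ext_mono = k_ext_mono)
  if (any(unlist(rc) < 0)) stop("rate constants must be non-negative")
  structure(rc, class = "rate_constants")
}

#' Initial species state
#'
#' @param mono,bridged,nmp,ai,primer Initial concentrations (mM).
#' @param ext Numeric vector of extended-primer concentrations
#'   `P+1, P+2, ...` (mM); its length sets the number of extension levels.
#' @return Named state vector (mM).
#' @export
species_state <- function(mono = 0, bridged = 0, nmp = 0, ai = 0,
                          primer = 0, ext = 0) {
  s <- c(mono = mono, bridged = bridged, nmp = nmp, ai = ai, primer = primer,
         stats::setNames(ext, paste0("ext", seq_along(ext))))
  if (any(s < 0)) stop("concentrations must be non-negative")
  s
}

#' Build the mass-action reaction list
#'
#' Returns the six-reaction network (formation, reversal, bridged hydrolysis,
#' monomer hydrolysis, and primer extension through the bridged and the
#' monomer pathway; extension reactions are replicated per extension level).
#' Each reaction carries integer stoichiometry and a mass-action rate law
#' (constant times the product of reactant concentrations). The nucleotide
#' unit vector (mono 1, bridged 2, nmp 1, P+k adds k) is a left null vector
#' of the stoichiometric matrix, so nucleotide units are conserved.
#'
#' @param rc A [rate_constants()] object.
#' @param n_ext Number of extension levels to track (`P+1 ... P+n_ext`);
#'   the last level is absorbing.
#' @return A `reaction_network`: list of reactions, each with `name`, `k`,
#'   `reactants` (with multiplicity) and `stoich` (named increments).
#' @export
build_network <- function(rc, n_ext = 1) {
  stopifnot(inherits(rc, "rate_constants"), n_ext >= 1)
  species <- names(species_state(ext = numeric(n_ext)))
  rxn <- function(name, k, reactants, stoich) {
    list(name = name, k = k, reactants = reactants, stoich = stoich)
  }
  reactions <- list(
    rxn("formation", rc$k_form, c("mono", "mono"),
        c(mono = -2, bridged = 1, ai = 1)),
    rxn("reversal", rc$k_rev, c("bridged", "ai"),
        c(bridged = -1, ai = -1, mono = 2)),
    rxn("hydrolysis_bridged", rc$k_hyd_bridged, "bridged",
        c(bridged = -1, mono = 1, nmp = 1)),
    rxn("hydrolysis_mono", rc$k_hyd_mono, "mono",
        c(mono = -1, nmp = 1, ai = 1))
  )
  lev <- c("primer", paste0("ext", seq_len(n_ext)))
  for (i in seq_len(n_ext)) {
    from <- lev[i]; to <- lev[i + 1]
    st_b <- stats::setNames(c(-1, 1, -1, 1), c(from, to, "bridged", "mono"))
    st_m <- stats::setNames(c(-1, 1, -1, 1), c(from, to, "mono", "ai"))
    reactions <- c(reactions,
      list(rxn(paste0("extension_bridged_", i), rc$k_ext_bridged,
               c(from, "bridged"), st_b),
           rxn(paste0("extension_mono_", i), rc$k_ext_mono,
               c(from, "mono"), st_m)))
  }
  structure(list(reactions = reactions, species = species, n_ext = n_ext),
            class = "reaction_network")
}

#' Stoichiometric matrix of a network (species x reactions)
#' @param network A `reaction_network`.
#' @return Integer matrix, rows named by species, columns by reactions.
#' @export
stoichiometry_matrix <- function(network) {
  S <- matrix(0, nrow = length(network$species),
              ncol = length(network$reactions),
              dimnames = list(network$species,
                              vapply(network$reactions, `[[`, "", "name")))
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Nucleotide-unit weights per species (left null vector of the stoichiometry)
#' @param network A `reaction_network`.
#' @return Named numeric vector of nucleotide units carried by each species.
#' @export
nucleotide_unit_weights <- function(network) {
  w <- c(mono = 1, bridged = 2, nmp = 1, ai = 0, primer = 0,
         stats::setNames(seq_len(network$n_ext),
                         paste0("ext", seq_len(network$n_ext))))
  w[network$species]
}

#' Integrate the network deterministically
#'
#' Solves the mass-action ODE system with a stiff-capable integrator
#' (`deSolve::lsoda`). For stiff parameter regimes (very fast reversal with
#' large 2AI excess) the default tolerances are tight enough that `lsoda`
#' switches to BDF automatically; if the integrator reports trouble, loosen
#' `rtol`/`atol` or refine the time grid.
#'
#' @param network A [build_network()] result.
#' @param state0 Initial state from [species_state()] (mM).
#' @param times Increasing time grid (hours) starting at 0.
#' @param rtol,atol Integrator tolerances.
#' @return Data frame: `time` plus one column per species (mM).
#' @export
simulate_network <- function(network, state0, times, rtol = 1e-8,
                             atol = 1e-10) {
  stopifnot(inherits(network, "reaction_network"))
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing and start at 0")
  }
  if (!identical(names(state0), network$species)) {
    if (length(setdiff(names(state0), network$species))) {
      stop("state0 has species not in the network")
    }
    full <- stats::setNames(numeric(length(network$species)),
                            network$species)
    full[names(state0)] <- state0
    state0 <- full
  }
  S <- stoichiometry_matrix(network)
  ks <- vapply(network$reactions, `[[`, numeric(1), "k")
  reactant_idx <- lapply(network$reactions, function(r) {
    match(r$reactants, network$species)
  })
  deriv <- function(t, y, parms) {
    yc <- pmax(y, 0)  # guard tiny negative excursions inside the stepper
    v <- ks * vapply(reactant_idx, function(ix) prod(yc[ix]), numeric(1))
    list(as.vector(S %*% v))
  }
  out <- deSolve::lsoda(y = state0, times = times, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed (istate = ", attr(out, "istate")[1],
         "); consider loosening tolerances or refining the grid")
  }
  as.data.frame(out)
}

#' Quasi-steady-state bridged-dinucleotide concentration
#'
#' Solves the balance `formation = reversal + hydrolysis` for the bridged
#' concentration `b` under the fast-subsystem mass balance
#' `*N + 2 N*N = total` and free 2AI = `added_2AI + b` (one 2AI released per
#' bridge formed):
#' `k_form (total - 2b)^2 = k_rev b (added_2AI + b) + k_hyd_bridged b`.
#' With zero hydrolysis this is the true detailed-balance equilibrium and
#' agrees with the long-time trajectory; with hydrolysis it is the
#' quasi-steady plateau that the trajectory visits before the slow decay of
#' the total activated pool.
#'
#' @param rc A [rate_constants()] object.
#' @param total_nucleotide Total nucleotide units in the activated pool (mM).
#' @param added_2AI Initially added free 2AI (mM).
#' @return Bridged-dinucleotide concentration (mM) in `[0, total/2]`.
#' @export
steady_state_bridged <- function(rc, total_nucleotide, added_2AI = 0) {
  stopifnot(total_nucleotide >= 0, added_2AI >= 0)
  if (rc$k_form == 0 || total_nucleotide == 0) return(0)
  g <- function(b) {
    rc$k_form * (total_nucleotide - 2 * b)^2 -
      rc$k_rev * b * (added_2AI + b) - rc$k_hyd_bridged * b
  }
  hi <- total_nucleotide / 2
  if (g(hi) > 0) return(hi)  # no loss terms: fully bridged
  r <- stats::uniroot(g, c(0, hi), tol = 1e-12)
  if (is.na(r$root)) stop("no quasi-steady root found in [0, total/2]")
  r$root
}

#' Calibrate the bridge-reversal constant against 2AI suppression
#'
#' Finds, by bisection, the smallest `k_rev` such that a reaction started
#' from `mono0` mM activated monomer with `added_2AI` mM free 2AI never
#' accumulates more than `bound` mM of bridged dinucleotide. This encodes
#' the observation that 100 mM added 2AI keeps bridged species below
#' 0.25 mM when starting from 20 mM activated monomer.
#'
#' @param rc Rate constants; `k_rev` is ignored and replaced.
#' @param mono0 Initial activated-monomer concentration (mM).
#' @param added_2AI Added free 2AI (mM).
#' @param bound Maximum tolerated bridged concentration (mM).
#' @param t_max,dt Simulation horizon and grid step (hours).
#' @param tol Relative bisection tolerance on `k_rev`.
#' @return Calibrated `k_rev` (h^-1 mM^-1).
#' @export
calibrate_k_rev <- function(rc, mono0 = 20, added_2AI = 100, bound = 0.25,
                            t_max = 50, dt = 0.25, tol = 1e-4) {
  times <- seq(0, t_max, by = dt)
  peak_bridged <- function(k_rev) {
    rc2 <- rate_constants(rc$k_form, k_rev, rc$k_hyd_bridged, rc$k_hyd_mono,
                          rc$k_ext_bridged, rc$k_ext_mono)
    net <- build_network(rc2)
    tr <- simulate_network(net, species_state(mono = mono0, ai = added_2AI),
                           times)
    max(tr$bridged)
  }
  lo <- 0; hi <- 1
  while (peak_bridged(hi) > bound) hi <- hi * 2
  if (peak_bridged(lo) <= bound) return(lo)
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (peak_bridged(mid) > bound) lo <- mid else hi <- mid
  }
  hi
}

#' First-order half-life
#'
#' @param k First-order rate constant (h^-1), must be positive.
#' @return Half-life in hours, `ln(2)/k`.
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("half_life requires k > 0")
  log(2) / k
}

#' Read rate constants and an initial state from a YAML/JSON-style list
#'
#' @param path JSON file with fields `rate_constants` (named list) and
#'   `state0` (named list).
#' @return List with `rc` and `state0` ready for [simulate_network()].
#' @export
read_network_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  rc <- do.call(rate_constants, as.list(x$rate_constants))
  st <- do.call(species_state, as.list(x$state0))
  list(rc = rc, state0 = st)
}
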