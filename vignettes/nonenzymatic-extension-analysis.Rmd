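---
title: "Models and methods: non-templated primer extension with mixed-sugar activated nucleotides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: non-templated primer extension with mixed-sugar activated nucleotides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primext)
```

## The chemistry being modeled

Before enzymes, oligonucleotides must have grown by spontaneous,
template-free chemistry. `primext` analyzes the quantitative side of that
process for pools of 2-aminoimidazole (2AI)-activated ribo-, arabino- and
threo-nucleotides (`*N`): how fast a primer extends, through which
substrate, and which sugar ends up incorporated when several compete.

Two activated substrates matter. Activated mononucleotides `*N` can react
with each other to form 5′-5′ (for threo, 3′-3′) imidazolium-bridged
dinucleotides `N*N`, and both species can add a nucleotide to a primer's
terminal hydroxyls. The bridged species is by far the better electrophile —
its leaving group needs no protonation — so the observable extension rate
tracks the bridged concentration, which is itself set by a tug-of-war
between formation, reversal by free 2AI, and hydrolysis.

The package has five analysis layers, each usable on its own:

1. a **mass engine** for chimeric RNA/ANA/TNA/DNA oligomers
   (`residue_formula()`, `oligomer_formula()`, `adducted_mz()`);
2. a **mass-action network simulator** for the activation chemistry
   (`build_network()`, `simulate_network()`, `steady_state_bridged()`);
3. **rate estimation** from gel time courses and concentration series
   (`fit_kobs()`, `fit_decay()`, `fold_ratio()`);
4. **LC–MS product matching and quantification**
   (`enumerate_candidates()`, `match_compounds()`,
   `incorporation_percentages()`, `site_reactivity()`);
5. a **chain-growth competition model** (`propensity_model()`,
   `enumerate_products()`, `sample_chains()`).

A sixth layer, the synthetic-data generators (`gen_gel_timecourse()`,
`gen_species_timecourse()`, `gen_compound_list()`, `scenario_preset()`),
emulates the three measurement types so every stage can be exercised and
tested end to end with no instrument data.

## The mass engine

Identification of extension products rests entirely on neutral
monoisotopic mass. Residues are described by base, sugar family and
isotope label; sugar families are composition offsets from the
ribonucleoside: arabino is the 2′-epimer of ribo and therefore **exactly
isobaric** with it; threo lacks the 5′-methylene carbon, so every threo
residue is one CH2 (14.01565 Da) lighter; deoxyribo and dideoxy drop one
and two oxygens. A chain is the sum of its free nucleosides plus one
H3PO4 and minus two H2O per internucleotide linkage, with 5′-end
adjustments for hexynyl or phosphate caps. Because a branched product
(addition at an internal 2′-OH) gains one residue and one linkage just as
terminal extension does, branching never changes mass — which is exactly
why the analysis treats site class as an annotation, never as a mass
discriminant, and why linkage regiochemistry (2′-5′ versus 3′-5′, TNA's
3′→2′) is metadata only.

The ribo/arabino isobarity would make the central competition experiment
unanalyzable, so the experimental design is encoded in the presets: the
ribo monomer carries a uniform ¹³C/¹⁵N label, displacing it by ≥ 9 Da from
the unlabeled arabino product for every base (+12.0213 Da for cytidine).
Atomic monoisotopic masses are pinned to IUPAC/AME values in
`ATOMIC_MASSES` so candidate masses are bit-reproducible. Negative-mode
spectra are handled by the deprotonation series
`m/z = (M + n_Na (m_Na − m_H) − z m_p)/z`; sodium is the only adduct series
implemented (the measurements report unspeciated "salt adducts";
potassium would be a one-line extension).

## The activation-chemistry network

Six irreversible mass-action reactions, in mM and hours:

| reaction | rate law | default constant |
|---|---|---|
| 2 `*N` → `N*N` + 2AI | `k_form [*N]²` | 4.5e-3 h⁻¹mM⁻¹ |
| `N*N` + 2AI → 2 `*N` | `k_rev [N*N][2AI]` | calibrated (see below) |
| `N*N` → `*N` + NMP | `k_hyd_bridged [N*N]` | 0.105 h⁻¹ |
| `*N` → NMP + 2AI | `k_hyd_mono [*N]` | 1.96e-3 h⁻¹ |
| P + `N*N` → P₊₁ + `*N` | `k_ext_bridged [P][N*N]` | 1.25e-3 h⁻¹mM⁻¹ |
| P + `*N` → P₊₁ + 2AI | `k_ext_mono [P][*N]` | 1e-5 h⁻¹mM⁻¹ |

Formation is modeled second-order in `*N` because its measured constant
carries the bimolecular unit h⁻¹ mM⁻¹. The extension defaults are derived
from observed pseudo-first-order rates at 20 mM substrate:
`2.5e-2 h⁻¹ / 20 mM` for the bridged pathway, and an upper-bound-consistent
`1e-5 h⁻¹ mM⁻¹` for the monomer pathway (extension with monomer alone
under excess 2AI sits below the 2e-4 h⁻¹ gel detection floor at 20 mM).
Primer concentrations are a thousandfold below monomer concentrations, so
extension never perturbs the monomer pools measurably, but it is modeled
explicitly so that nucleotide-unit conservation can be asserted exactly:
the weight vector (1 per `*N` and NMP, 2 per `N*N`, k per P₊ₖ) is a left
null vector of the stoichiometric matrix, and trajectories conserve it to
better than 1e-9 relative with the default integrator tolerances
(`deSolve::lsoda`, rtol 1e-8, atol 1e-10).

`k_rev` is not directly measured. It is calibrated once, by bisection, as
the smallest value for which a mixture of 20 mM `*N` and 100 mM added 2AI
never accumulates more than 0.25 mM of bridged dinucleotide — the
suppression observed experimentally. With that calibrated value
(≈ 0.067 h⁻¹ mM⁻¹), integrating from 20 mM `*N` with no added 2AI drives
the bridged species to a quasi-steady plateau of ≈ 2.6 mM, consistent with
the ~3 mM equilibration observed by ³¹P NMR, followed by the slow decline
that hydrolysis imposes.

`steady_state_bridged()` solves the algebraic balance
`k_form (total − 2b)² = k_rev b (2AI₀ + b) + k_hyd_bridged b` on
`[0, total/2]`. Two caveats are deliberate. First, with nonzero hydrolysis
nothing is truly stationary — the whole activated pool decays — so the
root is a *quasi*-steady value that matches the trajectory's plateau, not
its (zero) long-time limit; the exact-agreement regime is the
hydrolysis-free detailed-balance case, which the tests verify to 1e-6 mM
against long simulations. Second, free 2AI at the plateau is approximated
as `added + b` (one 2AI released per bridge formed); the small additional
release from monomer hydrolysis is negligible on the equilibration
timescale. pH is not a state variable: the pH dependence of extension
enters as different `rate_constants()` sets, mirroring how it was
measured.

## Rate estimation

Extension kinetics arrive as gel-band fractions `P/P0` over time.
`fit_kobs()` regresses `ln(P/P0)` on time with a free intercept, per
replicate, and reports `k_obs = −mean(slopes)` with the across-replicate
standard error — the pseudo-first-order reading of "linear least-square
fits". The raw-fraction alternative (initial slope) is available behind
`space = "linear"` because the published description does not fix the
functional form; log space is the default since the reported quantities
are pseudo-first-order constants. The free intercept absorbs constant
quantification offsets (including the small negative bias that clipping
`P/P0` at 1 introduces near t = 0). Gel noise handling is explicit:
values above 1 are clipped, non-positive values are dropped with a
warning, and estimates below 2e-4 h⁻¹ — the floor implied by a 52-hour
window on this assay — carry a `below_floor` flag. `windowed_rates()`
applies the same fit to disjoint windows (0–8 h versus 8–52 h), which is
how fast-then-slow kinetics of bridged-substrate reactions are resolved;
`fit_decay()` is the same log-linear machinery for NMR-derived
concentration series, returning `ln 2 / k` half-lives.

## LC–MS matching and quantification

`enumerate_candidates()` builds every added-sugar sequence up to the
requested depth at the chain terminus and, when the primer has free
internal 2′-OH groups, depth-1 internal-branch candidates. The two site
classes are exact isobars, so records are assigned to a *compound
identity* (the added-sugar sequence); retention time is never used for
identity, and co-eluting or doubled peaks simply sum. `match_compounds()`
tests each record against each candidate's neutral mass and sodium-adduct
ladder and keeps the best match within the ppm tolerance (default 10 ppm,
TOF-class accuracy). Ties between candidates of different identity are
flagged ambiguous and excluded; ties between same-identity isobars resolve
to the terminal candidate. `incorporation_percentages()` then normalizes
summed per-identity abundances within each replicate — valid under the
stated equal-ionization assumption for same-length oligomers, with a
per-sugar response-factor override for sensitivity analysis — and averages
across replicates. Means always sum to 100% per depth.

`site_reactivity()` is the small deconvolution used for branching: if a
fraction `f_int` of products formed at `n_int` internal hydroxyls and
`f_term` at `n_term` terminal ones, the average per-site relative
reactivity is `(f_int/n_int)/(f_term/n_term)`. The measured 1:1.6
internal:terminal ratio over 5 internal and 2 terminal sites gives 25%;
with a complementary strand pairing down the internal sites (21%:79%) it
falls to ~10.6%.

## Chain growth and competition

`propensity_model()` captures the minimal memoryless picture: one
dimensionless incorporation weight per sugar and one extendability per
terminal sugar. Step fractions are `f_i = w_i x_i / Σ w_j x_j`, so equal
weights reproduce the null model in which products mirror the input pool.
`fit_weights()` inverts this exactly. The observed equal-pool composition
(30.9/44.7/24.4% for ribo/arabino/threo) fitted this way predicts an
81.7% ribo share at a 10:1:1 pool — within five points of the observed
85.8% — which is the quantitative content of the "products mirror inputs,
with a bias against threo" conclusion.

Extendability encodes chain termination: an arabino 3′-terminus blocks
further extension (e = 0, so no sequence ever continues past arabino), a
ribo terminus extends freely (e = 1), and threo defaults to e = 0.17 —
the ~6-fold rate penalty of the slowest versus fastest activated
guanosine monomer mapped onto a relative extendability, exposed in the
model object because it is an assumption, not a measurement.
`enumerate_products()` computes the exact distribution over added-sugar
sequences (terminated chains are a reported outcome class, not
renormalized away, since gels and LC–MS observe them);
`conditional_composition()` restricts to a given length, reproducing the
observed +2 ranking (ribo-ribo first, ribo-then-arabino second, the
arabino necessarily last because of termination). `sample_chains()` is
the seeded Monte-Carlo twin, used in tests to bound the total-variation
distance against the exact enumeration. Whether the measured +2 profile
conditions on all +2 species or only ribo-first ones is not documented;
both views are computable, which is why the conditional helper exists.

## What the synthetic data emulates — and what it does not

The generators reproduce the *statistical structure* of the three
measurement types, not the instruments:

* **Gel time courses**: multiplicative Gaussian noise (CV 5% by default)
  on an exponential or piecewise-exponential decay, clipped to [0, 1].
  The piecewise preset (`gel_bridged_rCrC`: 2.5e-2 h⁻¹ before 8 h,
  5e-3 h⁻¹ after — the later-window value is a generator choice set to the
  printed monomer-start rate, since no later-window constant is printed)
  emulates substrate equilibration. The pH-series preset uses CV 0.5%,
  calibrated to the printed pH-rate uncertainties (SE 3–6e-5 h⁻¹), which
  a 5% gel CV would be inconsistent with by an order of magnitude.
* **NMR-like series**: the ODE solution with multiplicative noise and an
  optional exact renormalization of the nucleotide-unit total to the known
  input concentration, as peak integrals are converted in practice.
* **LC–MS compound lists**: per-replicate compositions around the preset
  truth, split over a sodium-adduct series (70/20/10%), with per-record
  relative mass error (Normal, SD 5 ppm). For the competition presets the
  replicate noise is a zero-sum Gaussian whose per-sugar SDs equal the
  printed replicate SDs. A plain Dirichlet is available
  (`dirichlet_conc`), but no independent-component model can reproduce the
  printed SD sets: compositions sum to 100%, so the printed
  (1.1, 3.5, 2.5) pattern forces a deviation correlation near −1 between
  the arabino and threo components, and the zero-sum construction encodes
  that constraint directly (its covariance has the printed variances on
  the diagonal and off-diagonals fixed by the row-sum-zero condition).

Passing the recovery tests therefore shows that the pipeline is unbiased
and correctly calibrated *under these noise models*. It does not validate
peak picking, deconvolution, ionization-efficiency equality, retention
behavior, or gel densitometry — all of which live upstream of the
package's inputs. One consequence worth knowing: with 5 ppm mass error
and a 10 ppm matching window, roughly 5% of generated records fall
outside the window and are correctly reported unmatched; when such a
record carries a dominant compound's parent peak, that replicate's
normalized composition shifts by several points. Real analyses would
inspect the unmatched list and widen the window or recalibrate; the
defaults here keep the documented 2-sigma window.

## Numerical choices and degenerate inputs

* Times and concentrations are hours and mM throughout; rescaling time
  rescales fitted rates exactly (tested).
* `lsoda` defaults rtol 1e-8 / atol 1e-10; a tiny `pmax(y, 0)` guard
  inside the derivative prevents negative-concentration rate evaluations
  during stepping. Integration failures surface as errors with the
  integrator state.
* `calibrate_k_rev()` bisects to a relative width of 1e-4 and returns the
  upper end of the bracket, i.e. the smallest constant satisfying the
  bound on the simulated grid (0.25 h steps).
* Log-linear fits require ≥ 3 positive in-window samples per replicate; a
  fitted decay slope below 1e-10 h⁻¹ reports `k = 0` with infinite
  half-life rather than a meaningless ~1e-17 from floating-point noise.
* `fit_kobs()` reports `max(−mean(slope), 0)`: negative point estimates
  (pure noise at sub-floor rates) are truncated to the physical boundary
  and flagged `below_floor`.
* Matching ties at *identical* ppm across different identities are
  excluded rather than guessed; the candidate sets are designed (isotope
  label, CH2 offset) so this occurs only for true epimers on unlabeled
  pools.
* The zero-sum noise covariance is near-singular by construction (its
  rows sum to zero); eigenvalues below 0 from rounding are clamped.

## Problem sizes used in the shipped tests

The test-suite and acceptance computations use the study's designs
directly: 3 gel replicates over 9–14 time points, 6 LC–MS replicates of
~9 compound records, 13-point decay series, ODE grids of 100–400 points,
Monte-Carlo samples of 1e4–2e4 chains, and 100–200-dataset property
sweeps for estimator bias. All of it runs in well under a minute on a
single core.

## Known limitations

* Hetero-bridged dinucleotides (e.g. `rN*tN`), invoked qualitatively to
  explain the softened anti-threo bias in mixtures, have no measured rate
  constants; the network ships no defaults for them.
* Dry-down (evaporative concentration) is represented only as an
  effective-rate multiplier on presets, not as time-dependent volume
  dynamics.
* The chain-growth model is memoryless in the terminal sugar; longer-range
  sequence effects, branched-product placement, and time-resolved coupling
  to the monomer pools are out of scope.
* Isotope fine structure, MS/MS fragmentation and retention-time
  prediction are out of scope; identity rests on monoisotopic mass alone.
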