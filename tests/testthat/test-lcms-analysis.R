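# Candidate enumeration, ppm matching, normalized incorporation, and
# internal-versus-terminal hydroxyl reactivity.

LAB_MONOMERS <- list(parse_residue("13C15N-rC"), parse_residue("araC"),
                     parse_residue("tC"))
DNA_RC_PRIMER <- oligomer_spec(c(rep("dC", 5), "rC"),
                               five_prime_end = "hexynyl")
RNA6_PRIMER <- oligomer_spec(rep("rC", 6), five_prime_end = "hexynyl")

test_that("candidate counts follow the enumeration combinatorics", {
  # terminal-only primer (no free internal 2'-OH): 3 monomers, depth 1
  c1 <- enumerate_candidates(DNA_RC_PRIMER, LAB_MONOMERS, max_depth = 1,
                             include_primer = FALSE)
  expect_equal(nrow(c1), 3)
  expect_true(all(c1$site_class == "terminal"))
  # depth 2: 3 + 9 sequences
  c2 <- enumerate_candidates(DNA_RC_PRIMER, LAB_MONOMERS, max_depth = 2,
                             include_primer = FALSE)
  expect_equal(nrow(c2), 12)
  expect_equal(sum(c2$depth == 2), 9)
  # RNA 6-mer with 5 internal 2'-OH: 3 terminal + 3 internal-branch
  c3 <- enumerate_candidates(RNA6_PRIMER, LAB_MONOMERS, max_depth = 1,
                             include_primer = FALSE)
  expect_equal(n_internal_2oh(RNA6_PRIMER), 5L)
  expect_equal(sum(c3$site_class == "terminal"), 3)
  expect_equal(sum(c3$site_class == "internal_branch"), 3)
  # terminal and branch additions of the same monomer are exact isobars
  for (key in unique(c3$sugar_key)) {
    grp <- c3$isobar_group[c3$sugar_key == key]
    expect_length(unique(grp), 1)
  }
})

test_that("isotope labeling separates every +1 candidate pair by more than 5 ppm", {
  cand <- enumerate_candidates(RNA6_PRIMER, LAB_MONOMERS, max_depth = 1,
                               include_primer = FALSE)
  keys <- unique(cand$sugar_key)
  masses <- vapply(keys, function(k) {
    cand$neutral_mass[cand$sugar_key == k][1]
  }, numeric(1))
  for (i in seq_along(masses)) {
    for (j in seq_along(masses)) {
      if (i < j) {
        ppm <- abs(masses[i] - masses[j]) / masses[j] * 1e6
        expect_gt(ppm, 5)
      }
    }
  }
})

test_that("records are assigned by best ppm within tolerance, adducts included", {
  cand <- enumerate_candidates(DNA_RC_PRIMER, LAB_MONOMERS, max_depth = 1,
                               include_primer = FALSE)
  m_ara <- cand$neutral_mass[cand$sugar_key == "arabino"]
  rec <- data.frame(
    replicate = "r1",
    neutral_mass_da = c(m_ara,                      # exact hit
                        m_ara * (1 + 20e-6),        # 20 ppm off: unmatched
                        m_ara - 14.0157,            # the threo candidate
                        m_ara + 21.98194),          # arabino + 1 Na
    abundance = c(10, 10, 10, 5))
  mt <- match_compounds(rec, cand, tol_ppm = 10)
  expect_equal(nrow(mt$matches), 3)
  expect_equal(mt$matches$ppm_error[1], 0)
  expect_equal(nrow(mt$unmatched), 1)
  expect_equal(mt$matches$sugar_key[mt$matches$neutral_mass_da ==
                                      rec$neutral_mass_da[3]], "threo")
  na_row <- mt$matches[mt$matches$n_sodium == 1, ]
  expect_equal(na_row$sugar_key, "arabino")
})

test_that("exact isobars of different identity are flagged ambiguous, same identity are not", {
  # unlabeled ribo and arabino monomers: epimeric +1 products, identical mass
  cand <- enumerate_candidates(DNA_RC_PRIMER,
                               list(parse_residue("rC"),
                                    parse_residue("araC")),
                               max_depth = 1, include_primer = FALSE)
  rec <- data.frame(replicate = "r1",
                    neutral_mass_da = cand$neutral_mass[1], abundance = 1)
  mt <- match_compounds(rec, cand)
  expect_equal(nrow(mt$ambiguous), 1)
  expect_equal(nrow(mt$matches), 0)
  # terminal vs internal-branch isobars share identity: resolved, not flagged
  cand2 <- enumerate_candidates(RNA6_PRIMER, LAB_MONOMERS, max_depth = 1,
                                include_primer = FALSE)
  rec2 <- data.frame(replicate = "r1",
                     neutral_mass_da =
                       cand2$neutral_mass[cand2$sugar_key == "threo"][1],
                     abundance = 1)
  mt2 <- match_compounds(rec2, cand2)
  expect_equal(nrow(mt2$matches), 1)
  expect_equal(mt2$matches$site_class, "terminal")
})

test_that("matching is permutation-invariant in record order", {
  rec <- generate_scenario("competition_1_1_1", seed = 9)
  cand <- enumerate_candidates(RNA6_PRIMER, LAB_MONOMERS, max_depth = 1)
  mt1 <- match_compounds(rec, cand)
  set.seed(1)
  perm <- sample(nrow(rec))
  mt2 <- match_compounds(rec[perm, ], cand)
  res1 <- incorporation_percentages(mt1)
  res2 <- incorporation_percentages(mt2)
  expect_equal(res1$mean_percent, res2$mean_percent, tolerance = 1e-12)
})

test_that("incorporation percentages normalize abundances per replicate", {
  cand <- enumerate_candidates(DNA_RC_PRIMER, LAB_MONOMERS, max_depth = 1,
                               include_primer = FALSE)
  # one replicate at the observed 1:1:1 competition abundances
  rec <- data.frame(replicate = "r1",
                    neutral_mass_da = cand$neutral_mass,
                    abundance = c(30.9, 44.7, 24.4)[
                      match(cand$sugar_key, c("ribo", "arabino", "threo"))])
  mt <- match_compounds(rec, cand)
  res <- incorporation_percentages(mt, depth = 1)
  expect_equal(res$mean_percent[res$sugar_key == "ribo"], 30.9)
  expect_equal(res$mean_percent[res$sugar_key == "arabino"], 44.7)
  expect_equal(res$mean_percent[res$sugar_key == "threo"], 24.4)
  expect_equal(sum(res$mean_percent), 100, tolerance = 1e-9)
  # sodium-adduct records fold back into their parent compound
  rec_split <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    data.frame(replicate = "r1",
               neutral_mass_da = rec$neutral_mass_da[i] +
                 c(0, 1, 2) * SODIUM_ADDUCT_SHIFT,
               abundance = rec$abundance[i] * c(0.7, 0.2, 0.1))
  }))
  res_split <- incorporation_percentages(match_compounds(rec_split, cand))
  expect_equal(res_split$mean_percent, res$mean_percent, tolerance = 1e-9)
})

test_that("zero-abundance replicates are dropped with a warning", {
  cand <- enumerate_candidates(DNA_RC_PRIMER, LAB_MONOMERS, max_depth = 1,
                               include_primer = FALSE)
  rec <- data.frame(replicate = c("r1", "r1", "r2"),
                    neutral_mass_da = cand$neutral_mass[c(1, 2, 1)],
                    abundance = c(3, 1, 0))
  expect_warning(res <- incorporation_percentages(match_compounds(rec, cand)),
                 "zero total abundance")
  expect_equal(res$n_replicates[1], 1L)
})

test_that("per-sugar response factors rescale the composition", {
  cand <- enumerate_candidates(DNA_RC_PRIMER, LAB_MONOMERS, max_depth = 1,
                               include_primer = FALSE)
  rec <- data.frame(replicate = "r1", neutral_mass_da = cand$neutral_mass,
                    abundance = c(1, 1, 1))
  mt <- match_compounds(rec, cand)
  equal <- incorporation_percentages(mt)
  expect_equal(equal$mean_percent, rep(100 / 3, 3), tolerance = 1e-9)
  # a sugar ionizing twice as efficiently is halved before normalization
  adj <- incorporation_percentages(mt, response_factors = c(ribo = 2))
  expect_equal(adj$mean_percent[adj$sugar_key == "ribo"], 20, tolerance = 1e-9)
})

test_that("pipeline recovers true compositions, tighter with more replicates", {
  truth <- c(ribo = 0.309, arabino = 0.447, threo = 0.244)
  run_n <- function(n, seed) {
    rec <- gen_compound_list(truth, RNA6_PRIMER, LAB_MONOMERS, n_reps = n,
                             mass_ppm_sd = 5, seed = seed)
    cand <- enumerate_candidates(RNA6_PRIMER, LAB_MONOMERS, max_depth = 1)
    res <- incorporation_percentages(match_compounds(rec, cand))
    dev <- abs(res$mean_percent[match(names(truth), res$sugar_key)] -
                 100 * truth)
    max(dev)
  }
  expect_lt(run_n(6, 31), 6)
  expect_lt(run_n(60, 31), 1.8)
})

test_that("site reactivity deconvolution reproduces the printed per-site ratios", {
  # 1 : 1.6 internal:terminal over 5 vs 2 sites -> 25% per-site reactivity
  expect_equal(site_reactivity(1, 1.6, 5, 2), 0.25, tolerance = 1e-12)
  # with a complementary oligomer: 21% vs 79% -> ~10.6%, printed as 10(1)%
  expect_equal(site_reactivity(0.21, 0.79, 5, 2), 0.106, tolerance = 0.005)
  # equal per-site reactivity input returns exactly 1
  expect_equal(site_reactivity(5, 2, 5, 2), 1)
  expect_error(site_reactivity(1, 0), "positive")
})
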