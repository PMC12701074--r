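# Elemental-composition and fragment-mass model.

ppm_between <- function(obs, theo) abs(obs - theo) / theo * 1e6

test_that("composition masses match standard monoisotopic constants", {
  expect_identical(composition_mass(""), 0)
  expect_equal(composition_mass("H2O"), 18.010565, tolerance = 1e-6)
  # the RSOH neutral loss from oxidized carbamidomethyl cysteine
  expect_equal(composition_mass("C2H5NO2S"), 107.004099, tolerance = 1e-6)
  expect_error(composition_mass("Xx2"), "unknown element")
})

test_that("composition arithmetic is commutative and mass is linear", {
  a <- parse_composition("C2H5NO2S")
  b <- parse_composition("H2O")
  s1 <- composition_sum(a, b)
  s2 <- composition_sum(b, a)
  expect_equal(composition_mass(s1), composition_mass(s2))
  expect_equal(composition_mass(s1), composition_mass(a) + composition_mass(b),
               tolerance = 1e-12)
  # net losses are representable
  expect_lt(composition_mass(c(H = -2, S = -1)), 0)
})

test_that("peptide neutral masses agree with an independent calculator", {
  # frozen from pyteomics mass.calculate_mass on the same sequences
  expect_equal(peptide_neutral_mass(peptide("G")), 75.032028, tolerance = 1e-5)
  expect_equal(peptide_neutral_mass(peptide("SAKAYEHR", nterm = "acetyl")),
               1002.488293, tolerance = 1e-5)
  expect_equal(peptide_neutral_mass(peptide("LADVCAHER", nterm = "acetyl")),
               1054.486579, tolerance = 1e-5)
  expect_error(peptide("SAB1"), "unknown residue")
  expect_error(peptide("GAK", mods = data.frame(pos = 9, mod = "oxidation")),
               "out of range")
})

test_that("remnant arithmetic satisfies the cleavage identities for every linker", {
  for (lname in c("SIA", "SIAB", "SBAP")) {
    r <- remnants_for(lname)
    expect_equal(r$alpha_S_mod + r$beta_A_mod, r$intact_ox_addition,
                 tolerance = 1e-12)
    expect_equal(r$alpha_T_mod, r$alpha_S_mod - 18.010565, tolerance = 1e-6)
    # the sulfur leaves with the alpha fragment: beta_A is linker-independent
    expect_equal(r$beta_A_mod, -33.987721, tolerance = 1e-6)
  }
  r <- remnants_for("SIA")
  expect_equal(r$intact_ox_addition, 55.9898, tolerance = 1e-4)
  expect_equal(r$alpha_S_mod, 89.9775, tolerance = 1e-4)
  expect_equal(remnants_for("SBAP")$intact_ox_addition, 127.0269,
               tolerance = 1e-4)
})

test_that("printed worked-example m/z values reproduce within 10 ppm", {
  observed <- list(
    SIA  = list(prec = 529.2494, aS = 547.2418, bA = 511.2581),
    SIAB = list(prec = 559.0103, aS = 606.7592, bA = 511.2569),
    SBAP = list(prec = 547.0079, aS = 582.7581, bA = 511.2558)
  )
  for (lname in names(observed)) {
    pair <- fig2_pair(lname)
    o <- observed[[lname]]
    expect_lt(ppm_between(o$prec, precursor_mz(pair, 4)), 10)
    sig <- signature_fragment_mzs(pair)
    expect_lt(ppm_between(o$aS, sig$mz[sig$fragment == "alpha_S"]), 10)
    expect_lt(ppm_between(o$bA, sig$mz[sig$fragment == "beta_A"]), 10)
  }
})

test_that("signature fragments conserve mass exactly for random pairs", {
  set.seed(42)
  aas <- names(kcxlink:::AA_COMPOSITION)
  for (i in 1:25) {
    for (lname in c("SIA", "SIAB", "SBAP")) {
      sa <- paste(c(sample(aas, 6, TRUE), "K",
                    sample(aas, 2, TRUE)), collapse = "")
      sb <- paste(c(sample(aas, 3, TRUE), "C",
                    sample(aas, 4, TRUE)), collapse = "")
      pair <- crosslink_pair(peptide(sa), peptide(sb), lname,
                             alpha_site = 7, beta_site = 4)
      sig <- signature_fragment_mzs(pair)
      total <- sig$neutral[sig$fragment == "alpha_S"] +
        sig$neutral[sig$fragment == "beta_A"]
      expect_equal(total, pair_neutral_mass(pair), tolerance = 1e-9)
      expect_equal(sig$neutral[sig$fragment == "alpha_T"],
                   sig$neutral[sig$fragment == "alpha_S"] - 18.010565,
                   tolerance = 1e-6)
    }
  }
})

test_that("precursor charge arithmetic follows the protonation convention", {
  pair <- fig2_pair("SIA")
  m <- pair_neutral_mass(pair)
  expect_equal(precursor_mz(pair, 1), m + 1.007276, tolerance = 1e-6)
  expect_error(precursor_mz(pair, 0), "charge")
  # round trips
  expect_equal(mz_to_neutral(precursor_mz(pair, 4), 4), m, tolerance = 1e-9)
  expect_equal(mz_to_neutral(18.010565 + 1.007276466, 1), 18.010565,
               tolerance = 1e-9)
  expect_equal(mz_to_neutral(529.2494, 4), 2112.9685, tolerance = 1e-3)
})

test_that("pre-oxidation (non-cleavable) pair mass omits the sulfoxide oxygen", {
  ox <- fig2_pair("SIA")
  pre <- crosslink_pair("Ac-SAKAYEHR:K3", "Ac-LADVCAHER:C5", "SIA",
                        oxidized = FALSE)
  expect_equal(pair_neutral_mass(ox) - pair_neutral_mass(pre),
               composition_mass("O"), tolerance = 1e-9)
  expect_error(signature_fragment_mzs(pre), "oxidized")
})

test_that("fragment ladders localize modifications and end at the precursor", {
  lad_r <- fragment_ladder(peptide("R"))
  expect_equal(lad_r$mz[lad_r$ion == "y1"], 175.118952, tolerance = 1e-5)
  p <- peptide("SAKAYEHR", nterm = "acetyl")
  lad <- fragment_ladder(p)
  yn <- lad$mz[lad$series == "y" & lad$index == 8]
  expect_equal(yn, peptide_neutral_mass(p) + 1.007276466, tolerance = 1e-6)
  # remnant on K3 shifts b>=3 and y>=6, leaves b1/b2 untouched
  aS <- remnants_for("SIA")$alpha_S_mod
  pm <- peptide("SAKAYEHR", nterm = "acetyl",
                mods = data.frame(pos = 3, mod = aS))
  lm <- fragment_ladder(pm)
  pick <- function(l, s, i) l$mz[l$series == s & l$index == i]
  for (i in 1:2) expect_equal(pick(lm, "b", i), pick(lad, "b", i))
  for (i in 3:7) expect_equal(pick(lm, "b", i), pick(lad, "b", i) + aS,
                              tolerance = 1e-9)
  for (i in 6:8) expect_equal(pick(lm, "y", i), pick(lad, "y", i) + aS,
                              tolerance = 1e-9)
})

test_that("user-registered linkers behave like shipped ones", {
  register_linker("XL1", spacer_angstrom = 5.5, bridge = "C3H4O")
  r <- remnants_for("XL1")
  expect_equal(r$alpha_S_mod + r$beta_A_mod, r$intact_ox_addition)
  expect_true("XL1" %in% linkers()$name)
  expect_error(register_linker("BAD", spacer_angstrom = 0, bridge = "C2H2O"),
               "spacer")
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(list(name = "XL2", spacer_angstrom = 7.0,
                                 bridge = list(C = 4, H = 6, O = 2))),
                       cfg, auto_unbox = TRUE)
  read_linker_config(cfg)
  expect_equal(kcxlink::linker("XL2")$bridge, "C4H6O2")
})
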