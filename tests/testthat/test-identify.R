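# Signature-pair detection, MS3/MS2 search, FDR and linkage aggregation.

test_that("signature pairs are recovered from the worked-example spectrum", {
  pair <- fig2_pair("SIA")
  run <- as_run(signature_spectrum(pair))
  found <- detect_signature_pairs(run, "SIA")
  aS <- found[found$pair_type == "alpha_S", ]
  expect_equal(nrow(aS), 1)
  sig <- signature_fragment_mzs(pair)
  expect_equal(sort(c(aS$mz_1, aS$mz_2)),
               sort(sig$mz[sig$fragment %in% c("alpha_S", "beta_A")]),
               tolerance = 1e-4)
  # the dehydrated alpha_T corroborates the alpha_S member
  expect_false(is.na(aS$alpha_T_mz))
  # removing alpha_S leaves nothing summing to the precursor
  run2 <- as_run(signature_spectrum(pair, drop = c("alpha_S", "alpha_T")))
  expect_equal(nrow(detect_signature_pairs(run2, "SIA",
                                           search_alpha_t = FALSE)), 0)
})

test_that("pair detection matches a brute-force all-pairs scan on random spectra", {
  set.seed(7)
  z <- 4L
  prec <- 700
  M <- mz_to_neutral(prec, z)
  mz <- sort(runif(200, 150, 1300))
  run <- as_run(spectrum_row(1L, 2L, mz, rep(1, 200), precursor_mz = prec,
                             precursor_charge = z))
  tol_ppm <- 10
  found <- detect_signature_pairs(run, "SIA", tol_ppm = tol_ppm,
                                  search_alpha_t = FALSE)
  # brute-force oracle over every peak pair and charge assignment
  brute <- 0L
  seen <- character()
  for (i in 1:200) for (j in 1:200) {
    if (i == j) next
    for (za in 1:(z - 1)) for (zb in 1:(z - 1)) {
      if (za + zb > z) next
      s <- mz_to_neutral(mz[i], za) + mz_to_neutral(mz[j], zb)
      if (abs(s - M) <= M * tol_ppm * 1e-6) {
        ni <- mz_to_neutral(mz[i], za)
        nj <- mz_to_neutral(mz[j], zb)
        key <- if (ni <= nj) paste(mz[i], za, mz[j], zb)
        else paste(mz[j], zb, mz[i], za)
        if (!key %in% seen) {
          seen <- c(seen, key)
          brute <- brute + 1L
        }
      }
    }
  }
  expect_equal(nrow(found), brute)
})

test_that("tightening the tolerance never grows the candidate pair set", {
  set.seed(8)
  mz <- sort(runif(300, 150, 1300))
  run <- as_run(spectrum_row(1L, 2L, mz, rep(1, 300), precursor_mz = 650,
                             precursor_charge = 4L))
  n_prev <- Inf
  for (tol in c(50, 20, 10, 5)) {
    n <- nrow(detect_signature_pairs(run, "SIA", tol_ppm = tol))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("MS3 matching ranks the true remnant-modified peptide first", {
  db <- c(P1 = "GGGRSAKAYEHRGGKA", P2 = "GGGRLADVCAHERGGKA",
          P3 = "MMMWWWFFFYYYK")
  idx <- digest(db, length_range = c(5, 50))
  r <- remnants_for("SIA")
  # noiseless MS3 of the alpha_S-modified tryptic peptide SAKAYEHR
  p <- peptide("SAKAYEHR", mods = data.frame(pos = 3, mod = r$alpha_S_mod))
  lad <- fragment_ladder(p)
  prec <- neutral_to_mz(peptide_neutral_mass(p), 2)
  run <- as_run(
    spectrum_row(1L, 2L, 500, 1, precursor_mz = 600, precursor_charge = 4L),
    spectrum_row(2L, 3L, lad$mz, rep(1e4, nrow(lad)), precursor_mz = prec,
                 precursor_charge = 2L, parent_scan = 1L, selected_mz = prec)
  )
  psms <- match_ms3(run, idx, "SIA")
  top <- psms[psms$rank == 1 & psms$remnant == "alpha_S", ]
  expect_equal(top$peptide, "SAKAYEHR")
  expect_equal(top$site, 3L)
  expect_equal(top$matched, top$total)
  expect_false(top$is_decoy)
  # index without the peptide yields no alpha candidates at this mass
  idx2 <- digest(db["P3"], length_range = c(5, 50))
  psms2 <- match_ms3(run, idx2, "SIA")
  expect_equal(nrow(psms2[psms2$remnant == "alpha_S", ]), 0)
})

test_that("isobaric candidates are both returned with deterministic tie-break", {
  # LI swap gives exactly isobaric peptides
  db <- c(P1 = "GGGRALIKAGGRGGG", P2 = "GGGRAILKAGGRGGG")
  idx <- digest(db, length_range = c(5, 50), decoy = "none")
  r <- remnants_for("SIA")
  p <- peptide("ALIKAGGR", mods = data.frame(pos = 4, mod = r$alpha_S_mod))
  lad <- fragment_ladder(p)
  prec <- neutral_to_mz(peptide_neutral_mass(p), 2)
  run <- as_run(
    spectrum_row(1L, 2L, 500, 1, precursor_mz = 600, precursor_charge = 4L),
    spectrum_row(2L, 3L, lad$mz, rep(1e4, nrow(lad)), precursor_mz = prec,
                 precursor_charge = 2L, parent_scan = 1L, selected_mz = prec)
  )
  psms <- match_ms3(run, idx, "SIA", remnant_types = "alpha_S")
  expect_setequal(psms$peptide, c("ALIKAGGR", "AILKAGGR"))
  # scores differ (different ladders) or tie broken lexicographically
  expect_equal(psms$rank, seq_len(nrow(psms)))
  psms_again <- match_ms3(run, idx, "SIA", remnant_types = "alpha_S")
  expect_identical(psms$peptide, psms_again$peptide)
})

test_that("MSn integration emits one TT CSM per planted link and flags partial evidence", {
  cfg <- sim_config(seed = 5, n_proteins = 8, n_links = 5, noise_peaks = 0,
                    ppm_sigma = 0, detection_prob = 1)
  prot <- simulate_proteome(cfg)
  sim <- simulate_msn_run(prot, cfg)
  idx <- digest(prot$sequences)
  pairs <- detect_signature_pairs(sim$run, "SIA")
  psms <- match_ms3(sim$run, idx, "SIA")
  csms <- integrate_msn(sim$run, pairs, psms, "SIA")
  two_sided <- csms[!csms$single_sided, ]
  expect_equal(nrow(two_sided), nrow(prot$links))
  expect_true(all(two_sided$class == "TT"))
  # removing the alpha MS3 scans leaves single-sided beta evidence
  run_b <- sim$run[!(sim$run$scan %in% sim$provenance$ms3_alpha_scan), ]
  psms_b <- match_ms3(run_b, idx, "SIA")
  csms_b <- integrate_msn(run_b, pairs, psms_b, "SIA")
  expect_true(all(csms_b$single_sided))
  # a precursor violating the alpha + beta + intact sum yields no CSM
  run_bad <- sim$run
  run_bad$precursor_mz[run_bad$ms_level == 2] <-
    run_bad$precursor_mz[run_bad$ms_level == 2] + 0.5
  csms_bad <- integrate_msn(run_bad, pairs, psms, "SIA")
  expect_equal(sum(!csms_bad$single_sided), 0)
})

test_that("stepped-HCD MS2 search recovers planted links and matches brute-force enumeration", {
  cfg <- sim_config(seed = 6, n_proteins = 8, n_links = 5, mode = "ms2",
                    noise_peaks = 0, ppm_sigma = 0, detection_prob = 1)
  prot <- simulate_proteome(cfg)
  sim <- simulate_msn_run(prot, cfg)
  idx <- digest(prot$sequences)
  ranked <- search_ms2_stepped_hcd(sim$run, idx, "SIA", use_doublets = FALSE)
  top <- ranked[ranked$rank == 1, ]
  hits <- purrr::map_lgl(seq_len(nrow(prot$links)), function(i) {
    lk <- prot$links[i, ]
    scan <- sim$provenance$ms2_scan[sim$provenance$link_id == lk$link_id]
    any(top$scan == scan & top$alpha_peptide == lk$pep_a &
          top$beta_peptide == lk$pep_b)
  })
  expect_true(all(hits))
  # candidate enumeration equals a brute-force double loop for one precursor
  r <- remnants_for("SIA")
  cam <- composition_mass("C2H3NO")
  ms2 <- sim$run[sim$run$ms_level == 2, ][1, ]
  M <- mz_to_neutral(ms2$precursor_mz, ms2$precursor_charge)
  tol <- M * 10e-6
  cand <- kcxlink:::collapse_index(idx)
  brute <- 0L
  for (i in seq_len(nrow(cand))) for (j in seq_len(nrow(cand))) {
    if (length(cand$k_pos[[i]]) == 0 || cand$n_c[[j]] == 0) next
    tot <- cand$mass_cam[i] + cand$mass_cam[j] - cam + r$intact_ox_addition
    if (abs(tot - M) <= tol) brute <- brute + 1L
  }
  got <- search_ms2_stepped_hcd(ms2, idx, "SIA", use_doublets = FALSE,
                                max_rank = Inf)
  expect_equal(nrow(got), brute)
  # a precursor matching no pair yields nothing
  lonely <- spectrum_row(999L, 2L, 500, 1, precursor_mz = 123.456,
                         precursor_charge = 4L)
  expect_equal(nrow(search_ms2_stepped_hcd(lonely, idx, "SIA")), 0)
})

test_that("FDR estimator implements (TD - DD) / TT with monotone q-values", {
  mk <- function(n, cls, score) {
    tibble::tibble(scan = seq_len(n), score = score, class = cls,
                   prec_err_ppm = 0, single_sided = FALSE,
                   alpha_proteins = rep(list(tibble::tibble(
                     protein = "P", start = 1L)), n),
                   beta_peptide = "B", alpha_site = 1L, beta_site = 1L)
  }
  csms <- dplyr::bind_rows(mk(100, "TT", 10), mk(1, "TD", 5))
  res <- estimate_fdr(csms)
  worst <- res$csms[nrow(res$csms), ]
  expect_equal(worst$fdr, 1 / 100, tolerance = 1e-12)
  expect_true(all(diff(res$csms$q) >= 0))
  # all-decoy input: FDR capped at 1
  res2 <- estimate_fdr(mk(10, "TD", 1))
  expect_true(all(res2$csms$fdr == 1))
  # no decoy classes at all is an error
  expect_error(estimate_fdr(dplyr::mutate(mk(5, "TT", 1),
                                          class = NA_character_)),
               "decoys")
  g <- glance(res)
  expect_equal(g$n_tt, 100L)
  expect_equal(nrow(apply_fdr(res, 0.02)), 100)
  expect_equal(nrow(tidy(res)), 101)
})

test_that("CSMs collapse to unique linkages with support accounting", {
  prots <- list(tibble::tibble(protein = "PA", start = 10L))
  protb <- list(tibble::tibble(protein = "PB", start = 20L))
  mk_csm <- function(scan, linker, rep) {
    tibble::tibble(
      scan = scan, alpha_peptide = "GAKAR", alpha_site = 3L,
      alpha_proteins = prots, beta_peptide = "GGCGR", beta_site = 3L,
      beta_proteins = protb, score = 10, linker = linker, replicate = rep,
      single_sided = FALSE
    )
  }
  seqs <- c(PA = paste0(strrep("G", 9), "GAKAR"),
            PB = paste0(strrep("G", 19), "GGCGR"))
  csms <- dplyr::bind_rows(mk_csm(1, "SIA", "rep1"), mk_csm(2, "SIA", "rep2"),
                           mk_csm(3, "SBAP", "rep1"))
  lk <- collapse_to_unique_linkages(csms, sequences = seqs)
  expect_equal(nrow(lk), 1)
  expect_equal(lk$n_csms, 3L)
  expect_equal(lk$res_a, 12L)
  expect_equal(lk$res_b, 22L)
  expect_false(lk$intra)
  expect_setequal(lk$linkers[[1]], c("SIA", "SBAP"))
  # residue identity validation catches index corruption
  bad <- c(PA = strrep("G", 20), PB = seqs[["PB"]])
  expect_error(collapse_to_unique_linkages(csms, sequences = bad),
               "index corruption")
  # shared peptides set the ambiguity flag
  amb <- mk_csm(4, "SIA", "rep1")
  amb$alpha_proteins <- list(tibble::tibble(protein = c("PA", "PA2"),
                                            start = c(10L, 10L)))
  lk2 <- collapse_to_unique_linkages(amb)
  expect_true(lk2$ambiguous)
})

test_that("reproducibility filter requires two replicates of one linker", {
  lk <- mk_linkages(
    protein_a = c("A", "B", "C"), res_a = c(1, 1, 1),
    protein_b = c("X", "Y", "Z"), res_b = c(2, 2, 2),
    linkers = list("SIA", c("SIA", "SBAP"), "SIA"),
    replicates = list(c("rep1", "rep2"), "rep1", "rep1")
  )
  # linkage 2: SIA rep1 + SBAP rep1 only -> dropped at the default
  kept <- reproducibility_filter(lk)
  expect_equal(kept$protein_a, "A")
  expect_identical(reproducibility_filter(lk, min_replicates = 1), lk)
})
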