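# Distance mapping, confidence gating and secondary-structure summaries.

test_that("minimal distance and homomer rescue follow the hand-computed geometry", {
  # two parallel chains 12 A apart; explicit coordinates so distances are exact
  atoms <- dplyr::bind_rows(
    tibble::tibble(chain = "A", resno = 1:12,
                   aa = rep(c("K", "A", "C", "G"), 3),
                   x = (0:11) * 3.5, y = 0, z = 0),
    tibble::tibble(chain = "B", resno = 1:12,
                   aa = rep(c("K", "A", "C", "G"), 3),
                   x = (0:11) * 3.5, y = 12, z = 0)
  )
  st <- structure_from_coords(atoms, "DIMER")
  links <- tibble::tibble(protein_a = "P1", res_a = c(1L, 1L),
                          protein_b = "P1", res_b = c(11L, 3L))
  mapping <- tibble::tibble(protein = "P1", structure_id = "DIMER",
                            chain = c("A", "B"), offset = 0L)
  recs <- map_linkages(links, list(DIMER = st), mapping)
  # linkage 1: same-chain 35.0 A, inter-chain sqrt(35^2 + 12^2)
  m <- minimal_distances(recs)
  expect_equal(m$distance[m$linkage_id == 1], 35.0, tolerance = 1e-9)
  expect_equal(m$distance[m$linkage_id == 2], 7.0, tolerance = 1e-9)
  # brute-force scan over every combination confirms minimality
  for (id in unique(m$linkage_id)) {
    all_d <- recs$distance[recs$linkage_id == id & recs$outcome == "mapped"]
    expect_equal(min(all_d), m$distance[m$linkage_id == id])
  }
  # swap-site mapping: distance symmetry d(i,j) = d(j,i)
  links_swap <- tibble::tibble(protein_a = "P1", res_a = 9L,
                               protein_b = "P1", res_b = 3L)
  links_fwd <- tibble::tibble(protein_a = "P1", res_a = 3L,
                              protein_b = "P1", res_b = 9L)
  d1 <- minimal_distances(map_linkages(links_swap, list(DIMER = st), mapping))
  d2 <- minimal_distances(map_linkages(links_fwd, list(DIMER = st), mapping,
                                       check_identity = FALSE))
  expect_equal(d1$distance, d2$distance)
})

test_that("a cross-link rescued only by the inter-chain distance is counted as rescue", {
  # same-chain distance 35 A (violating), inter-chain 12 A (satisfied):
  # chain B is reversed so residue 1 of A sits next to residue 11 of B
  atoms <- dplyr::bind_rows(
    tibble::tibble(chain = "A", resno = 1:12,
                   aa = rep(c("K", "A", "C", "G"), 3),
                   x = (0:11) * 3.5, y = 0, z = 0),
    tibble::tibble(chain = "B", resno = 1:12,
                   aa = rep(c("K", "A", "C", "G"), 3),
                   x = (11:0) * 3.5, y = 12, z = 0)
  )
  st <- structure_from_coords(atoms, "DIMER")
  mapping <- tibble::tibble(protein = "P1", structure_id = "DIMER",
                            chain = c("A", "B"), offset = 0L)
  links <- tibble::tibble(protein_a = "P1", res_a = 1L,
                          protein_b = "P1", res_b = 11L)
  recs <- map_linkages(links, list(DIMER = st), mapping)
  inter <- recs[recs$context == "inter-chain-homomer", ]
  expect_equal(min(inter$distance), sqrt(3.5^2 + 12^2), tolerance = 1e-9)
  s <- satisfaction_summary(recs)
  expect_equal(s$mapped, 1L)
  expect_equal(s$satisfied, 1L)
  expect_equal(s$rescued, 1L)
  # without chain B there is no rescue
  recs_mono <- map_linkages(links, list(DIMER = st), mapping[1, ])
  s_mono <- satisfaction_summary(recs_mono)
  expect_equal(s_mono$satisfied, 0L)
  expect_gte(s$satisfied, s_mono$satisfied)
})

test_that("satisfaction threshold is strict and medians use mapped records only", {
  mk_rec <- function(id, d) {
    tibble::tibble(linkage_id = id, protein_a = "P", res_a = 1L,
                   protein_b = "P", res_b = 2L, intra = TRUE,
                   structure_id = "S", chain_a = "A", chain_b = "A",
                   resno_a = 1L, resno_b = 2L, distance = d,
                   context = "same-chain", outcome = "mapped",
                   satisfied = d < 30, min_plddt = NA_real_,
                   model_class = "experimental")
  }
  recs <- dplyr::bind_rows(mk_rec(1, 10), mk_rec(2, 29.9), mk_rec(3, 30.0))
  s <- satisfaction_summary(recs)
  expect_equal(s$satisfied, 2L)   # 30.0 is NOT satisfied (strict <)
  recs2 <- dplyr::bind_rows(mk_rec(1, 20), mk_rec(2, 25), mk_rec(3, 31))
  expect_equal(satisfaction_summary(recs2)$median_distance, 25.0)
  expect_equal(nrow(satisfaction_summary(recs2[0, ])), 0)
  # unmapped linkages are reported as such
  st <- toy_dimer()
  out <- map_linkages(tibble::tibble(protein_a = "PX", res_a = 1L,
                                     protein_b = "PX", res_b = 3L),
                      list(TOY1 = st), toy_mapping("P1"))
  expect_equal(out$outcome, "unmapped")
})

test_that("self-distance of a residue to itself is zero", {
  st <- toy_dimer(offset = 12)
  links <- tibble::tibble(protein_a = "P1", res_a = 5L,
                          protein_b = "P1", res_b = 5L)
  recs <- map_linkages(links, list(TOY1 = st), toy_mapping()[1, ],
                       check_identity = FALSE)
  expect_equal(recs$distance[recs$context == "same-chain"], 0)
})

test_that("PAE symmetrization, strict gating and stratified satisfaction behave", {
  pae <- matrix(0, 4, 4)
  pae[1, 2] <- 4; pae[2, 1] <- 6
  expect_equal(pae_for_pair(pae, 1, 2), 5.0)
  sym <- matrix(7, 3, 3)
  expect_equal(pae_for_pair(sym, 1, 3), 7)
  expect_error(pae_for_pair(pae, 1, 9), "outside")
  # JSON round trip in the standard predicted_aligned_error layout
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(predicted_aligned_error = pae)), f,
                       digits = NA)
  expect_equal(read_pae(f), pae)
  # strict cutoff keeps 5 and 19.9 but not 20.0
  recs <- tibble::tibble(outcome = "mapped", distance = c(5, 5, 5),
                         pae = c(5, 19.9, 20.0), min_plddt = NA_real_)
  expect_equal(nrow(confidence_gate(recs)), 2)
  # constructed satisfied-iff-PAE<20 fixture stratifies to rates 1 and 0
  recs2 <- tibble::tibble(outcome = "mapped",
                          distance = c(10, 10, 50, 50),
                          pae = c(5, 15, 25, 35))
  strat <- confidence_stratified_satisfaction(recs2, breaks = c(0, 20, Inf))
  expect_equal(strat$rate, c(1, 0))
  strat2 <- confidence_stratified_satisfaction(recs2[recs2$pae < 20, ],
                                               breaks = c(0, 20, Inf))
  expect_equal(strat2$mapped[2], 0L)
  expect_true(is.na(strat2$rate[2]))
})

test_that("secondary-structure enrichment equals hand-computed normalized counts", {
  st <- toy_dimer(offset = 12)
  links <- tibble::tibble(protein_a = "P1", res_a = c(1L, 5L),
                          protein_b = "P1", res_b = c(3L, 7L))
  recs <- map_linkages(links, list(TOY1 = st), toy_mapping()[1, ])
  # all K in helix, all C in sheet; uniform background over the 3 classes
  ss <- tibble::tibble(structure_id = "TOY1", chain = "A",
                       resno = 1:40,
                       ss = rep(c("H", "C", "E", "T"), 10))
  background <- tidyr::expand_grid(aa = c("K", "C"),
                                   ss = c("H", "E", "T"))
  prof <- secstruct_enrichment(recs, ss, background)
  k_helix <- prof$enrichment[prof$residue == "K" & prof$class == "helix"]
  expect_equal(k_helix, 3)
  expect_equal(prof$enrichment[prof$residue == "K" & prof$class == "sheet"], 0)
  # invariant under duplication of the background set
  prof2 <- secstruct_enrichment(recs, ss,
                                dplyr::bind_rows(background, background))
  expect_equal(prof$enrichment, prof2$enrichment)
  # zero-background class reports NA
  bg0 <- background[background$ss != "E", ]
  prof3 <- secstruct_enrichment(recs, ss, bg0)
  expect_true(is.na(prof3$enrichment[prof3$residue == "K" &
                                       prof3$class == "sheet"]))
})

test_that("distances grouped by secondary-structure class partition the records", {
  st <- toy_dimer(offset = 12)
  links <- tibble::tibble(protein_a = "P1", res_a = c(1L, 5L, 9L),
                          protein_b = "P1", res_b = c(3L, 7L, 15L))
  recs <- map_linkages(links, list(TOY1 = st), toy_mapping()[1, ])
  ss <- tibble::tibble(structure_id = "TOY1", chain = "A", resno = 1:40,
                       ss = ifelse(1:40 <= 8, "H", "T"))
  grp <- distance_by_secstruct(recs, ss)
  expect_equal(sum(grp$n), nrow(minimal_distances(recs)))
  # loop-involving pairs sit farther apart in this fixture
  helix_med <- grp$median_distance[grp$class_a == "helix" &
                                     grp$class_b == "helix"]
  loop_med <- grp$median_distance[grp$class_b == "loop"]
  expect_gt(loop_med, helix_med)
})

test_that("mapping validation excludes structures whose numbering disagrees", {
  st <- toy_dimer()
  seqs <- c(P1 = paste(rep(c("K", "A", "C", "G"), 10), collapse = ""))
  good <- residue_mapping(toy_mapping(), structures = list(TOY1 = st),
                          sequences = seqs)
  expect_true(all(good$valid))
  expect_warning(
    bad <- residue_mapping(dplyr::mutate(toy_mapping(), offset = 1L),
                           structures = list(TOY1 = st), sequences = seqs),
    "disagrees"
  )
  expect_false(any(bad$valid))
})

test_that("the Calpha heuristic calls an ideal helix helical", {
  # ideal alpha-helix Calpha trace: radius 2.3 A, 100 deg turn, 1.5 A rise
  n <- 20
  t <- (0:(n - 1)) * 100 * pi / 180
  atoms <- tibble::tibble(chain = "A", resno = 1:n, aa = "A",
                          x = 2.3 * cos(t), y = 2.3 * sin(t), z = 1.5 * (0:(n - 1)))
  st <- structure_from_coords(atoms, "HELIX")
  ss <- assign_secstruct_ca(st)
  expect_gt(mean(ss$ss[1:(n - 3)] == "H"), 0.9)
  # straight chain at full extension is not helical
  ext <- simulate_toy_structure(n_res = 20, spacing = 3.8)
  ss2 <- assign_secstruct_ca(ext)
  expect_true(all(ss2$ss != "H"))
})
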