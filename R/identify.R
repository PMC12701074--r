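# MS2 signature-pair detection and cross-link search.
#
# The scorer is a self-contained probabilistic one: the per-side score is
# -log10 of the binomial tail probability of matching k of n theoretical b/y
# ions given the spectrum peak density. Deterministic, intensity-free.

#' Detect alpha_S / beta_A signature pairs in MS2 spectra
#'
#' Finds all peak pairs (over fragment charge hypotheses `1..z-1` with the
#' pair's charges summing to at most the precursor charge) whose neutral
#' masses sum to the precursor neutral within a ppm tolerance. Pairs whose
#' neutrals sum to precursor minus water are also reported (the dehydrated
#' alpha_T / beta_A pair) with `pair_type = "alpha_T"`. For each pair an
#' alpha_T corroborating peak (at the candidate alpha_S neutral minus water,
#' same charge) is searched and recorded; it is optional evidence only.
#'
#' @param run A run tibble (MS2 rows are searched; precursor charge must be
#'   known).
#' @param linker Linker name or `kcx_linker` (recorded in the output).
#' @param tol_ppm Mass-conservation tolerance in ppm on the precursor neutral
#'   (default 20, the MS2 fragment tolerance).
#' @param search_alpha_t Also search the dehydrated pair sum (default TRUE).
#' @return A tibble with one row per detected pair, ranked within scan by
#'   summed intensity: `scan`, `pair_type`, peak m/z / charge / intensity /
#'   neutral for both members (`_1` is the lower-neutral member), `err_ppm`,
#'   `alpha_T_mz` (corroborating peak or NA), `linker`.
#' @export
detect_signature_pairs <- function(run, linker, tol_ppm = 20,
                                   search_alpha_t = TRUE) {
  lname <- kcxlink::linker(linker)$name
  ms2 <- dplyr::filter(run, .data$ms_level == 2L, .data$precursor_charge > 1L)
  out <- purrr::map(seq_len(nrow(ms2)), function(i) {
    detect_pairs_one(ms2$peaks[[i]], ms2$precursor_mz[i],
                     ms2$precursor_charge[i], tol_ppm, search_alpha_t,
                     ms2$scan[i])
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    return(tibble::tibble(
      scan = integer(), pair_type = character(),
      mz_1 = numeric(), z_1 = integer(), intensity_1 = numeric(),
      neutral_1 = numeric(), mz_2 = numeric(), z_2 = integer(),
      intensity_2 = numeric(), neutral_2 = numeric(), err_ppm = numeric(),
      alpha_T_mz = numeric(), linker = character()
    ))
  }
  out$linker <- lname
  dplyr::arrange(out, .data$scan, dplyr::desc(.data$intensity_1 + .data$intensity_2))
}

detect_pairs_one <- function(pk, prec_mz, z, tol_ppm, search_alpha_t, scan) {
  if (!nrow(pk) || z < 2) return(NULL)
  M <- mz_to_neutral(prec_mz, z)
  water <- composition_mass("H2O")
  targets <- c(alpha_S = M)
  if (search_alpha_t) targets <- c(targets, alpha_T = M - water)
  tol <- M * tol_ppm * 1e-6
  np <- nrow(pk)
  res <- list()
  for (za in 1:(z - 1)) {
    for (zb in 1:(z - 1)) {
      if (za + zb > z) next
      na <- mz_to_neutral(pk$mz, za)
      nb <- mz_to_neutral(pk$mz, zb)
      for (tname in names(targets)) {
        tgt <- targets[[tname]]
        # all (i, j) with na[i] + nb[j] within tol; j over sorted nb
        lo <- findInterval(tgt - na - tol, nb)
        hi <- findInterval(tgt - na + tol, nb)
        keep <- which(hi > lo)
        for (i in keep) {
          for (j in (lo[i] + 1):hi[i]) {
            if (i == j) next
            res[[length(res) + 1]] <- tibble::tibble(
              scan = scan, pair_type = tname,
              mz_a = pk$mz[i], z_a = za, int_a = pk$intensity[i], n_a = na[i],
              mz_b = pk$mz[j], z_b = zb, int_b = pk$intensity[j], n_b = nb[j],
              err_ppm = (na[i] + nb[j] - tgt) / M * 1e6
            )
          }
        }
      }
    }
  }
  if (!length(res)) return(NULL)
  d <- dplyr::bind_rows(res)
  # canonical orientation: member 1 has the lower neutral; drop mirrored dups
  flip <- d$n_a > d$n_b
  d2 <- d
  d2[flip, c("mz_a", "z_a", "int_a", "n_a", "mz_b", "z_b", "int_b", "n_b")] <-
    d[flip, c("mz_b", "z_b", "int_b", "n_b", "mz_a", "z_a", "int_a", "n_a")]
  d2 <- dplyr::distinct(d2, .data$pair_type, .data$mz_a, .data$z_a,
                        .data$mz_b, .data$z_b, .keep_all = TRUE)
  # alpha_T corroboration: peak at (neutral - water) at the same charge
  corr <- function(neutral, zc) {
    cand_mz <- neutral_to_mz(neutral - water, zc)
    hit <- which(abs(pk$mz - cand_mz) <= cand_mz * 20e-6 + 0.005)
    if (length(hit)) pk$mz[hit[1]] else NA_real_
  }
  at <- purrr::map2_dbl(d2$n_a, d2$z_a, corr)
  at2 <- purrr::map2_dbl(d2$n_b, d2$z_b, corr)
  tibble::tibble(
    scan = d2$scan, pair_type = d2$pair_type,
    mz_1 = d2$mz_a, z_1 = as.integer(d2$z_a), intensity_1 = d2$int_a,
    neutral_1 = d2$n_a,
    mz_2 = d2$mz_b, z_2 = as.integer(d2$z_b), intensity_2 = d2$int_b,
    neutral_2 = d2$n_b,
    err_ppm = d2$err_ppm,
    alpha_T_mz = ifelse(is.na(at), at2, at)
  )
}

# Collapse index rows to one candidate per (peptide, is_decoy), carrying all
# protein mappings for ambiguity tracking.
collapse_index <- function(index) {
  grp <- dplyr::group_by(index, .data$peptide, .data$is_decoy)
  dplyr::summarise(
    grp,
    mass_cam = .data$mass_cam[1], n_c = .data$n_c[1],
    k_pos = .data$k_pos[1], c_pos = .data$c_pos[1],
    proteins = list(tibble::tibble(protein = protein, start = start)),
    .groups = "drop"
  )
}

score_match <- function(pk, theo_mz, tol, relative) {
  n <- length(theo_mz)
  if (!n || !nrow(pk)) {
    return(list(score = 0, matched = 0L, total = n))
  }
  tolv <- if (relative) theo_mz * tol * 1e-6 else rep(tol, n)
  lo <- findInterval(theo_mz - tolv, pk$mz)
  hi <- findInterval(theo_mz + tolv, pk$mz)
  k <- sum(hi > lo)
  # match probability from spectrum peak density
  rng <- max(max(pk$mz) - min(pk$mz), 100)
  w <- if (relative) mean(theo_mz) * tol * 1e-6 else tol
  p <- min(0.5, nrow(pk) * 2 * w / rng)
  s <- -pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
  list(score = s, matched = as.integer(k), total = as.integer(n))
}

# b/y ladder m/z values for a peptide with remnant mass at `site`, fixed CAM
# on every Cys except an excluded (cross-linked) one.
remnant_ladder <- function(seq_res, site, remnant_mass, c_pos, cam_exclude = NA) {
  cam <- composition_mass(NAMED_MODS[["carbamidomethyl"]])
  mods <- tibble::tibble(pos = site, mod = list(remnant_mass))
  cp <- setdiff(c_pos, cam_exclude)
  if (length(cp)) {
    mods <- dplyr::bind_rows(mods, tibble::tibble(pos = cp, mod = list(cam)))
  }
  p <- peptide(paste(seq_res, collapse = ""), mods = mods)
  fragment_ladder(p, max_charge = 1)$mz
}

#' Match an MS3 spectrum against the peptide index
#'
#' Candidates are peptides whose (carbamidomethylated) mass plus the remnant
#' mass equals the MS3 precursor neutral (the selected MS2 fragment) within a
#' ppm tolerance, with the remnant localized on K (alpha_S / alpha_T) or on C
#' (beta_A; that Cys is then not carbamidomethylated). Candidates are scored
#' against the MS3 sequence ions with an absolute fragment tolerance
#' (ion-trap MS3) and ranked; ties are broken by smaller absolute precursor
#' ppm error, then lexicographic sequence.
#'
#' @param run A run tibble; all non-orphan MS3 rows are searched.
#' @param index A `kcx_index` from [digest()].
#' @param linker Linker name or `kcx_linker`.
#' @param remnant_types Remnant hypotheses to try.
#' @param precursor_ppm MS3 precursor (selected fragment) tolerance in ppm.
#' @param fragment_tol Absolute fragment tolerance in Da (default 0.6).
#' @param max_rank Keep at most this many ranked matches per (scan, remnant).
#' @return A PSM tibble: `scan`, `parent_scan`, `selected_mz`, `remnant`,
#'   `peptide`, `site`, `score`, `matched`, `total`, `prec_err_ppm`,
#'   `is_decoy`, `proteins` (list column), `rank`.
#' @export
match_ms3 <- function(run, index, linker,
                      remnant_types = c("alpha_S", "alpha_T", "beta_A"),
                      precursor_ppm = 20, fragment_tol = 0.6, max_rank = 5) {
  r <- remnants_for(linker)
  cand <- collapse_index(index)
  cam <- composition_mass(NAMED_MODS[["carbamidomethyl"]])
  ms3 <- dplyr::filter(run, .data$ms_level == 3L, !.data$orphan)
  out <- list()
  for (i in seq_len(nrow(ms3))) {
    z <- max(1L, ms3$precursor_charge[i])
    neutral <- mz_to_neutral(ms3$precursor_mz[i], z)
    for (rt in remnant_types) {
      rmass <- r[[paste0(rt, "_mod")]]
      if (rt == "beta_A") {
        cc <- dplyr::filter(cand, .data$n_c >= 1)
        cand_mass <- cc$mass_cam - cam + rmass
      } else {
        cc <- dplyr::filter(cand, lengths(.data$k_pos) >= 1)
        cand_mass <- cc$mass_cam + rmass
      }
      tol <- neutral * precursor_ppm * 1e-6
      hit <- which(abs(cand_mass - neutral) <= tol)
      if (!length(hit)) next
      rows <- purrr::map(hit, function(h) {
        cr <- cc[h, ]
        seq_res <- strsplit(cr$peptide, "")[[1]]
        sites <- if (rt == "beta_A") cr$c_pos[[1]] else cr$k_pos[[1]]
        best <- NULL
        for (s in sites) {
          theo <- remnant_ladder(seq_res, s, rmass, cr$c_pos[[1]],
                                 cam_exclude = if (rt == "beta_A") s else NA)
          sc <- score_match(ms3$peaks[[i]], sort(theo), fragment_tol,
                            relative = FALSE)
          if (is.null(best) || sc$score > best$score) {
            best <- c(sc, site = s)
          }
        }
        tibble::tibble(
          scan = ms3$scan[i], parent_scan = ms3$parent_scan[i],
          selected_mz = ms3$selected_mz[i] %|na|% ms3$precursor_mz[i],
          remnant = rt, peptide = cr$peptide, site = as.integer(best$site),
          score = best$score, matched = best$matched, total = best$total,
          prec_err_ppm = (neutral - cand_mass[h]) / neutral * 1e6,
          is_decoy = cr$is_decoy, proteins = list(cr$proteins[[1]])
        )
      })
      out[[length(out) + 1]] <- dplyr::bind_rows(rows)
    }
  }
  psms <- dplyr::bind_rows(out)
  if (!nrow(psms)) {
    return(tibble::tibble(
      scan = integer(), parent_scan = integer(), selected_mz = numeric(),
      remnant = character(), peptide = character(), site = integer(),
      score = numeric(), matched = integer(), total = integer(),
      prec_err_ppm = numeric(), is_decoy = logical(), proteins = list(),
      rank = integer()
    ))
  }
  psms <- dplyr::arrange(psms, .data$scan, .data$remnant,
                         dplyr::desc(.data$score), abs(.data$prec_err_ppm),
                         .data$peptide)
  psms <- dplyr::group_by(psms, .data$scan, .data$remnant)
  psms <- dplyr::mutate(psms, rank = dplyr::row_number())
  dplyr::filter(dplyr::ungroup(psms), .data$rank <= max_rank)
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Integrate MS1/MS2/MS3 evidence into cross-link spectrum matches
#'
#' A CSM is emitted when an MS2 signature pair exists, MS3 identifications
#' exist for fragments matching the pair's alpha (alpha_S or alpha_T) and
#' beta_A masses, and the theoretical alpha + beta + intact oxidized addition
#' matches the MS1 precursor within the precursor tolerance. Single-sided MS3
#' evidence is emitted with `single_sided = TRUE` (excluded from default FDR
#' reporting).
#'
#' @param run A run tibble.
#' @param pairs Output of [detect_signature_pairs()].
#' @param psms Output of [match_ms3()].
#' @param linker Linker name or `kcx_linker`.
#' @param precursor_ppm MS1 precursor tolerance in ppm (default 10).
#' @param selected_mz_tol Tolerance (Da) for matching an MS3 selected m/z to a
#'   signature-pair peak.
#' @return A CSM tibble (class `kcx_csms` columns): scan, peptides, sites,
#'   decoy class (`TT`/`TD`/`DD`), combined score, precursor error, flags.
#' @export
integrate_msn <- function(run, pairs, psms, linker, precursor_ppm = 10,
                          selected_mz_tol = 0.01) {
  r <- remnants_for(linker)
  cam <- composition_mass(NAMED_MODS[["carbamidomethyl"]])
  rmv <- residue_mass_vector()
  water <- composition_mass("H2O")
  ms2 <- dplyr::filter(run, .data$ms_level == 2L)
  out <- list()
  for (scan_id in unique(pairs$scan)) {
    sp <- dplyr::filter(pairs, .data$scan == scan_id)
    meta <- ms2[ms2$scan == scan_id, ]
    if (!nrow(meta)) next
    M <- mz_to_neutral(meta$precursor_mz, meta$precursor_charge)
    child <- dplyr::filter(psms, .data$parent_scan == scan_id)
    if (!nrow(child)) next
    for (pi in seq_len(nrow(sp))) {
      for (orient in 1:2) {
        a_mz <- if (orient == 1) sp$mz_1[pi] else sp$mz_2[pi]
        b_mz <- if (orient == 1) sp$mz_2[pi] else sp$mz_1[pi]
        a_rem <- if (sp$pair_type[pi] == "alpha_T") "alpha_T" else "alpha_S"
        a_psm <- dplyr::filter(child,
                               abs(.data$selected_mz - a_mz) <= selected_mz_tol,
                               .data$remnant %in% c("alpha_S", "alpha_T"))
        b_psm <- dplyr::filter(child,
                               abs(.data$selected_mz - b_mz) <= selected_mz_tol,
                               .data$remnant == "beta_A")
        if (!nrow(a_psm) && !nrow(b_psm)) next
        a_psm <- utils::head(dplyr::arrange(a_psm, dplyr::desc(.data$score)), 1)
        b_psm <- utils::head(dplyr::arrange(b_psm, dplyr::desc(.data$score)), 1)
        single <- !nrow(a_psm) || !nrow(b_psm)
        if (!single) {
          pep_mass <- function(seqs) {
            res <- strsplit(seqs, "")[[1]]
            sum(rmv[res]) + water + cam * sum(res == "C")
          }
          ma <- pep_mass(a_psm$peptide)
          mb <- pep_mass(b_psm$peptide) - cam
          total <- ma + mb + r$intact_ox_addition
          err <- (M - total) / total * 1e6
          if (abs(err) > precursor_ppm) next
          out[[length(out) + 1]] <- tibble::tibble(
            scan = scan_id, precursor_mz = meta$precursor_mz,
            precursor_charge = meta$precursor_charge,
            alpha_peptide = a_psm$peptide, alpha_site = a_psm$site,
            alpha_decoy = a_psm$is_decoy, alpha_proteins = a_psm$proteins,
            beta_peptide = b_psm$peptide, beta_site = b_psm$site,
            beta_decoy = b_psm$is_decoy, beta_proteins = b_psm$proteins,
            score = a_psm$score + b_psm$score,
            prec_err_ppm = err, single_sided = FALSE,
            alpha_remnant = a_psm$remnant
          )
        } else if (nrow(b_psm)) {
          out[[length(out) + 1]] <- tibble::tibble(
            scan = scan_id, precursor_mz = meta$precursor_mz,
            precursor_charge = meta$precursor_charge,
            alpha_peptide = NA_character_, alpha_site = NA_integer_,
            alpha_decoy = NA, alpha_proteins = list(NULL),
            beta_peptide = b_psm$peptide, beta_site = b_psm$site,
            beta_decoy = b_psm$is_decoy, beta_proteins = b_psm$proteins,
            score = b_psm$score, prec_err_ppm = NA_real_, single_sided = TRUE,
            alpha_remnant = a_rem
          )
        } else if (nrow(a_psm)) {
          out[[length(out) + 1]] <- tibble::tibble(
            scan = scan_id, precursor_mz = meta$precursor_mz,
            precursor_charge = meta$precursor_charge,
            alpha_peptide = a_psm$peptide, alpha_site = a_psm$site,
            alpha_decoy = a_psm$is_decoy, alpha_proteins = a_psm$proteins,
            beta_peptide = NA_character_, beta_site = NA_integer_,
            beta_decoy = NA, beta_proteins = list(NULL),
            score = a_psm$score, prec_err_ppm = NA_real_, single_sided = TRUE,
            alpha_remnant = a_psm$remnant
          )
        }
      }
    }
  }
  csms <- dplyr::bind_rows(out)
  if (!nrow(csms)) return(empty_csms())
  # best CSM per MS2 scan (two-sided preferred, then score)
  csms <- dplyr::arrange(csms, .data$scan, .data$single_sided,
                         dplyr::desc(.data$score))
  csms <- dplyr::distinct(csms, .data$scan, .keep_all = TRUE)
  finalize_csms(csms, linker, mode = "msn", run = run)
}

empty_csms <- function() {
  tibble::tibble(
    scan = integer(), precursor_mz = numeric(), precursor_charge = integer(),
    alpha_peptide = character(), alpha_site = integer(), alpha_decoy = logical(),
    alpha_proteins = list(), beta_peptide = character(), beta_site = integer(),
    beta_decoy = logical(), beta_proteins = list(), score = numeric(),
    prec_err_ppm = numeric(), single_sided = logical(),
    alpha_remnant = character(), class = character(), linker = character(),
    replicate = character(), mode = character()
  )
}

finalize_csms <- function(csms, linker, mode, run = NULL) {
  csms$class <- dplyr::case_when(
    is.na(csms$alpha_decoy) | is.na(csms$beta_decoy) ~ NA_character_,
    csms$alpha_decoy & csms$beta_decoy ~ "DD",
    csms$alpha_decoy | csms$beta_decoy ~ "TD",
    TRUE ~ "TT"
  )
  csms$linker <- kcxlink::linker(linker)$name
  rep_lab <- NA_character_
  if (!is.null(run) && nrow(run) && "replicate" %in% names(run)) {
    rep_lab <- run$replicate[1]
  }
  csms$replicate <- rep_lab
  csms$mode <- mode
  csms
}

#' Single-spectrum stepped-HCD MS2 cross-link search
#'
#' Enumerates candidate alpha (K-containing) / beta (C-containing) peptide
#' pairs whose masses plus the intact oxidized addition match the precursor
#' within tolerance; when signature doublets are detected they constrain the
#' alpha mass. Each side is scored on its remnant-modified sequence ions in
#' the same spectrum; the combined score is the sum. Ties are broken by
#' smaller absolute precursor ppm error, then lexicographic sequences.
#'
#' @param run A run tibble; MS2 rows with known precursor charge are searched.
#' @param index A `kcx_index`.
#' @param linker Linker name or `kcx_linker`.
#' @param precursor_ppm Precursor tolerance in ppm (default 10).
#' @param fragment_ppm Fragment tolerance in ppm (default 20).
#' @param use_doublets Constrain alpha mass with detected signature doublets
#'   when available (default TRUE).
#' @param max_rank Ranked matches kept per scan.
#' @return A ranked CSM tibble; `rank == 1` rows are the search result proper.
#' @export
search_ms2_stepped_hcd <- function(run, index, linker, precursor_ppm = 10,
                                   fragment_ppm = 20, use_doublets = TRUE,
                                   max_rank = 5) {
  r <- remnants_for(linker)
  cam <- composition_mass(NAMED_MODS[["carbamidomethyl"]])
  cand <- collapse_index(index)
  a_cand <- dplyr::filter(cand, lengths(.data$k_pos) >= 1)
  b_cand <- dplyr::filter(cand, .data$n_c >= 1)
  b_cand$mass_link <- b_cand$mass_cam - cam
  b_ord <- order(b_cand$mass_link)
  b_cand <- b_cand[b_ord, ]
  pairs <- if (use_doublets) {
    detect_signature_pairs(run, linker, tol_ppm = fragment_ppm)
  } else NULL
  ms2 <- dplyr::filter(run, .data$ms_level == 2L, .data$precursor_charge > 1L)
  out <- list()
  for (i in seq_len(nrow(ms2))) {
    M <- mz_to_neutral(ms2$precursor_mz[i], ms2$precursor_charge[i])
    target <- M - r$intact_ox_addition
    tol <- M * precursor_ppm * 1e-6
    pk <- ms2$peaks[[i]]
    # optional doublet constraint on the alpha mass
    a_mass_windows <- NULL
    if (!is.null(pairs)) {
      sp <- dplyr::filter(pairs, .data$scan == ms2$scan[i],
                          .data$pair_type == "alpha_S")
      if (nrow(sp)) {
        a_neutrals <- c(sp$neutral_1 - r$alpha_S_mod,
                        sp$neutral_2 - r$alpha_S_mod)
        a_mass_windows <- a_neutrals
      }
    }
    need <- target - a_cand$mass_cam
    lo <- findInterval(need - tol, b_cand$mass_link)
    hi <- findInterval(need + tol, b_cand$mass_link)
    rows <- list()
    for (ai in which(hi > lo)) {
      if (!is.null(a_mass_windows) &&
          !any(abs(a_cand$mass_cam[ai] - a_mass_windows) <=
                 a_cand$mass_cam[ai] * 2 * fragment_ppm * 1e-6)) next
      for (bi in (lo[ai] + 1):hi[ai]) {
        ca <- a_cand[ai, ]; cb <- b_cand[bi, ]
        sa <- best_site_score(pk, ca, "alpha_S", r$alpha_S_mod, fragment_ppm)
        sb <- best_site_score(pk, cb, "beta_A", r$beta_A_mod, fragment_ppm)
        total <- ca$mass_cam + cb$mass_link + r$intact_ox_addition
        rows[[length(rows) + 1]] <- tibble::tibble(
          scan = ms2$scan[i], precursor_mz = ms2$precursor_mz[i],
          precursor_charge = ms2$precursor_charge[i],
          alpha_peptide = ca$peptide, alpha_site = sa$site,
          alpha_decoy = ca$is_decoy, alpha_proteins = list(ca$proteins[[1]]),
          beta_peptide = cb$peptide, beta_site = sb$site,
          beta_decoy = cb$is_decoy, beta_proteins = list(cb$proteins[[1]]),
          score = sa$score + sb$score,
          prec_err_ppm = (M - total) / total * 1e6,
          single_sided = FALSE, alpha_remnant = "alpha_S"
        )
      }
    }
    out[[length(out) + 1]] <- dplyr::bind_rows(rows)
  }
  csms <- dplyr::bind_rows(out)
  if (!nrow(csms)) return(dplyr::mutate(empty_csms(), rank = integer()))
  csms <- dplyr::arrange(csms, .data$scan, dplyr::desc(.data$score),
                         abs(.data$prec_err_ppm), .data$alpha_peptide,
                         .data$beta_peptide)
  csms <- dplyr::group_by(csms, .data$scan)
  csms <- dplyr::ungroup(dplyr::mutate(csms, rank = dplyr::row_number()))
  csms <- dplyr::filter(csms, .data$rank <= max_rank)
  finalize_csms(csms, linker, mode = "ms2", run = run)
}

best_site_score <- function(pk, cand_row, side, rmass, fragment_ppm) {
  sites <- if (side == "beta_A") cand_row$c_pos[[1]] else cand_row$k_pos[[1]]
  seq_res <- strsplit(cand_row$peptide, "")[[1]]
  best <- list(score = -Inf, site = NA_integer_)
  for (s in sites) {
    theo <- remnant_ladder(seq_res, s, rmass, cand_row$c_pos[[1]],
                           cam_exclude = if (side == "beta_A") s else NA)
    sc <- score_match(pk, sort(theo), fragment_ppm, relative = TRUE)
    if (sc$score > best$score) best <- list(score = sc$score, site = as.integer(s))
  }
  best
}
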