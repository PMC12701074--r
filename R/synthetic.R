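# Seeded synthetic fixtures: proteomes, planted K-C cross-links, MSn / MS2
# runs and toy structures. Every generator is deterministic under the
# config seed.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is validated under: a
#' 50-protein proteome, 100 planted cross-links, precursor charges 4-8, and a
#' noisy acquisition (100 noise peaks per spectrum, 5 ppm mass-error sigma,
#' 0.9 fragment-detection probability). Set `noise_peaks = 0`,
#' `ppm_sigma = 0`, `detection_prob = 1` for the noiseless limit.
#'
#' @param seed Integer random seed; fixed seed gives byte-identical outputs.
#' @param n_proteins,protein_length Proteome size.
#' @param aa_freq Named amino-acid sampling frequencies (default roughly
#'   human-like, K ~ 5.7%, C ~ 2.3%).
#' @param n_links Planted cross-link count.
#' @param intra_fraction Fraction of planted links that are intra-protein.
#' @param linker Linker name.
#' @param charge_range Precursor charge support (default 4:8).
#' @param noise_peaks Noise peaks per spectrum.
#' @param ppm_sigma Gaussian m/z error sigma in ppm.
#' @param detection_prob Detection probability for sequence (b/y) fragment
#'   ions; the signature fragments and precursors are the dominant cleavage
#'   products and are always emitted.
#' @param emit_alpha_t Emit the dehydrated alpha_T peak in MS2 (default TRUE
#'   except for SIAB, whose sulfenic acid is less prone to dehydration).
#' @param mode `"msn"` or `"ms2"` acquisition.
#' @param ms3_top_n MS3 scans per MS2 (top signature-candidate peaks).
#' @return A list of class `kcx_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 50L, protein_length = 200L,
                       aa_freq = NULL, n_links = 100L, intra_fraction = 0.5,
                       linker = "SIA", charge_range = 4:8,
                       noise_peaks = 100L, ppm_sigma = 5,
                       detection_prob = 0.9, emit_alpha_t = NULL,
                       mode = c("msn", "ms2"), ms3_top_n = 4L) {
  mode <- match.arg(mode)
  if (is.null(aa_freq)) {
    aa_freq <- c(A = 0.074, R = 0.057, N = 0.044, D = 0.054, C = 0.023,
                 E = 0.062, Q = 0.045, G = 0.074, H = 0.026, I = 0.045,
                 L = 0.099, K = 0.057, M = 0.022, F = 0.038, P = 0.057,
                 S = 0.081, T = 0.062, W = 0.013, Y = 0.033, V = 0.068)
  }
  stopifnot(detection_prob >= 0, detection_prob <= 1, intra_fraction >= 0,
            intra_fraction <= 1)
  if (is.null(emit_alpha_t)) emit_alpha_t <- !identical(linker, "SIAB")
  structure(
    list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
         protein_length = as.integer(protein_length), aa_freq = aa_freq,
         n_links = as.integer(n_links), intra_fraction = intra_fraction,
         linker = linker, charge_range = charge_range,
         noise_peaks = as.integer(noise_peaks), ppm_sigma = ppm_sigma,
         detection_prob = detection_prob, emit_alpha_t = emit_alpha_t,
         mode = mode, ms3_top_n = as.integer(ms3_top_n)),
    class = "kcx_sim_config"
  )
}

#' Simulate a ground-truthed proteome with planted K-C cross-links
#'
#' Random sequences with the configured residue frequencies; planted links
#' are realizability-checked at planting time: both residues must sit in a
#' tryptic peptide within the digest length bounds, the lysine internal to
#' its peptide.
#'
#' @param config A [sim_config()].
#' @param prefix Protein id prefix (default `"SYN"`).
#' @return A list with `sequences` (named character), `links` (the planted
#'   linkage truth tibble) and `config`.
#' @export
simulate_proteome <- function(config, prefix = "SYN") {
  stopifnot(inherits(config, "kcx_sim_config"))
  if (config$n_links > 0 &&
      (config$aa_freq[["K"]] == 0 || config$aa_freq[["C"]] == 0)) {
    rlang::abort("cannot plant K-C links in a proteome without K or C")
  }
  set.seed(config$seed)
  aas <- names(config$aa_freq)
  seqs <- vapply(seq_len(config$n_proteins), function(i) {
    paste(sample(aas, config$protein_length, replace = TRUE,
                 prob = config$aa_freq), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("%s%03d", prefix, seq_len(config$n_proteins))
  if (config$n_links == 0) {
    return(list(sequences = seqs, links = NULL, config = config))
  }
  idx <- digest(seqs, decoy = "none")
  # eligible sites: use fully tryptic host peptides (missed <= 1 so the
  # cross-linked K's own blocked cleavage stays within the search bounds)
  k_sites <- site_table(idx, "k_pos")
  c_sites <- site_table(idx, "c_pos")
  if (!nrow(k_sites) || !nrow(c_sites)) {
    rlang::abort("proteome has no digest-realizable K or C sites")
  }
  n_intra <- round(config$n_links * config$intra_fraction)
  links <- list()
  used <- character()
  tries <- 0
  while (length(links) < config$n_links && tries < config$n_links * 200) {
    tries <- tries + 1
    want_intra <- length(links) < n_intra
    ka <- k_sites[sample(nrow(k_sites), 1), ]
    cb_pool <- if (want_intra) {
      dplyr::filter(c_sites, .data$protein == ka$protein)
    } else {
      dplyr::filter(c_sites, .data$protein != ka$protein)
    }
    if (!nrow(cb_pool)) next
    cb <- cb_pool[sample(nrow(cb_pool), 1), ]
    if (identical(ka$protein, cb$protein) && ka$peptide == cb$peptide) next
    key <- paste(ka$protein, ka$res, cb$protein, cb$res)
    if (key %in% used) next
    used <- c(used, key)
    links[[length(links) + 1]] <- tibble::tibble(
      link_id = length(links) + 1L,
      protein_a = ka$protein, res_a = ka$res, pep_a = ka$peptide,
      start_a = ka$start, site_a = ka$site,
      protein_b = cb$protein, res_b = cb$res, pep_b = cb$peptide,
      start_b = cb$start, site_b = cb$site,
      linker = config$linker
    )
  }
  links <- dplyr::bind_rows(links)
  if (nrow(links) < config$n_links) {
    rlang::warn(sprintf("planted only %d of %d requested links", nrow(links),
                        config$n_links))
  }
  list(sequences = seqs, links = links, config = config)
}

site_table <- function(idx, col) {
  idx0 <- dplyr::filter(idx, .data$missed <= 1)
  rows <- purrr::map(seq_len(nrow(idx0)), function(i) {
    pos <- idx0[[col]][[i]]
    if (!length(pos)) return(NULL)
    tibble::tibble(protein = idx0$protein[i], peptide = idx0$peptide[i],
                   start = idx0$start[i], site = pos,
                   res = idx0$start[i] + pos - 1L)
  })
  d <- dplyr::bind_rows(rows)
  if (!nrow(d)) return(d)
  # one host peptide per (protein, residue): shortest, fewest missed
  dplyr::distinct(dplyr::arrange(d, .data$protein, .data$res,
                                 nchar(.data$peptide)),
                  .data$protein, .data$res, .keep_all = TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Simulate an MSn (or stepped-HCD MS2) run from planted cross-links
#'
#' Per planted link: an MS1 scan with the precursor at the theoretical m/z
#' plus Gaussian ppm error; an MS2 scan with the alpha_S / beta_A signature
#' fragments (plus alpha_T when configured) and noise; and (in `msn` mode)
#' MS3 scans of the signature fragments carrying remnant-modified b/y
#' ladders. Sequence-ion peaks are dropped independently with probability
#' `1 - detection_prob`. In `ms2` mode one stepped-HCD spectrum carries both
#' signature fragments and both remnant-modified ladders.
#'
#' @param proteome Output of [simulate_proteome()].
#' @param config A [sim_config()]; defaults to the proteome's.
#' @param replicate Replicate label stored on the run.
#' @return A list with `run` (run tibble) and `provenance` (per-link scan ids
#'   and true peptide assignments).
#' @export
simulate_msn_run <- function(proteome, config = proteome$config,
                             replicate = "rep1") {
  stopifnot(inherits(config, "kcx_sim_config"))
  links <- proteome$links
  if (is.null(links) || !nrow(links)) rlang::abort("no planted links to simulate")
  set.seed(config$seed + 1L)
  r <- remnants_for(config$linker)
  cam <- composition_mass(NAMED_MODS[["carbamidomethyl"]])
  jitter_mz <- function(mz) mz * (1 + rnorm(length(mz), 0, config$ppm_sigma) * 1e-6)
  sig_int <- function(n) rlnorm(n, log(1e5), 0.3)
  rows <- list()
  prov <- list()
  for (i in seq_len(nrow(links))) {
    lk <- links[i, ]
    res_a <- strsplit(lk$pep_a, "")[[1]]
    res_b <- strsplit(lk$pep_b, "")[[1]]
    ca_all <- which(res_a == "C")
    cb_all <- which(res_b == "C")
    ma <- sum(residue_mass_vector()[res_a]) + composition_mass("H2O") +
      cam * length(ca_all)
    mb <- sum(residue_mass_vector()[res_b]) + composition_mass("H2O") +
      cam * (length(cb_all) - 1)
    M <- ma + mb + r$intact_ox_addition
    z <- sample(config$charge_range, 1)
    prec_mz <- jitter_mz(neutral_to_mz(M, z))
    n_aS <- ma + r$alpha_S_mod
    n_bA <- mb + r$beta_A_mod
    mz_aS <- jitter_mz(neutral_to_mz(n_aS, 2))
    mz_bA <- jitter_mz(neutral_to_mz(n_bA, 2))
    base <- (i - 1L) * 10L
    noise <- function() {
      if (config$noise_peaks == 0) {
        return(tibble::tibble(mz = numeric(), intensity = numeric()))
      }
      tibble::tibble(mz = runif(config$noise_peaks, 200, 2000),
                     intensity = rexp(config$noise_peaks, 1 / 1e3))
    }
    ladder <- function(seq_res, site, rmass, exclude_cam) {
      mz <- remnant_ladder(seq_res, site, rmass,
                           which(seq_res == "C"), cam_exclude = exclude_cam)
      keep <- runif(length(mz)) < config$detection_prob
      tibble::tibble(mz = jitter_mz(mz[keep]), intensity = sig_int(sum(keep)))
    }
    # MS1
    rows[[length(rows) + 1]] <- spectrum_row(base + 1L, 1L, prec_mz, 1e7)
    # MS2: signature fragments + noise (+ ladders in ms2 mode)
    sig <- tibble::tibble(mz = c(mz_aS, mz_bA), intensity = sig_int(2))
    if (config$emit_alpha_t) {
      sig <- dplyr::bind_rows(sig, tibble::tibble(
        mz = jitter_mz(neutral_to_mz(n_aS - composition_mass("H2O"), 2)),
        intensity = sig_int(1) * 0.5
      ))
    }
    ms2_peaks <- dplyr::bind_rows(sig, noise())
    if (config$mode == "ms2") {
      ms2_peaks <- dplyr::bind_rows(
        ms2_peaks,
        ladder(res_a, lk$site_a, r$alpha_S_mod, NA),
        ladder(res_b, lk$site_b, r$beta_A_mod, lk$site_b)
      )
    }
    rows[[length(rows) + 1]] <- spectrum_row(
      base + 2L, 2L, ms2_peaks$mz, ms2_peaks$intensity,
      precursor_mz = prec_mz, precursor_charge = z,
      activation = if (config$mode == "ms2") "stepped-HCD" else "CID"
    )
    ms3_a <- ms3_b <- NA_integer_
    if (config$mode == "msn") {
      lad_a <- dplyr::bind_rows(ladder(res_a, lk$site_a, r$alpha_S_mod, NA),
                                noise())
      lad_b <- dplyr::bind_rows(ladder(res_b, lk$site_b, r$beta_A_mod,
                                       lk$site_b), noise())
      ms3_a <- base + 3L
      ms3_b <- base + 4L
      rows[[length(rows) + 1]] <- spectrum_row(
        ms3_a, 3L, lad_a$mz, lad_a$intensity,
        precursor_mz = mz_aS, precursor_charge = 2L,
        parent_scan = base + 2L, selected_mz = mz_aS, activation = "HCD"
      )
      rows[[length(rows) + 1]] <- spectrum_row(
        ms3_b, 3L, lad_b$mz, lad_b$intensity,
        precursor_mz = mz_bA, precursor_charge = 2L,
        parent_scan = base + 2L, selected_mz = mz_bA, activation = "HCD"
      )
    }
    prov[[length(prov) + 1]] <- tibble::tibble(
      link_id = lk$link_id, ms2_scan = base + 2L,
      ms3_alpha_scan = ms3_a, ms3_beta_scan = ms3_b,
      precursor_charge = z, precursor_mz = prec_mz,
      alpha_S_mz = mz_aS, beta_A_mz = mz_bA
    )
  }
  run <- as_run(dplyr::bind_rows(rows), linker = config$linker,
                replicate = replicate)
  list(run = run, provenance = dplyr::bind_rows(prov))
}

#' Run the full identification pipeline on a simulated run
#'
#' Convenience wrapper: digest (with reverse decoys), signature-pair
#' detection + MS3 matching + integration (msn mode) or stepped-HCD search
#' (ms2 mode), FDR estimation and filtering.
#'
#' @param proteome Output of [simulate_proteome()].
#' @param run_sim Output of [simulate_msn_run()].
#' @param extra_sequences Optional additional (entrapment) proteins appended
#'   to the search database.
#' @param fdr FDR threshold (default 0.01).
#' @return A list with `csms` (all, classed), `accepted` (FDR-filtered TT),
#'   `fdr` (the `kcx_fdr` object) and `index`.
#' @export
search_simulated <- function(proteome, run_sim, extra_sequences = NULL,
                             fdr = 0.01) {
  cfg <- proteome$config
  db <- c(proteome$sequences, extra_sequences)
  index <- digest(db, decoy = "reverse")
  run <- run_sim$run
  if (cfg$mode == "msn") {
    pairs <- detect_signature_pairs(run, cfg$linker)
    psms <- match_ms3(run, index, cfg$linker)
    csms <- integrate_msn(run, pairs, psms, cfg$linker)
  } else {
    ranked <- search_ms2_stepped_hcd(run, index, cfg$linker)
    csms <- dplyr::filter(ranked, .data$rank == 1)
  }
  fdr_res <- estimate_fdr(csms)
  list(csms = csms, accepted = apply_fdr(fdr_res, fdr), fdr = fdr_res,
       index = index)
}

#' Fraction of planted links recovered as rank-1 target CSMs
#'
#' @param accepted FDR-filtered CSM tibble.
#' @param links Planted truth tibble from [simulate_proteome()].
#' @param provenance Provenance tibble from [simulate_msn_run()].
#' @return Recovery fraction in `[0, 1]`.
#' @export
planted_recovery <- function(accepted, links, provenance) {
  hit <- vapply(seq_len(nrow(links)), function(i) {
    lk <- links[i, ]
    scan <- provenance$ms2_scan[provenance$link_id == lk$link_id]
    rows <- accepted[accepted$scan == scan, ]
    any(rows$alpha_peptide == lk$pep_a & rows$alpha_site == lk$site_a &
          rows$beta_peptide == lk$pep_b & rows$beta_site == lk$site_b)
  }, logical(1))
  mean(hit)
}

#' Entrapment false-discovery proportion
#'
#' Simulates spectra from proteome A and searches them against A plus an
#' entrapment proteome B; any accepted CSM touching a B protein is a known
#' false discovery, so the observed proportion calibrates the target-decoy
#' FDR estimate.
#'
#' @param seed Seed for both proteomes and the run.
#' @param config Base [sim_config()] (seed is overridden).
#' @param n_entrap Number of entrapment proteins.
#' @param fdr Nominal FDR thresholds to evaluate.
#' @return A tibble with `fdr_nominal`, `n_accepted`, `n_entrap_hits`, `fdp`.
#' @export
entrapment_fdp <- function(seed, config = sim_config(), n_entrap = 50L,
                           fdr = c(0.01, 0.05)) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  prot <- simulate_proteome(cfg)
  sim <- simulate_msn_run(prot, cfg)
  ecfg <- cfg
  ecfg$seed <- cfg$seed + 77777L
  ecfg$n_links <- 0L
  entrap <- simulate_proteome(ecfg, prefix = "ENT")
  res <- search_simulated(prot, sim, extra_sequences = entrap$sequences,
                          fdr = max(fdr))
  purrr::map_dfr(fdr, function(f) {
    acc <- apply_fdr(res$fdr, f)
    in_entrap <- vapply(seq_len(nrow(acc)), function(i) {
      any(startsWith(acc$alpha_proteins[[i]]$protein, "ENT")) ||
        any(startsWith(acc$beta_proteins[[i]]$protein, "ENT"))
    }, logical(1))
    tibble::tibble(fdr_nominal = f, n_accepted = nrow(acc),
                   n_entrap_hits = sum(in_entrap),
                   fdp = if (nrow(acc)) mean(in_entrap) else 0)
  })
}

#' Simulate toy structures with known geometry
#'
#' Builds Calpha-only models from explicit coordinates: a straight-line chain
#' with fixed spacing, optionally duplicated into a rigid-offset homodimer,
#' so every pairwise distance has a closed-form truth.
#'
#' @param n_res Residues per chain.
#' @param spacing Calpha spacing along the chain axis in Angstrom
#'   (default 3.8).
#' @param homodimer_offset Optional rigid offset (Angstrom) of a second copy
#'   perpendicular to the chain axis; `NULL` for a monomer.
#' @param sequence Optional sequence (defaults to alternating `KACG`).
#' @param structure_id Structure identifier.
#' @param plddt Optional per-residue pLDDT vector (marks the model predicted).
#' @return A `kcx_structure` (see [read_structure()]) with a `truth` attribute
#'   function `d(i, j, chains)` is unnecessary: distances follow from the
#'   explicit coordinates stored in the object.
#' @export
simulate_toy_structure <- function(n_res = 40L, spacing = 3.8,
                                   homodimer_offset = NULL, sequence = NULL,
                                   structure_id = "TOY1", plddt = NULL) {
  if (is.null(sequence)) {
    sequence <- paste(rep(c("K", "A", "C", "G"), length.out = n_res),
                      collapse = "")
  }
  res <- strsplit(sequence, "")[[1]][seq_len(n_res)]
  chainA <- tibble::tibble(
    chain = "A", resno = seq_len(n_res), aa = res,
    x = (seq_len(n_res) - 1) * spacing, y = 0, z = 0,
    plddt = if (is.null(plddt)) NA_real_ else plddt
  )
  atoms <- chainA
  if (!is.null(homodimer_offset)) {
    chainB <- dplyr::mutate(chainA, chain = "B", y = homodimer_offset)
    atoms <- dplyr::bind_rows(chainA, chainB)
  }
  new_structure(atoms, structure_id,
                model_class = if (is.null(plddt)) "experimental" else "predicted")
}

#' Write a Calpha-only structure to a PDB file
#'
#' @param structure A `kcx_structure`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_toy_pdb <- function(structure, path) {
  atoms <- structure$atoms
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
           Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
    seq_len(nrow(atoms)), aa3[atoms$aa], atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z,
    ifelse(is.na(atoms$plddt), 0, atoms$plddt)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
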