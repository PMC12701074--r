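# Distance mapping of K-C linkages onto experimental and predicted
# structures. Distances are straight-line Calpha-Calpha in Angstrom;
# satisfaction is strict (< threshold, default 30 A).

#' Build a structure from explicit Calpha coordinates
#'
#' @param atoms Data frame with columns `chain`, `resno`, `aa` (one-letter),
#'   `x`, `y`, `z` and optional `plddt`.
#' @param structure_id Identifier.
#' @param model_class `"experimental"` or `"predicted"`.
#' @return A `kcx_structure`.
#' @export
structure_from_coords <- function(atoms, structure_id,
                                  model_class = "experimental") {
  new_structure(atoms, structure_id, model_class)
}

new_structure <- function(atoms, structure_id, model_class = "experimental") {
  stopifnot(all(c("chain", "resno", "aa", "x", "y", "z") %in% names(atoms)))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    rlang::abort("structure coordinates must be finite")
  }
  if (!"plddt" %in% names(atoms)) atoms$plddt <- NA_real_
  if (any(!is.na(atoms$plddt) & (atoms$plddt < 0 | atoms$plddt > 100))) {
    rlang::abort("pLDDT values must lie in [0, 100]")
  }
  structure(list(structure_id = structure_id, model_class = model_class,
                 atoms = tibble::as_tibble(atoms)),
            class = "kcx_structure")
}

#' @export
print.kcx_structure <- function(x, ...) {
  cat(sprintf("<kcx_structure> %s (%s): %d chain(s), %d residues\n",
              x$structure_id, x$model_class,
              dplyr::n_distinct(x$atoms$chain), nrow(x$atoms)))
  invisible(x)
}

#' Read a structure (PDB or mmCIF) as Calpha records
#'
#' Uses the bio3d backend. For predicted models the B-factor column is read
#' as per-residue pLDDT.
#'
#' @param path PDB or mmCIF file path.
#' @param structure_id Identifier (default: file base name).
#' @param model_class `"experimental"` or `"predicted"`; for predicted
#'   models the B-factor is interpreted as pLDDT.
#' @return A `kcx_structure`: per-residue Calpha coordinates by chain.
#' @export
read_structure <- function(path, structure_id = NULL,
                           model_class = c("experimental", "predicted")) {
  model_class <- match.arg(model_class)
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  a <- pdb$atom
  a <- a[a$elety == "CA", ]
  aa1 <- bio3d::aa321(a$resid)
  atoms <- tibble::tibble(
    chain = a$chain, resno = a$resno, aa = aa1,
    x = a$x, y = a$y, z = a$z,
    plddt = if (model_class == "predicted") a$b else NA_real_
  )
  atoms <- dplyr::distinct(atoms, .data$chain, .data$resno, .keep_all = TRUE)
  new_structure(atoms, structure_id, model_class)
}

#' Build a residue-mapping table
#'
#' Maps protein (UniProt-style, 1-based) residue numbering to structure
#' chain/residue numbering by a constant offset per (protein, structure,
#' chain): `structure_resno = protein_resno + offset`. When protein
#' sequences are supplied, mappings whose structure residues disagree with
#' the sequence are excluded with a flag rather than silently used.
#'
#' @param mapping A data frame with columns `protein`, `structure_id`,
#'   `chain`, `offset` (or a TSV path to one).
#' @param structures Optional named list of `kcx_structure` used for
#'   sequence validation.
#' @param sequences Optional named character vector of protein sequences.
#' @return The mapping tibble with a logical `valid` column.
#' @export
residue_mapping <- function(mapping, structures = NULL, sequences = NULL) {
  if (is.character(mapping)) {
    mapping <- readr::read_tsv(mapping, show_col_types = FALSE)
  }
  mapping <- tibble::as_tibble(mapping)
  stopifnot(all(c("protein", "structure_id", "chain", "offset") %in% names(mapping)))
  mapping$valid <- TRUE
  if (!is.null(structures) && !is.null(sequences)) {
    for (i in seq_len(nrow(mapping))) {
      st <- structures[[mapping$structure_id[i]]]
      sq <- sequences[[mapping$protein[i]]]
      if (is.null(st) || is.null(sq)) next
      at <- dplyr::filter(st$atoms, .data$chain == mapping$chain[i])
      prot_res <- at$resno - mapping$offset[i]
      ok <- prot_res >= 1 & prot_res <= nchar(sq)
      exp_aa <- substring(sq, prot_res[ok], prot_res[ok])
      mismatch <- mean(exp_aa != at$aa[ok])
      if (!is.nan(mismatch) && mismatch > 0) mapping$valid[i] <- FALSE
    }
    if (any(!mapping$valid)) {
      rlang::warn(sprintf("%d mapping row(s) excluded: structure numbering disagrees with sequence",
                          sum(!mapping$valid)))
    }
  }
  mapping
}

ca_lookup <- function(st, chain, resno) {
  at <- st$atoms
  hit <- which(at$chain == chain & at$resno == resno)
  if (!length(hit)) return(NULL)
  at[hit[1], ]
}

#' Map linkages onto structures and compute Calpha-Calpha distances
#'
#' Computes the distance in every (structure, chain pair) combination that
#' covers both residues. For intra-protein linkages, same-chain distances and
#' inter-chain (homo-oligomer) distances are both computed; the per-linkage
#' minimal distance and its provenance are what downstream summaries use.
#' Residues whose mapped amino acid does not match K / C are excluded with a
#' reason.
#'
#' @param linkages Linkage tibble (needs `protein_a`, `res_a`, `protein_b`,
#'   `res_b`; an `intra` column is derived if absent).
#' @param structures Named list of `kcx_structure` objects.
#' @param mapping Residue-mapping tibble from [residue_mapping()].
#' @param threshold Satisfaction threshold in Angstrom, strict (default 30).
#' @param check_identity Exclude combinations whose structure residues are
#'   not K / C (default TRUE); disable for residue-agnostic geometry checks.
#' @return A distance-record tibble: one row per linkage x structure x chain
#'   pair, with `distance`, `context` (`same-chain`, `inter-chain-homomer`,
#'   `inter-chain-heteromer`), `satisfied`, `min_plddt`, `model_class`, and a
#'   `linkage_id` key; plus rows with `outcome = "unmapped"` for linkages not
#'   covered by any structure. `outcome = "mapped"` rows carry distances.
#' @export
map_linkages <- function(linkages, structures, mapping, threshold = 30,
                         check_identity = TRUE) {
  mapping <- tibble::as_tibble(mapping)
  if ("valid" %in% names(mapping)) {
    mapping <- dplyr::filter(mapping, .data$valid)
  }
  if (!"intra" %in% names(linkages)) {
    linkages$intra <- linkages$protein_a == linkages$protein_b
  }
  if (!"linkage_id" %in% names(linkages)) {
    linkages$linkage_id <- seq_len(nrow(linkages))
  }
  out <- list()
  for (i in seq_len(nrow(linkages))) {
    lk <- linkages[i, ]
    map_a <- dplyr::filter(mapping, .data$protein == lk$protein_a)
    map_b <- dplyr::filter(mapping, .data$protein == lk$protein_b)
    shared <- intersect(map_a$structure_id, map_b$structure_id)
    found <- FALSE
    for (sid in shared) {
      st <- structures[[sid]]
      if (is.null(st)) next
      ma <- dplyr::filter(map_a, .data$structure_id == sid)
      mb <- dplyr::filter(map_b, .data$structure_id == sid)
      for (ia in seq_len(nrow(ma))) {
        for (ib in seq_len(nrow(mb))) {
          at_a <- ca_lookup(st, ma$chain[ia], lk$res_a + ma$offset[ia])
          at_b <- ca_lookup(st, mb$chain[ib], lk$res_b + mb$offset[ib])
          if (is.null(at_a) || is.null(at_b)) next
          if (check_identity && (at_a$aa != "K" || at_b$aa != "C")) {
            out[[length(out) + 1]] <- record_row(
              lk, sid, st, at_a, at_b, NA_real_, "excluded",
              reason = "residue identity mismatch", threshold
            )
            next
          }
          d <- sqrt((at_a$x - at_b$x)^2 + (at_a$y - at_b$y)^2 +
                      (at_a$z - at_b$z)^2)
          context <- if (at_a$chain == at_b$chain) "same-chain"
          else if (lk$intra) "inter-chain-homomer"
          else "inter-chain-heteromer"
          out[[length(out) + 1]] <- record_row(lk, sid, st, at_a, at_b, d,
                                               "mapped", context, threshold)
          found <- TRUE
        }
      }
    }
    if (!found) {
      out[[length(out) + 1]] <- tibble::tibble(
        linkage_id = lk$linkage_id, protein_a = lk$protein_a,
        res_a = lk$res_a, protein_b = lk$protein_b, res_b = lk$res_b,
        intra = lk$intra, structure_id = NA_character_,
        chain_a = NA_character_, chain_b = NA_character_,
        resno_a = NA_integer_, resno_b = NA_integer_,
        distance = NA_real_, context = NA_character_, outcome = "unmapped",
        satisfied = NA, min_plddt = NA_real_, model_class = NA_character_
      )
    }
  }
  dplyr::bind_rows(out)
}

record_row <- function(lk, sid, st, at_a, at_b, d, outcome,
                       context = NA_character_, threshold = 30,
                       reason = NULL) {
  tibble::tibble(
    linkage_id = lk$linkage_id, protein_a = lk$protein_a, res_a = lk$res_a,
    protein_b = lk$protein_b, res_b = lk$res_b, intra = lk$intra,
    structure_id = sid, chain_a = at_a$chain, chain_b = at_b$chain,
    resno_a = at_a$resno, resno_b = at_b$resno,
    distance = d,
    context = if (outcome == "excluded") reason else context,
    outcome = outcome,
    satisfied = if (is.na(d)) NA else d < threshold,
    min_plddt = suppressWarnings(min(c(at_a$plddt, at_b$plddt))),
    model_class = st$model_class
  )
}

#' Minimal distance record per linkage
#'
#' @param records Distance records from [map_linkages()].
#' @return One row per mapped linkage: the record with the smallest distance
#'   over all structures and chain pairs.
#' @export
minimal_distances <- function(records) {
  m <- dplyr::filter(records, .data$outcome == "mapped")
  m <- dplyr::arrange(m, .data$linkage_id, .data$distance)
  dplyr::distinct(m, .data$linkage_id, .keep_all = TRUE)
}

#' Satisfaction summary of mapped linkages
#'
#' Uses the per-linkage minimal distance. Satisfaction is strict
#' (`distance < threshold`). Homo-oligomer rescue — linkages satisfied only
#' through an inter-chain distance — is reported separately: rescue can only
#' increase the satisfied count.
#'
#' @param records Distance records from [map_linkages()].
#' @param threshold Angstrom threshold, strict (default 30).
#' @param group Optional character vector of grouping columns (e.g.
#'   `"intra"`).
#' @return A tibble with `mapped`, `satisfied`, `rate`, `median_distance`,
#'   `rescued` per group (one row when `group` is NULL). Empty input gives an
#'   empty summary.
#' @export
satisfaction_summary <- function(records, threshold = 30, group = NULL) {
  m <- dplyr::filter(records, .data$outcome == "mapped")
  if (!nrow(m)) {
    return(tibble::tibble(mapped = integer(), satisfied = integer(),
                          rate = numeric(), median_distance = numeric(),
                          rescued = integer()))
  }
  per_link <- dplyr::summarise(
    dplyr::group_by(m, dplyr::across(dplyr::all_of(c("linkage_id", group)))),
    min_dist = min(.data$distance),
    min_same_chain = suppressWarnings(
      min(.data$distance[.data$context == "same-chain"])),
    .groups = "drop"
  )
  per_link$satisfied <- per_link$min_dist < threshold
  per_link$rescued <- per_link$satisfied &
    !(is.finite(per_link$min_same_chain) &
        per_link$min_same_chain < threshold)
  dplyr::summarise(
    dplyr::group_by(per_link, dplyr::across(dplyr::all_of(group %||% character()))),
    mapped = dplyr::n(),
    satisfied = sum(.data$satisfied),
    rate = .data$satisfied / .data$mapped,
    median_distance = stats::median(.data$min_dist),
    rescued = sum(.data$rescued),
    .groups = "drop"
  )
}

#' Read a predicted-aligned-error matrix from JSON
#'
#' Accepts the standard layout: either a top-level object (or length-1 array
#' of objects) with a `predicted_aligned_error` field, or a bare square
#' array.
#'
#' @param path JSON file path.
#' @return A square numeric matrix (Angstrom); values must be non-negative.
#' @export
read_pae <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.data.frame(x) && "predicted_aligned_error" %in% names(x)) {
    m <- x$predicted_aligned_error[[1]]
  } else if (is.list(x) && "predicted_aligned_error" %in% names(x)) {
    m <- x$predicted_aligned_error
  } else {
    m <- x
  }
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) rlang::abort("PAE matrix must be square")
  if (any(m < 0)) rlang::abort("PAE values must be non-negative")
  m
}

#' Symmetrized PAE of a residue pair
#'
#' The predicted aligned error is directional; the pair value used here is
#' the mean of the (i, j) and (j, i) entries.
#'
#' @param pae A square PAE matrix.
#' @param i,j Residue indices (1-based over the model).
#' @return Symmetrized PAE in Angstrom.
#' @export
pae_for_pair <- function(pae, i, j) {
  n <- nrow(pae)
  if (any(c(i, j) < 1) || any(c(i, j) > n)) {
    rlang::abort("residue index outside the PAE matrix")
  }
  (pae[cbind(i, j)] + pae[cbind(j, i)]) / 2
}

#' Gate records on model confidence
#'
#' Keeps records whose confidence value is strictly below the cutoff
#' (PAE < 20 by default); pLDDT gating keeps pairs with min pLDDT strictly
#' above its cutoff.
#'
#' @param records Distance records carrying a `pae` (or `min_plddt`) column.
#' @param pae_cutoff Strict upper bound on pair PAE (default 20).
#' @param plddt_cutoff Optional strict lower bound on min pLDDT (default
#'   NULL = no pLDDT gate; 70 is the conventional choice).
#' @return The filtered records.
#' @export
confidence_gate <- function(records, pae_cutoff = 20, plddt_cutoff = NULL) {
  out <- records
  if ("pae" %in% names(out) && !is.null(pae_cutoff)) {
    out <- dplyr::filter(out, is.na(.data$pae) | .data$pae < pae_cutoff)
  }
  if (!is.null(plddt_cutoff)) {
    out <- dplyr::filter(out, is.na(.data$min_plddt) |
                           .data$min_plddt > plddt_cutoff)
  }
  out
}

#' Satisfaction stratified by model confidence
#'
#' @param records Distance records with a confidence column.
#' @param by Confidence column name (default `"pae"`).
#' @param breaks Stratum breaks passed to [cut()].
#' @param threshold Distance threshold (strict).
#' @return A tibble `(stratum, mapped, satisfied, rate)`; empty strata are
#'   reported with `rate = NA`.
#' @export
confidence_stratified_satisfaction <- function(records, by = "pae",
                                               breaks = c(0, 10, 20, 30, Inf),
                                               threshold = 30) {
  m <- dplyr::filter(records, .data$outcome == "mapped", !is.na(.data[[by]]))
  m$stratum <- cut(m[[by]], breaks, include.lowest = TRUE, right = FALSE)
  full <- tibble::tibble(stratum = levels(m$stratum))
  got <- dplyr::summarise(
    dplyr::group_by(m, stratum = as.character(.data$stratum)),
    mapped = dplyr::n(),
    satisfied = sum(.data$distance < threshold),
    .groups = "drop"
  )
  out <- dplyr::left_join(full, got, by = "stratum")
  out$mapped[is.na(out$mapped)] <- 0L
  out$satisfied[is.na(out$satisfied)] <- 0L
  out$rate <- ifelse(out$mapped > 0, out$satisfied / out$mapped, NA_real_)
  out
}

# ---- secondary structure ----

#' Group a secondary-structure label into helix / sheet / loop
#'
#' DSSP-style labels H, G, I map to helix; E, B to sheet; everything else
#' (T, S, P, blank) to loop, so the grouping covers the whole alphabet.
#'
#' @param label Character vector of per-residue labels.
#' @return Character vector in `c("helix", "sheet", "loop")`.
#' @export
ss_group <- function(label) {
  dplyr::case_when(
    label %in% c("H", "G", "I") ~ "helix",
    label %in% c("E", "B") ~ "sheet",
    TRUE ~ "loop"
  )
}

#' Secondary-structure enrichment of cross-linked residues
#'
#' Counts the helix/sheet/loop classes of the cross-linked lysines and
#' cysteines among satisfied records (minimal distance strictly below the
#' threshold) and normalizes each class count by the background class
#' frequency of that residue type over the model set. The profile is
#' invariant under duplication of the background set.
#'
#' @param records Distance records from [map_linkages()].
#' @param ss_labels Tibble `(structure_id, chain, resno, ss)` of per-residue
#'   assignment labels.
#' @param background Tibble `(aa, ss)` (one row per background residue) used
#'   for normalization.
#' @param threshold Distance threshold (strict, default 30).
#' @return A tibble `(residue, class, count, background_freq, enrichment,
#'   n_skipped)`; classes with zero background are reported with
#'   `enrichment = NA`.
#' @export
secstruct_enrichment <- function(records, ss_labels, background,
                                 threshold = 30) {
  m <- minimal_distances(records)
  m <- dplyr::filter(m, .data$distance < threshold)
  classes <- c("helix", "sheet", "loop")
  lab <- function(sid, chain, resno) {
    hit <- ss_labels$ss[ss_labels$structure_id == sid &
                          ss_labels$chain == chain & ss_labels$resno == resno]
    if (length(hit)) ss_group(hit[1]) else NA_character_
  }
  k_class <- purrr::pmap_chr(list(m$structure_id, m$chain_a, m$resno_a), lab)
  c_class <- purrr::pmap_chr(list(m$structure_id, m$chain_b, m$resno_b), lab)
  bg <- dplyr::mutate(tibble::as_tibble(background), class = ss_group(.data$ss))
  out <- purrr::map_dfr(list(c("K", "a"), c("C", "b")), function(side) {
    obs <- if (side[2] == "a") k_class else c_class
    skipped <- sum(is.na(obs))
    obs <- obs[!is.na(obs)]
    bg_side <- dplyr::filter(bg, .data$aa == side[1])
    bg_tot <- nrow(bg_side)
    purrr::map_dfr(classes, function(cl) {
      cnt <- sum(obs == cl)
      bgf <- if (bg_tot > 0) sum(bg_side$class == cl) / bg_tot else NA_real_
      obsf <- if (length(obs)) cnt / length(obs) else NA_real_
      tibble::tibble(
        residue = side[1], class = cl, count = cnt,
        background_freq = bgf,
        enrichment = if (!is.na(bgf) && bgf > 0) obsf / bgf else NA_real_,
        n_skipped = skipped
      )
    })
  })
  out
}

#' Distance distributions keyed by secondary-structure class pair
#'
#' @param records Distance records.
#' @param ss_labels Per-residue label tibble (see [secstruct_enrichment()]).
#' @return A tibble `(class_a, class_b, n, median_distance, distances)`;
#'   the groups partition the labeled records.
#' @export
distance_by_secstruct <- function(records, ss_labels) {
  m <- minimal_distances(records)
  lab <- function(sid, chain, resno) {
    hit <- ss_labels$ss[ss_labels$structure_id == sid &
                          ss_labels$chain == chain & ss_labels$resno == resno]
    if (length(hit)) ss_group(hit[1]) else NA_character_
  }
  m$class_a <- purrr::pmap_chr(list(m$structure_id, m$chain_a, m$resno_a), lab)
  m$class_b <- purrr::pmap_chr(list(m$structure_id, m$chain_b, m$resno_b), lab)
  m <- dplyr::filter(m, !is.na(.data$class_a), !is.na(.data$class_b))
  dplyr::summarise(
    dplyr::group_by(m, .data$class_a, .data$class_b),
    n = dplyr::n(),
    median_distance = stats::median(.data$distance),
    distances = list(.data$distance),
    .groups = "drop"
  )
}

#' Calpha-geometry secondary-structure heuristic
#'
#' A hydrogen-bond-free fallback assigner for Calpha-only models: residue i
#' is called helix when the i to i+3 Calpha distance is below 6.5 A, sheet
#' when the local chain is nearly fully extended (i to i+2 distance above
#' 6.4 A), loop otherwise. Intended for fixtures and rough profiles, not as
#' a DSSP replacement.
#'
#' @param structure A `kcx_structure`.
#' @return A tibble `(structure_id, chain, resno, ss)` with DSSP-style
#'   letters (`H`, `E`, `C`).
#' @export
assign_secstruct_ca <- function(structure) {
  purrr::map_dfr(split(structure$atoms, structure$atoms$chain), function(at) {
    at <- dplyr::arrange(at, .data$resno)
    n <- nrow(at)
    d_k <- function(k) {
      i <- seq_len(max(0, n - k))
      sqrt((at$x[i + k] - at$x[i])^2 + (at$y[i + k] - at$y[i])^2 +
             (at$z[i + k] - at$z[i])^2)
    }
    d3 <- c(d_k(3), rep(NA, min(n, 3)))
    d2 <- c(d_k(2), rep(NA, min(n, 2)))
    helix <- !is.na(d3) & d3 < 6.5
    sheet <- !helix & !is.na(d2) & d2 > 6.4
    ss <- rep("C", n)
    ss[helix] <- "H"
    ss[sheet] <- "E"
    tibble::tibble(structure_id = structure$structure_id, chain = at$chain,
                   resno = at$resno, ss = ss)
  })
}
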