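#' Collapse CSMs to unique residue-to-residue K-C linkages
#'
#' Maps peptide cross-link sites to protein coordinates, groups by
#' (protein A, lysine residue, protein B, cysteine residue), aggregates
#' supporting CSMs per linker and replicate, classifies intra vs inter, and
#' flags ambiguous linkages whose peptide maps to multiple proteins.
#' Representative proteins for ambiguous peptides are chosen by sorted id;
#' the full mapping is retained in `alpha_all_proteins` / `beta_all_proteins`.
#'
#' @param csms FDR-filtered CSM tibble (two-sided rows only).
#' @param sequences Optional named character vector of protein sequences; when
#'   given, the mapped residues are validated to be K and C (an index
#'   inconsistency is an error).
#' @return A linkage tibble: `protein_a`, `res_a` (K), `protein_b`, `res_b`
#'   (C), `intra`, `ambiguous`, `n_csms`, `best_score`, `linkers`, `support`
#'   (list column of per linker x replicate CSM counts).
#' @export
collapse_to_unique_linkages <- function(csms, sequences = NULL) {
  csms <- dplyr::filter(csms, !.data$single_sided)
  if (!nrow(csms)) {
    return(tibble::tibble(
      protein_a = character(), res_a = integer(), protein_b = character(),
      res_b = integer(), intra = logical(), ambiguous = logical(),
      n_csms = integer(), best_score = numeric(), linkers = list(),
      support = list()
    ))
  }
  side_map <- function(prot_list, site) {
    # one row per protein mapping of the cross-linked residue
    dplyr::mutate(prot_list, res = .data$start + site - 1L)
  }
  rows <- purrr::map(seq_len(nrow(csms)), function(i) {
    am <- side_map(csms$alpha_proteins[[i]], csms$alpha_site[i])
    bm <- side_map(csms$beta_proteins[[i]], csms$beta_site[i])
    am <- dplyr::arrange(am, .data$protein)
    bm <- dplyr::arrange(bm, .data$protein)
    if (!is.null(sequences)) {
      for (k in seq_len(nrow(am))) {
        aa <- substr(sequences[[am$protein[k]]], am$res[k], am$res[k])
        if (!identical(aa, "K")) {
          rlang::abort(sprintf("index corruption: %s residue %d is '%s', expected K",
                               am$protein[k], am$res[k], aa))
        }
      }
      for (k in seq_len(nrow(bm))) {
        aa <- substr(sequences[[bm$protein[k]]], bm$res[k], bm$res[k])
        if (!identical(aa, "C")) {
          rlang::abort(sprintf("index corruption: %s residue %d is '%s', expected C",
                               bm$protein[k], bm$res[k], aa))
        }
      }
    }
    tibble::tibble(
      protein_a = am$protein[1], res_a = am$res[1],
      protein_b = bm$protein[1], res_b = bm$res[1],
      ambiguous = nrow(am) > 1 || nrow(bm) > 1,
      alpha_all_proteins = list(am), beta_all_proteins = list(bm),
      score = csms$score[i], linker = csms$linker[i],
      replicate = csms$replicate[i]
    )
  })
  d <- dplyr::bind_rows(rows)
  grp <- dplyr::group_by(d, .data$protein_a, .data$res_a,
                         .data$protein_b, .data$res_b)
  out <- dplyr::summarise(
    grp,
    intra = .data$protein_a[1] == .data$protein_b[1],
    ambiguous = any(.data$ambiguous),
    n_csms = dplyr::n(),
    best_score = max(.data$score),
    linkers = list(sort(unique(.data$linker))),
    support = list(dplyr::count(
      tibble::tibble(linker = linker, replicate = replicate),
      .data$linker, .data$replicate, name = "n_csms"
    )),
    alpha_all_proteins = .data$alpha_all_proteins[1],
    beta_all_proteins = .data$beta_all_proteins[1],
    .groups = "drop"
  )
  dplyr::arrange(out, .data$protein_a, .data$res_a, .data$protein_b, .data$res_b)
}

#' Keep linkages reproducibly identified across biological replicates
#'
#' A linkage is kept when it was identified in at least `min_replicates`
#' distinct replicates with the same cross-linker (for at least one linker).
#'
#' @param linkages Linkage tibble from [collapse_to_unique_linkages()].
#' @param min_replicates Minimum replicates per linker (default 2;
#'   `min_replicates = 1` is the identity).
#' @return The filtered linkage tibble.
#' @export
reproducibility_filter <- function(linkages, min_replicates = 2) {
  if (min_replicates <= 1 || !nrow(linkages)) return(linkages)
  keep <- purrr::map_lgl(linkages$support, function(s) {
    reps <- dplyr::summarise(dplyr::group_by(s, .data$linker),
                             n_rep = dplyr::n_distinct(.data$replicate))
    any(reps$n_rep >= min_replicates)
  })
  linkages[keep, ]
}

#' Write a CSM or linkage table to TSV
#'
#' List columns are flattened to `;`-separated strings for interchange.
#'
#' @param x A CSM or linkage tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_kcx_tsv <- function(x, path) {
  flat <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.list),
    function(col) purrr::map_chr(col, function(v) {
      if (is.null(v)) return(NA_character_)
      if (is.data.frame(v)) {
        return(paste(apply(v, 1, paste, collapse = ":"), collapse = ";"))
      }
      paste(v, collapse = ";")
    })
  ))
  readr::write_tsv(flat, path)
  invisible(path)
}
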