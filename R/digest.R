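#' In-silico tryptic digestion into a searchable peptide index
#'
#' Cleaves after K/R (not before P). A cross-linked lysine blocks cleavage,
#' so a cross-linkable K must be internal; internal K/R count toward missed
#' cleavages. Decoys are full-sequence reversals that keep the C-terminal
#' residue (preserving the tryptic terminus), interleaved with `is_decoy`
#' flags and proteins prefixed `DECOY_`.
#'
#' @param fasta Path to a FASTA file, or a named character vector of protein
#'   sequences.
#' @param missed_cleavages Maximum missed cleavages (default 2).
#' @param length_range Peptide length bounds, inclusive (default 5-50).
#' @param decoy `"reverse"` (default) or `"none"`.
#' @param carbamidomethyl Logical; precompute masses with fixed
#'   carbamidomethyl on every Cys (default TRUE). Cross-link candidate masses
#'   subtract one CAM for the linked Cys (see the search functions).
#' @return A `kcx_index`: a tibble with columns `peptide`, `protein`, `start`,
#'   `end`, `missed`, `k_pos` / `c_pos` (list columns of 1-based positions
#'   within the peptide; `k_pos` excludes a C-terminal K, which cannot be
#'   cross-linked without blocking its own cleavage), `is_decoy`,
#'   `shared_with_target`, `base_mass` (unmodified) and `mass_cam` (all Cys
#'   carbamidomethylated), plus a `sequences` attribute with the protein
#'   sequences (targets and decoys).
#' @export
digest <- function(fasta, missed_cleavages = 2, length_range = c(5L, 50L),
                   decoy = c("reverse", "none"), carbamidomethyl = TRUE) {
  decoy <- match.arg(decoy)
  seqs <- read_fasta_sequences(fasta)
  if (!length(seqs)) rlang::abort("empty sequence database")
  valid <- vapply(seqs, function(s) {
    all(strsplit(s, "")[[1]] %in% names(AA_COMPOSITION))
  }, logical(1))
  if (any(!valid)) {
    rlang::warn(sprintf("skipping %d protein(s) with invalid residues: %s",
                        sum(!valid), paste(names(seqs)[!valid], collapse = ", ")))
    seqs <- seqs[valid]
  }
  if (!length(seqs)) rlang::abort("no valid proteins in database")

  all_seqs <- seqs
  if (decoy == "reverse") {
    dec <- vapply(seqs, reverse_keep_cterm, character(1))
    names(dec) <- paste0("DECOY_", names(seqs))
    all_seqs <- c(seqs, dec)
  }

  idx <- purrr::imap(all_seqs, function(s, id) {
    digest_one(s, id, missed_cleavages, length_range)
  })
  idx <- dplyr::bind_rows(idx)
  idx$is_decoy <- startsWith(idx$protein, "DECOY_")
  target_seqs <- unique(idx$peptide[!idx$is_decoy])
  idx$shared_with_target <- idx$is_decoy & idx$peptide %in% target_seqs

  rm_ <- residue_mass_vector()
  water <- composition_mass("H2O")
  cam <- composition_mass(NAMED_MODS[["carbamidomethyl"]])
  pep_res <- strsplit(idx$peptide, "")
  idx$base_mass <- vapply(pep_res, function(r) sum(rm_[r]) + water, numeric(1))
  idx$n_c <- vapply(pep_res, function(r) sum(r == "C"), integer(1))
  idx$mass_cam <- idx$base_mass + if (carbamidomethyl) cam * idx$n_c else 0
  idx <- dplyr::arrange(idx, .data$mass_cam)
  attr(idx, "sequences") <- all_seqs
  class(idx) <- c("kcx_index", class(idx))
  idx
}

read_fasta_sequences <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
    seqs <- as.character(aa)
    names(seqs) <- sub("\\s.*", "", names(aa))
    return(seqs)
  }
  if (is.character(fasta) && !is.null(names(fasta))) return(fasta)
  rlang::abort("fasta must be a file path or a named character vector")
}

reverse_keep_cterm <- function(s) {
  r <- strsplit(s, "")[[1]]
  n <- length(r)
  if (n <= 1) return(s)
  paste0(paste(rev(r[seq_len(n - 1)]), collapse = ""), r[n])
}

digest_one <- function(seq, id, missed, length_range) {
  r <- strsplit(seq, "")[[1]]
  n <- length(r)
  # cleavage after K/R not before P
  cut_after <- which(r %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & r[pmin(cut_after + 1, n)] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after[cut_after < n], n)  # segment boundaries
  bounds <- unique(bounds)
  nseg <- length(bounds) - 1
  out <- list()
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + missed)) {
      start <- bounds[i] + 1L
      end <- bounds[j + 1]
      len <- end - start + 1L
      if (len < length_range[1] || len > length_range[2]) next
      pep <- substr(seq, start, end)
      pr <- r[start:end]
      k_pos <- which(pr == "K")
      k_pos <- k_pos[k_pos < len]  # C-terminal K is the cleavage site
      out[[length(out) + 1]] <- tibble::tibble(
        peptide = pep, protein = id, start = start, end = end,
        missed = j - i,
        k_pos = list(as.integer(k_pos)),
        c_pos = list(which(pr == "C"))
      )
    }
  }
  dplyr::bind_rows(out)
}
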