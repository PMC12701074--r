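#' Residue mass table
#'
#' Monoisotopic residue masses (residue = amino acid minus water) for the 20
#' standard amino acids, derived from the internal elemental compositions.
#'
#' @return A tibble with columns `residue`, `composition`, `mass`.
#' @export
residue_masses <- function() {
  tibble::tibble(
    residue = names(AA_COMPOSITION),
    composition = purrr::map_chr(AA_COMPOSITION, function(v) {
      paste0(names(v), ifelse(v == 1, "", v), collapse = "")
    }),
    mass = purrr::map_dbl(AA_COMPOSITION, composition_mass)
  )
}

residue_mass_vector <- function() {
  purrr::map_dbl(AA_COMPOSITION, composition_mass)
}

mod_mass <- function(mod) {
  if (is.numeric(mod)) return(mod)
  if (mod %in% names(NAMED_MODS)) return(composition_mass(NAMED_MODS[[mod]]))
  composition_mass(mod)
}

#' Construct a modified peptide
#'
#' A peptide is a sequence of one-letter codes with an optional N-terminal
#' modification and positional modifications. Unknown residue codes are an
#' error, never silently mass zero.
#'
#' @param sequence One-letter amino-acid string.
#' @param nterm Optional N-terminal modification: a name in the shipped table
#'   (`"acetyl"`, `"carbamidomethyl"`, `"oxidation"`), a composition string,
#'   or a numeric mass in Da.
#' @param mods Optional data frame of positional modifications with columns
#'   `pos` (1-based residue index) and `mod` (name, composition string or
#'   numeric Da); a numeric named vector `c("3" = 89.98)` also works.
#' @return An object of class `kcx_peptide`.
#' @examples
#' peptide("SAKAYEHR", nterm = "acetyl")
#' @export
peptide <- function(sequence, nterm = NULL, mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(AA_COMPOSITION))
  if (length(bad)) {
    rlang::abort(paste0("unknown residue code(s): ", paste(unique(bad), collapse = ", ")))
  }
  if (is.numeric(mods) && !is.null(names(mods))) {
    mods <- tibble::tibble(pos = as.integer(names(mods)), mod = as.list(unname(mods)))
  }
  if (!is.null(mods)) {
    mods <- tibble::as_tibble(mods)
    if (!all(c("pos", "mod") %in% names(mods))) {
      rlang::abort("mods must have columns pos and mod")
    }
    if (any(mods$pos < 1 | mods$pos > length(res))) {
      rlang::abort("modification position out of range")
    }
    mods$mass <- purrr::map_dbl(mods$mod, mod_mass)
  } else {
    mods <- tibble::tibble(pos = integer(), mod = list(), mass = numeric())
  }
  structure(
    list(sequence = sequence, residues = res,
         nterm = nterm, nterm_mass = if (is.null(nterm)) 0 else mod_mass(nterm),
         mods = mods),
    class = "kcx_peptide"
  )
}

#' Parse a peptide from a compact string
#'
#' Grammar: `[Ac-]SEQUENCE[:K3]` — an optional `Ac-` prefix for N-terminal
#' acetylation and an optional `:<residue><pos>` suffix naming a cross-linked
#' site, returned separately.
#'
#' @param spec String such as `"Ac-SAKAYEHR:K3"`.
#' @return A list with elements `peptide` (a `kcx_peptide`) and `site`
#'   (integer position or `NA`).
#' @export
parse_peptide <- function(spec) {
  site <- NA_integer_
  if (grepl(":", spec, fixed = TRUE)) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    spec <- parts[1]
    site_spec <- parts[2]
    site <- as.integer(sub("^[A-Z]", "", site_spec))
    site_res <- sub("[0-9]+$", "", site_spec)
  } else {
    site_res <- NA_character_
  }
  nterm <- NULL
  if (startsWith(spec, "Ac-")) {
    nterm <- "acetyl"
    spec <- sub("^Ac-", "", spec)
  }
  p <- peptide(spec, nterm = nterm)
  if (!is.na(site) && !is.na(site_res) && p$residues[site] != site_res) {
    rlang::abort(sprintf("site %s%d does not match sequence residue %s",
                         site_res, site, p$residues[site]))
  }
  list(peptide = p, site = site)
}

#' @export
print.kcx_peptide <- function(x, ...) {
  pre <- if (!is.null(x$nterm)) paste0(x$nterm, "-") else ""
  cat(sprintf("<kcx_peptide> %s%s  M = %.5f Da", pre, x$sequence,
              peptide_neutral_mass(x)))
  if (nrow(x$mods)) {
    cat(sprintf("  [+%d mod(s)]", nrow(x$mods)))
  }
  cat("\n")
  invisible(x)
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water plus all modifications.
#'
#' @param p A `kcx_peptide` (or a plain sequence string, taken unmodified).
#' @return Neutral mass in Da.
#' @examples
#' peptide_neutral_mass(peptide("G"))  # 75.03203
#' @export
peptide_neutral_mass <- function(p) {
  if (is.character(p)) p <- peptide(p)
  rm_ <- residue_mass_vector()
  m <- sum(rm_[p$residues]) + composition_mass("H2O") + p$nterm_mass +
    sum(p$mods$mass)
  if (m <= 0) rlang::abort("peptide neutral mass must be > 0")
  m
}

#' Theoretical b/y fragment ladder
#'
#' Standard monoisotopic b and y sequence ions with all modifications
#' (including cross-link remnant masses) localized to their residues: a
#' modification at position i shifts b ions with index >= i and y ions that
#' include residue i.
#'
#' @param p A `kcx_peptide`.
#' @param series Character vector from `c("b", "y")`.
#' @param max_charge Maximum fragment charge (default 1).
#' @return A tibble with columns `ion`, `series`, `index`, `charge`, `mz`.
#' @export
fragment_ladder <- function(p, series = c("b", "y"), max_charge = 1) {
  if (is.character(p)) p <- peptide(p)
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  rm_ <- residue_mass_vector()
  n <- length(p$residues)
  res_mass <- unname(rm_[p$residues])
  mod_by_pos <- numeric(n)
  if (nrow(p$mods)) {
    for (k in seq_len(nrow(p$mods))) {
      mod_by_pos[p$mods$pos[k]] <- mod_by_pos[p$mods$pos[k]] + p$mods$mass[k]
    }
  }
  res_mass <- res_mass + mod_by_pos
  water <- composition_mass("H2O")
  rows <- list()
  for (z in seq_len(max_charge)) {
    if ("b" %in% series) {
      # b_i = sum(residues 1..i) + nterm mod, protonated
      bm <- cumsum(res_mass)[seq_len(n - 1)] + p$nterm_mass
      rows[[length(rows) + 1]] <- tibble::tibble(
        series = "b", index = seq_len(n - 1), charge = z,
        mz = neutral_to_mz(bm, z)
      )
    }
    if ("y" %in% series) {
      # y_i = sum(residues n-i+1..n) + water; y_n carries the N-term mod too
      ym <- rev(cumsum(rev(res_mass))) + water
      ym[1] <- ym[1] + p$nterm_mass  # ym[1] is y_n (full peptide)
      idx <- rev(seq_len(n))
      rows[[length(rows) + 1]] <- tibble::tibble(
        series = "y", index = idx, charge = z,
        mz = neutral_to_mz(ym, z)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$ion <- paste0(out$series, out$index,
                    ifelse(out$charge > 1, paste0("^", out$charge, "+"), ""))
  dplyr::arrange(dplyr::select(out, "ion", "series", "index", "charge", "mz"),
                 .data$series, .data$index, .data$charge)
}
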