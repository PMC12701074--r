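#' Construct a K-C cross-linked peptide pair
#'
#' The alpha peptide carries the cross-linked lysine, the beta peptide the
#' cross-linked cysteine. After oxidation the cross-link contains the
#' MS-cleavable C-S bond; `oxidized = FALSE` gives the pre-oxidation,
#' non-cleavable species.
#'
#' @param alpha,beta `kcx_peptide` objects or compact strings understood by
#'   [parse_peptide()] (e.g. `"Ac-SAKAYEHR:K3"`).
#' @param alpha_site,beta_site 1-based cross-linked residue positions; may be
#'   omitted when encoded in the compact string.
#' @param linker Linker name or `kcx_linker`.
#' @param oxidized Logical; `TRUE` (default) for the MS-cleavable form.
#' @return An object of class `kcx_pair`.
#' @export
crosslink_pair <- function(alpha, beta, linker, alpha_site = NULL,
                           beta_site = NULL, oxidized = TRUE) {
  if (is.character(alpha)) {
    pa <- parse_peptide(alpha)
    alpha <- pa$peptide
    if (is.null(alpha_site)) alpha_site <- pa$site
  }
  if (is.character(beta)) {
    pb <- parse_peptide(beta)
    beta <- pb$peptide
    if (is.null(beta_site)) beta_site <- pb$site
  }
  if (is.null(alpha_site) || is.na(alpha_site) ||
      is.null(beta_site) || is.na(beta_site)) {
    rlang::abort("cross-linked sites must be given (e.g. \"Ac-SAKAYEHR:K3\")")
  }
  if (alpha$residues[alpha_site] != "K") {
    rlang::abort(sprintf("alpha position %d is %s, not K", alpha_site,
                         alpha$residues[alpha_site]))
  }
  if (beta$residues[beta_site] != "C") {
    rlang::abort(sprintf("beta position %d is %s, not C", beta_site,
                         beta$residues[beta_site]))
  }
  structure(
    list(alpha = alpha, alpha_site = alpha_site,
         beta = beta, beta_site = beta_site,
         linker = kcxlink::linker(linker), oxidized = oxidized),
    class = "kcx_pair"
  )
}

#' @export
print.kcx_pair <- function(x, ...) {
  cat(sprintf("<kcx_pair> %s(K%d) - %s(C%d) via %s%s  M = %.5f Da\n",
              x$alpha$sequence, x$alpha_site, x$beta$sequence, x$beta_site,
              x$linker$name, if (x$oxidized) " (oxidized)" else "",
              pair_neutral_mass(x)))
  invisible(x)
}

#' Neutral mass of a cross-linked pair
#'
#' `mass(alpha) + mass(beta) + intact addition` (oxidized or pre-oxidation
#' variant according to the pair).
#'
#' @param pair A `kcx_pair`.
#' @return Neutral monoisotopic mass in Da.
#' @export
pair_neutral_mass <- function(pair) {
  r <- remnants_for(pair$linker)
  add <- if (pair$oxidized) r$intact_ox_addition else r$intact_addition
  peptide_neutral_mass(pair$alpha) + peptide_neutral_mass(pair$beta) + add
}

#' Precursor m/z of a cross-linked pair
#'
#' @param pair A `kcx_pair`.
#' @param charge Positive integer precursor charge.
#' @return m/z of the protonated precursor.
#' @examples
#' p <- crosslink_pair("Ac-SAKAYEHR:K3", "Ac-LADVCAHER:C5", "SIA")
#' precursor_mz(p, 4)  # 529.249 (4+)
#' @export
precursor_mz <- function(pair, charge) {
  if (charge < 1) rlang::abort("charge must be >= 1")
  neutral_to_mz(pair_neutral_mass(pair), charge)
}

#' Signature fragment m/z values of an oxidized cross-linked pair
#'
#' MS2 cleavage of the C-S bond yields the alpha_S / beta_A fragment pair;
#' alpha_T is the dehydrated alpha_S. Neutral masses conserve exactly:
#' `neutral(alpha_S) + neutral(beta_A) = neutral(precursor)`.
#'
#' @param pair An oxidized `kcx_pair`.
#' @param charge_alpha,charge_beta Fragment charges (default 2, as commonly
#'   observed for 4+ precursors).
#' @return A tibble with columns `fragment` (`alpha_S`, `alpha_T`, `beta_A`),
#'   `charge`, `neutral`, `mz`.
#' @export
signature_fragment_mzs <- function(pair, charge_alpha = 2, charge_beta = 2) {
  if (!pair$oxidized) rlang::abort("signature fragments require an oxidized pair")
  if (charge_alpha < 1 || charge_beta < 1) rlang::abort("charge must be >= 1")
  r <- remnants_for(pair$linker)
  ma <- peptide_neutral_mass(pair$alpha)
  mb <- peptide_neutral_mass(pair$beta)
  neutral <- c(alpha_S = ma + r$alpha_S_mod,
               alpha_T = ma + r$alpha_T_mod,
               beta_A = mb + r$beta_A_mod)
  charge <- c(charge_alpha, charge_alpha, charge_beta)
  tibble::tibble(
    fragment = names(neutral),
    charge = charge,
    neutral = unname(neutral),
    mz = neutral_to_mz(unname(neutral), charge)
  )
}

#' Worked m/z table for a cross-linked pair
#'
#' Convenience wrapper printing the precursor and signature-fragment m/z
#' values for one pair; this is what the `calc` command of the CLI shows.
#'
#' @param alpha,beta Compact peptide strings (see [parse_peptide()]).
#' @param linker Linker name.
#' @param charge Precursor charge (default 4).
#' @param charge_alpha,charge_beta Signature fragment charges (default 2).
#' @return A tibble with columns `species`, `charge`, `mz`.
#' @export
kcx_calc <- function(alpha, beta, linker, charge = 4,
                     charge_alpha = 2, charge_beta = 2) {
  pair <- crosslink_pair(alpha, beta, linker)
  sig <- signature_fragment_mzs(pair, charge_alpha, charge_beta)
  dplyr::bind_rows(
    tibble::tibble(species = "precursor", charge = as.numeric(charge),
                   mz = precursor_mz(pair, charge)),
    tibble::tibble(species = sig$fragment, charge = sig$charge, mz = sig$mz)
  )
}
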