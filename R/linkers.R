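# Built-in heterobifunctional K-C cross-linkers. The bridge composition is
# the net set of atoms left between the lysine side-chain nitrogen and the
# cysteine sulfur after both coupling reactions (NHS ester on K, haloacetamide
# on C), before oxidation. One H is lost from the lysine amine at NHS coupling
# and one from the cysteine thiol at alkylation.
BUILTIN_LINKERS <- list(
  SIA  = list(name = "SIA",  spacer_angstrom = 4.2,
              amine_side = "NHS ester", thiol_side = "iodoacetamide",
              bridge = "C2H2O"),
  SIAB = list(name = "SIAB", spacer_angstrom = 10.6,
              amine_side = "NHS ester", thiol_side = "iodoacetamide",
              bridge = "C9H7NO2"),
  SBAP = list(name = "SBAP", spacer_angstrom = 9.0,
              amine_side = "NHS ester", thiol_side = "bromoacetamide",
              bridge = "C5H7NO2")
)

.linker_registry <- new.env(parent = emptyenv())

#' Shipped and registered cross-linker definitions
#'
#' @return A tibble with one row per known linker: `name`, `spacer_angstrom`,
#'   `amine_side`, `thiol_side`, `bridge` (elemental composition string) and
#'   `bridge_mass` (Da).
#' @export
linkers <- function() {
  all <- c(BUILTIN_LINKERS, as.list(.linker_registry))
  all <- all[!duplicated(names(all))]
  tibble::tibble(
    name = purrr::map_chr(all, "name"),
    spacer_angstrom = purrr::map_dbl(all, "spacer_angstrom"),
    amine_side = purrr::map_chr(all, "amine_side"),
    thiol_side = purrr::map_chr(all, "thiol_side"),
    bridge = purrr::map_chr(all, "bridge"),
    bridge_mass = purrr::map_dbl(all, function(l) composition_mass(l$bridge))
  )
}

#' Look up or construct a cross-linker
#'
#' @param name Linker name. `"SIA"`, `"SIAB"` and `"SBAP"` are shipped;
#'   others must be registered first with [register_linker()].
#' @return An object of class `kcx_linker`.
#' @export
linker <- function(name) {
  if (inherits(name, "kcx_linker")) return(name)
  l <- .linker_registry[[name]]
  if (is.null(l)) l <- BUILTIN_LINKERS[[name]]
  if (is.null(l)) {
    rlang::abort(paste0("unknown linker: ", name,
                        " (register it with register_linker())"))
  }
  structure(l, class = "kcx_linker")
}

#' Register a user-defined K-C cross-linker
#'
#' @param name Linker name.
#' @param spacer_angstrom Spacer length in Angstrom (> 0).
#' @param bridge Bridge elemental composition (net atoms between Lys N-zeta
#'   and Cys S-gamma after both couplings, before oxidation); mass must be > 0.
#' @param amine_side,thiol_side Reactive-group descriptors.
#' @return The new `kcx_linker`, invisibly.
#' @export
register_linker <- function(name, spacer_angstrom, bridge,
                            amine_side = "NHS ester",
                            thiol_side = "haloacetamide") {
  if (spacer_angstrom <= 0) rlang::abort("spacer length must be > 0")
  if (composition_mass(bridge) <= 0) rlang::abort("bridge composition mass must be > 0")
  l <- list(name = name, spacer_angstrom = spacer_angstrom,
            amine_side = amine_side, thiol_side = thiol_side,
            bridge = if (is.character(bridge)) bridge else
              paste0(names(bridge), ifelse(bridge == 1, "", bridge), collapse = ""))
  assign(name, l, envir = .linker_registry)
  invisible(structure(l, class = "kcx_linker"))
}

#' Load linker definitions from a JSON config
#'
#' The config is a JSON array of objects with fields `name`,
#' `spacer_angstrom`, `bridge` (composition as element-count map or formula
#' string) and optional `amine_side` / `thiol_side`, so new linkers can be
#' used without code changes.
#'
#' @param path Path to the JSON file.
#' @return A tibble of the registered linkers.
#' @export
read_linker_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  for (l in cfg) {
    bridge <- l$bridge
    if (is.list(bridge)) bridge <- unlist(bridge)
    register_linker(l$name, l$spacer_angstrom, bridge,
                    amine_side = l$amine_side %||% "NHS ester",
                    thiol_side = l$thiol_side %||% "haloacetamide")
  }
  dplyr::filter(linkers(), .data$name %in% purrr::map_chr(cfg, "name"))
}

#' @export
print.kcx_linker <- function(x, ...) {
  cat(sprintf("<kcx_linker> %s  spacer %.1f A  bridge %s (%.4f Da)\n",
              x$name, x$spacer_angstrom, x$bridge, composition_mass(x$bridge)))
  invisible(x)
}

#' Remnant masses of an oxidized K-C cross-link
#'
#' Collision-induced cleavage of the single MS-labile C-S bond adjacent to
#' the sulfoxide splits the oxidized cross-link into a lysine-side fragment
#' carrying a sulfenic-acid remnant (alpha_S; may dehydrate to the
#' unsaturated-thiol alpha_T) and a cysteine-side fragment carrying an
#' alkene/dehydroalanine remnant (beta_A). The sulfur leaves with the alpha
#' fragment, so beta_A is linker-independent (-H2S = -33.987721 Da).
#'
#' @param linker A linker name or `kcx_linker`.
#' @return A tibble with one row: `intact_ox_addition` (net Da added to the
#'   sum of the two peptide neutral masses by the oxidized cross-link),
#'   `intact_addition` (pre-oxidation, non-cleavable form), `alpha_S_mod`,
#'   `alpha_T_mod`, `beta_A_mod`, `rsoh_loss` (neutral loss from oxidized
#'   carbamidomethyl cysteine), and the dead-end modification masses
#'   `deadend_hydrolyzed` (hydrolyzed NHS side left on K: bridge + H2O) and
#'   `deadend_cys_quench` (free-cysteine quench on the thiol side:
#'   bridge + Cys - H).
#' @examples
#' remnants_for("SIA")
#' @export
remnants_for <- function(linker) {
  l <- kcxlink::linker(linker)
  bridge <- composition_mass(l$bridge)
  h <- composition_mass("H")
  intact <- bridge - 2 * h                      # non-cleavable cross-link
  intact_ox <- intact + composition_mass("O")   # after sulfoxide formation
  beta_A <- -composition_mass("H2S")
  alpha_S <- intact_ox - beta_A
  tibble::tibble(
    linker = l$name,
    intact_ox_addition = intact_ox,
    intact_addition = intact,
    alpha_S_mod = alpha_S,
    alpha_T_mod = alpha_S - composition_mass("H2O"),
    beta_A_mod = beta_A,
    rsoh_loss = composition_mass("C2H5NO2S"),
    deadend_hydrolyzed = bridge - h + composition_mass("OH"),
    deadend_cys_quench = bridge - h +
      composition_mass(AA_COMPOSITION$C) + composition_mass("H2O") - h
  )
}
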