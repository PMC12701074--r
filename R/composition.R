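#' Parse an elemental composition
#'
#' Compositions are signed element counts (net losses allowed), written either
#' as a formula string such as `"C2H5NO2S"` or as a named numeric vector
#' `c(C = 2, H = 5, ...)`. Element symbols must be known to the internal
#' monoisotopic mass table (C, H, N, O, S, P).
#'
#' @param x A formula string or named numeric vector of element counts.
#' @return A named numeric vector of element counts.
#' @examples
#' parse_composition("C2H5NO2S")
#' @export
parse_composition <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      rlang::abort("numeric compositions must be fully named by element symbol")
    }
    comp <- x
  } else if (is.character(x) && length(x) == 1) {
    if (!nzchar(x)) {
      return(stats::setNames(numeric(0), character(0)))
    }
    m <- gregexpr("([A-Z][a-z]?)(-?[0-9]*)", x)[[1]]
    toks <- regmatches(x, list(m))[[1]]
    toks <- toks[nzchar(toks)]
    if (!identical(paste(toks, collapse = ""), x)) {
      rlang::abort(paste0("cannot parse composition string: ", x))
    }
    el <- sub("-?[0-9]*$", "", toks)
    n <- sub("^[A-Za-z]+", "", toks)
    comp <- stats::setNames(ifelse(n == "", 1, suppressWarnings(as.numeric(n))), el)
  } else {
    rlang::abort("composition must be a formula string or a named numeric vector")
  }
  unknown <- setdiff(names(comp), names(ATOMIC_MASS))
  if (length(unknown)) {
    rlang::abort(paste0("unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  # collapse repeated symbols
  tapply(comp, names(comp), sum)[unique(names(comp))]
}

#' Add elemental compositions
#'
#' Composition arithmetic is associative and commutative and mass is linear in
#' composition, so compositions can be combined freely before taking masses.
#'
#' @param ... Compositions (strings or named numeric vectors).
#' @return A named numeric vector; counts may be negative (net losses).
#' @export
composition_sum <- function(...) {
  comps <- lapply(list(...), parse_composition)
  all_el <- unique(unlist(lapply(comps, names)))
  out <- stats::setNames(numeric(length(all_el)), all_el)
  for (comp in comps) out[names(comp)] <- out[names(comp)] + comp
  out
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp A composition (formula string or named numeric vector).
#' @return Monoisotopic mass in Da. Additive over [composition_sum()].
#' @examples
#' composition_mass("H2O")       # 18.010565
#' composition_mass("C2H5NO2S")  # 107.0041, the RSOH neutral loss
#' @export
composition_mass <- function(comp) {
  comp <- parse_composition(comp)
  if (!length(comp)) return(0)
  sum(ATOMIC_MASS[names(comp)] * comp)
}

#' Convert m/z and charge to neutral mass
#'
#' @param mz Observed m/z.
#' @param z Positive integer charge.
#' @return Neutral monoisotopic mass in Da: `z * mz - z * 1.007276466`.
#' @export
mz_to_neutral <- function(mz, z) {
  if (any(z < 1)) rlang::abort("charge must be >= 1")
  z * mz - z * PROTON_MASS
}

#' Convert neutral mass and charge to m/z
#'
#' @param neutral Neutral monoisotopic mass in Da.
#' @param z Positive integer charge.
#' @return m/z of the protonated species.
#' @export
neutral_to_mz <- function(neutral, z) {
  if (any(z < 1)) rlang::abort("charge must be >= 1")
  (neutral + z * PROTON_MASS) / z
}

#' Parts-per-million difference between two masses
#'
#' @param observed,theoretical Masses or m/z values on the same scale.
#' @return Signed ppm error of `observed` relative to `theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
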