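# Monoisotopic constants used throughout. All masses in Da.
# Charge arithmetic uses the proton mass (not the H atom), the standard MS
# convention for protonated species.

#' @keywords internal
ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

#' @keywords internal
PROTON_MASS <- 1.007276466

# Residue elemental compositions (residue = amino acid minus water).
#' @keywords internal
AA_COMPOSITION <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

# Named modifications shipped with the package. Values are elemental
# composition strings; dead-end (mono-link) species for the hydrolyzed NHS
# side and the cysteine-quenched side of each linker are registered at
# linker construction (see remnants_for()).
#' @keywords internal
NAMED_MODS <- c(
  acetyl = "C2H2O",            # +42.010565, peptide N-terminus
  carbamidomethyl = "C2H3NO",  # +57.021464, alkylated Cys
  oxidation = "O"              # +15.994915, Met/Trp/Cys-CAM oxidation
)
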