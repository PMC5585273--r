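# Physical constants and mass tables.  All masses are monoisotopic Daltons.

ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

PROTON_MASS <- 1.007276466

# Mass added per 15N (vs 14N) and per 13C (vs 12C) atom.
N15_SHIFT <- 0.9970349
C13_SHIFT <- 1.0033548

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Named numeric vector of atom counts over C, H, N, O, S,
#'   e.g. `c(C = 8, H = 13, N = 1, O = 5)` for a HexNAc residue.
#' @return Mass in Daltons.
#' @examples
#' formula_mass(c(C = 8, H = 13, N = 1, O = 5))
#' @export
formula_mass <- function(formula) {
  if (!length(formula)) return(0)
  bad <- setdiff(names(formula), names(ATOMIC_MASS))
  if (length(bad))
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  sum(ATOMIC_MASS[names(formula)] * formula)
}

# Sum elemental formulas given as (possibly partial) named count vectors.
add_formulas <- function(...) {
  out <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (f in list(...)) {
    if (!length(f)) next
    out[names(f)] <- out[names(f)] + f
  }
  out
}

WATER_FORMULA <- c(H = 2, O = 1)
WATER_MASS <- formula_mass(WATER_FORMULA)

# Monosaccharide residue formulas (water of the glycosidic bond removed).
MONOSACCHARIDES <- list(
  H = c(C = 6, H = 10, O = 5),          # Hex
  N = c(C = 8, H = 13, N = 1, O = 5),   # HexNAc
  F = c(C = 6, H = 10, O = 4),          # Fuc / dHex
  A = c(C = 11, H = 17, N = 1, O = 8),  # NeuAc
  G = c(C = 11, H = 17, N = 1, O = 9)   # NeuGc
)
MONO_MASS <- vapply(MONOSACCHARIDES, formula_mass, numeric(1))
MONO_ORDER <- c("H", "N", "F", "A", "G")

# Trimannosyl-core Y-ion ladder deltas: pep, pep+N, pep+2N, pep+2N+H,
# pep+2N+2H, pep+2N+3H.
CORE_LADDER <- c(
  0,
  MONO_MASS[["N"]],
  2 * MONO_MASS[["N"]],
  2 * MONO_MASS[["N"]] + MONO_MASS[["H"]],
  2 * MONO_MASS[["N"]] + 2 * MONO_MASS[["H"]],
  2 * MONO_MASS[["N"]] + 3 * MONO_MASS[["H"]]
)

# Amino-acid residue formulas; J marks the glycosylated sequon Asn and has
# the composition (hence mass) of N.
AA_FORMULA <- list(
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
AA_FORMULA$J <- AA_FORMULA$N
AA_MASS <- vapply(AA_FORMULA, formula_mass, numeric(1))

# Modification registry: fixed carbamidomethyl on Cys, variable oxidation on
# Met and protein N-terminal acetylation.
MODIFICATIONS <- list(
  Carbamidomethyl = list(formula = c(C = 2, H = 3, N = 1, O = 1), site = "C"),
  Oxidation       = list(formula = c(O = 1),                      site = "M"),
  Acetyl          = list(formula = c(C = 2, H = 2, O = 1), site = "N-term")
)
MOD_MASS <- vapply(MODIFICATIONS, function(m) formula_mass(m$formula),
                   numeric(1))

#' Convert between neutral mass and m/z
#'
#' Charge carriers are protons (1.007276466 Da).
#'
#' @param neutral Neutral monoisotopic mass (Da).
#' @param mz Observed m/z (Th).
#' @param z Charge state.
#' @return `mz_from_neutral()` returns m/z; `neutral_from_mz()` returns the
#'   neutral mass.
#' @export
mz_from_neutral <- function(neutral, z) neutral / z + PROTON_MASS

#' @rdname mz_from_neutral
#' @export
neutral_from_mz <- function(mz, z) (mz - PROTON_MASS) * z

# Signed relative mass error in parts per million.
ppm_error <- function(observed, theoretical)
  (observed - theoretical) / theoretical * 1e6
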