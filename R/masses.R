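## Monoisotopic mass bookkeeping. All fragment arithmetic in the package is
## singly protonated ([M+H]+); spectra are assumed decharged and deisotoped.

#' Monoisotopic mass constants
#'
#' Community-standard monoisotopic masses used throughout the package:
#' the proton (1.00727646688 Da), water (18.0105646863 Da), ammonia
#' (17.0265491 Da) and carbon monoxide (27.99491462 Da, the b/a-ion offset).
#'
#' @format A named numeric vector with elements `proton`, `water`, `ammonia`,
#'   and `co`.
#' @export
MASS_CONST <- c(
  proton  = 1.00727646688,
  water   = 18.0105646863,
  ammonia = 17.0265491,
  co      = 27.99491461957
)

#' Monoisotopic residue masses
#'
#' Monoisotopic masses of the 20 standard amino-acid residues, in Da, named
#' by one-letter code.
#'
#' @format A named numeric vector of length 20.
#' @export
AA_MONO <- c(
  G = 57.02146373, A = 71.03711378, S = 87.03202840, P = 97.05276384,
  V = 99.06841391, T = 101.04767846, C = 103.00918478, L = 113.08406397,
  I = 113.08406397, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496301, E = 129.04259308, M = 131.04048491, H = 137.05891185,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931294
)

#' Parts-per-million mass matching tolerance in Da
#'
#' @param mass reference mass in Da (the theoretical mass being matched).
#' @param tol_ppm tolerance in parts per million.
#' @return absolute tolerance in Da, `tol_ppm * abs(mass) / 1e6`.
#' @keywords internal
ppm_tol <- function(mass, tol_ppm) tol_ppm * abs(mass) / 1e6
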