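# Isotope dimensions used throughout the package, in canonical display order:
# C, [13C], S, [34S], O, N, H, then the remaining elements alphabetically.
.ISO_DIMS <- c("C", "C13", "S", "S34", "O", "N", "H", "Cl", "F", "K", "Na", "P")

# Monoisotopic atomic masses (Da), CODATA/AME values.
.ISO_MASS <- c(
  C   = 12,
  C13 = 13.00335484,
  S   = 31.97207117,
  S34 = 33.96786701,
  O   = 15.99491462,
  N   = 14.00307401,
  H   = 1.00782503207,
  Cl  = 34.96885268,
  F   = 18.99840316,
  K   = 38.96370649,
  Na  = 22.98976928,
  P   = 30.97376200
)[.ISO_DIMS]

.ISO_LABEL <- c(
  C = "C", C13 = "[13C]", S = "S", S34 = "[34S]", O = "O", N = "N", H = "H",
  Cl = "Cl", F = "F", K = "K", Na = "Na", P = "P"
)[.ISO_DIMS]

.ELECTRON_MASS <- 0.00054857991

#' Supported isotopes and their monoisotopic masses
#'
#' The annotation alphabet covers the most abundant isotope of H, C, N, O, F,
#' Na, P, S, Cl and K, plus the heavy isotopes 13C and 34S, each treated as an
#' independent dimension of a formula vector.
#'
#' @return A tibble with columns `isotope` (internal name), `label` (display
#'   notation, heavy isotopes bracketed as `[13C]`, `[34S]`) and `mass_da`
#'   (monoisotopic mass in Da).
#' @examples
#' isotope_masses()
#' @export
isotope_masses <- function() {
  tibble::tibble(
    isotope = .ISO_DIMS,
    label = unname(.ISO_LABEL),
    mass_da = unname(.ISO_MASS)
  )
}

#' Electron rest mass in Da
#'
#' Used to convert between the exact mass of a formula and the m/z of its
#' singly charged ion: a cation is lighter than its neutral composition by one
#' electron, an anion heavier.
#'
#' @return Electron mass in Da (scalar).
#' @examples
#' electron_mass()
#' @export
electron_mass <- function() .ELECTRON_MASS
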