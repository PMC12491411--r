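# Embedded monoisotopic atomic masses (Da), most abundant isotope of each
# element. Fixed in the package rather than taken from an external library so
# that calculated masses are reproducible across installations. Values for
# C/H/N/O carry the precision used throughout the mass tables; the remaining
# entries cover elements common in natural products and their salts.
.MONOISOTOPIC_MASS <- c(
  H  = 1.00782503,
  C  = 12,
  N  = 14.00307401,
  O  = 15.99491462,
  F  = 18.99840322,
  Na = 22.98976928,
  Mg = 23.98504170,
  Si = 27.97692653,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.96370668,
  Ca = 39.96259098,
  Fe = 55.93493750,
  Zn = 63.92914220,
  Se = 79.91652130,
  Br = 78.91833710,
  I  = 126.90447300
)

# Electron rest mass in Da; subtracted per unit positive charge when the
# electron correction is requested.
.ELECTRON_MASS <- 0.00054858

#' Monoisotopic atomic mass table
#'
#' Returns the fixed monoisotopic mass table embedded in the package, as a
#' tibble. All mass arithmetic in [monoisotopic_mass()] uses exactly these
#' values, so calculated masses are reproducible independent of any external
#' element database.
#'
#' @return A tibble with columns `element` and `mass` (Da).
#' @examples
#' atomic_masses()
#' @export
atomic_masses <- function() {
  tibble::tibble(
    element = names(.MONOISOTOPIC_MASS),
    mass = unname(.MONOISOTOPIC_MASS)
  )
}
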