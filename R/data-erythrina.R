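# Published reference values for the four Erythrina crista-galli twig
# alkaloids (crystamidine, 8-oxoerythraline, erythrinine, erythraline) and
# the twelve tentatively identified twig alkaloids. These tables are the
# worked-example inputs used in the vignette and tests.

#' LC-MS peak table of tentatively identified twig alkaloids
#'
#' Twelve positive-mode peaks from an *Erythrina crista-galli* twig ethanol
#' extract: retention time, observed m/z, cation formula, the mass error as
#' printed (absolute ppm), and the compound name where one was reported
#' (`NA` where the published table's identification could not be recovered).
#'
#' @return A tibble with columns `rt_min`, `mz`, `formula`, `ppm_printed`,
#'   `name`.
#' @examples
#' peaks <- erythrina_peaks()
#' annotate_peaks(peaks[c("rt_min", "mz")],
#'                tibble::tibble(name = peaks$formula, formula = peaks$formula),
#'                tolerance_ppm = 5)
#' @export
erythrina_peaks <- function() {
  tibble::tribble(
    ~rt_min, ~mz,      ~formula,      ~ppm_printed, ~name,
    4.66,  332.1513, "C18H22NO5+",  4.5, NA_character_,
    5.13,  316.1556, "C18H22NO4+",  2.2, NA_character_,
    5.27,  476.1917, "C24H30NO9+",  0.8, "6-O-beta-glucococcoline",
    5.42,  492.1862, "C24H30NO10+", 1.6, "erythrinine N-oxide-11-O-beta-D-glucose",
    5.69,  346.1653, "C19H24NO5+",  0.3, NA_character_,
    5.85,  314.1393, "C18H20NO4+",  0.3, "erythrinine",
    5.97,  330.1343, "C18H20NO5+",  0.6, "erythrinine N-oxide",
    7.26,  344.1503, "C19H22NO5+",  1.5, NA_character_,
    7.41,  298.1439, "C18H20NO3+",  1.0, "erythraline",
    7.49,  310.1087, "C18H16NO4+",  2.6, "crystamidine",
    8.61,  326.1039, "C18H16NO5+",  3.4, "10,11-dioxoerythraline",
    8.90,  312.1243, "C18H18NO4+",  2.2, "8-oxoerythraline"
  )
}

#' Published vertical I and A of the four isolated alkaloids
#'
#' Vertical ionization potentials and electron affinities (eV, B3LYP
#' energy-vertical values) of crystamidine, 8-oxoerythraline, erythrinine and
#' erythraline in gas phase and in ethanol. Gas-phase electron affinities of
#' erythrinine and erythraline are negative; they are legitimate vertical
#' values and are not clamped.
#'
#' @return A tibble with columns `compound`, `phase`, `I`, `A`.
#' @examples
#' descriptors_from_IA(erythrina_ia()$I, erythrina_ia()$A)
#' @export
erythrina_ia <- function() {
  tibble::tribble(
    ~compound,          ~phase,    ~I,     ~A,
    "1 crystamidine",     "gas",     7.2116, 0.6463,
    "2 8-oxoerythraline", "gas",     7.7258, 0.3074,
    "3 erythrinine",      "gas",     7.2313, -0.250,
    "4 erythraline",      "gas",     7.1690, -0.3188,
    "1 crystamidine",     "ethanol", 5.6812, 2.2985,
    "2 8-oxoerythraline", "ethanol", 6.0510, 2.0469,
    "3 erythrinine",      "ethanol", 5.8319, 1.2792,
    "4 erythraline",      "ethanol", 5.4294, 1.2680
  )
}

#' Published DPPH IC50 values of the four isolated alkaloids
#'
#' Half-inhibition concentrations (ug/mL, duplicate assays, spread as
#' published) for the four twig alkaloids and the ascorbic-acid positive
#' control.
#'
#' @return A tibble with columns `compound`, `ic50`, `spread`.
#' @examples
#' erythrina_ic50()
#' @export
erythrina_ic50 <- function() {
  tibble::tribble(
    ~compound,            ~ic50, ~spread,
    "1 crystamidine",     681.4, 20.2,
    "2 8-oxoerythraline", 868.2, 0.26,
    "3 erythrinine",      285,   10.9,
    "4 erythraline",      182.5, 5.3,
    "ascorbic acid",      4.8,   0.12
  )
}
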