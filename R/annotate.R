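#' Annotate observed peaks against a candidate formula library
#'
#' For each peak, computes the calculated m/z of every library candidate and
#' keeps those whose absolute ppm error is within `tolerance_ppm`. Hits are
#' ordered, within each peak, by ascending absolute ppm error with ties broken
#' by candidate name. Peaks with no candidate in tolerance are kept as a row
#' with `NA` candidate columns and `within_tol = FALSE`, so the output always
#' accounts for every input peak.
#'
#' @param peaks A data frame with columns `rt_min` (retention time, minutes,
#'   >= 0) and `mz` (observed m/z of a singly charged cation, Da, > 0).
#' @param library A data frame with columns `name` and `formula` (formula
#'   strings as accepted by [parse_formula()]).
#' @param tolerance_ppm Positive ppm tolerance.
#' @param electron_correction Passed to [monoisotopic_mass()]; default `FALSE`.
#' @return A tibble of class `mass_annotation` with columns `rt_min`, `mz`,
#'   `name`, `formula`, `calc_mz`, `ppm_error` (signed), `within_tol`.
#' @examples
#' peaks <- tibble::tibble(rt_min = 7.41, mz = 298.1439)
#' lib <- tibble::tibble(name = "erythraline", formula = "C18H20NO3+")
#' annotate_peaks(peaks, lib, tolerance_ppm = 5)
#' @export
annotate_peaks <- function(peaks, library, tolerance_ppm,
                           electron_correction = FALSE) {
  peaks <- as_tibble(peaks)
  library <- as_tibble(library)
  check_columns(peaks, c("rt_min", "mz"), "peaks")
  check_columns(library, c("name", "formula"), "library")
  if (nrow(library) == 0L) abort("`library` must contain at least one candidate.")
  if (!is.numeric(tolerance_ppm) || length(tolerance_ppm) != 1L ||
      !is.finite(tolerance_ppm) || tolerance_ppm <= 0) {
    abort("`tolerance_ppm` must be a single positive number.")
  }
  if (any(peaks$mz <= 0)) abort("Observed m/z must be positive.")
  if (any(peaks$rt_min < 0)) abort("Retention times must be >= 0.")

  lib <- library |>
    dplyr::mutate(
      calc_mz = purrr::map_dbl(.data$formula, monoisotopic_mass,
                               electron_correction = electron_correction)
    )

  out <- peaks |>
    dplyr::mutate(.peak = dplyr::row_number()) |>
    dplyr::cross_join(lib) |>
    dplyr::mutate(
      ppm_error = ppm_error(.data$mz, .data$calc_mz),
      within_tol = abs(.data$ppm_error) <= tolerance_ppm
    ) |>
    dplyr::filter(.data$within_tol) |>
    dplyr::arrange(.data$.peak, abs(.data$ppm_error), .data$name)

  missed <- peaks |>
    dplyr::mutate(.peak = dplyr::row_number()) |>
    dplyr::anti_join(out, by = ".peak") |>
    dplyr::mutate(
      name = NA_character_, formula = NA_character_,
      calc_mz = NA_real_, ppm_error = NA_real_, within_tol = FALSE
    )

  res <- dplyr::bind_rows(out, missed) |>
    dplyr::arrange(.data$.peak, abs(.data$ppm_error)) |>
    dplyr::select("rt_min", "mz", "name", "formula", "calc_mz",
                  "ppm_error", "within_tol")
  attr(res, "tolerance_ppm") <- tolerance_ppm
  class(res) <- c("mass_annotation", class(res))
  res
}

#' @export
autoplot.mass_annotation <- function(object, ...) {
  tol <- attr(object, "tolerance_ppm") %||% NA_real_
  dat <- dplyr::filter(object, .data$within_tol)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mz, y = .data$ppm_error)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = c(-tol, tol), linetype = 3,
                        colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed m/z (Da)", y = "mass error (ppm)",
                  title = "Peak annotation mass errors") +
    ggplot2::theme_minimal()
}

#' Read a peak list CSV
#'
#' Expects a header with columns `rt_min, mz` (dot decimal separator).
#' @param path CSV path.
#' @return A tibble with columns `rt_min`, `mz`.
#' @export
read_peaks <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(x, c("rt_min", "mz"), "peak list")
  dplyr::select(x, "rt_min", "mz")
}

#' Read a candidate library CSV
#'
#' Expects a header with columns `name, formula`.
#' @param path CSV path.
#' @return A tibble with columns `name`, `formula`.
#' @export
read_library <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(x, c("name", "formula"), "candidate library")
  dplyr::select(x, "name", "formula")
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(paste0(
      "The ", what, " is missing required column(s): ",
      paste(sQuote(missing), collapse = ", "), "."
    ))
  }
  invisible(df)
}
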