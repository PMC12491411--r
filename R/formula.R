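#' Parse an elemental formula string
#'
#' Parses a Hill-style elemental formula such as `"C18H22NO5"` into an element
#' count table. A single trailing `"+"` marks the species as a singly charged
#' cation (the form in which protonated molecules are written in positive-mode
#' LC-MS tables). Only singly charged cations are supported: multiply charged
#' markers such as `"2+"` are rejected.
#'
#' @param text A single formula string. Bare element symbols have an implicit
#'   count of 1; explicit zero counts are an error.
#' @return An object of class `chem_formula`: a list with `counts` (named
#'   integer vector, element -> count) and `charge` (0 or 1).
#' @examples
#' parse_formula("C18H22NO5+")
#' parse_formula("H2O")
#' @seealso [monoisotopic_mass()], [annotate_peaks()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single formula string.")
  }
  raw <- trimws(text)
  if (raw == "") abort("Empty formula string.")

  charge <- 0L
  if (grepl("\\+\\+$", raw) || grepl("\\^[0-9]+\\+$", raw)) {
    abort(paste0(
      "Multiply charged species are not supported: ", sQuote(text),
      ". Only singly charged cations (one trailing '+') are modelled."
    ))
  }
  if (grepl("\\+$", raw)) {
    charge <- 1L
    raw <- sub("\\+$", "", raw)
  }
  if (grepl("[+-]", raw)) {
    abort(paste0("Malformed charge marker in formula ", sQuote(text), "."))
  }

  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", raw, perl = TRUE)[[1]]
  parts <- regmatches(raw, gregexpr("[A-Z][a-z]?[0-9]*", raw, perl = TRUE))[[1]]
  if (length(parts) == 0L || paste(parts, collapse = "") != raw) {
    abort(paste0("Malformed formula ", sQuote(text),
                 ": expected tokens like 'C18', 'H', 'Cl2'."))
  }

  elems <- sub("[0-9]*$", "", parts)
  nums <- sub("^[A-Za-z]+", "", parts)
  counts_each <- ifelse(nums == "", 1L, suppressWarnings(as.integer(nums)))
  if (anyNA(counts_each)) {
    abort(paste0("Malformed count in formula ", sQuote(text), "."))
  }
  if (any(counts_each == 0L)) {
    abort(paste0("Explicit zero count in formula ", sQuote(text), "."))
  }
  unknown <- setdiff(unique(elems), names(.MONOISOTOPIC_MASS))
  if (length(unknown) > 0L) {
    abort(paste0(
      "Unknown element symbol(s) ", paste(sQuote(unknown), collapse = ", "),
      " in formula ", sQuote(text),
      ". Known elements: ", paste(names(.MONOISOTOPIC_MASS), collapse = ", "), "."
    ))
  }

  counts <- vapply(split(counts_each, elems), sum, integer(1))
  # keep first-appearance order for printing
  counts <- counts[unique(elems)]
  structure(list(counts = counts, charge = charge), class = "chem_formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  body <- paste0(
    names(x$counts), ifelse(x$counts == 1L, "", x$counts),
    collapse = ""
  )
  cat("<chem_formula> ", body, if (x$charge == 1L) "+" else "", "\n", sep = "")
  invisible(x)
}

#' @export
format.chem_formula <- function(x, ...) {
  paste0(
    paste0(names(x$counts), ifelse(x$counts == 1L, "", x$counts), collapse = ""),
    if (x$charge == 1L) "+" else ""
  )
}

#' Combine two formulas
#'
#' Element counts add; the charge of the result is the sum of the charges
#' (capped at the supported +1).
#' @param e1,e2 `chem_formula` objects.
#' @return A `chem_formula`.
#' @export
"+.chem_formula" <- function(e1, e2) {
  stopifnot(inherits(e1, "chem_formula"), inherits(e2, "chem_formula"))
  charge <- e1$charge + e2$charge
  if (charge > 1L) {
    abort("Combined charge exceeds +1; only singly charged cations are modelled.")
  }
  all_elems <- union(names(e1$counts), names(e2$counts))
  counts <- vapply(all_elems, function(el) {
    sum(e1$counts[el], e2$counts[el], na.rm = TRUE)
  }, double(1))
  structure(
    list(counts = as.integer(counts) |> setNames(all_elems), charge = as.integer(charge)),
    class = "chem_formula"
  )
}

as_chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) x else parse_formula(x)
}

#' Monoisotopic mass of an elemental formula
#'
#' Sums `count * monoisotopic atomic mass` over the formula's elements, using
#' the fixed table in [atomic_masses()]. With `electron_correction = TRUE`,
#' one electron mass (0.00054858 Da) is subtracted per unit positive charge,
#' giving the physically strict mass of the cation. The correction is off by
#' default: published "calculated for" values for protonated natural products
#' are routinely plain atomic-mass sums of the cation formula, and the default
#' matches that convention.
#'
#' @param formula A `chem_formula` or a formula string (parsed on the fly).
#' @param electron_correction Subtract the electron mass per positive charge?
#'   Default `FALSE`.
#' @return Mass in Da (a single double). An empty formula has mass 0.
#' @examples
#' monoisotopic_mass("C18H16NO4") # 310.1079 at 4 decimals
#' monoisotopic_mass("C18H22NO5+", electron_correction = TRUE)
#' @export
monoisotopic_mass <- function(formula, electron_correction = FALSE) {
  f <- as_chem_formula(formula)
  m <- sum(.MONOISOTOPIC_MASS[names(f$counts)] * f$counts)
  if (length(f$counts) == 0L) m <- 0
  if (isTRUE(electron_correction)) m <- m - f$charge * .ELECTRON_MASS
  unname(m)
}

#' Signed ppm mass error
#'
#' `(observed - calculated) / calculated * 1e6`. Positive when the observed
#' m/z is heavier than calculated. Published tables often print the absolute
#' value; use `abs()` for that view.
#'
#' @param observed Observed m/z in Da (vectorised).
#' @param calculated Calculated m/z in Da (vectorised, must be > 0).
#' @return Signed error in ppm.
#' @examples
#' ppm_error(332.1513, monoisotopic_mass("C18H22NO5+"))
#' @export
ppm_error <- function(observed, calculated) {
  if (any(!is.finite(calculated)) || any(calculated <= 0)) {
    abort("`calculated` mass must be positive and finite.")
  }
  (observed - calculated) / calculated * 1e6
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of printed
#' chemistry tables), unlike base [round()] which rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.25, 1) # 2.3
#' round(2.25, 1)         # 2.2
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by sqrt(machine eps) so decimal halves stored just below .5 in
  # binary (e.g. 3.28265 -> 3.2826499...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
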