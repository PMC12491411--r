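# Conversion factor, CODATA 2018. Applied exactly once, when energies enter
# in hartree.
HARTREE_TO_EV <- 27.211386245988

#' Hartree to electronvolt conversion factor
#'
#' @return The factor 27.211386245988 eV/hartree used throughout the package.
#' @export
hartree_to_ev <- function() HARTREE_TO_EV

#' Extract the final SCF energy from a QM log file
#'
#' Scans the text for lines of the form `SCF Done:  E(...) =  <value>  A.U.`
#' and returns the value on the last such line (the final converged point of
#' the run). Only this fixture dialect is parsed; full quantum-chemistry
#' output formats vary and are out of scope.
#'
#' @param x Path to a log file, or a character vector of log lines.
#' @return The SCF energy in hartree (a single double).
#' @examples
#' extract_scf_energy("SCF Done:  E(RB3LYP) =  -1000.123456  A.U.")
#' @export
extract_scf_energy <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readr::read_lines(x)
    label <- x
  } else {
    lines <- unlist(strsplit(as.character(x), "\n", fixed = TRUE))
    label <- "<text>"
  }
  m <- stringr::str_match(
    lines, "SCF Done:\\s*\\S*\\s*=\\s*(-?[0-9]+\\.[0-9]+)\\s+A\\.U\\."
  )
  vals <- m[, 2][!is.na(m[, 2])]
  if (length(vals) == 0L) {
    abort(paste0("No 'SCF Done: ... A.U.' line found in ", label, "."))
  }
  as.numeric(vals[length(vals)])
}

#' Read vertical energies from a long-format CSV
#'
#' Expects columns `compound, phase, species, energy, unit` with
#' `species` in `neutral|cation|anion` and `unit` in `hartree|eV`. Returns
#' one row per compound x phase with the three energies converted to eV.
#'
#' @param path CSV path.
#' @return A tibble with columns `compound`, `phase`, `E_neutral`, `E_cation`,
#'   `E_anion` (all eV).
#' @export
read_energies <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(x, c("compound", "phase", "species", "energy", "unit"), "energies table")
  bad_sp <- setdiff(unique(x$species), c("neutral", "cation", "anion"))
  if (length(bad_sp) > 0L) {
    abort(paste0("Unknown species label(s): ", paste(sQuote(bad_sp), collapse = ", "), "."))
  }
  bad_u <- setdiff(unique(x$unit), c("hartree", "eV"))
  if (length(bad_u) > 0L) {
    abort(paste0("Unknown energy unit(s): ", paste(sQuote(bad_u), collapse = ", "), "."))
  }
  x |>
    dplyr::mutate(
      energy_ev = ifelse(.data$unit == "hartree",
                         .data$energy * HARTREE_TO_EV, .data$energy)
    ) |>
    dplyr::select("compound", "phase", "species", "energy_ev") |>
    tidyr::pivot_wider(names_from = "species", values_from = "energy_ev") |>
    dplyr::rename(E_neutral = "neutral", E_cation = "cation", E_anion = "anion") |>
    dplyr::mutate(unit = "eV")
}

#' Read vertical energies from fixture QM log files
#'
#' Reads every `<compound>_<phase>_<species>.log` file in `dir` with
#' [extract_scf_energy()] and assembles the long energies table.
#'
#' @param dir Directory of log files named `<compound>_<phase>_<species>.log`.
#' @return A tibble in the wide format of [read_energies()], energies in eV.
#' @export
read_qm_logs <- function(dir) {
  files <- list.files(dir, pattern = "\\.log$", full.names = TRUE)
  if (length(files) == 0L) abort(paste0("No .log files found in ", dir, "."))
  base <- sub("\\.log$", "", basename(files))
  parts <- stringr::str_match(base, "^(.*)_([^_]+)_(neutral|cation|anion)$")
  if (anyNA(parts[, 1])) {
    abort(paste0(
      "Log filename(s) not matching '<compound>_<phase>_<species>.log': ",
      paste(sQuote(basename(files)[is.na(parts[, 1])]), collapse = ", "), "."
    ))
  }
  long <- tibble::tibble(
    compound = parts[, 2], phase = parts[, 3], species = parts[, 4],
    energy = purrr::map_dbl(files, extract_scf_energy),
    unit = "hartree"
  )
  tmp <- withr_local_csv(long)
  on.exit(unlink(tmp), add = TRUE)
  read_energies(tmp)
}

# round-trip through the CSV reader so both input paths share one code path
withr_local_csv <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  readr::write_csv(df, tmp)
  tmp
}

#' Global conceptual-DFT reactivity descriptors from vertical energies
#'
#' Computes, per compound and phase, the nine global reactivity descriptors
#' of conceptual density-functional theory from single-point energies of the
#' neutral, cation and anion at the neutral geometry (the energy-vertical
#' method):
#'
#' * ionization potential `I = E_cation - E_neutral`
#' * electron affinity `A = E_neutral - E_anion`
#' * hardness `eta = (I - A)/2` and softness `sigma = 1/(2 eta)`
#' * electronegativity `chi = (I + A)/2` and chemical potential `mu = -chi`
#' * electrophilicity index: `omega = mu^2 / 2` under `variant = "paper"`;
#'   the standard Parr form `mu^2 / (2 eta)` is always reported alongside as
#'   `omega_std`
#' * electrodonating power `omega_minus = (3I + A)^2 / (16 (I - A))` and
#'   electroaccepting power `omega_plus = (I + 3A)^2 / (16 (I - A))`
#'
#' All outputs are in eV (softness in 1/eV). Identities `mu = -chi` and
#' `omega_minus - omega_plus = chi` hold algebraically. Degenerate inputs with
#' `I == A` make sigma, omega_minus and omega_plus undefined and raise an
#' error; `I < A` (negative hardness) is computed with a warning.
#'
#' @param energies A data frame with columns `compound`, `phase`, `E_neutral`,
#'   `E_cation`, `E_anion` and a `unit` column (`"hartree"` or `"eV"`; a
#'   single unit per row). [read_energies()] and [gen_energy_triples()]
#'   produce this format.
#' @param variant `"paper"` (electrophilicity mu^2/2, the published variant
#'   this package reproduces) or `"standard"` (Parr's mu^2/(2 eta)). Chooses
#'   which form fills the `omega` column; `omega_std` always holds the
#'   standard form.
#' @return A tibble of class `cdft_descriptors`: one row per compound x phase
#'   with columns `compound`, `phase`, `I`, `A`, `eta`, `sigma`, `chi`, `mu`,
#'   `omega`, `omega_std`, `omega_minus`, `omega_plus`, `variant`.
#' @examples
#' en <- gen_energy_triples(I = 7.2116, A = 0.6463, E_neutral = -800,
#'                          compound = "crystamidine")
#' compute_descriptors(en)
#' @export
compute_descriptors <- function(energies, variant = c("paper", "standard")) {
  variant <- match.arg(variant)
  energies <- as_tibble(energies)
  check_columns(energies, c("E_neutral", "E_cation", "E_anion"), "energies table")
  if (!"compound" %in% names(energies)) energies$compound <- "compound"
  if (!"phase" %in% names(energies)) energies$phase <- "gas"
  unit <- if ("unit" %in% names(energies)) energies$unit else "eV"
  if (length(unit) == 1L) unit <- rep(unit, nrow(energies))
  bad_u <- setdiff(unique(unit), c("hartree", "eV"))
  if (length(bad_u) > 0L) {
    abort(paste0("Unknown energy unit(s): ", paste(sQuote(bad_u), collapse = ", "), "."))
  }
  fac <- ifelse(unit == "hartree", HARTREE_TO_EV, 1)

  I <- (energies$E_cation - energies$E_neutral) * fac
  A <- (energies$E_neutral - energies$E_anion) * fac
  res <- descriptors_from_IA(I, A, variant = variant)
  res$compound <- energies$compound
  res$phase <- energies$phase
  res <- dplyr::relocate(res, "compound", "phase")
  class(res) <- c("cdft_descriptors", class(res))
  res
}

#' Descriptors directly from ionization potential and electron affinity
#'
#' Convenience entry point when I and A (eV) are already known, e.g. from a
#' published table. Equivalent to [compute_descriptors()] on the triple
#' `E_neutral = 0, E_cation = I, E_anion = -A`.
#'
#' @param I Vertical ionization potential, eV (vectorised).
#' @param A Vertical electron affinity, eV (vectorised; may be negative).
#' @inheritParams compute_descriptors
#' @return A tibble with the descriptor columns of [compute_descriptors()]
#'   (no compound/phase columns unless added by the caller).
#' @examples
#' descriptors_from_IA(7.2116, 0.6463)
#' @export
descriptors_from_IA <- function(I, A, variant = c("paper", "standard")) {
  variant <- match.arg(variant)
  if (length(I) != length(A)) abort("`I` and `A` must have the same length.")
  if (any(!is.finite(I)) || any(!is.finite(A))) {
    abort("`I` and `A` must be finite.")
  }
  if (any(I == A)) {
    abort(paste0(
      "Degenerate hardness: I == A for ", sum(I == A), " input(s); ",
      "softness and the electrodonating/accepting powers are undefined."
    ))
  }
  if (any(I < A)) {
    warn(paste0(
      "Negative hardness: I < A for ", sum(I < A), " input(s); ",
      "descriptors computed as defined, interpret with care."
    ))
  }
  eta <- (I - A) / 2
  chi <- (I + A) / 2
  mu <- -chi
  out <- tibble::tibble(
    I = I, A = A,
    eta = eta,
    sigma = 1 / (2 * eta),
    chi = chi,
    mu = mu,
    omega = if (variant == "paper") mu^2 / 2 else mu^2 / (2 * eta),
    omega_std = mu^2 / (2 * eta),
    omega_minus = (3 * I + A)^2 / (16 * (I - A)),
    omega_plus = (I + 3 * A)^2 / (16 * (I - A)),
    variant = variant
  )
  class(out) <- c("cdft_descriptors", class(out))
  out
}

#' @export
autoplot.cdft_descriptors <- function(object, descriptors = c("I", "A", "eta",
                                      "omega_minus", "omega_plus"), ...) {
  has_phase <- "phase" %in% names(object)
  if (!"compound" %in% names(object)) {
    object$compound <- as.character(seq_len(nrow(object)))
  }
  long <- object |>
    dplyr::select(dplyr::any_of(c("compound", "phase")),
                  dplyr::all_of(descriptors)) |>
    tidyr::pivot_longer(dplyr::all_of(descriptors),
                        names_to = "descriptor", values_to = "value") |>
    dplyr::mutate(descriptor = factor(.data$descriptor, levels = descriptors))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$compound, y = .data$value,
                                          fill = .data$descriptor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "eV", fill = NULL,
                  title = "Global reactivity descriptors") +
    ggplot2::theme_minimal()
  if (has_phase) p <- p + ggplot2::facet_wrap(~phase)
  p
}
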