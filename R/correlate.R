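#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. A thin, validating wrapper
#' around [stats::cor()] so pipelines get clear errors on the degenerate
#' cases (length mismatch, fewer than 3 pairs, constant vectors) instead of
#' `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3, no missing values.
#' @return The rank correlation, in \[-1, 1\].
#' @examples
#' spearman_rho(c(7.2116, 7.7258, 7.2313, 7.1690),
#'              c(681.4, 868.2, 285, 182.5)) # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  if (length(x) < 3L) abort("Need at least 3 pairs for a rank correlation.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not allowed.")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    abort("Rank correlation is undefined for a constant vector.")
  }
  cor(x, y, method = "spearman")
}

#' Join reactivity descriptors with antioxidant activity
#'
#' Inner-joins a descriptor table (one row per compound x phase) with an IC50
#' table (one row per compound) and computes, per phase, the Spearman rank
#' correlation of each descriptor with IC50. Every compound must appear
#' exactly once in each input (per phase for descriptors).
#'
#' @param descriptors A `cdft_descriptors` tibble with `compound` and `phase`
#'   columns (see [compute_descriptors()]).
#' @param ic50 A data frame with columns `compound` and `ic50` (e.g.
#'   `tidy()` of an [estimate_ic50()] fit, renamed, or [erythrina_ic50()]).
#' @param descriptor_cols Descriptor columns to correlate. Defaults to all
#'   nine.
#' @return A tibble with columns `phase`, `descriptor`, `rho`, `n`.
#' @examples
#' desc <- compute_descriptors(gen_energy_triples(
#'   I = c(7.2116, 7.7258, 7.2313, 7.1690),
#'   A = c(0.6463, 0.3074, -0.250, -0.3188),
#'   compound = c("crystamidine", "8-oxoerythraline", "erythrinine", "erythraline")
#' ))
#' correlate_activity(desc, erythrina_ic50())
#' @export
correlate_activity <- function(descriptors, ic50,
                               descriptor_cols = c("I", "A", "eta", "sigma",
                                                   "chi", "mu", "omega",
                                                   "omega_minus", "omega_plus")) {
  descriptors <- as_tibble(descriptors)
  ic50 <- as_tibble(ic50)
  check_columns(descriptors, c("compound", "phase", descriptor_cols), "descriptor table")
  check_columns(ic50, c("compound", "ic50"), "activity table")
  if (anyDuplicated(ic50$compound)) {
    abort("Each compound must appear exactly once in the activity table.")
  }
  dup <- descriptors |>
    dplyr::count(.data$compound, .data$phase) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort("Each compound x phase must appear exactly once in the descriptor table.")
  }
  joined <- dplyr::inner_join(descriptors, ic50, by = "compound")
  if (nrow(joined) == 0L) abort("No compounds shared between the two tables.")

  joined |>
    tidyr::pivot_longer(dplyr::all_of(descriptor_cols),
                        names_to = "descriptor", values_to = "value") |>
    dplyr::group_by(.data$phase, .data$descriptor) |>
    dplyr::summarise(
      rho = spearman_rho(.data$value, .data$ic50),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(descriptor = factor(.data$descriptor,
                                      levels = descriptor_cols)) |>
    dplyr::arrange(.data$phase, .data$descriptor) |>
    dplyr::mutate(descriptor = as.character(.data$descriptor))
}

# printed row labels for the report descriptor table
.DESCRIPTOR_LABELS <- c(
  I = "Ionization potential (I)",
  A = "Electron affinity (A)",
  eta = "Hardness (eta)",
  sigma = "Softness (sigma)",
  chi = "Electronegativity (chi)",
  mu = "Chemical potential (mu)",
  omega = "Electrophilicity index (Omega)",
  omega_minus = "Electron donating power (omega-)",
  omega_plus = "Electron accepting power (omega+)"
)

#' Render report tables for descriptors and activity
#'
#' Writes the publication-style tables: one descriptor table per phase block
#' (rows = the nine descriptors, columns = compounds, 4-decimal cells,
#' half-up rounding) and one activity table (`IC50 ± spread`). Compounds are
#' ordered by compound id, phases alphabetically, so output is deterministic.
#'
#' @param descriptors A `cdft_descriptors` tibble with `compound` and `phase`.
#' @param ic50 A data frame with columns `compound`, `ic50` and optionally
#'   `spread`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"`, `"markdown"` or both (default).
#' @return Invisibly, the paths of the files written.
#' @export
render_tables <- function(descriptors, ic50, dir,
                          format = c("csv", "markdown")) {
  format <- match.arg(format, several.ok = TRUE)
  descriptors <- as_tibble(descriptors)
  ic50 <- as_tibble(ic50)
  if (nrow(descriptors) == 0L || nrow(ic50) == 0L) {
    abort("Cannot render tables from an empty join.")
  }
  check_columns(descriptors, c("compound", "phase"), "descriptor table")
  check_columns(ic50, c("compound", "ic50"), "activity table")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  desc_cols <- intersect(names(.DESCRIPTOR_LABELS), names(descriptors))
  wide <- descriptors |>
    dplyr::arrange(.data$phase, .data$compound) |>
    tidyr::pivot_longer(dplyr::all_of(desc_cols),
                        names_to = "descriptor", values_to = "value") |>
    dplyr::mutate(
      descriptor = factor(.data$descriptor, levels = desc_cols),
      value = sprintf("%.4f", round_half_up(.data$value, 4))
    ) |>
    tidyr::pivot_wider(id_cols = c("phase", "descriptor"),
                       names_from = "compound", values_from = "value") |>
    dplyr::arrange(.data$phase, .data$descriptor) |>
    dplyr::mutate(descriptor = .DESCRIPTOR_LABELS[as.character(.data$descriptor)])

  act <- ic50 |>
    dplyr::arrange(.data$compound) |>
    dplyr::mutate(
      ic50_ug_ml = sprintf("%.1f", round_half_up(.data$ic50, 1)),
      spread_ug_ml = if ("spread" %in% names(ic50)) {
        ifelse(is.na(.data$spread), "",
               sprintf("%.1f", round_half_up(.data$spread, 1)))
      } else ""
    ) |>
    dplyr::select("compound", "ic50_ug_ml", "spread_ug_ml")

  paths <- character(0)
  if ("csv" %in% format) {
    p1 <- file.path(dir, "descriptors.csv")
    p2 <- file.path(dir, "activity.csv")
    readr::write_csv(wide, p1)
    readr::write_csv(act, p2)
    paths <- c(paths, p1, p2)
  }
  if ("markdown" %in% format) {
    p3 <- file.path(dir, "report.md")
    lines <- c("# Global reactivity descriptors", "")
    for (ph in unique(wide$phase)) {
      block <- dplyr::filter(wide, .data$phase == ph) |> dplyr::select(-"phase")
      lines <- c(lines, paste0("## ", ph, " phase"), "",
                 md_table(block), "")
    }
    act_md <- act |>
      dplyr::mutate(`IC50 (ug/mL)` = ifelse(
        .data$spread_ug_ml == "", .data$ic50_ug_ml,
        paste0(.data$ic50_ug_ml, " ± ", .data$spread_ug_ml))) |>
      dplyr::select("compound", "IC50 (ug/mL)")
    lines <- c(lines, "# DPPH radical-scavenging activity", "", md_table(act_md))
    writeLines(lines, p3)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

md_table <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}
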