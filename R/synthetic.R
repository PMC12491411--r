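# Seeded generators for every pipeline input. Each generator draws from its
# own RNG stream (local set.seed inside withr-style isolation) so identical
# arguments give byte-identical output without touching the caller's RNG.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Generate vertical energy triples with known I and A
#'
#' Inverse of the energy-vertical descriptor computation: given target
#' ionization potential and electron affinity (eV), emits neutral/cation/anion
#' single-point energies (hartree) such that [compute_descriptors()] recovers
#' exactly the requested I and A.
#'
#' @param I Target vertical ionization potential, eV (vectorised).
#' @param A Target vertical electron affinity, eV (vectorised). `I < A` is
#'   allowed, to exercise the negative-hardness warning downstream.
#' @param E_neutral Neutral-species energy in hartree (recycled).
#' @param phase Phase label (recycled), e.g. `"gas"` or `"solvent:ethanol"`.
#' @param compound Compound ids (default `"cmp1"`, `"cmp2"`, ...).
#' @return A tibble with columns `compound`, `phase`, `E_neutral`, `E_cation`,
#'   `E_anion`, `unit = "hartree"`, ready for [compute_descriptors()].
#' @examples
#' gen_energy_triples(I = 7.2116, A = 0.6463)
#' @export
gen_energy_triples <- function(I, A, E_neutral = -800, phase = "gas",
                               compound = paste0("cmp", seq_along(I))) {
  if (length(I) != length(A)) abort("`I` and `A` must have the same length.")
  n <- length(I)
  tibble::tibble(
    compound = rep_len(compound, n),
    phase = rep_len(phase, n),
    E_neutral = rep_len(E_neutral, n),
    E_cation = rep_len(E_neutral, n) + I / HARTREE_TO_EV,
    E_anion = rep_len(E_neutral, n) - A / HARTREE_TO_EV,
    unit = "hartree"
  )
}

#' Write fixture QM log files for an energy table
#'
#' Emits one `<compound>_<phase>_<species>.log` file per energy, in the
#' `SCF Done:` dialect that [extract_scf_energy()] and [read_qm_logs()] parse.
#' Energies already in eV are converted back to hartree for the log text.
#'
#' @param energies A tibble as returned by [gen_energy_triples()] (columns
#'   `compound`, `phase`, `E_neutral`, `E_cation`, `E_anion`, `unit`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_qm_logs <- function(energies, dir) {
  check_columns(energies, c("compound", "phase", "E_neutral", "E_cation",
                            "E_anion", "unit"), "energies table")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_len(nrow(energies))) {
    fac <- if (energies$unit[i] == "eV") 1 / HARTREE_TO_EV else 1
    vals <- c(neutral = energies$E_neutral[i],
              cation = energies$E_cation[i],
              anion = energies$E_anion[i]) * fac
    for (sp in names(vals)) {
      p <- file.path(dir, sprintf("%s_%s_%s.log",
                                  energies$compound[i], energies$phase[i], sp))
      writeLines(c(
        " Cycle  10  Energy converging.",
        sprintf(" SCF Done:  E(RB3LYP) =  %.9f  A.U. after   10 cycles",
                vals[[sp]])
      ), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Generate a synthetic DPPH plate with known IC50
#'
#' Simulates duplicate (or n-replicate) absorbance records for one sample on
#' a 96-well DPPH assay. True percent inhibition at concentration c follows
#' either a straight line through 50% at `true_ic50`
#' (`inhibition = 50 c / true_ic50`) or a four-parameter logistic with
#' midpoint `true_ic50`. Gaussian noise with `noise_sd` percentage points is
#' added on the inhibition scale and converted to absorbance through the
#' blank, so `noise_sd` keeps its model meaning regardless of the blank
#' level. Absorbances are floored at 0.
#'
#' @param true_ic50 True half-inhibition concentration, ug/mL.
#' @param model `"linear"` or `"4pl"`.
#' @param concentrations Tested concentrations, ug/mL. Default six points
#'   from 50 to 400.
#' @param replicates Number of replicates per concentration (default 2,
#'   "duplo").
#' @param noise_sd Gaussian noise, percentage points of inhibition.
#' @param blank_abs Blank (DPPH-only) absorbance at 517 nm.
#' @param hill,top,bottom 4PL shape parameters (used when `model = "4pl"`):
#'   `inhibition = bottom + (top - bottom) / (1 + (true_ic50/c)^hill)`.
#' @param sample_id Sample label.
#' @param seed Integer seed; identical arguments give identical records.
#' @return A tibble of absorbance records with columns `sample_id`,
#'   `concentration_ug_ml`, `replicate`, `abs_517`, `blank_abs`, plus assay
#'   metadata (`dpph_mM`, `sample_uL`, `dpph_uL`, `incubation_min`) and the
#'   generating truth (`true_ic50`, `model`, `noise_sd`, `seed`) as
#'   attributes.
#' @examples
#' plate <- gen_plate(true_ic50 = 182.5, noise_sd = 2, seed = 42)
#' estimate_ic50(build_curve(plate))
#' @export
gen_plate <- function(true_ic50, model = c("linear", "4pl"),
                      concentrations = seq(50, 400, length.out = 6),
                      replicates = 2, noise_sd = 2, blank_abs = 0.8,
                      hill = 1.5, top = 100, bottom = 0,
                      sample_id = "sample", seed = NULL) {
  model <- match.arg(model)
  if (length(concentrations) == 0L) abort("`concentrations` must be non-empty.")
  if (any(concentrations <= 0)) abort("Concentrations must be positive.")
  if (replicates < 1L) abort("`replicates` must be >= 1.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (true_ic50 <= 0) abort("`true_ic50` must be positive.")

  conc <- sort(concentrations)
  true_inh <- switch(model,
    linear = 50 * conc / true_ic50,
    `4pl` = bottom + (top - bottom) / (1 + (true_ic50 / conc)^hill)
  )
  grid <- tidyr::expand_grid(
    concentration_ug_ml = conc,
    replicate = seq_len(replicates)
  ) |>
    dplyr::left_join(
      tibble::tibble(concentration_ug_ml = conc, true_inh = true_inh),
      by = "concentration_ug_ml"
    )
  noise <- with_seed(seed, stats::rnorm(nrow(grid), 0, noise_sd))
  out <- grid |>
    dplyr::mutate(
      sample_id = sample_id,
      abs_517 = pmax(0, blank_abs * (1 - (.data$true_inh + noise) / 100)),
      blank_abs = blank_abs,
      dpph_mM = 1.0, sample_uL = 10, dpph_uL = 200, incubation_min = 30
    ) |>
    dplyr::select("sample_id", "concentration_ug_ml", "replicate", "abs_517",
                  "blank_abs", "dpph_mM", "sample_uL", "dpph_uL",
                  "incubation_min")
  attr(out, "truth") <- list(true_ic50 = true_ic50, model = model,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a synthetic peak list with controlled ppm error
#'
#' For each candidate formula, emits an observed m/z displaced from the
#' calculated monoisotopic mass by `ppm_offset` plus Gaussian ppm noise:
#' `observed = calculated * (1 + (offset + noise) * 1e-6)`. The returned
#' table doubles as peak list (columns `rt_min`, `mz`) and truth table
#' (`name`, `formula`, `calc_mz`, `true_ppm`).
#'
#' @param formulas Character vector of formula strings (see
#'   [parse_formula()]).
#' @param ppm_offset Systematic mass-error offset, ppm.
#' @param ppm_noise_sd Gaussian ppm noise standard deviation.
#' @param names Candidate names (default `"cand1"`, ...).
#' @param rt_min Retention times; default an evenly spaced ramp.
#' @param seed Integer seed.
#' @return A tibble with columns `rt_min`, `mz`, `name`, `formula`,
#'   `calc_mz`, `true_ppm`.
#' @examples
#' gen_peaklist("C18H22NO5+", ppm_offset = 4.5, seed = 1)
#' @export
gen_peaklist <- function(formulas, ppm_offset = 0, ppm_noise_sd = 0,
                         names = paste0("cand", seq_along(formulas)),
                         rt_min = seq(1, by = 0.5, length.out = length(formulas)),
                         seed = NULL) {
  calc <- purrr::map_dbl(formulas, monoisotopic_mass)
  noise <- with_seed(seed, stats::rnorm(length(formulas), 0, ppm_noise_sd))
  true_ppm <- ppm_offset + noise
  tibble::tibble(
    rt_min = rt_min,
    mz = calc * (1 + true_ppm * 1e-6),
    name = names,
    formula = as.character(formulas),
    calc_mz = calc,
    true_ppm = true_ppm
  )
}
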