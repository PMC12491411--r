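#' Percent inhibition of DPPH absorbance
#'
#' `(blank - sample) / blank * 100`: the fractional loss of DPPH absorbance
#' at 517 nm relative to the blank, in percent. Values outside \[0, 100\]
#' can occur with noisy plates and are returned as-is (never clipped;
#' clipping would bias IC50 estimation near the extremes).
#'
#' @param blank Blank absorbance (> 0, vectorised).
#' @param sample Sample absorbance (>= 0, vectorised).
#' @return Percent inhibition.
#' @examples
#' percent_inhibition(0.8, 0.4) # 50
#' @export
percent_inhibition <- function(blank, sample) {
  if (any(!is.finite(blank)) || any(blank <= 0)) {
    abort("`blank` absorbance must be positive.")
  }
  if (any(sample < 0)) abort("`sample` absorbance must be >= 0.")
  (blank - sample) / blank * 100
}

#' Read a DPPH plate CSV
#'
#' Expects columns `sample_id, concentration_ug_ml, replicate, abs_517,
#' blank_abs`.
#' @param path CSV path.
#' @return A tibble with those columns.
#' @export
read_plate <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(x, c("sample_id", "concentration_ug_ml", "replicate",
                     "abs_517", "blank_abs"), "plate table")
  x
}

#' Build dose-response curves from plate absorbance records
#'
#' Converts each record to percent inhibition against its blank, then
#' aggregates replicates per sample and concentration. Inhibition values
#' outside \[0, 100\] are flagged (`out_of_range`), not clipped.
#'
#' @param records A data frame with columns `sample_id`,
#'   `concentration_ug_ml`, `replicate`, `abs_517`, `blank_abs`.
#' @return A tibble of class `dpph_curve`: one row per sample x concentration
#'   with `inhibition` (replicate mean), `n_replicates`, `out_of_range`, and
#'   a list-column `replicate_inhibition` holding the per-replicate values
#'   (named by replicate id). Concentrations are strictly increasing within
#'   each sample.
#' @examples
#' plate <- gen_plate(true_ic50 = 200, noise_sd = 0, seed = 1)
#' build_curve(plate)
#' @export
build_curve <- function(records) {
  records <- as_tibble(records)
  check_columns(records, c("sample_id", "concentration_ug_ml", "replicate",
                           "abs_517", "blank_abs"), "plate records")
  if (any(records$blank_abs <= 0)) abort("Blank absorbance must be positive.")
  if (any(records$concentration_ug_ml < 0)) {
    abort("Concentrations must be >= 0.")
  }
  n_conc <- records |>
    dplyr::distinct(.data$sample_id, .data$concentration_ug_ml) |>
    dplyr::count(.data$sample_id)
  if (any(n_conc$n < 2L)) {
    abort(paste0(
      "Each sample needs >= 2 distinct concentrations; offending sample(s): ",
      paste(sQuote(n_conc$sample_id[n_conc$n < 2L]), collapse = ", "), "."
    ))
  }

  curve <- records |>
    dplyr::mutate(
      inhibition_rep = percent_inhibition(.data$blank_abs, .data$abs_517)
    ) |>
    dplyr::group_by(.data$sample_id, .data$concentration_ug_ml) |>
    dplyr::summarise(
      inhibition = mean(.data$inhibition_rep),
      n_replicates = dplyr::n(),
      out_of_range = any(.data$inhibition_rep < 0 | .data$inhibition_rep > 100),
      replicate_inhibition = list(
        setNames(.data$inhibition_rep, .data$replicate)
      ),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$sample_id, .data$concentration_ug_ml)
  class(curve) <- c("dpph_curve", class(curve))
  curve
}

#' Estimate IC50 from dose-response curves
#'
#' Finds, per sample, the concentration giving 50% inhibition:
#'
#' * `"bracket"` (default): linear interpolation between the two consecutive
#'   concentrations whose mean inhibitions straddle 50%. Assumption-free; if
#'   the curve crosses 50% more than once the first crossing is used, with a
#'   warning.
#' * `"linear_ls"`: least-squares straight line over all points, solved for
#'   50%.
#' * `"4pl"`: four-parameter logistic fit (in concentration), reporting the
#'   concentration at which the fitted curve reaches 50%.
#'
#' Replicate spread is obtained by re-estimating IC50 per replicate: for two
#' replicates it is half the range (labelled `half_range`), for three or more
#' the standard deviation (`sd`). Curves never reaching 50% are censored
#' (`censored = ">max tested"`); curves already above 50% at the lowest
#' concentration are censored `"<min tested"`; censored estimates have `NA`
#' `ic50`.
#'
#' @param curve A `dpph_curve` from [build_curve()], or raw plate records
#'   (passed through [build_curve()] first).
#' @param method `"bracket"`, `"linear_ls"` or `"4pl"`.
#' @return A tibble of class `ic50_fit`: one row per sample with columns
#'   `sample_id`, `ic50` (ug/mL), `spread` (ug/mL), `spread_type`, `method`,
#'   `censored` (`NA` when not censored), `n_replicates`.
#' @examples
#' plate <- gen_plate(true_ic50 = 200, noise_sd = 0, seed = 1)
#' estimate_ic50(build_curve(plate))
#' @export
estimate_ic50 <- function(curve, method = c("bracket", "linear_ls", "4pl")) {
  method <- match.arg(method)
  if (!inherits(curve, "dpph_curve")) curve <- build_curve(curve)

  per_sample <- split(curve, curve$sample_id)
  rows <- purrr::map(per_sample, function(cv) {
    est <- ic50_one(cv$concentration_ug_ml, cv$inhibition, method)
    # per-replicate estimates for the spread
    rep_ids <- sort(unique(unlist(purrr::map(cv$replicate_inhibition, names))))
    rep_ic50 <- purrr::map_dbl(rep_ids, function(r) {
      inh <- purrr::map_dbl(cv$replicate_inhibition, function(v) {
        if (r %in% names(v)) unname(v[r]) else NA_real_
      })
      keep <- !is.na(inh)
      if (sum(keep) < 2L) return(NA_real_)
      e <- tryCatch(
        suppressWarnings(ic50_one(cv$concentration_ug_ml[keep], inh[keep], method)),
        error = function(e) list(ic50 = NA_real_)
      )
      e$ic50
    })
    rep_ic50 <- rep_ic50[!is.na(rep_ic50)]
    if (length(rep_ic50) >= 3L) {
      spread <- sd(rep_ic50); spread_type <- "sd"
    } else if (length(rep_ic50) == 2L) {
      spread <- diff(range(rep_ic50)) / 2; spread_type <- "half_range"
    } else {
      spread <- NA_real_; spread_type <- NA_character_
    }
    tibble::tibble(
      sample_id = cv$sample_id[1],
      ic50 = est$ic50,
      spread = if (is.na(est$ic50)) NA_real_ else spread,
      spread_type = if (is.na(est$ic50)) NA_character_ else spread_type,
      method = method,
      censored = est$censored,
      n_replicates = max(cv$n_replicates)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "curve") <- curve
  class(out) <- c("ic50_fit", class(out))
  out
}

# single-curve IC50 on mean inhibitions; returns list(ic50, censored)
ic50_one <- function(conc, inh, method) {
  ord <- order(conc)
  conc <- conc[ord]; inh <- inh[ord]
  if (all(inh < 50)) return(list(ic50 = NA_real_, censored = ">max tested"))
  if (all(inh > 50)) return(list(ic50 = NA_real_, censored = "<min tested"))
  ic50 <- switch(method,
    bracket = ic50_bracket(conc, inh),
    linear_ls = ic50_linear_ls(conc, inh),
    `4pl` = ic50_4pl(conc, inh)
  )
  list(ic50 = ic50, censored = NA_character_)
}

ic50_bracket <- function(conc, inh) {
  below <- inh < 50
  crossings <- which(below[-length(below)] != below[-1])
  if (any(inh == 50)) return(conc[which(inh == 50)[1]])
  if (length(crossings) > 1L) {
    warn("Curve crosses 50% more than once; using the first crossing.")
  }
  i <- crossings[1]
  c1 <- conc[i]; c2 <- conc[i + 1]
  y1 <- inh[i]; y2 <- inh[i + 1]
  c1 + (50 - y1) * (c2 - c1) / (y2 - y1)
}

ic50_linear_ls <- function(conc, inh) {
  fit <- lm(inh ~ conc)
  b <- coef(fit)
  if (b[2] == 0) {
    abort("Flat least-squares line; IC50 undefined.")
  }
  unname((50 - b[1]) / b[2])
}

# Four-parameter log-logistic (Hill) model, the standard dose-response form:
#   inh(c) = bottom + (top - bottom) / (1 + (mid/c)^hill)
# Fitted with stats::nls (port algorithm), minpack.lm::nlsLM as fallback.
# The reported IC50 is the concentration at which the fitted curve reaches
# 50%, which coincides with `mid` when bottom and top are symmetric about 50.
ic50_4pl <- function(conc, inh) {
  df <- data.frame(conc = conc, inh = inh)
  start <- list(
    bottom = min(inh) - 1e-3, top = max(inh) + 1e-3,
    mid = conc[which.min(abs(inh - 50))],
    hill = 1.5
  )
  form <- inh ~ bottom + (top - bottom) / (1 + (mid / conc)^hill)
  fit <- tryCatch(
    nls(form, data = df, start = start, algorithm = "port",
        lower = c(bottom = -Inf, top = -Inf, mid = min(conc) / 100,
                  hill = 1e-3),
        control = stats::nls.control(tol = 1e-10, maxiter = 500,
                                     minFactor = 1e-12, warnOnly = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit) && requireNamespace("minpack.lm", quietly = TRUE)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) abort("Four-parameter logistic fit failed to converge.")
  p <- coef(fit)
  if (!(min(p["bottom"], p["top"]) < 50 && 50 < max(p["bottom"], p["top"]))) {
    abort("Fitted logistic never reaches 50% inhibition.")
  }
  # invert: 50 = bottom + (top - bottom)/(1 + (mid/c)^hill)
  unname(p[["mid"]] /
           ((p[["top"]] - 50) / (50 - p[["bottom"]]))^(1 / p[["hill"]]))
}

#' @export
tidy.ic50_fit <- function(x, ...) {
  out <- x
  attr(out, "curve") <- NULL
  class(out) <- setdiff(class(out), "ic50_fit")
  as_tibble(out)
}

#' @export
glance.ic50_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    n_censored = sum(!is.na(x$censored)),
    method = x$method[1]
  )
}

#' @export
autoplot.ic50_fit <- function(object, ...) {
  curve <- attr(object, "curve")
  p <- autoplot(curve, ...)
  marks <- dplyr::filter(tidy(object), !is.na(.data$ic50))
  if (nrow(marks) > 0L) {
    p <- p +
      ggplot2::geom_vline(
        data = marks,
        ggplot2::aes(xintercept = .data$ic50),
        linetype = 2, colour = "firebrick"
      )
  }
  p
}

#' @export
autoplot.dpph_curve <- function(object, ...) {
  pts <- object |>
    dplyr::select("sample_id", "concentration_ug_ml", "replicate_inhibition") |>
    dplyr::mutate(replicate_inhibition = purrr::map(
      .data$replicate_inhibition, ~tibble::tibble(inhibition = unname(.x))
    )) |>
    tidyr::unnest("replicate_inhibition")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$concentration_ug_ml,
                                       y = .data$inhibition)) +
    ggplot2::geom_hline(yintercept = 50, linetype = 3, colour = "grey40") +
    ggplot2::geom_point(data = pts, alpha = 0.4, size = 1) +
    ggplot2::geom_line() +
    ggplot2::geom_point(shape = 21, fill = "white") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "concentration (µg/mL)", y = "% inhibition",
                  title = "DPPH dose-response") +
    ggplot2::theme_minimal()
}
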