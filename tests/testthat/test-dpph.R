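test_that("percent inhibition is the relative absorbance drop", {
  expect_equal(percent_inhibition(0.8, 0.4), 50)
  expect_equal(percent_inhibition(0.8, 0.8), 0)
  expect_equal(percent_inhibition(0.5, 0), 100)
  expect_error(percent_inhibition(0, 0.2), "positive")
  expect_error(percent_inhibition(0.5, -0.1), ">= 0")
})

test_that("percent inhibition decreases in sample absorbance and is scale-invariant", {
  s <- seq(0, 1, by = 0.1)
  v <- percent_inhibition(1, s)
  expect_true(all(diff(v) < 0))
  for (c_ in c(0.1, 2, 17)) {
    expect_equal(percent_inhibition(0.8 * c_, 0.3 * c_),
                 percent_inhibition(0.8, 0.3))
  }
})

test_that("build_curve averages replicates and flags gaps and excursions", {
  plate <- gen_plate(true_ic50 = 200, noise_sd = 0, seed = 1,
                     concentrations = c(100, 200, 300))
  cv <- build_curve(plate)
  expect_s3_class(cv, "dpph_curve")
  expect_equal(nrow(cv), 3L)
  expect_true(all(cv$n_replicates == 2L))
  expect_true(all(diff(cv$concentration_ug_ml) > 0))
  expect_equal(cv$inhibition, 50 * c(100, 200, 300) / 200)

  # a missing replicate leaves n = 1 at that point
  cv1 <- build_curve(plate[-1, ])
  expect_equal(cv1$n_replicates, c(1L, 2L, 2L))

  # inhibition above 100% is flagged, not clipped
  hot <- plate
  hot$abs_517[6] <- -0  # 100% exactly stays in range
  hot$abs_517[5] <- 0
  hot$blank_abs <- 0.8
  hot$abs_517[1] <- 0.9 # negative inhibition
  cvh <- build_curve(hot)
  expect_true(cvh$out_of_range[1])
  expect_lt(cvh$inhibition[1], 25)

  expect_error(build_curve(plate[plate$concentration_ug_ml == 100, ]),
               ">= 2 distinct concentrations")
})

test_that("bracket interpolation crosses 50% between the straddling points", {
  rec <- tibble::tibble(
    sample_id = "s", concentration_ug_ml = rep(c(100, 300), each = 2),
    replicate = rep(1:2, 2),
    abs_517 = 0.8 * (1 - rep(c(30, 70), each = 2) / 100),
    blank_abs = 0.8
  )
  est <- estimate_ic50(build_curve(rec))
  expect_equal(est$ic50, 200)
  expect_true(is.na(est$censored))
  expect_equal(est$spread, 0)
})

test_that("estimators agree on noiseless curves from their own model family", {
  # linear curve: interpolation and least squares are both exact; the
  # logistic is a different family and only approximates a line, so it is
  # held to 0.1% here
  conc <- seq(50, 350, length.out = 6) # symmetric about the true IC50
  plate <- gen_plate(true_ic50 = 200, concentrations = conc,
                     noise_sd = 0, seed = 1)
  cv <- build_curve(plate)
  ests <- vapply(c("bracket", "linear_ls", "4pl"),
                 function(m) estimate_ic50(cv, method = m)$ic50, double(1))
  expect_equal(unname(ests[["bracket"]]), 200, tolerance = 1e-12)
  expect_equal(unname(ests[["linear_ls"]]), 200, tolerance = 1e-9)
  expect_equal(unname(ests[["4pl"]]), 200, tolerance = 1e-3)

  # logistic curve with a design point at the midpoint: the 4PL fit and the
  # bracket both recover the midpoint to solver precision
  p4 <- gen_plate(true_ic50 = 150, model = "4pl", hill = 1.5,
                  concentrations = c(50, 100, 150, 225, 340), noise_sd = 0,
                  seed = 1)
  cv4 <- build_curve(p4)
  expect_equal(estimate_ic50(cv4, method = "4pl")$ic50, 150, tolerance = 1e-6)
  expect_equal(estimate_ic50(cv4, method = "bracket")$ic50, 150,
               tolerance = 1e-12)
})

test_that("curves that never straddle 50% are censored", {
  low <- gen_plate(true_ic50 = 1000, concentrations = seq(50, 400, 70),
                   noise_sd = 0, seed = 1) # maxes at 20%
  e1 <- estimate_ic50(build_curve(low))
  expect_true(is.na(e1$ic50))
  expect_equal(e1$censored, ">max tested")

  high <- gen_plate(true_ic50 = 10, concentrations = c(50, 100, 200),
                    noise_sd = 0, seed = 1)
  e2 <- estimate_ic50(build_curve(high))
  expect_equal(e2$censored, "<min tested")
})

test_that("estimates are invariant to row order of the input records", {
  plate <- gen_plate(true_ic50 = 182.5, noise_sd = 2, seed = 99)
  shuffled <- plate[sample(nrow(plate)), ]
  e1 <- tidy(estimate_ic50(build_curve(plate)))
  e2 <- tidy(estimate_ic50(build_curve(shuffled)))
  expect_equal(e1, e2)
})

test_that("duplicate spread is the half-range of per-replicate estimates", {
  conc <- c(100, 300)
  # replicate 1 crosses at 200, replicate 2 at 220
  inh1 <- 50 * conc / 200
  inh2 <- 50 * conc / 220
  rec <- tibble::tibble(
    sample_id = "s",
    concentration_ug_ml = rep(conc, each = 2),
    replicate = rep(1:2, 2),
    abs_517 = 0.8 * (1 - c(inh1[1], inh2[1], inh1[2], inh2[2]) / 100),
    blank_abs = 0.8
  )
  est <- estimate_ic50(build_curve(rec))
  expect_equal(est$spread_type, "half_range")
  expect_equal(est$spread, (220 - 200) / 2)
  expect_equal(est$n_replicates, 2)
})

test_that("ic50_fit provides tidy, glance and plate CSV round-trips", {
  plate <- gen_plate(true_ic50 = 182.5, noise_sd = 2, seed = 4)
  f <- tempfile(fileext = ".csv")
  readr::write_csv(plate[c("sample_id", "concentration_ug_ml", "replicate",
                           "abs_517", "blank_abs")], f)
  fit <- estimate_ic50(build_curve(read_plate(f)))
  unlink(f)
  td <- tidy(fit)
  expect_false(inherits(td, "ic50_fit"))
  expect_named(td, c("sample_id", "ic50", "spread", "spread_type", "method",
                     "censored", "n_replicates"))
  gl <- glance(fit)
  expect_equal(gl$n_samples, 1L)
  expect_equal(gl$n_censored, 0L)
  expect_equal(gl$method, "bracket")
})
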