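test_that("formula strings parse to exact element counts and charge", {
  f <- parse_formula("C18H22NO5+")
  expect_equal(f$counts, c(C = 18L, H = 22L, N = 1L, O = 5L))
  expect_equal(f$charge, 1L)

  w <- parse_formula("H2O")
  expect_equal(w$counts, c(H = 2L, O = 1L))
  expect_equal(w$charge, 0L)

  f1 <- parse_formula("C18H16NO4")
  expect_equal(f1$counts, c(C = 18L, H = 16L, N = 1L, O = 4L))

  # two-letter symbols are distinguished from stacked one-letter symbols
  expect_equal(parse_formula("NaCl")$counts, c(Na = 1L, Cl = 1L))
  expect_equal(parse_formula("CO")$counts, c(C = 1L, O = 1L))

  expect_error(parse_formula("C18X2"), "Unknown element")
  expect_error(parse_formula("C0H2"), "zero count")
  expect_error(parse_formula("C6H12++"), "Multiply charged")
  expect_error(parse_formula(""), "Empty")
  expect_error(parse_formula("c6h6"), "Malformed")
})

test_that("monoisotopic masses match printed HRMS calculated-for values", {
  # protonated-cation compositions of the four isolated alkaloids
  expect_equal(round(monoisotopic_mass("C18H16NO4"), 4), 310.1079)
  expect_equal(round(monoisotopic_mass("C18H18NO4"), 4), 312.1236)
  expect_equal(round(monoisotopic_mass("C18H20NO4"), 4), 314.1392)
  expect_equal(round(monoisotopic_mass("C18H20NO3"), 4), 298.1443)
  # hand-summed oracle value
  expect_equal(round(monoisotopic_mass("C18H22NO5"), 4),
               round(oracle_mass(18, 22, 1, 5), 4))
  expect_equal(round(monoisotopic_mass("C18H22NO5"), 4), 332.1498)
})

test_that("mass is additive and the electron correction is one electron per charge", {
  set.seed(11)
  for (i in 1:25) {
    a <- random_formula()
    b <- random_formula()
    fa <- parse_formula(a$text)
    fb <- parse_formula(b$text)
    expect_equal(monoisotopic_mass(fa + fb),
                 monoisotopic_mass(fa) + monoisotopic_mass(fb))
  }
  f <- "C18H22NO5+"
  expect_equal(monoisotopic_mass(f, electron_correction = TRUE),
               monoisotopic_mass(f) - 0.00054858)
  # uncharged species are unaffected by the flag
  expect_equal(monoisotopic_mass("C6H6", electron_correction = TRUE),
               monoisotopic_mass("C6H6"))
})

test_that("ppm error is the signed relative deviation in parts per million", {
  expect_equal(ppm_error(500.0005, 500), 1)
  expect_equal(ppm_error(123.456, 123.456), 0)
  expect_equal(ppm_error(499.9995, 500), -1)
  expect_equal(round(abs(ppm_error(332.1513, monoisotopic_mass("C18H22NO5+"))), 1),
               4.5)
  expect_error(ppm_error(500, 0), "positive")
  expect_error(ppm_error(500, -1), "positive")
})

test_that("annotate_peaks keeps candidates within tolerance, ranked by |ppm|", {
  lib <- tibble::tibble(
    name = c("erythraline", "erysodine-like", "far"),
    formula = c("C18H20NO3+", "C18H22NO3+", "C10H10NO2+")
  )
  peaks <- tibble::tibble(rt_min = 7.41, mz = 298.1439)
  hits <- annotate_peaks(peaks, lib, tolerance_ppm = 5)
  hit <- dplyr::filter(hits, within_tol)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$formula, "C18H20NO3+")
  expect_lt(abs(hit$ppm_error), 5)

  # exact match ranks first with ppm_error 0
  m <- monoisotopic_mass("C18H20NO3+")
  peaks2 <- tibble::tibble(rt_min = 1, mz = m)
  hits2 <- annotate_peaks(peaks2, lib, tolerance_ppm = 1000)
  expect_equal(hits2$ppm_error[1], 0)
  expect_equal(hits2$formula[1], "C18H20NO3+")

  # huge tolerance returns every candidate for every peak
  expect_equal(nrow(annotate_peaks(peaks, lib, tolerance_ppm = 1e9)), nrow(lib))

  # ties in |ppm| break by candidate name
  twin <- tibble::tibble(name = c("b-cand", "a-cand"),
                         formula = c("C18H20NO3+", "C18H20NO3+"))
  tied <- annotate_peaks(peaks, twin, tolerance_ppm = 5)
  expect_equal(tied$name, c("a-cand", "b-cand"))

  expect_error(annotate_peaks(peaks, lib[0, ], 5), "at least one")
  expect_error(annotate_peaks(peaks, lib, -1), "positive")
})

test_that("peaks beyond tolerance are reported unannotated", {
  pk <- gen_peaklist(c("C18H22NO5+", "C18H20NO3+"), ppm_offset = 3, seed = 7)
  # brute-force check of the injected error before using it
  expect_true(all(abs((pk$mz - pk$calc_mz) / pk$calc_mz * 1e6 - 3) < 1e-9))
  res <- annotate_peaks(pk[c("rt_min", "mz")], pk[c("name", "formula")],
                        tolerance_ppm = 2)
  expect_equal(nrow(res), 2L)
  expect_false(any(res$within_tol))
  expect_true(all(is.na(res$name)))
})

test_that("peak and library CSV readers round-trip the documented dialect", {
  pk <- gen_peaklist(c("C18H22NO5+", "C18H20NO3+"), ppm_offset = 1, seed = 3)
  fp <- tempfile(fileext = ".csv")
  fl <- tempfile(fileext = ".csv")
  readr::write_csv(pk[c("rt_min", "mz")], fp)
  readr::write_csv(pk[c("name", "formula")], fl)
  expect_equal(as.data.frame(read_peaks(fp)), as.data.frame(pk[c("rt_min", "mz")]))
  expect_equal(as.data.frame(read_library(fl)), as.data.frame(pk[c("name", "formula")]))
  hits <- annotate_peaks(read_peaks(fp), read_library(fl), tolerance_ppm = 2)
  expect_true(all(hits$within_tol))
  unlink(c(fp, fl))
})
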