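test_that("spectra CSVs are parsed and validated", {
  wl <- 250:350
  p1 <- write_spectra_csv(wl, data.frame(A1 = exp(-((wl - 262) / 10)^2)))
  sp <- read_spectra(p1)
  expect_length(sp, 1L)
  expect_s3_class(sp$A1, "spectrum")
  expect_identical(sp$A1$wavelengths, as.numeric(wl))

  p3 <- write_spectra_csv(wl, data.frame(s1 = wl * 0 + 1, s2 = wl * 0.01,
                                         s3 = rev(wl) * 0.01))
  expect_length(read_spectra(p3), 3L)

  pdesc <- write_spectra_csv(rev(wl), data.frame(A1 = seq_along(wl)))
  expect_error(read_spectra(pdesc), "ascending")

  pmiss <- tempfile(fileext = ".csv")
  write.csv(data.frame(nm = wl, A1 = 1), pmiss, row.names = FALSE)
  expect_error(read_spectra(pmiss), "wavelength_nm")

  pbad <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,A1", "250,0.1", "251,oops", "252,0.3"), pbad)
  expect_error(read_spectra(pbad), "row 2")

  pempty <- tempfile(fileext = ".csv")
  writeLines("wavelength_nm,A1", pempty)
  expect_error(read_spectra(pempty), "empty")
})

test_that("noise-free linear combinations are recovered exactly", {
  refs <- make_reference_spectra(synthetic_spec())
  pure <- simulate_mixture(0, refs)
  res0 <- unmix(pure, refs)
  expect_equal(res0$conversion, 0, tolerance = 1e-10)
  expect_lt(res0$residual_rms, 1e-12)

  for (c_true in c(0.2, 0.5, 0.65, 1)) {
    res <- unmix(simulate_mixture(c_true, refs), refs)
    expect_equal(res$conversion, c_true, tolerance = 1e-10)
    expect_false(res$flag)
  }
})

test_that("conversion is invariant to overall spectrum scale", {
  refs <- make_reference_spectra(synthetic_spec())
  mix <- simulate_mixture(0.37, refs, noise_sd = 0.003, seed = 5)
  base <- unmix(mix, refs)$conversion
  for (s in c(0.1, 3, 40)) {
    scaled <- spectrum(mix$wavelengths, s * mix$absorbances, "scaled")
    expect_equal(unmix(scaled, refs)$conversion, base, tolerance = 1e-10)
  }
})

test_that("a constant baseline offset of either sign is absorbed", {
  refs <- make_reference_spectra(synthetic_spec())
  mix <- simulate_mixture(0.4, refs)
  for (off in c(0.05, -0.02)) {
    shifted <- spectrum(mix$wavelengths, mix$absorbances + off, "offset")
    res <- unmix(shifted, refs, baseline = TRUE)
    expect_equal(res$conversion, 0.4, tolerance = 1e-8)
    expect_equal(res$baseline, off, tolerance = 1e-8)
  }
})

test_that("blank and ill-conditioned inputs raise informative errors", {
  refs <- make_reference_spectra(synthetic_spec())
  wl <- refs$nucleoside_ref$wavelengths
  blank <- spectrum(wl, rep(0, length(wl)), "blank")
  expect_error(unmix(blank, refs), "undefined")
  # identical reference shapes: designed conditioning failure downstream
  spec_bad <- synthetic_spec(
    nucleobase_peaks = data.frame(center = 262, width = 10, height = 1.0),
    min_peak_separation = 0)
  refs_bad <- make_reference_spectra(spec_bad)
  expect_error(unmix(simulate_mixture(0.5, refs_bad), refs_bad),
               "ill-conditioned")
})

test_that("references are interpolated onto the sample grid, never extrapolated", {
  refs <- make_reference_spectra(synthetic_spec())
  inner <- seq(255, 345, by = 0.7)  # off-grid interior wavelengths
  y <- 0.3 * approx(refs$nucleoside_ref$wavelengths,
                    refs$nucleoside_ref$absorbances, inner)$y +
       0.7 * approx(refs$nucleobase_ref$wavelengths,
                    refs$nucleobase_ref$absorbances, inner)$y
  res <- unmix(spectrum(inner, y, "interp"), refs)
  expect_equal(res$conversion, 0.7, tolerance = 1e-3)
  wide <- spectrum(seq(240, 360, by = 1), rep(0.5, 121), "wide")
  expect_error(unmix(wide, refs), "extrapolation")
})

test_that("the conversion estimator is accurate and unbiased under noise", {
  refs <- make_reference_spectra(synthetic_spec())
  ests <- vapply(1:40, function(s) {
    unmix(simulate_mixture(0.65, refs, noise_sd = 0.005, seed = s),
          refs)$conversion
  }, numeric(1))
  expect_true(all(abs(ests - 0.65) <= 0.01))
  expect_lt(abs(mean(ests) - 0.65), 0.002)
  # spread shrinks with the noise level
  ests_lo <- vapply(1:40, function(s) {
    unmix(simulate_mixture(0.65, refs, noise_sd = 0.001, seed = s),
          refs)$conversion
  }, numeric(1))
  expect_lt(sd(ests_lo), sd(ests))
})

test_that("batch conversion tables carry labels, flags and errors", {
  refs <- make_reference_spectra(synthetic_spec())
  wl <- refs$nucleoside_ref$wavelengths
  ref_path <- write_spectra_csv(wl, data.frame(
    nucleoside = refs$nucleoside_ref$absorbances,
    nucleobase = refs$nucleobase_ref$absorbances))

  cols <- data.frame(
    t0 = simulate_mixture(0, refs)$absorbances,
    mid = simulate_mixture(0.5, refs)$absorbances,
    done = simulate_mixture(1, refs)$absorbances)
  tab <- conversions_from_files(write_spectra_csv(wl, cols), ref_path)
  expect_identical(tab$label, c("t0", "mid", "done"))
  expect_equal(tab$conversion, c(0, 0.5, 1), tolerance = 1e-10)
  expect_false(any(tab$flag))

  noisy <- as.data.frame(lapply(setNames(1:12, paste0("s", 1:12)),
    function(s) simulate_mixture(0.4, refs, 0.003, seed = s)$absorbances))
  tabn <- conversions_from_files(write_spectra_csv(wl, noisy), ref_path)
  expect_identical(nrow(tabn), 12L)
  expect_false(any(tabn$flag))

  pempty <- tempfile(fileext = ".csv")
  writeLines("wavelength_nm,A1", pempty)
  expect_error(conversions_from_files(pempty, ref_path), "empty")
  # per-sample errors name the sample
  cols_bad <- data.frame(ok = simulate_mixture(0.5, refs)$absorbances,
                         blank = rep(0, length(wl)))
  expect_error(
    conversions_from_files(write_spectra_csv(wl, cols_bad), ref_path),
    "blank")
})
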