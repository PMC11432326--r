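test_that("spectrum preprocessing averages scans and subtracts the blank", {
  wl <- seq(190, 260, by = 2)
  one <- data.frame(wavelength_nm = wl, signal = sin(wl / 10), scan_id = 1)
  scans <- dplyr::bind_rows(lapply(1:6, function(i) transform(one, scan_id = i)))
  blank <- data.frame(wavelength_nm = wl, signal = 0.3)
  out <- preprocess_spectrum(scans, blank)
  expect_equal(out$signal, sin(wl / 10) - 0.3)
  expect_equal(unique(out$n_scans), 6L)

  # opposite scans cancel
  pm <- dplyr::bind_rows(
    data.frame(wavelength_nm = wl, signal = sin(wl / 10), scan_id = "a"),
    data.frame(wavelength_nm = wl, signal = -sin(wl / 10), scan_id = "b"))
  expect_equal(preprocess_spectrum(pm)$signal, rep(0, length(wl)))

  # randomized scans agree with plain arithmetic
  set.seed(9)
  rnd <- dplyr::bind_rows(lapply(1:4, function(i) {
    data.frame(wavelength_nm = wl, signal = rnorm(length(wl)), scan_id = i)
  }))
  manual <- as.numeric(tapply(rnd$signal, rnd$wavelength_nm, mean))
  expect_equal(preprocess_spectrum(rnd)$signal, manual)

  bad <- dplyr::bind_rows(one,
                          data.frame(wavelength_nm = wl + 1, signal = 0,
                                     scan_id = 2))
  expect_error(preprocess_spectrum(bad), "grid")
})

test_that("two-state signal hits the baseline midpoint at Tm and the folded limit", {
  Tm <- 357.36
  s_mid <- two_state_signal(Tm, Tm, 150, -20, 0.01, -5, 0.005)
  expect_equal(s_mid, ((-20 + 0.01 * Tm) + (-5 + 0.005 * Tm)) / 2)
  # far below the transition the native baseline is returned
  s_cold <- two_state_signal(250, Tm, 150, -20, 0.01, -5, 0.005)
  expect_equal(s_cold, -20 + 0.01 * 250, tolerance = 1e-9)
  # extreme arguments do not overflow
  expect_true(is.finite(two_state_signal(1e4, Tm, 5000, -20, 0.01, -5, 0.005)))
})

test_that("two-state signal equals the independently coded Boltzmann form", {
  set.seed(13)
  Tk <- seq(335, 368, length.out = 50)
  for (i in 1:5) {
    Tm <- runif(1, 340, 365); dH <- runif(1, 50, 300)
    b <- rnorm(4, c(-20, 0.01, -5, 0.005), c(5, 0.005, 2, 0.002))
    expect_equal(two_state_signal(Tk, Tm, dH, b[1], b[2], b[3], b[4]),
                 melt_signal_oracle(Tk, Tm, dH, b[1], b[2], b[3], b[4]))
  }
})

test_that("fraction unfolded is 0.5 at Tm, monotone, and saturates", {
  expect_equal(fraction_unfolded(357.36, 357.36, 150), 0.5)
  expect_equal(fraction_unfolded(357.36, 357.36, 10), 0.5)
  Tk <- seq(330, 380, by = 0.5)
  fU <- fraction_unfolded(Tk, 357, 150)
  expect_true(all(diff(fU) > 0))
  expect_true(all(fU >= 0 & fU <= 1))
  # sharp-transition limit
  expect_equal(fraction_unfolded(357.5, 357, 1e6), 1)
  expect_equal(fraction_unfolded(356.5, 357, 1e6), 0)
})

test_that("noiseless melt recovers the generating midpoint to 0.01 K", {
  mc <- sim_melt_curve(Tm = 357.36, dHvH = 150, A_N = -20, B_N = 0.01,
                       A_U = -5, B_U = 0.005, noise_sd = 0, seed = 1)
  f <- fit_two_state_melt(mc)
  expect_true(f$converged)
  expect_lt(abs(f$Tm - 357.36), 0.01)
  expect_equal(f$dHvH, 150, tolerance = 1e-3)
  expect_equal(f$A_N, -20, tolerance = 1e-2)
})

test_that("noisy melt recovers Tm within 3 standard errors", {
  mc <- sim_melt_curve(Tm = 355.20, dHvH = 120, noise_sd = 0.02, seed = 77)
  f <- fit_two_state_melt(mc)
  expect_true(f$converged)
  expect_lt(abs(f$Tm - 355.20), 3 * f$se_Tm)
})

test_that("a pure straight line is flagged as having no transition", {
  line <- data.frame(temperature = seq(336, 367, by = 0.2))
  line$signal <- -20 + 0.01 * line$temperature
  expect_warning(f <- fit_two_state_melt(line), "no transition|grid edge")
  expect_false(f$converged)
})

test_that("the fit is invariant under affine rescaling of the signal", {
  mc <- sim_melt_curve(Tm = 357.36, dHvH = 150, noise_sd = 0.01, seed = 5)
  f1 <- fit_two_state_melt(mc)
  mc2 <- dplyr::mutate(mc, signal = 3.3 * signal + 41)
  f2 <- fit_two_state_melt(mc2)
  expect_equal(f2$Tm, f1$Tm, tolerance = 1e-6)
  expect_equal(f2$dHvH, f1$dHvH, tolerance = 1e-4)
})

test_that("refitting from a recovered curve reproduces the parameters", {
  mc <- sim_melt_curve(Tm = 351.85, dHvH = 130, noise_sd = 0.02, seed = 8)
  f1 <- fit_two_state_melt(mc)
  refit_curve <- data.frame(temperature = f1$data$temperature,
                            signal = predict(f1))
  f2 <- fit_two_state_melt(refit_curve)
  expect_equal(f2$Tm, f1$Tm, tolerance = 1e-4)
  expect_equal(f2$dHvH, f1$dHvH, tolerance = 1e-3)
})

test_that("the optimizer matches a (Tm, dHvH) grid oracle on RSS", {
  mc <- sim_melt_curve(Tm = 357.36, dHvH = 150,
                       grid = seq(336, 367, length.out = 180),
                       noise_sd = 0.02, seed = 31)
  f <- fit_two_state_melt(mc)
  oracle <- melt_grid_min_rss(mc$temperature, mc$signal)
  expect_lte(f$rss, oracle + 1e-12)
})

test_that("Tm shifts against the wild type reproduce the published deltas", {
  ref <- melt_reference()
  fits <- lapply(ref$Tm, function(tm) {
    fit_two_state_melt(sim_melt_curve(Tm = tm, dHvH = 150, noise_sd = 0,
                                      seed = 17))
  })
  names(fits) <- ref$enzyme
  expect_equal(delta_tm(fits$F325Y, fits$WT), -5.51, tolerance = 0.01 / 5.51)
  # the published shift column lists 1.40 for R280K, but the published Tm
  # values themselves differ by 358.80 - 357.36 = 1.44; the arithmetic wins
  expect_equal(delta_tm(fits$R280K, fits$WT), 1.44, tolerance = 0.01 / 1.44)
  expect_equal(delta_tm(fits$Q274N, fits$WT), -2.16, tolerance = 0.01 / 2.16)
  expect_equal(delta_tm(fits$WT, fits$WT), 0, tolerance = 1e-9)

  broken <- fits$WT; broken$converged <- FALSE
  expect_error(delta_tm(broken, fits$WT), "converged")
})

test_that("melt fit accessors return tidy structures", {
  mc <- sim_melt_curve(Tm = 357.36, dHvH = 150, noise_sd = 0, seed = 2)
  f <- fit_two_state_melt(mc)
  td <- tidy(f)
  expect_setequal(td$term, c("Tm", "dHvH", "A_N", "B_N", "A_U", "B_U"))
  expect_true(glance(f)$converged)
  expect_s3_class(autoplot(f), "ggplot")
})
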