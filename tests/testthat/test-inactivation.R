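test_that("an exact exponential decay is fitted exactly", {
  t <- c(0, 60, 120, 240, 480)
  d <- data.frame(time_min = t, residual = exp(-0.0031 * t))
  f <- fit_decay(d)
  expect_equal(f$kd, 0.0031, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_equal(f$t_half * f$kd, log(2))
})

test_that("noisy decays recover kd within 10% and the nls variant agrees", {
  d <- sim_decay_series(kd = 0.02, times = c(0, 10, 25, 40, 60, 80, 100, 120),
                        noise_sd = 0.03, seed = 21)
  f <- fit_decay(d)
  expect_lt(abs(f$kd - 0.02) / 0.02, 0.10)
  f2 <- fit_decay(d, method = "nls")
  expect_lt(abs(f2$kd - f$kd) / f$kd, 0.10)
})

test_that("rising activity is flagged and kept out of thermodynamics", {
  expect_warning(
    f <- fit_decay(data.frame(time_min = c(0, 10, 20),
                              residual = c(1.0, 1.1, 1.2))),
    "nonpositive|percentages")
  expect_false(f$ok)
  expect_true(is.na(f$t_half))
})

test_that("nonpositive residuals are dropped with a warning", {
  d <- data.frame(time_min = c(0, 10, 20, 30, 40),
                  residual = c(1, 0.8, 0, 0.5, 0.4))
  expect_warning(f <- fit_decay(d), "dropped")
  expect_equal(f$n_points, 4)
})

test_that("half-life reproduces the printed column to the minute", {
  ref <- inactivation_reference()
  expect_equal(round(half_life(ref$kd)), ref$t_half)
  expect_equal(half_life(log(2)), 1)
  expect_error(half_life(0), "> 0")
})

test_that("Arrhenius regression reproduces the published activation energies", {
  ref <- inactivation_reference()
  # R280K's printed Ea is not reproducible from its printed kd values
  # (least squares gives ~56 kcal/mol); the other three blocks are.
  for (enz in c("WT", "Q274N", "F325Y")) {
    block <- ref[ref$enzyme == enz, ]
    fit <- arrhenius_fit(block[, c("temperature", "kd")])
    expect_equal(fit$Ea, block$Ea[1], tolerance = 0.1 / block$Ea[1],
                 label = paste(enz, "Ea"))
    expect_gt(fit$r_squared, 0.8)
  }
})

test_that("two exact Arrhenius points are reproduced to machine precision", {
  R <- 1.987e-3; Ea <- 10; lnA <- 5
  Tk <- c(330, 350)
  kd <- exp(lnA - Ea / (R * Tk))
  expect_warning(fit <- arrhenius_fit(data.frame(temperature = Tk, kd = kd)),
                 "only 2")
  expect_equal(fit$Ea, Ea, tolerance = 1e-10)
  expect_equal(fit$lnA, lnA, tolerance = 1e-10)
  expect_error(arrhenius_fit(data.frame(temperature = c(350, 350),
                                        kd = c(0.1, 0.2))), "distinct")
})

test_that("kd generated exactly from (Ea, lnA) round-trips with R^2 = 1", {
  R <- 1.987e-3; Ea <- 49.42; lnA <- 66
  Tk <- c(338, 343, 348, 353)
  kd <- exp(lnA - Ea / (R * Tk))
  fit <- arrhenius_fit(data.frame(temperature = Tk, kd = kd))
  expect_equal(fit$Ea, Ea, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1)
})

test_that("Eyring parameters reproduce every published table cell", {
  ref <- inactivation_reference()
  ey <- eyring_parameters(ref$temperature, ref$kd,
                          rep(unique(ref$Ea), each = 4))
  # published 2-dp energies carry +-0.005 print rounding plus the rounding
  # of the block Ea itself (+-0.005 more); entropies are printed to 3 dp
  expect_equal(ey$dG, ref$dG, tolerance = 0.015 / min(abs(ref$dG)))
  expect_lt(max(abs(ey$dG - ref$dG)), 0.015)
  expect_lt(max(abs(ey$dH - ref$dH)), 0.015)
  expect_lt(max(abs(ey$dS - ref$dS)), 0.0015)
  # spot values, including the sign change for the F325Y entropy
  wt <- eyring_parameters(353, 0.0206, 49.42)
  expect_equal(round(wt$dG, 2), 26.38)
  expect_equal(round(wt$dH, 2), 48.72)
  expect_equal(round(wt$dS, 3), 0.063)
  f325y <- eyring_parameters(353, 0.0079, 25.11)
  expect_equal(round(f325y$dS, 3), -0.007)
  expect_lt(f325y$dS, 0)
})

test_that("Eyring identities hold exactly and dH decreases with temperature", {
  k <- hal_constants()
  ey <- eyring_parameters(c(338, 343, 348, 353), c(0.001, 0.002, 0.004, 0.01),
                          Ea = 40, constants = k)
  expect_equal(ey$dG, ey$dH - ey$temperature * ey$dS)
  expect_equal(ey$dH, 40 - k$R_kcal * ey$temperature)
  expect_true(all(diff(ey$dH) < 0))
  expect_error(eyring_parameters(353, -0.1, 40), "kd")
})

test_that("a noiseless campaign reproduces the wild-type table block", {
  ref <- inactivation_reference()
  wt <- ref[ref$enzyme == "WT", ]
  camp <- sim_arrhenius_campaign(Ea = 49.42, anchor = c(353, 0.0206),
                                 temperatures = c(353, 348, 343, 338),
                                 noise_sd = 0, seed = 1, enzyme = "WT")
  tab <- build_inactivation_table(camp)
  expect_equal(tab$Ea, rep(49.42, 4), tolerance = 1e-6)
  expect_equal(tab$kd[tab$temperature == 353], 0.0206, tolerance = 1e-6)
  # anchored row matches the published cells at print precision
  row353 <- tab[tab$temperature == 353, ]
  expect_equal(round(row353$t_half), 34)
  expect_equal(round(row353$dG, 2), 26.38)
  expect_equal(round(row353$dH, 2), 48.72)
  expect_equal(round(row353$dS, 3), 0.063)
  # identities hold across the whole table
  expect_equal(tab$t_half * tab$kd, rep(log(2), 4))
})

test_that("campaign analysis rejects a single temperature and drops dead series", {
  single <- sim_arrhenius_campaign(Ea = 40, anchor = c(353, 0.02),
                                   temperatures = 353, noise_sd = 0, seed = 2)
  expect_error(build_inactivation_table(single), "fewer than 2")

  camp <- sim_arrhenius_campaign(Ea = 40, anchor = c(353, 0.02),
                                 temperatures = c(353, 348, 343),
                                 noise_sd = 0, seed = 3)
  # sabotage one temperature: activity rising instead of decaying
  bad <- camp$temperature_K == 343
  camp$residual[bad] <- rev(sort(camp$residual[bad])) + c(0, 1e-4) # non-decay
  camp$residual[bad] <- seq(1, 1.4, length.out = sum(bad))
  w <- testthat::capture_warnings(tab <- build_inactivation_table(camp))
  expect_true(any(grepl("dropping", w)))
  expect_equal(sort(unique(tab$temperature)), c(348, 353))
  expect_equal(unique(tab$Ea), 40, tolerance = 1e-6)
})

test_that("Celsius input and the legacy integer-kelvin mode are honoured", {
  camp <- sim_arrhenius_campaign(Ea = 49.42, anchor = c(338, 0.0007),
                                 temperatures = c(353, 348, 343, 338),
                                 noise_sd = 0, seed = 4)
  camp_c <- dplyr::mutate(camp, temperature_C = temperature_K - 273,
                          temperature_K = NULL)
  tab <- build_inactivation_table(camp_c, legacy_kelvin = TRUE)
  expect_equal(sort(unique(tab$temperature)), c(338, 343, 348, 353))
  expect_equal(unique(round(tab$Ea, 2)), 49.42)
})

test_that("for fixed Ea, kd rises and half-life falls with temperature", {
  R <- 1.987e-3
  Tk <- seq(330, 360, by = 5)
  kd <- exp(60 - 45 / (R * Tk))
  expect_true(all(diff(kd) > 0))
  expect_true(all(diff(half_life(kd)) < 0))
})
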