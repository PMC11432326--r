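#' Fit a first-order thermal-inactivation decay
#'
#' Residual activity after heat preincubation is modelled as
#' `A(t)/A0 = exp(-kd * t)`. The fit is ordinary least squares of
#' `ln(residual)` on time with a free intercept, so a normalisation error at
#' t = 0 does not bias the rate constant; `kd` is minus the slope and the
#' half-life is `ln 2 / kd`. A direct nonlinear exponential fit is available
#' behind `method = "nls"` for comparison.
#'
#' Non-positive residuals cannot enter the log fit and are dropped with a
#' warning. Residuals above 1.5 are taken to be percentages and divided by
#' 100 (with a warning).
#'
#' @param data Data frame with columns `time_min` and `residual`
#'   (fraction of unincubated activity); at least 3 usable points.
#' @param temperature Optional preincubation temperature (K), carried into
#'   the result for downstream Arrhenius analysis.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return Object of class `"decay_fit"` with fields `kd` (min^-1),
#'   `t_half` (min), `r_squared`, `n_points`, `temperature`, `ok` (FALSE
#'   when the estimated kd is nonpositive, i.e. no decay).
#' @examples
#' d <- sim_decay_series(kd = 0.0206, times = c(0, 15, 30, 60),
#'                       noise_sd = 0, seed = 1)
#' fit_decay(d)
#' @export
fit_decay <- function(data, temperature = NA_real_,
                      method = c("loglinear", "nls")) {
  stopifnot(is.data.frame(data))
  method <- match.arg(method)
  .require_cols(data, c("time_min", "residual"), "decay series")
  if (any(data$time_min < 0)) stop("times must be nonnegative", call. = FALSE)
  data$residual <- .normalize_residual(data$residual)
  usable <- data$residual > 0
  if (any(!usable)) {
    warning(sum(!usable), " nonpositive residual(s) dropped from log fit",
            call. = FALSE)
  }
  d <- data[usable, , drop = FALSE]
  if (nrow(d) < 3L) stop("need >= 3 points with residual > 0", call. = FALSE)

  if (method == "loglinear") {
    fit <- stats::lm(log(residual) ~ time_min, data = d)
    kd <- -unname(stats::coef(fit)[2])
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    fit <- minpack.lm::nlsLM(residual ~ A0 * exp(-kd * time_min), data = d,
                             start = list(A0 = max(d$residual), kd = 0.01))
    kd <- unname(stats::coef(fit)[["kd"]])
    r2 <- 1 - sum(stats::resid(fit)^2) /
      sum((d$residual - mean(d$residual))^2)
  }

  ok <- is.finite(kd) && kd > 0
  if (!ok) {
    warning("estimated kd is nonpositive (activity not decaying); ",
            "no thermodynamics can be derived from this series", call. = FALSE)
  }
  structure(
    list(kd = kd, t_half = if (ok) log(2) / kd else NA_real_,
         r_squared = r2, n_points = nrow(d),
         temperature = temperature, ok = ok, method = method, fit = fit,
         data = tibble::as_tibble(d)),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("First-order inactivation fit (%d points%s): kd = %.4g min^-1, t1/2 = %.4g min, R^2 = %.4f\n",
              x$n_points,
              if (is.finite(x$temperature)) sprintf(", %g K", x$temperature) else "",
              x$kd, x$t_half, x$r_squared))
  if (!x$ok) cat("  WARNING: kd <= 0, series unusable downstream\n")
  invisible(x)
}

#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("kd", "t_half"),
                 estimate = c(x$kd, x$t_half))
}

#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_points = x$n_points,
                 temperature = x$temperature, ok = x$ok)
}

#' Half-life from a first-order rate constant
#'
#' @param kd First-order inactivation rate constant, min^-1 (vectorised).
#' @return `ln 2 / kd`, min.
#' @examples
#' half_life(0.0206)  # about 34 min
#' @export
half_life <- function(kd) {
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  log(2) / kd
}

#' Arrhenius regression of inactivation rate constants
#'
#' Ordinary least squares of `ln(kd)` on `1/T`. The activation energy for
#' deactivation is `Ea = -slope * R` and `lnA` is the intercept
#' (A in min^-1 when kd is in min^-1). All supplied temperatures enter the
#' regression unweighted; no outlier rejection is performed.
#'
#' @param data Data frame with columns `temperature` (K) and `kd` (min^-1);
#'   at least 2 distinct temperatures (a 2-point fit is exact and triggers a
#'   warning since no residual information remains).
#' @param constants A [hal_constants()] bundle (supplies R).
#' @return Object of class `"arrhenius_fit"` with `Ea` (kcal mol^-1),
#'   `se_Ea`, `lnA`, `r_squared`, `n_temperatures`.
#' @examples
#' wt <- tibble::tibble(temperature = c(353, 348, 343, 338),
#'                      kd = c(0.0206, 0.0031, 0.0023, 0.0007))
#' arrhenius_fit(wt)
#' @export
arrhenius_fit <- function(data, constants = hal_constants()) {
  stopifnot(is.data.frame(data), inherits(constants, "hal_constants"))
  .require_cols(data, c("temperature", "kd"), "Arrhenius input")
  if (anyDuplicated(data$temperature)) {
    stop("temperatures must be distinct", call. = FALSE)
  }
  if (nrow(data) < 2L) stop("need >= 2 temperatures", call. = FALSE)
  if (any(data$kd <= 0) || any(data$temperature <= 0)) {
    stop("kd and temperature must be > 0", call. = FALSE)
  }
  if (nrow(data) == 2L) {
    warning("only 2 temperatures: Arrhenius line is exact, no fit diagnostics",
            call. = FALSE)
  }
  fit <- stats::lm(log(kd) ~ I(1 / temperature), data = data)
  slope <- unname(stats::coef(fit)[2])
  se_slope <- if (nrow(data) > 2L) {
    suppressWarnings(summary(fit)$coefficients[2, "Std. Error"])
  } else NA_real_
  structure(
    list(Ea = -slope * constants$R_kcal,
         se_Ea = se_slope * constants$R_kcal,
         lnA = unname(stats::coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         n_temperatures = nrow(data), fit = fit,
         data = tibble::as_tibble(data), constants = constants),
    class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit (%d temperatures): Ea = %.2f kcal mol^-1 (SE %.2g), lnA = %.3f, R^2 = %.4f\n",
              x$n_temperatures, x$Ea, x$se_Ea, x$lnA, x$r_squared))
  invisible(x)
}

#' @method tidy arrhenius_fit
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble::tibble(term = c("Ea", "lnA"),
                 estimate = c(x$Ea, x$lnA),
                 std.error = c(x$se_Ea, NA_real_))
}

#' @method glance arrhenius_fit
#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_temperatures = x$n_temperatures)
}

#' Plot an Arrhenius regression
#'
#' @param object An `"arrhenius_fit"` object.
#' @param ... Unused.
#' @return A ggplot of ln(kd) against 1000/T with the fitted line.
#' @method autoplot arrhenius_fit
#' @export
autoplot.arrhenius_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = 1000 / .data$temperature,
                                  y = log(.data$kd))) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "1000 / T (K^-1)", y = "ln kd",
                  title = sprintf("Ea = %.2f kcal mol^-1", object$Ea)) +
    ggplot2::theme_minimal()
}

#' Eyring transition-state thermodynamics of inactivation
#'
#' From a first-order rate constant at one temperature and the Arrhenius
#' activation energy of the process, computes the activation free energy,
#' enthalpy and entropy of the transition state:
#' \deqn{\Delta G^* = -R T \ln\left(\frac{k_d h}{\kappa k_B T}\right), \quad
#'       \Delta H^* = E_a - R T, \quad
#'       \Delta S^* = \frac{\Delta H^* - \Delta G^*}{T}}
#' with `kd` converted from min^-1 to s^-1 before entering the Eyring
#' expression and all energies in kcal mol^-1.
#'
#' @param temperature Absolute temperature, K (vectorised).
#' @param kd Inactivation rate constant, min^-1 (vectorised).
#' @param Ea Arrhenius activation energy, kcal mol^-1.
#' @param constants A [hal_constants()] bundle.
#' @return Tibble with columns `temperature`, `kd`, `t_half`, `dG`, `dH`,
#'   `dS` (kcal-based units; `dS` in kcal K^-1 mol^-1).
#' @examples
#' eyring_parameters(353, 0.0206, Ea = 49.42)
#' @export
eyring_parameters <- function(temperature, kd, Ea,
                              constants = hal_constants()) {
  stopifnot(inherits(constants, "hal_constants"))
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  if (any(temperature <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  kd_s <- kd / 60
  dG <- -constants$R_kcal * temperature *
    log(kd_s * constants$h / (constants$kappa * constants$kB * temperature))
  dH <- Ea - constants$R_kcal * temperature
  dS <- (dH - dG) / temperature
  tibble::tibble(temperature = temperature, kd = kd, t_half = log(2) / kd,
                 dG = dG, dH = dH, dS = dS)
}

#' Full thermal-inactivation analysis across temperatures
#'
#' Chains the whole inactivation pipeline for one or several enzymes: each
#' residual-activity time course is fitted for its first-order rate
#' constant, the rate constants are regressed on inverse temperature for a
#' single activation energy per enzyme, and each temperature then receives
#' its Eyring activation thermodynamics.
#'
#' Series whose fitted kd is nonpositive (no decay) are dropped from the
#' Arrhenius stage with a warning; the enzyme's Ea is estimated from the
#' remaining temperatures.
#'
#' @param data Tidy data frame of decay measurements with columns
#'   `time_min`, `residual`, a temperature column (`temperature_K`, or
#'   `temperature_C` which is converted), and optionally `enzyme`
#'   (one block per enzyme).
#' @param constants A [hal_constants()] bundle.
#' @param legacy_kelvin Convert Celsius with the integer offset 273 instead
#'   of 273.15 (matches tables typeset with integer kelvins).
#' @return A tibble of class `"inactivation_table"`, one row per enzyme and
#'   temperature, with columns `enzyme`, `temperature`, `t_half`, `kd`,
#'   `r_squared`, `Ea`, `dG`, `dH`, `dS`. The per-enzyme
#'   `"arrhenius_fit"` objects are attached as attribute `"arrhenius"`.
#' @examples
#' camp <- sim_arrhenius_campaign(Ea = 49.42, anchor = c(353, 0.0206),
#'                                noise_sd = 0, seed = 1)
#' build_inactivation_table(camp)
#' @export
build_inactivation_table <- function(data, constants = hal_constants(),
                                     legacy_kelvin = FALSE) {
  stopifnot(is.data.frame(data))
  .require_cols(data, c("time_min", "residual"), "decay campaign")
  if (!"temperature_K" %in% names(data)) {
    .require_cols(data, "temperature_C", "decay campaign")
    data$temperature_K <- celsius_to_kelvin(data$temperature_C,
                                            legacy = legacy_kelvin)
  }
  if (!"enzyme" %in% names(data)) data$enzyme <- "enzyme"

  per_series <- data |>
    dplyr::group_by(.data$enzyme, .data$temperature_K) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(fit = purrr::map2(.data$data, .data$temperature_K,
                                    \(d, tk) fit_decay(d, temperature = tk)))

  rows <- per_series |>
    dplyr::mutate(
      kd = purrr::map_dbl(.data$fit, "kd"),
      r_squared = purrr::map_dbl(.data$fit, "r_squared"),
      ok = purrr::map_lgl(.data$fit, "ok"))

  bad <- !rows$ok
  if (any(bad)) {
    warning("dropping ", sum(bad), " series with nonpositive kd (",
            paste(sprintf("%s @ %g K", rows$enzyme[bad],
                          rows$temperature_K[bad]), collapse = "; "),
            ")", call. = FALSE)
    rows <- rows[!bad, , drop = FALSE]
  }

  n_temp <- table(rows$enzyme)
  if (any(n_temp < 2)) {
    stop("enzyme(s) with fewer than 2 usable temperatures: ",
         paste(names(n_temp)[n_temp < 2], collapse = ", "), call. = FALSE)
  }

  arr_fits <- rows |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::summarise(arr = list(arrhenius_fit(
      data.frame(temperature = temperature_K, kd = kd),
      constants = constants)), .groups = "drop")

  out <- rows |>
    dplyr::left_join(arr_fits, by = "enzyme") |>
    dplyr::mutate(Ea = purrr::map_dbl(.data$arr, "Ea")) |>
    dplyr::rowwise() |>
    dplyr::mutate(eyr = list(eyring_parameters(.data$temperature_K, .data$kd,
                                               .data$Ea, constants))) |>
    dplyr::ungroup() |>
    tidyr::unnest_wider("eyr", names_sep = ".") |>
    dplyr::transmute(
      enzyme = .data$enzyme,
      temperature = .data$temperature_K,
      t_half = .data$eyr.t_half,
      kd = .data$kd,
      r_squared = .data$r_squared,
      Ea = .data$Ea,
      dG = .data$eyr.dG, dH = .data$eyr.dH, dS = .data$eyr.dS) |>
    dplyr::arrange(.data$enzyme, dplyr::desc(.data$temperature))

  attr(out, "arrhenius") <- stats::setNames(arr_fits$arr, arr_fits$enzyme)
  class(out) <- c("inactivation_table", class(out))
  out
}
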