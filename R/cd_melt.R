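#' Average repeated CD scans and subtract a blank
#'
#' Far-UV spectra are routinely recorded as several scans over the same
#' wavelength grid and corrected by subtracting the buffer baseline. This
#' averages the scans pointwise and subtracts the blank.
#'
#' @param scans Data frame with columns `wavelength_nm`, `signal`,
#'   `scan_id`; every scan must share the same wavelength grid.
#' @param blank Optional data frame with columns `wavelength_nm`, `signal`
#'   on the same grid (omit for no blank correction).
#' @return Tibble with columns `wavelength_nm`, `signal` (mean minus
#'   blank), `n_scans`.
#' @export
preprocess_spectrum <- function(scans, blank = NULL) {
  stopifnot(is.data.frame(scans))
  .require_cols(scans, c("wavelength_nm", "signal", "scan_id"), "CD scans")
  grids <- scans |>
    dplyr::group_by(.data$scan_id) |>
    dplyr::summarise(g = list(sort(.data$wavelength_nm)), .groups = "drop")
  ref <- grids$g[[1]]
  same <- purrr::map_lgl(grids$g, \(g) length(g) == length(ref) &&
                           all(g == ref))
  if (!all(same)) stop("scans do not share a wavelength grid", call. = FALSE)

  avg <- scans |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::summarise(signal = mean(.data$signal),
                     n_scans = dplyr::n(), .groups = "drop")
  if (!is.null(blank)) {
    .require_cols(blank, c("wavelength_nm", "signal"), "blank trace")
    blank <- dplyr::arrange(blank, .data$wavelength_nm)
    if (nrow(blank) != nrow(avg) ||
        !all(blank$wavelength_nm == avg$wavelength_nm)) {
      stop("blank trace is not on the scan wavelength grid", call. = FALSE)
    }
    avg$signal <- avg$signal - blank$signal
  }
  avg
}

#' Two-state thermal-denaturation signal
#'
#' Predicted observable for a protein unfolding between a native state N and
#' an unfolded state U, each with a linear temperature baseline
#' `S_N = A_N + B_N T` and `S_U = A_U + B_U T`, linked by the van't Hoff
#' equilibrium
#' \deqn{K_{eq}(T) = \exp\left[-\frac{\Delta H_{vH}}{R}
#'   \left(\frac{1}{T}-\frac{1}{T_m}\right)\right]}
#' so that the observed signal is
#' `(S_N + S_U * K_eq) / (1 + K_eq)`. At `T = Tm` exactly half the protein
#' is unfolded and the signal is the baseline midpoint.
#'
#' @param temperature Temperature, K (vectorised).
#' @param Tm Transition midpoint, K.
#' @param dHvH Apparent van't Hoff enthalpy, kcal mol^-1.
#' @param A_N,B_N Native baseline intercept (signal units) and slope
#'   (signal K^-1).
#' @param A_U,B_U Unfolded baseline intercept and slope.
#' @param constants A [hal_constants()] bundle (supplies R).
#' @return Predicted signal, same units as the baselines.
#' @export
two_state_signal <- function(temperature, Tm, dHvH, A_N, B_N, A_U, B_U,
                             constants = hal_constants()) {
  if (any(temperature <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  fU <- fraction_unfolded(temperature, Tm, dHvH, constants)
  sN <- A_N + B_N * temperature
  sU <- A_U + B_U * temperature
  sN * (1 - fU) + sU * fU
}

#' Fraction of unfolded protein in the two-state model
#'
#' `K_eq / (1 + K_eq)` with the van't Hoff equilibrium constant of
#' [two_state_signal()]. Strictly increasing in temperature for positive
#' `dHvH` and exactly 0.5 at `Tm`. The exponent is computed on the log
#' scale, so extreme enthalpies or temperatures saturate to 0/1 instead of
#' overflowing.
#'
#' @inheritParams two_state_signal
#' @return Fraction unfolded in `[0, 1]`.
#' @examples
#' fraction_unfolded(357.36, Tm = 357.36, dHvH = 150)  # 0.5
#' @export
fraction_unfolded <- function(temperature, Tm, dHvH,
                              constants = hal_constants()) {
  if (any(temperature <= 0) || Tm <= 0) {
    stop("temperatures must be > 0 K", call. = FALSE)
  }
  lnK <- -(dHvH / constants$R_kcal) * (1 / temperature - 1 / Tm)
  stats::plogis(lnK)  # K/(1+K), overflow-safe
}

#' Fit the two-state model to a CD melt curve
#'
#' Six-parameter nonlinear least squares of the two-state denaturation
#' signal (transition midpoint, van't Hoff enthalpy, and two linear
#' baselines) to an ellipticity-vs-temperature trace. The fit is performed
#' on the signal as supplied -- the model is invariant under affine
#' rescaling of the signal, so fitting in mdeg or mean-residue ellipticity
#' yields the same midpoint and enthalpy.
#'
#' Initialisation: the midpoint starts at the extremum of the
#' central-difference derivative of signal versus temperature, the enthalpy
#' at 100 kcal/mol, and the baselines from straight-line fits to the first
#' and last 10% of points. The enthalpy is log-parameterised during
#' optimisation, which keeps it positive (a cooperative unfolding
#' transition). When the derivative extremum falls on the edge of the grid
#' there is no transition inside the window and the fit is flagged instead
#' of returned as converged.
#'
#' Because thermal unfolding of these proteins is irreversible (aggregation
#' upon heating), the midpoint and enthalpy are apparent quantities --
#' `Tm(app)` and `dHvH(app)` -- and no equilibrium unfolding free energy is
#' derived from them.
#'
#' @param data Data frame with columns `temperature` (K, or
#'   `temperature_C`) and `signal` (ellipticity at 222 nm, any linear
#'   units); at least 20 points spanning both baselines and the transition.
#' @param window Temperature window (K) actually fitted; points outside are
#'   excluded with a message. Default 335.15-368.15 K (62-95 C, the span
#'   over which these melts are analysed). Use `NULL` to fit everything.
#' @param constants A [hal_constants()] bundle.
#' @return Object of class `"two_state_fit"` with fields `Tm`, `dHvH`,
#'   `A_N`, `B_N`, `A_U`, `B_U`, `se_Tm`, `rss`, `n_points`, `converged`.
#' @examples
#' mc <- sim_melt_curve(Tm = 357.36, dHvH = 150, noise_sd = 0, seed = 1)
#' fit_two_state_melt(mc)
#' @export
fit_two_state_melt <- function(data, window = c(335.15, 368.15),
                               constants = hal_constants()) {
  stopifnot(is.data.frame(data))
  if (!"temperature" %in% names(data)) {
    .require_cols(data, "temperature_C", "melt curve")
    data$temperature <- celsius_to_kelvin(data$temperature_C)
  }
  .require_cols(data, c("temperature", "signal"), "melt curve")
  data <- dplyr::arrange(tibble::as_tibble(data), .data$temperature)
  if (!is.null(window)) {
    keep <- data$temperature >= window[1] & data$temperature <= window[2]
    if (any(!keep)) {
      message(sum(!keep), " point(s) outside the fitting window [",
              window[1], ", ", window[2], "] K excluded")
      data <- data[keep, , drop = FALSE]
    }
  }
  if (nrow(data) < 20L) stop("need >= 20 points in the window", call. = FALSE)

  Tv <- data$temperature
  Sv <- data$signal

  # Tm start: extremum of the central-difference derivative. The signal is
  # median-smoothed and differenced over a few grid steps first, otherwise
  # point-to-point noise on a dense grid swamps the transition slope.
  n <- length(Sv)
  k_med <- min(7L, if (n %% 2L == 1L) n else n - 1L)
  sm <- stats::runmed(Sv, k = k_med)
  gap <- max(1L, min(5L, n - 2L))
  idx <- seq_len(n - gap)
  dS <- (sm[idx + gap] - sm[idx]) / (Tv[idx + gap] - Tv[idx])
  Tmid <- (Tv[idx + gap] + Tv[idx]) / 2
  imax <- which.max(abs(dS))
  tm0 <- Tmid[imax]
  edge <- imax <= 2L || imax >= length(dS) - 1L

  n_base <- max(3L, ceiling(0.1 * length(Tv)))
  head_fit <- stats::lm(Sv[seq_len(n_base)] ~ Tv[seq_len(n_base)])
  tail_idx <- seq(length(Tv) - n_base + 1L, length(Tv))
  tail_fit <- stats::lm(Sv[tail_idx] ~ Tv[tail_idx])
  start <- list(Tm = tm0, ldH = log(100),
                A_N = unname(stats::coef(head_fit)[1]),
                B_N = unname(stats::coef(head_fit)[2]),
                A_U = unname(stats::coef(tail_fit)[1]),
                B_U = unname(stats::coef(tail_fit)[2]))

  failed <- function(msg) {
    structure(list(Tm = NA_real_, dHvH = NA_real_, A_N = NA_real_,
                   B_N = NA_real_, A_U = NA_real_, B_U = NA_real_,
                   se_Tm = NA_real_, rss = NA_real_, n_points = nrow(data),
                   converged = FALSE, message = msg,
                   data = data, fit = NULL, constants = constants),
              class = "two_state_fit")
  }
  if (edge) {
    warning("transition midpoint initialises at the grid edge; ",
            "no transition inside the fitted window", call. = FALSE)
    return(failed("no transition in window"))
  }

  d <- tibble::tibble(temperature = Tv, signal = Sv)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ two_state_signal(temperature, Tm, exp(ldH), A_N, B_N, A_U,
                                B_U, constants),
      data = d, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))

  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) rep(NA_real_, length(cf)) |>
                   stats::setNames(names(cf)))
  Tm <- cf[["Tm"]]
  converged <- isTRUE(fit$convInfo$isConv) &&
    Tm >= min(Tv) && Tm <= max(Tv)
  structure(
    list(Tm = Tm, dHvH = exp(cf[["ldH"]]),
         A_N = cf[["A_N"]], B_N = cf[["B_N"]],
         A_U = cf[["A_U"]], B_U = cf[["B_U"]],
         se_Tm = unname(se["Tm"]), rss = sum(stats::resid(fit)^2),
         n_points = nrow(data), converged = converged, message = NULL,
         data = d, fit = fit, constants = constants),
    class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Two-state melt fit: NOT CONVERGED",
        if (!is.null(x$message)) paste0(" (", x$message, ")"), "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Two-state melt fit (%d points):\n", x$n_points))
  cat(sprintf("  Tm(app)   = %.2f K (SE %.3g)\n", x$Tm, x$se_Tm))
  cat(sprintf("  dHvH(app) = %.1f kcal mol^-1\n", x$dHvH))
  cat(sprintf("  baselines: N %.3g %+.3g*T ; U %.3g %+.3g*T\n",
              x$A_N, x$B_N, x$A_U, x$B_U))
  invisible(x)
}

#' @method tidy two_state_fit
#' @export
tidy.two_state_fit <- function(x, ...) {
  tibble::tibble(
    term = c("Tm", "dHvH", "A_N", "B_N", "A_U", "B_U"),
    estimate = c(x$Tm, x$dHvH, x$A_N, x$B_N, x$A_U, x$B_U),
    std.error = c(x$se_Tm, rep(NA_real_, 5)))
}

#' @method glance two_state_fit
#' @export
glance.two_state_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_points = x$n_points, converged = x$converged)
}

#' @export
predict.two_state_fit <- function(object, temperature = NULL, ...) {
  if (is.null(temperature)) temperature <- object$data$temperature
  two_state_signal(temperature, object$Tm, object$dHvH, object$A_N,
                   object$B_N, object$A_U, object$B_U, object$constants)
}

#' Plot a two-state melt fit
#'
#' @param object A `"two_state_fit"` object.
#' @param ... Unused.
#' @return A ggplot of the trace, the fitted curve and the midpoint.
#' @method autoplot two_state_fit
#' @export
autoplot.two_state_fit <- function(object, ...) {
  grid <- tibble::tibble(
    temperature = seq(min(object$data$temperature),
                      max(object$data$temperature), length.out = 400))
  grid$signal <- predict(object, grid$temperature)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$temperature, y = .data$signal)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$Tm, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Temperature (K)", y = "Ellipticity at 222 nm",
                  title = sprintf("Tm(app) = %.2f K", object$Tm)) +
    ggplot2::theme_minimal()
}

#' Melting-temperature shift between variant and reference
#'
#' @param variant,reference Converged `"two_state_fit"` objects.
#' @return `variant$Tm - reference$Tm`, K.
#' @export
delta_tm <- function(variant, reference) {
  stopifnot(inherits(variant, "two_state_fit"),
            inherits(reference, "two_state_fit"))
  if (!variant$converged || !reference$converged) {
    stop("delta_tm requires converged fits", call. = FALSE)
  }
  variant$Tm - reference$Tm
}
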