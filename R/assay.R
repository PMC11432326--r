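#' Convert an absorbance slope into a molar rate
#'
#' Beer-Lambert conversion of product appearance: an absorbance change per
#' minute observed in a cuvette of path length `pathlength` corresponds to a
#' molar concentration change `dA_per_min / (eps * pathlength)`, which times
#' the reaction volume gives moles of product per minute.
#'
#' @param dA_per_min Absorbance change, AU min^-1 (vectorised).
#' @param eps Molar extinction coefficient of the product, M^-1 cm^-1.
#'   Defaults to the trans-urocanic acid value at 280 nm.
#' @param pathlength Optical path length, cm.
#' @param volume Reaction volume, L.
#' @return Rate in mol min^-1.
#' @examples
#' # 1 uM min^-1 in 500 uL:
#' absorbance_to_rate(0.0188, volume = 5e-4)
#' @export
absorbance_to_rate <- function(dA_per_min, eps = 18800, pathlength = 1,
                               volume = 5e-4) {
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (!is.numeric(pathlength) || pathlength <= 0) {
    stop("pathlength must be > 0", call. = FALSE)
  }
  if (!is.numeric(volume) || volume <= 0) stop("volume must be > 0", call. = FALSE)
  dA_per_min / (eps * pathlength) * volume
}

#' Locate the optimum of an activity profile
#'
#' Returns the condition (pH, temperature, ...) at which the measured rate
#' is maximal, together with the plateau: the contiguous range of conditions
#' whose rate is within a given fraction of the maximum. No smoothing is
#' applied -- the argmax is reported at the resolution of the assay grid.
#' Ties are broken toward the lower condition value.
#'
#' @param data Data frame with columns `condition` and `rate`
#'   (rate in nmol min^-1 or any common unit; the result is scale-invariant).
#' @param plateau_frac Rates above `plateau_frac * max(rate)` count as part
#'   of the plateau (default 0.95).
#' @return A one-row tibble: `optimum`, `max_rate`, `plateau_lo`, `plateau_hi`.
#' @examples
#' prof <- tibble::tibble(condition = c(75, 80, 85, 90),
#'                        rate = c(80, 95, 100, 70))
#' profile_optimum(prof)
#' @export
profile_optimum <- function(data, plateau_frac = 0.95) {
  stopifnot(is.data.frame(data))
  .require_cols(data, c("condition", "rate"), "activity profile")
  if (nrow(data) < 2L) stop("need at least 2 profile points", call. = FALSE)
  if (anyDuplicated(data$condition)) {
    stop("conditions must be distinct", call. = FALSE)
  }
  if (any(data$rate < 0)) stop("rates must be nonnegative", call. = FALSE)
  data <- dplyr::arrange(data, .data$condition)
  mx <- max(data$rate)
  opt <- data$condition[which.max(data$rate)]  # which.max: first = lowest
  plateau <- data$condition[data$rate >= plateau_frac * mx]
  tibble::tibble(optimum = opt, max_rate = mx,
                 plateau_lo = min(plateau), plateau_hi = max(plateau))
}

#' Classify substrates as active or inactive
#'
#' Applies a limit-of-detection rule: a substrate is called active when its
#' rate strictly exceeds `k` standard deviations of the blank. The audit
#' trail for each call is kept in `threshold_used`.
#'
#' @param data Data frame with columns `substrate` and `rate` (nmol min^-1).
#' @param blank_sd Standard deviation of blank (no-substrate) rates.
#' @param k Detection multiplier (default 3, the conventional LOD rule).
#' @return Tibble sorted by rate descending with columns `substrate`,
#'   `rate`, `active`, `threshold_used`.
#' @examples
#' screen_substrates(
#'   tibble::tibble(substrate = c("L-histidine", "L-histidinamide"),
#'                  rate = c(20.4, 0)),
#'   blank_sd = 0.2)
#' @export
screen_substrates <- function(data, blank_sd, k = 3) {
  stopifnot(is.data.frame(data))
  .require_cols(data, c("substrate", "rate"), "substrate screen")
  if (blank_sd < 0) stop("blank_sd must be >= 0", call. = FALSE)
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  if (any(data$rate < 0)) stop("rates must be nonnegative", call. = FALSE)
  thr <- k * blank_sd
  data |>
    dplyr::mutate(active = .data$rate > thr, threshold_used = thr) |>
    dplyr::arrange(dplyr::desc(.data$rate)) |>
    tibble::as_tibble()
}

#' Calibrate a size-exclusion column
#'
#' Globular proteins elute from a size-exclusion column at retention times
#' that decrease linearly with the logarithm of molecular mass. This fits
#' ordinary least squares of log10(mass) on retention time to a set of
#' standards, the direction used for read-off of unknowns.
#'
#' @param markers Data frame with columns `rt_min` (retention time, min) and
#'   `mass_kda` (molecular mass, kDa); at least 3 markers with distinct
#'   retention times.
#' @return An object of class `"sec_calibration"`: list with `slope`,
#'   `intercept`, `r_squared`, `rt_range`, `n_markers`, `markers` and the
#'   underlying `lm` fit.
#' @examples
#' mk <- tibble::tibble(rt_min = c(20, 25, 30), mass_kda = 10^(6 - 0.1 * c(20, 25, 30)))
#' fit_sec_calibration(mk)
#' @export
fit_sec_calibration <- function(markers) {
  stopifnot(is.data.frame(markers))
  .require_cols(markers, c("rt_min", "mass_kda"), "SEC markers")
  if (nrow(markers) < 3L) stop("need at least 3 SEC markers", call. = FALSE)
  if (length(unique(markers$rt_min)) < 3L) {
    stop("SEC marker retention times must be distinct", call. = FALSE)
  }
  if (any(markers$mass_kda <= 0)) stop("marker masses must be > 0", call. = FALSE)
  fit <- stats::lm(log10(mass_kda) ~ rt_min, data = markers)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    warning("SEC calibration slope is nonnegative; larger proteins should elute earlier",
            call. = FALSE)
  }
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         rt_range = range(markers$rt_min),
         n_markers = nrow(markers),
         markers = tibble::as_tibble(markers),
         fit = fit),
    class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf("SEC calibration (%d markers): log10(Mm/kDa) = %.4f %+.4f * Rt,  R^2 = %.4f\n",
              x$n_markers, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @method tidy sec_calibration
#' @export
tidy.sec_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = summary(x$fit)$coefficients[, "Std. Error"])
}

#' @method glance sec_calibration
#' @export
glance.sec_calibration <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_markers = x$n_markers,
                 rt_min = x$rt_range[1], rt_max = x$rt_range[2])
}

#' Estimate a native molecular mass from a retention time
#'
#' Inverts a SEC calibration: mass = 10^(intercept + slope * rt). Retention
#' times more than 20% outside the calibrated range trigger an
#' extrapolation warning but still return a value.
#'
#' @param cal A `"sec_calibration"` object.
#' @param rt Retention time, min (vectorised).
#' @return Estimated molecular mass, kDa.
#' @export
estimate_native_mass <- function(cal, rt) {
  stopifnot(inherits(cal, "sec_calibration"))
  span <- diff(cal$rt_range)
  lo <- cal$rt_range[1] - 0.2 * span
  hi <- cal$rt_range[2] + 0.2 * span
  if (any(rt < lo | rt > hi)) {
    warning("retention time outside calibrated range; extrapolating",
            call. = FALSE)
  }
  10^(cal$intercept + cal$slope * rt)
}

#' Infer the oligomeric state from native and monomer masses
#'
#' @param native_mass Native (e.g. SEC-derived) mass, kDa.
#' @param monomer_mass Monomer (sequence or SDS-PAGE) mass, kDa.
#' @return One-row tibble with the raw mass `ratio` and the rounded integer
#'   `subunits`.
#' @examples
#' oligomeric_state(220, 54.7)  # tetramer
#' @export
oligomeric_state <- function(native_mass, monomer_mass) {
  if (native_mass <= 0 || monomer_mass <= 0) {
    stop("masses must be > 0", call. = FALSE)
  }
  ratio <- native_mass / monomer_mass
  tibble::tibble(ratio = ratio, subunits = as.integer(round(ratio)))
}

.require_cols <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(data)
}
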