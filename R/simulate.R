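#' Simulate a Michaelis-Menten initial-rate dataset
#'
#' Draws velocities on a substrate grid from the hyperbola
#' `v = Vmax S / (Km + S)` plus noise. Multiplicative gaussian noise is the
#' default (assay error scales with signal in absorbance-based rate
#' measurements); additive noise (scaled by Vmax) is available. Negative
#' draws are clipped to zero and counted in the `clipped` attribute.
#'
#' @param Km True Michaelis constant, mM.
#' @param Vmax True maximal velocity, mol min^-1.
#' @param S Substrate grid, mM. Defaults to a 12-point geometric ladder
#'   over 0.25-50 mM, the span typical of these assays.
#' @param noise_sd Relative noise SD (fraction of signal for multiplicative
#'   noise, fraction of Vmax for additive).
#' @param noise_model `"multiplicative"` or `"additive"`.
#' @param seed Integer seed; mandatory so every dataset is reproducible.
#' @return Tibble with columns `S`, `v`; attribute `truth` holds the
#'   generating parameters, `clipped` the number of clipped draws.
#' @examples
#' sim_mm_dataset(Km = 4.83, Vmax = 4.243e-7, noise_sd = 0.02, seed = 7)
#' @export
sim_mm_dataset <- function(Km, Vmax,
                           S = exp(seq(log(0.25), log(50), length.out = 12)),
                           noise_sd = 0.02,
                           noise_model = c("multiplicative", "additive"),
                           seed) {
  noise_model <- match.arg(noise_model)
  .check_sim_args(seed, noise_sd)
  if (Km <= 0 || Vmax <= 0) stop("Km and Vmax must be > 0", call. = FALSE)
  v0 <- mm_velocity(S, Km, Vmax)
  v <- withr::with_seed(seed, {
    eps <- stats::rnorm(length(S), 0, 1)
    if (noise_model == "multiplicative") v0 * (1 + noise_sd * eps)
    else v0 + noise_sd * Vmax * eps
  })
  clipped <- sum(v < 0)
  if (clipped > 0) {
    message(clipped, " negative velocity draw(s) clipped to 0")
    v <- pmax(v, 0)
  }
  out <- tibble::tibble(S = S, v = v)
  attr(out, "truth") <- list(Km = Km, Vmax = Vmax, noise_sd = noise_sd,
                             noise_model = noise_model, seed = seed)
  attr(out, "clipped") <- clipped
  out
}

#' Simulate a residual-activity decay series
#'
#' First-order loss of activity during heat preincubation:
#' `residual(t) = exp(-kd t) * (1 + noise)`. Draws that come out
#' nonpositive are resampled (with a message) so the series stays usable on
#' the log scale.
#'
#' @param kd True inactivation rate constant, min^-1.
#' @param times Preincubation times, min.
#' @param noise_sd Relative (multiplicative) noise SD.
#' @param seed Integer seed.
#' @param temperature Optional temperature (K) recorded alongside.
#' @return Tibble with columns `time_min`, `residual` (plus
#'   `temperature_K` when given); attribute `truth`.
#' @export
sim_decay_series <- function(kd, times = c(0, 5, 10, 15, 20, 30, 45, 60),
                             noise_sd = 0.03, seed, temperature = NULL) {
  .check_sim_args(seed, noise_sd)
  if (kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("times must be nonnegative and strictly increasing", call. = FALSE)
  }
  r0 <- exp(-kd * times)
  residual <- withr::with_seed(seed, {
    r <- r0 * (1 + noise_sd * stats::rnorm(length(times)))
    n_resampled <- 0L
    while (any(r <= 0)) {
      i <- which(r <= 0)
      n_resampled <- n_resampled + length(i)
      r[i] <- r0[i] * (1 + noise_sd * stats::rnorm(length(i)))
    }
    if (n_resampled > 0) {
      message(n_resampled, " nonpositive residual draw(s) resampled")
    }
    r
  })
  out <- tibble::tibble(time_min = times, residual = residual)
  if (!is.null(temperature)) out$temperature_K <- temperature
  attr(out, "truth") <- list(kd = kd, noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a thermal-inactivation campaign across temperatures
#'
#' Rate constants follow an Arrhenius law
#' `kd(T) = exp(lnA - Ea / (R T))`; one decay series is generated per
#' temperature. Either `lnA` or an anchor pair `(T_ref, kd_ref)` fixes the
#' prefactor; with an anchor, `kd(T_ref)` equals `kd_ref` exactly.
#'
#' Preincubation-time grids follow assay practice: short (minutes) at the
#' hottest temperatures, long (hours) at the coolest, so each series decays
#' over an informative range.
#'
#' @param Ea True activation energy, kcal mol^-1 (>= 0; 0 gives identical
#'   kd at every temperature).
#' @param temperatures Campaign temperatures, K. Default 338-353 K
#'   (65-80 C), the span over which these enzymes are profiled.
#' @param lnA Log pre-exponential factor (A in min^-1).
#' @param anchor Length-2 numeric `c(T_ref, kd_ref)`; alternative to `lnA`.
#' @param noise_sd Relative noise SD passed to [sim_decay_series()].
#' @param seed Integer seed (per-temperature streams are derived from it).
#' @param enzyme Label recorded in the output.
#' @param constants A [hal_constants()] bundle.
#' @return Tidy tibble with columns `enzyme`, `temperature_K`, `time_min`,
#'   `residual`, ready for [build_inactivation_table()]; attribute `truth`.
#' @examples
#' sim_arrhenius_campaign(Ea = 49.42, anchor = c(353, 0.0206),
#'                        noise_sd = 0, seed = 1)
#' @export
sim_arrhenius_campaign <- function(Ea, temperatures = c(353, 348, 343, 338),
                                   lnA = NULL, anchor = NULL,
                                   noise_sd = 0.03, seed,
                                   enzyme = "enzyme",
                                   constants = hal_constants()) {
  .check_sim_args(seed, noise_sd)
  if (Ea < 0) stop("Ea must be >= 0", call. = FALSE)
  if (is.null(lnA) && is.null(anchor)) {
    stop("supply either lnA or an anchor (T_ref, kd_ref)", call. = FALSE)
  }
  R <- constants$R_kcal
  if (!is.null(anchor)) {
    stopifnot(length(anchor) == 2, anchor[1] > 0, anchor[2] > 0)
    lnA <- log(anchor[2]) + Ea / (R * anchor[1])
  }
  kds <- exp(lnA - Ea / (R * temperatures))

  series <- purrr::map2(kds, seq_along(kds), function(kd, i) {
    # time grid spanning roughly two half-lives, capped at 24 h
    t_half <- log(2) / kd
    t_max <- min(2.2 * t_half, 1440)
    times <- round(seq(0, t_max, length.out = 8), 3)
    sim_decay_series(kd, times = times, noise_sd = noise_sd,
                     seed = seed + i, temperature = temperatures[i])
  })
  out <- dplyr::bind_rows(series) |>
    dplyr::mutate(enzyme = enzyme, .before = 1)
  attr(out, "truth") <- list(Ea = Ea, lnA = lnA, kd = kds,
                             temperatures = temperatures,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a CD melt curve
#'
#' Signal on a dense temperature grid from the two-state model with linear
#' baselines, plus additive gaussian noise scaled by the transition
#' amplitude (detector noise does not scale with the ellipticity signal).
#'
#' @param Tm True transition midpoint, K.
#' @param dHvH True van't Hoff enthalpy, kcal mol^-1.
#' @param A_N,B_N,A_U,B_U Baseline coefficients (defaults give the native
#'   state a deep negative 222 nm ellipticity that relaxes toward zero on
#'   unfolding, as in a helical protein).
#' @param grid Temperature grid, K. Default 335-368 K in 0.2 K steps, the
#'   acquisition density of a thermostated CD melt.
#' @param noise_sd Noise SD as a fraction of the transition amplitude
#'   `|S_U(Tm) - S_N(Tm)|`.
#' @param seed Integer seed.
#' @param constants A [hal_constants()] bundle.
#' @return Tibble with columns `temperature`, `signal`; attribute `truth`.
#'   A midpoint outside the grid is allowed (the curve is intentionally
#'   unfittable) but warned about.
#' @examples
#' sim_melt_curve(Tm = 357.36, dHvH = 150, noise_sd = 0, seed = 1)
#' @export
sim_melt_curve <- function(Tm, dHvH, A_N = -20, B_N = 0.01,
                           A_U = -5, B_U = 0.005,
                           grid = seq(335, 368, by = 0.2),
                           noise_sd = 0.02, seed,
                           constants = hal_constants()) {
  .check_sim_args(seed, noise_sd)
  if (Tm <= 0 || dHvH <= 0) stop("Tm and dHvH must be > 0", call. = FALSE)
  if (Tm < min(grid) || Tm > max(grid)) {
    warning("Tm lies outside the temperature grid; curve will show no transition",
            call. = FALSE)
  }
  s0 <- two_state_signal(grid, Tm, dHvH, A_N, B_N, A_U, B_U, constants)
  amplitude <- abs((A_U + B_U * Tm) - (A_N + B_N * Tm))
  signal <- withr::with_seed(
    seed, s0 + noise_sd * amplitude * stats::rnorm(length(grid)))
  out <- tibble::tibble(temperature = grid, signal = signal)
  attr(out, "truth") <- list(Tm = Tm, dHvH = dHvH, A_N = A_N, B_N = B_N,
                             A_U = A_U, B_U = B_U, noise_sd = noise_sd,
                             seed = seed)
  out
}

.check_sim_args <- function(seed, noise_sd) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      length(seed) != 1L || !is.finite(seed)) {
    stop("an integer seed is required", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(TRUE)
}
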