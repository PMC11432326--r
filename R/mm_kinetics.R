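#' Michaelis-Menten velocity
#'
#' The rectangular hyperbola `v = Vmax * S / (Km + S)`.
#'
#' @param S Substrate concentration, mM (vectorised).
#' @param Km Michaelis constant, mM.
#' @param Vmax Maximal velocity, mol min^-1.
#' @return Velocity in the units of `Vmax`.
#' @export
mm_velocity <- function(S, Km, Vmax) {
  Vmax * S / (Km + S)
}

#' Fit the Michaelis-Menten equation to initial-rate data
#'
#' Unweighted nonlinear least squares of `v = Vmax * S / (Km + S)` by
#' Levenberg-Marquardt. Initial values follow the usual heuristic:
#' `Vmax0 = 1.2 * max(v)` and `Km0` the first substrate concentration at
#' which the velocity reaches half its maximum. A `1/v^2` weighted variant
#' is available for assays whose error scales with signal.
#'
#' If a molar enzyme amount is supplied the turnover number
#' `kcat = Vmax / 60 / enzyme_moles` (s^-1) and the catalytic efficiency
#' `kcat / Km` (mM^-1 s^-1) are attached to the fit.
#'
#' @param data Data frame with columns `S` (substrate concentration, mM) and
#'   `v` (velocity, mol min^-1); at least 4 points with at least 3 distinct
#'   positive concentrations.
#' @param enzyme_moles Optional molar enzyme amount (mol) for kcat.
#' @param init Optional named list or vector with `Km` and `Vmax` start
#'   values, overriding the heuristic.
#' @param weights `"none"` (default) or `"1/v2"`.
#' @return Object of class `"mm_fit"`; see [tidy.mm_fit()] and
#'   [glance.mm_fit()]. Key fields: `Km`, `Vmax`, `se_Km`, `se_Vmax`,
#'   `kcat`, `efficiency`, `converged`, `rss`, `data`.
#' @examples
#' d <- sim_mm_dataset(Km = 4.83, Vmax = 4.243e-7, noise_sd = 0, seed = 1)
#' fit_michaelis_menten(d)
#' @export
fit_michaelis_menten <- function(data, enzyme_moles = NULL, init = NULL,
                                 weights = c("none", "1/v2")) {
  stopifnot(is.data.frame(data))
  weights <- match.arg(weights)
  .require_cols(data, c("S", "v"), "kinetic dataset")
  if (any(data$S < 0) || any(data$v < 0)) {
    stop("substrate concentrations and velocities must be nonnegative",
         call. = FALSE)
  }
  if (nrow(data) < 4L || length(unique(data$S[data$S > 0])) < 3L) {
    stop("need >= 4 points with >= 3 distinct positive substrate concentrations",
         call. = FALSE)
  }
  if (all(data$v == 0)) stop("all velocities are zero", call. = FALSE)

  vmax0 <- if (!is.null(init)) init[["Vmax"]] else 1.2 * max(data$v)
  km0 <- if (!is.null(init)) init[["Km"]] else {
    half <- data$S[data$v >= max(data$v) / 2]
    if (length(half) > 0) min(half) else stats::median(data$S)
  }
  if (km0 <= 0) km0 <- stats::median(data$S[data$S > 0])

  args <- list(v ~ Vmax * S / (Km + S), data = data,
               start = list(Km = km0, Vmax = vmax0),
               lower = c(Km = 0, Vmax = 0),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (weights == "1/v2") {
    args$weights <- 1 / pmax(data$v, max(data$v) * 1e-6)^2
  }
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)

  if (inherits(fit, "error")) {
    res <- list(Km = NA_real_, Vmax = NA_real_, se_Km = NA_real_,
                se_Vmax = NA_real_, kcat = NA_real_, efficiency = NA_real_,
                rss = NA_real_, n_points = nrow(data), converged = FALSE,
                message = conditionMessage(fit), data = tibble::as_tibble(data),
                fit = NULL, enzyme_moles = enzyme_moles)
    return(structure(res, class = "mm_fit"))
  }

  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) c(Km = NA_real_, Vmax = NA_real_))
  converged <- isTRUE(fit$convInfo$isConv) && all(is.finite(cf)) && all(cf > 0)
  kcat <- if (!is.null(enzyme_moles)) {
    turnover_number(cf[["Vmax"]], enzyme_moles)
  } else NA_real_
  efficiency <- if (!is.na(kcat)) catalytic_efficiency(kcat, cf[["Km"]]) else NA_real_

  km_inside <- any(data$S < cf[["Km"]]) && any(data$S > cf[["Km"]])
  if (converged && !km_inside) {
    warning("fitted Km lies outside the sampled substrate range; fit is poorly constrained",
            call. = FALSE)
  }

  structure(
    list(Km = cf[["Km"]], Vmax = cf[["Vmax"]],
         se_Km = unname(se["Km"]), se_Vmax = unname(se["Vmax"]),
         kcat = kcat, efficiency = efficiency,
         rss = sum(stats::resid(fit)^2), n_points = nrow(data),
         converged = converged, message = NULL,
         data = tibble::as_tibble(data), fit = fit,
         enzyme_moles = enzyme_moles),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Michaelis-Menten fit: NOT CONVERGED",
        if (!is.null(x$message)) paste0(" (", x$message, ")"), "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Michaelis-Menten fit (%d points):\n", x$n_points))
  cat(sprintf("  Km   = %.4g mM (SE %.2g)\n", x$Km, x$se_Km))
  cat(sprintf("  Vmax = %.4g mol min^-1 (SE %.2g)\n", x$Vmax, x$se_Vmax))
  if (!is.na(x$kcat)) {
    cat(sprintf("  kcat = %.4g s^-1;  kcat/Km = %.4g mM^-1 s^-1\n",
                x$kcat, x$efficiency))
  }
  invisible(x)
}

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `"mm_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`Km`, `Vmax`, and when an
#'   enzyme amount was supplied `kcat` and `efficiency`).
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("Km", "Vmax"),
    estimate = c(x$Km, x$Vmax),
    std.error = c(x$se_Km, x$se_Vmax))
  if (!is.na(x$kcat)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = c("kcat", "efficiency"),
      estimate = c(x$kcat, x$efficiency),
      std.error = NA_real_))
  }
  out
}

#' @rdname tidy.mm_fit
#' @return `glance()`: a one-row tibble with fit-level summaries.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_points = x$n_points, converged = x$converged)
}

#' @export
predict.mm_fit <- function(object, S = NULL, ...) {
  if (is.null(S)) S <- object$data$S
  mm_velocity(S, object$Km, object$Vmax)
}

#' Plot a Michaelis-Menten fit
#'
#' Points are the observed initial rates; the curve is the fitted
#' hyperbola, with Km marked.
#'
#' @param object An `"mm_fit"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble::tibble(S = seq(0, max(object$data$S), length.out = 200))
  grid$v <- predict(object, grid$S)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$S, y = .data$v)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$Km, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "[S] (mM)", y = "v (mol min^-1)",
                  title = sprintf("Km = %.3g mM, Vmax = %.3g", object$Km,
                                  object$Vmax)) +
    ggplot2::theme_minimal()
}

#' Turnover number from maximal velocity
#'
#' `kcat = Vmax / 60 / enzyme_moles`: the per-minute maximal velocity is
#' converted to per second and normalised by the molar amount of enzyme in
#' the assay. The enzyme amount is always an explicit input; it is never
#' inferred from the data.
#'
#' @param Vmax Maximal velocity, mol min^-1.
#' @param enzyme_moles Moles of enzyme in the reaction.
#' @return kcat in s^-1.
#' @export
turnover_number <- function(Vmax, enzyme_moles) {
  if (any(Vmax <= 0) || any(enzyme_moles <= 0)) {
    stop("Vmax and enzyme_moles must be > 0", call. = FALSE)
  }
  Vmax / 60 / enzyme_moles
}

#' Catalytic efficiency kcat/Km
#'
#' @param kcat Turnover number, s^-1.
#' @param Km Michaelis constant, mM.
#' @return Efficiency in mM^-1 s^-1.
#' @export
catalytic_efficiency <- function(kcat, Km) {
  if (any(Km <= 0)) stop("Km must be > 0", call. = FALSE)
  kcat / Km
}

#' Fold-decrease of catalytic efficiency relative to a reference
#'
#' @param reference_eff Reference (e.g. wild-type) efficiency, mM^-1 s^-1.
#' @param variant_eff Variant efficiency, mM^-1 s^-1.
#' @return The ratio `reference_eff / variant_eff` at full precision;
#'   display layers round it to an integer fold.
#' @export
relative_decrease <- function(reference_eff, variant_eff) {
  if (any(reference_eff <= 0) || any(variant_eff <= 0)) {
    stop("efficiencies must be > 0", call. = FALSE)
  }
  reference_eff / variant_eff
}
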