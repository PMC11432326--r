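#' Physical constants used throughout the pipeline
#'
#' Bundles the constants every downstream calculation depends on: the gas
#' constant in the kcal-based unit system the thermodynamic tables use, the
#' Boltzmann and Planck constants for the Eyring equation, the transmission
#' coefficient, and the molar extinction coefficient of trans-urocanic acid
#' at 280 nm used to convert absorbance slopes into molar rates.
#'
#' All energies downstream are in kcal mol^-1 and entropies in
#' kcal K^-1 mol^-1; a display-layer conversion to kJ is available in the
#' reporting functions but never used internally.
#'
#' @param R_kcal Gas constant, kcal mol^-1 K^-1.
#' @param kB Boltzmann constant, J K^-1.
#' @param h Planck constant, J s.
#' @param kappa Eyring transmission coefficient (dimensionless). The
#'   conventional value of 1 reproduces the published activation free
#'   energies; override only with good reason.
#' @param eps_urocanate Molar extinction coefficient of trans-urocanic acid
#'   at 280 nm, M^-1 cm^-1.
#' @param config Optional named list (for example parsed from a JSON
#'   `constants` block) whose entries override the defaults above.
#'
#' @return A named list of class `"hal_constants"`.
#' @examples
#' hal_constants()
#' hal_constants(config = list(kappa = 0.5))
#' @export
hal_constants <- function(R_kcal = 1.987e-3,
                          kB = 1.380649e-23,
                          h = 6.62607015e-34,
                          kappa = 1,
                          eps_urocanate = 18800,
                          config = NULL) {
  out <- list(R_kcal = R_kcal, kB = kB, h = h, kappa = kappa,
              eps_urocanate = eps_urocanate)
  if (!is.null(config)) {
    stopifnot(is.list(config))
    unknown <- setdiff(names(config), names(out))
    if (length(unknown) > 0) {
      stop("unknown constants field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out[names(config)] <- config
  }
  for (nm in names(out)) {
    val <- out[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop("constant '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  structure(out, class = "hal_constants")
}

#' @export
print.hal_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  R       = %.4g kcal mol^-1 K^-1\n", x$R_kcal))
  cat(sprintf("  kB      = %.6g J K^-1\n", x$kB))
  cat(sprintf("  h       = %.6g J s\n", x$h))
  cat(sprintf("  kappa   = %g\n", x$kappa))
  cat(sprintf("  epsilon(urocanate, 280 nm) = %g M^-1 cm^-1\n",
              x$eps_urocanate))
  invisible(x)
}

#' Convert between Celsius and Kelvin
#'
#' `celsius_to_kelvin()` adds 273.15 by default. Published inactivation
#' tables in this field frequently label 65/70/75/80 degrees C as
#' 338/343/348/353 K, i.e. with the 0.15 dropped; `legacy = TRUE` uses the
#' integer offset 273 so such tables can be reproduced cell-for-cell. All
#' internal computation uses the exact offset.
#'
#' @param t Temperature in degrees Celsius (vectorised).
#' @param k Temperature in Kelvin (vectorised).
#' @param legacy If `TRUE`, use the integer offset 273 instead of 273.15.
#' @return Temperature in the other scale.
#' @examples
#' celsius_to_kelvin(65)                # 338.15
#' celsius_to_kelvin(65, legacy = TRUE) # 338
#' @export
celsius_to_kelvin <- function(t, legacy = FALSE) {
  offset <- if (legacy) 273 else 273.15
  if (any(!is.finite(t)) || any(t <= -273.15)) {
    stop("temperature at or below absolute zero (-273.15 C)", call. = FALSE)
  }
  t + offset
}

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(k, legacy = FALSE) {
  offset <- if (legacy) 273 else 273.15
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("temperature at or below 0 K", call. = FALSE)
  }
  k - offset
}

# Residual activities arrive either as fractions or as percentages; values
# above this cutoff are taken to be percent and divided by 100.
.normalize_residual <- function(residual) {
  if (any(residual > 1.5, na.rm = TRUE)) {
    warning("residual activities look like percentages (> 1.5); dividing by 100",
            call. = FALSE)
    residual <- residual / 100
  }
  residual
}
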