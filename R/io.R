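#' Read a typed assay table from CSV
#'
#' Thin, schema-checked CSV reader for the file layouts the pipeline
#' consumes. Headers are matched order-insensitively; extra columns are
#' kept; a missing column or a non-numeric cell is reported with its row
#' and column so instrument exports can be fixed quickly.
#'
#' Available schemas and their required columns:
#' \describe{
#'   \item{`activity_profile`}{`condition`, `rate`}
#'   \item{`substrate_screen`}{`substrate`, `rate`}
#'   \item{`sec_markers`}{`rt_min`, `mass_kda`}
#'   \item{`rates`}{`substrate_mM`, `v_mol_per_min` (renamed to `S`, `v`)}
#'   \item{`decay`}{`temperature_C`, `time_min`, `residual_fraction`
#'     (renamed to `residual`); optional `enzyme`}
#'   \item{`melt`}{`temperature_C`, `signal`}
#'   \item{`spectrum`}{`wavelength_nm`, `signal`, `scan_id`}
#' }
#'
#' @param path Path to a CSV file.
#' @param schema One of the schema names above.
#' @return A tibble with the schema's canonical column names.
#' @export
read_assay_table <- function(path, schema = c("activity_profile",
                                              "substrate_screen",
                                              "sec_markers", "rates",
                                              "decay", "melt", "spectrum")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schemas <- list(
    activity_profile = list(num = c("condition", "rate"), chr = character()),
    substrate_screen = list(num = "rate", chr = "substrate"),
    sec_markers = list(num = c("rt_min", "mass_kda"), chr = character()),
    rates = list(num = c("substrate_mM", "v_mol_per_min"), chr = character(),
                 rename = c(S = "substrate_mM", v = "v_mol_per_min")),
    decay = list(num = c("temperature_C", "time_min", "residual_fraction"),
                 chr = character(),
                 rename = c(residual = "residual_fraction")),
    melt = list(num = c("temperature_C", "signal"), chr = character()),
    spectrum = list(num = c("wavelength_nm", "signal"), chr = "scan_id"))
  sc <- schemas[[schema]]

  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  missing <- setdiff(c(sc$num, sc$chr), names(raw))
  if (length(missing) > 0) {
    stop("'", basename(path), "' (schema ", schema, ") is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in sc$num) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !raw[[col]] %in% c("", NA))
    bad <- c(bad, which(is.na(vals) & is.na(raw[[col]])))
    if (anyNA(vals)) {
      row <- which(is.na(vals))[1]
      stop("non-numeric value '", raw[[col]][row], "' in column '", col,
           "', row ", row, " of ", basename(path), call. = FALSE)
    }
    raw[[col]] <- vals
  }
  out <- tibble::as_tibble(raw)
  if (!is.null(sc$rename)) out <- dplyr::rename(out, dplyr::all_of(sc$rename))
  out
}

#' Render result tables in publication shape
#'
#' Formats fitted results as the three standard characterization tables:
#' kinetic constants per enzyme/substrate (`render_table1`), thermal
#' inactivation thermodynamics per enzyme/temperature (`render_table2`),
#' and apparent melting temperatures with shifts against a reference
#' (`render_table3`). All rounding happens here, in the display layer;
#' the fitted objects keep full precision.
#'
#' @param fits For `render_table1`: a tibble with columns `enzyme`,
#'   `substrate` and a list-column `fit` of [fit_michaelis_menten()]
#'   results (fitted with `enzyme_moles` so kcat is available). For
#'   `render_table3`: columns `enzyme` and list-column `fit` of
#'   [fit_two_state_melt()] results.
#' @param reference Enzyme label used as the efficiency / Tm reference
#'   (default the first row).
#' @return A display tibble mirroring the corresponding table's columns and
#'   rounding.
#' @export
render_table1 <- function(fits, reference = fits$enzyme[1]) {
  stopifnot(is.data.frame(fits))
  .require_cols(fits, c("enzyme", "substrate", "fit"), "table 1 input")
  rows <- fits |>
    dplyr::mutate(
      Km = purrr::map_dbl(.data$fit, "Km"),
      kcat = purrr::map_dbl(.data$fit, "kcat"),
      Vmax = purrr::map_dbl(.data$fit, "Vmax"),
      efficiency = purrr::map_dbl(.data$fit, "efficiency"))
  ref <- rows |>
    dplyr::filter(.data$enzyme == reference) |>
    dplyr::select("substrate", ref_eff = "efficiency")
  rows |>
    dplyr::left_join(ref, by = "substrate") |>
    dplyr::transmute(
      enzyme = .data$enzyme, substrate = .data$substrate,
      Km_mM = round(.data$Km, 2),
      kcat_s = round(.data$kcat, 3),
      Vmax_1e7_mol_min = round(.data$Vmax * 1e7, 3),
      efficiency_mM_s = round(.data$efficiency, 4),
      rel_decrease = as.integer(round(.data$ref_eff / .data$efficiency)))
}

#' @rdname render_table1
#' @param table An `"inactivation_table"` from [build_inactivation_table()].
#' @export
render_table2 <- function(table) {
  stopifnot(inherits(table, "inactivation_table"))
  table |>
    dplyr::transmute(
      enzyme = .data$enzyme,
      Ea_kcal_mol = round(.data$Ea, 2),
      temperature_K = round(.data$temperature),
      t_half_min = round(.data$t_half),
      kd_min = round(.data$kd, 4),
      dG_kcal_mol = round(.data$dG, 2),
      dH_kcal_mol = round(.data$dH, 2),
      dS_kcal_K_mol = round(.data$dS, 3)) |>
    (\(x) { attr(x, "arrhenius") <- NULL; tibble::as_tibble(as.data.frame(x)) })()
}

#' @rdname render_table1
#' @export
render_table3 <- function(fits, reference = fits$enzyme[1]) {
  stopifnot(is.data.frame(fits))
  .require_cols(fits, c("enzyme", "fit"), "table 3 input")
  rows <- fits |>
    dplyr::mutate(Tm = purrr::map_dbl(.data$fit, "Tm"),
                  se_Tm = purrr::map_dbl(.data$fit, "se_Tm"),
                  converged = purrr::map_lgl(.data$fit, "converged"))
  if (!all(rows$converged)) {
    stop("unconverged melt fit(s): ",
         paste(rows$enzyme[!rows$converged], collapse = ", "), call. = FALSE)
  }
  tm_ref <- rows$Tm[rows$enzyme == reference][1]
  rows |>
    dplyr::transmute(
      enzyme = .data$enzyme,
      Tm_app_K = round(.data$Tm, 2),
      se_Tm_K = round(.data$se_Tm, 2),
      dTm_K = ifelse(.data$enzyme == reference, NA_real_,
                     round(.data$Tm - tm_ref, 2)))
}

#' Write a rendered table to TSV plus a full-precision JSON sidecar
#'
#' The TSV carries the display rounding of the `render_table*` functions;
#' the JSON sidecar carries the same rows at full precision together with
#' reproducibility metadata (package version, timestamp, optional seed and
#' extra fields), so the TSV can be regenerated deterministically.
#'
#' @param display Rounded display tibble (from a `render_table*` function).
#' @param full Full-precision data frame (e.g. the unrounded table).
#' @param path Output stem: writes `<path>.tsv` and `<path>.json`.
#' @param seed Optional seed recorded in the metadata.
#' @param extra Optional named list merged into the metadata.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(display, full = display, path, seed = NULL,
                         extra = NULL) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  readr::write_tsv(display, tsv)
  payload <- list(
    metadata = c(list(package = "thermolyase",
                      version = as.character(utils::packageVersion("thermolyase")),
                      written = format(Sys.time(), tz = "UTC",
                                       "%Y-%m-%dT%H:%M:%SZ"),
                      seed = seed),
                 extra),
    rows = full)
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(tsv = tsv, json = json))
}
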