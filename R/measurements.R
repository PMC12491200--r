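#' Replicate elemental concentration sets
#'
#' A `measurement_set` is a tidy tibble of replicate elemental concentrations
#' in a liquid herbal preparation, one row per
#' (sample, element, replicate). Non-detects (instrument readings below the
#' limit of detection) carry `NA` in the `concentration` column and `TRUE` in
#' `nondetect`; they never contribute a numeric value downstream.
#'
#' @param x A data frame with columns `sample_id`, `element`, `replicate`
#'   (integer index, unique within each sample/element cell), `concentration`
#'   (mg/kg, `NA` for non-detects) and optionally `nondetect` (logical;
#'   derived from `concentration` when missing).
#'
#' @return A tibble of class `measurement_set`.
#' @export
#' @examples
#' as_measurement_set(data.frame(
#'   sample_id = "A", element = "Mn", replicate = 1:3,
#'   concentration = c(1.37e-2, 1.49e-2, 1.61e-2)
#' ))
as_measurement_set <- function(x) {
  required <- c("sample_id", "element", "replicate", "concentration")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("measurement table is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "herbrisk_schema_error"
    )
  }
  x <- tibble::as_tibble(x)
  if (!"nondetect" %in% names(x)) {
    x$nondetect <- is.na(x$concentration)
  }
  x$sample_id <- as.character(x$sample_id)
  x$element <- as.character(x$element)
  x$replicate <- as.integer(x$replicate)
  x$concentration <- as.double(x$concentration)
  x$nondetect <- as.logical(x$nondetect)
  validate_measurement_set(x)
  class(x) <- c("measurement_set", class(tibble::tibble()))
  x
}

validate_measurement_set <- function(x) {
  if (nrow(x) == 0) {
    rlang::abort("measurement set contains no records",
                 class = "herbrisk_schema_error")
  }
  bad <- which(!x$nondetect & (is.na(x$concentration) | x$concentration < 0))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("detected concentrations must be numeric and >= 0; offending row(s): ",
             paste(bad, collapse = ", ")),
      class = "herbrisk_validation_error"
    )
  }
  if (any(x$nondetect & !is.na(x$concentration))) {
    rlang::abort("non-detect records must not carry a numeric concentration",
                 class = "herbrisk_validation_error")
  }
  dup <- duplicated(x[, c("sample_id", "element", "replicate")])
  if (any(dup)) {
    rlang::abort(
      paste0("replicate index must be unique within (sample, element); row(s): ",
             paste(which(dup), collapse = ", ")),
      class = "herbrisk_validation_error"
    )
  }
  invisible(x)
}

#' @export
print.measurement_set <- function(x, ...) {
  n_cells <- nrow(unique(x[, c("sample_id", "element")]))
  cat(sprintf(
    "<measurement_set> %d records, %d (sample, element) cells, %d non-detect record(s)\n",
    nrow(x), n_cells, sum(x$nondetect)))
  NextMethod()
}

#' Exposure parameters for the ingestion pathway
#'
#' The concentration-independent terms of the estimated-daily-intake model
#' EDI = C * IR * EF * ED / (BW * AT). Defaults describe chronic adult
#' consumption of a liquid herbal preparation: 8 g/day ingested, daily
#' exposure over a 70-year duration, 70 kg body weight, and an averaging
#' time equal to the exposure duration (so for non-carcinogenic endpoints
#' EF * ED / AT cancels and EDI reduces to C * IR / BW).
#'
#' @param ir Ingestion rate, kg of preparation per person per day.
#' @param ef Exposure frequency, days/year.
#' @param ed Exposure duration, years.
#' @param bw Body weight, kg.
#' @param at Averaging time, days. Defaults to `365 * ed`.
#'
#' @return An object of class `exposure_parameters`.
#' @export
#' @examples
#' exposure_parameters() # adult defaults
exposure_parameters <- function(ir = 0.008, ef = 365, ed = 70, bw = 70,
                                at = 365 * ed) {
  p <- list(ir = ir, ef = ef, ed = ed, bw = bw, at = at)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      rlang::abort(
        paste0("exposure parameter '", nm, "' must be a single positive number"),
        class = "herbrisk_validation_error"
      )
    }
  }
  structure(p, class = "exposure_parameters")
}

#' @export
print.exposure_parameters <- function(x, ...) {
  cat("<exposure_parameters>\n")
  cat(sprintf("  IR = %g kg/day  EF = %g d/y  ED = %g y  BW = %g kg  AT = %g d\n",
              x$ir, x$ef, x$ed, x$bw, x$at))
  invisible(x)
}
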