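#' Instrument limit of detection from calibration blanks
#'
#' LOD = 3 * SD(blank signals) / calibration slope, with SD the sample
#' standard deviation (n - 1 denominator). This is the conventional
#' 3-sigma criterion for emission/absorbance instruments (ICP-OES, AAS).
#'
#' @param blanks Numeric vector of blank signal readings (instrument
#'   units), or a list with components `blank_signals` and `slope` such as
#'   returned by [generate_blank_series()].
#' @param slope Calibration-curve slope (signal per mg/L); ignored when
#'   `blanks` carries its own slope.
#'
#' @return The limit of detection, in the concentration units implied by
#'   the slope.
#' @export
#' @examples
#' compute_lod(c(0.001, 0.002, 0.003), slope = 3) # 0.001
compute_lod <- function(blanks, slope = NULL) {
  if (is.list(blanks) && !is.null(blanks$blank_signals)) {
    if (is.null(slope)) slope <- blanks$slope
    blanks <- blanks$blank_signals
  }
  if (!is.numeric(blanks) || length(blanks) < 2) {
    rlang::abort("at least 2 blank readings are required to estimate LOD",
                 class = "herbrisk_insufficient_data_error")
  }
  if (is.null(slope) || !is.numeric(slope) || length(slope) != 1 ||
      !is.finite(slope) || slope <= 0) {
    rlang::abort("calibration slope must be a single positive number",
                 class = "herbrisk_domain_error")
  }
  3 * stats::sd(blanks) / slope
}

#' Read a calibration-blank table and compute per-element LODs
#'
#' Expects CSV columns `element`, `slope` and two or more `blank_*`
#' columns holding replicate blank signal readings.
#'
#' @param path Path to the calibration CSV.
#' @return A tibble with columns `element`, `slope`, `sd_blank`, `lod`.
#' @export
read_calibration <- function(path) {
  raw <- read_csv_strict(path)
  if (!all(c("element", "slope") %in% names(raw))) {
    rlang::abort(
      paste0("calibration table '", path,
             "' is missing column(s): ",
             paste(setdiff(c("element", "slope"), names(raw)),
                   collapse = ", ")),
      class = "herbrisk_schema_error"
    )
  }
  blank_cols <- grep("^blank", names(raw), value = TRUE)
  if (length(blank_cols) < 2) {
    rlang::abort("calibration table needs at least 2 blank_* columns",
                 class = "herbrisk_schema_error")
  }
  blanks <- vapply(blank_cols, function(cn) as.double(raw[[cn]]),
                   double(nrow(raw)))
  blanks <- matrix(blanks, nrow = nrow(raw))
  slope <- as.double(raw$slope)
  tibble::tibble(
    element = as.character(raw$element),
    slope = slope,
    sd_blank = apply(blanks, 1, stats::sd),
    lod = vapply(seq_len(nrow(raw)), function(i) {
      compute_lod(blanks[i, ], slope[i])
    }, double(1))
  )
}

#' Re-flag measurements below the limit of detection as non-detects
#'
#' Detected values strictly below their element's LOD become non-detects;
#' values at or above the LOD are kept (a reading exactly at the LOD counts
#' as a detection). Elements without an entry in `lods` are left untouched.
#'
#' @param ms A [as_measurement_set()] tibble.
#' @param lods Named numeric vector of LODs (mg/kg), names are elements.
#' @return The measurement set with updated non-detect flags.
#' @export
flag_nondetects <- function(ms, lods) {
  ms <- as_measurement_set(ms)
  if (length(lods) == 0) return(ms)
  if (is.null(names(lods)) || any(!nzchar(names(lods)))) {
    rlang::abort("lods must be a named numeric vector (names = elements)",
                 class = "herbrisk_validation_error")
  }
  el_lod <- unname(lods[ms$element])
  below <- !ms$nondetect & !is.na(el_lod) & ms$concentration < el_lod
  ms$nondetect[below] <- TRUE
  ms$concentration[below] <- NA_real_
  ms
}

#' Descriptive summary of a replicate series
#'
#' Arithmetic mean, sample standard deviation (n - 1), coefficient of
#' variation (CV% = 100 * sd / mean, reported only for positive means) and
#' a Student-t confidence interval mean +/- t(1 - alpha/2, n - 1) * sd/sqrt(n).
#'
#' @param values Numeric vector of replicate measurements (mg/kg), n >= 2.
#' @param confidence Confidence level for the interval, default 0.95.
#' @return A one-row tibble: `n`, `mean`, `sd`, `cv_percent`, `ci_low`,
#'   `ci_high`.
#' @export
#' @examples
#' summarize_replicates(c(1, 2, 3))
summarize_replicates <- function(values, confidence = 0.95) {
  if (!is.numeric(values) || length(values) < 2 || any(!is.finite(values))) {
    rlang::abort("need >= 2 finite replicate values",
                 class = "herbrisk_insufficient_data_error")
  }
  if (confidence <= 0 || confidence >= 1) {
    rlang::abort("confidence must be in (0, 1)",
                 class = "herbrisk_domain_error")
  }
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - confidence) / 2, df = n - 1) * s / sqrt(n)
  tibble::tibble(
    n = n, mean = m, sd = s,
    cv_percent = if (m > 0) 100 * s / m else NA_real_,
    ci_low = m - half, ci_high = m + half
  )
}

#' Per-cell descriptive statistics for a measurement set
#'
#' Applies [summarize_replicates()] to each (sample, element) cell with at
#' least two detected replicates; non-detect records are excluded and
#' all-non-detect cells are dropped.
#'
#' @inheritParams flag_nondetects
#' @param confidence Confidence level, default 0.95.
#' @return A tibble with one row per summarised cell.
#' @export
concentration_summary <- function(ms, confidence = 0.95) {
  ms <- as_measurement_set(ms)
  det <- ms[!ms$nondetect, , drop = FALSE]
  det |>
    dplyr::group_by(.data$sample_id, .data$element) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::reframe(summarize_replicates(.data$concentration, confidence))
}

#' One-sample t-test of replicates against a regulatory limit
#'
#' Two-sided test of H0: true mean equals the permissible limit, via the
#' standard one-sample t statistic (mean - limit) / (sd / sqrt(n)) with
#' n - 1 degrees of freedom.
#'
#' @param values Numeric replicate measurements (mg/kg), n >= 2, sd > 0.
#' @param limit Permissible concentration limit (mg/kg).
#' @param alpha Significance level for the `significant` flag, default 0.05.
#' @return A one-row tibble: `mean`, `sd`, `limit`, `t_statistic`,
#'   `p_value`, `significant`.
#' @export
limit_t_test <- function(values, limit, alpha = 0.05) {
  if (!is.numeric(values) || length(values) < 2 || any(!is.finite(values))) {
    rlang::abort("need >= 2 finite replicate values",
                 class = "herbrisk_insufficient_data_error")
  }
  if (stats::sd(values) == 0) {
    rlang::abort("t statistic undefined: replicates have zero variance",
                 class = "herbrisk_degenerate_test_error")
  }
  fit <- stats::t.test(values, mu = limit, alternative = "two.sided")
  tibble::tibble(
    mean = mean(values),
    sd = stats::sd(values),
    limit = limit,
    t_statistic = unname(fit$statistic),
    p_value = fit$p.value,
    significant = fit$p.value < alpha
  )
}

#' Limit tests for every cell with a permissible limit
#'
#' Runs [limit_t_test()] for each detected (sample, element) cell whose
#' element has a `who_limit` in the toxicity reference.
#'
#' @inheritParams flag_nondetects
#' @param tox Toxicity reference tibble from [read_toxicity_reference()].
#' @param alpha Significance level, default 0.05.
#' @return A tibble with one row per tested cell.
#' @export
limit_tests <- function(ms, tox, alpha = 0.05) {
  ms <- as_measurement_set(ms)
  limits <- tox[!is.na(tox$who_limit), c("element", "who_limit")]
  det <- ms[!ms$nondetect & ms$element %in% limits$element, , drop = FALSE]
  det |>
    dplyr::group_by(.data$sample_id, .data$element) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::reframe(limit_t_test(
      .data$concentration,
      limits$who_limit[match(.data$element[1], limits$element)],
      alpha
    ))
}
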