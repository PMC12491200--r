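#' Estimated daily intake of an element through ingestion
#'
#' EDI = C * IR * EF * ED / (BW * AT), in mg per kg body weight per day.
#' With the default averaging time AT = 365 * ED the frequency and duration
#' terms cancel and the intake reduces to C * IR / BW.
#'
#' @param concentration Elemental concentration C in the preparation,
#'   mg/kg. Vectorised.
#' @param params An [exposure_parameters()] object.
#' @return Estimated daily intake, mg/kg/day.
#' @export
#' @examples
#' estimated_daily_intake(3.92e-3, exposure_parameters())
estimated_daily_intake <- function(concentration, params = exposure_parameters()) {
  stopifnot(inherits(params, "exposure_parameters"))
  if (any(!is.na(concentration) & concentration < 0)) {
    rlang::abort("concentration must be >= 0",
                 class = "herbrisk_domain_error")
  }
  concentration * params$ir * params$ef * params$ed / (params$bw * params$at)
}

#' Target hazard quotient
#'
#' THQ = EDI / RfD: the ratio of the estimated daily intake to the oral
#' reference dose. Values below 1 indicate no expected non-carcinogenic
#' effect over a lifetime of exposure.
#'
#' @param edi Estimated daily intake, mg/kg/day. Vectorised.
#' @param rfd Oral reference dose, mg/kg/day (> 0).
#' @return The dimensionless hazard quotient.
#' @export
target_hazard_quotient <- function(edi, rfd) {
  if (any(!is.na(rfd) & rfd <= 0)) {
    rlang::abort("rfd must be > 0", class = "herbrisk_domain_error")
  }
  edi / rfd
}

#' Hazard index
#'
#' Sum of the target hazard quotients of the toxicants co-occurring in one
#' exposure medium: HI = THQ_1 + THQ_2 + ... + THQ_n.
#'
#' @param thqs Non-empty numeric vector of hazard quotients.
#' @return The dimensionless hazard index.
#' @export
hazard_index <- function(thqs) {
  if (length(thqs) == 0 || any(is.na(thqs))) {
    rlang::abort("hazard index needs at least one non-missing THQ",
                 class = "herbrisk_insufficient_data_error")
  }
  sum(thqs)
}

#' Lifetime cancer risk
#'
#' CR = EDI * CSF: excess lifetime cancer probability from chronic intake,
#' computed only for elements with a published cancer slope factor.
#'
#' @param edi Estimated daily intake, mg/kg/day. Vectorised.
#' @param csf Cancer slope factor, (mg/kg/day)^-1 (>= 0).
#' @return The dimensionless cancer risk.
#' @export
cancer_risk <- function(edi, csf) {
  if (any(!is.na(csf) & csf < 0)) {
    rlang::abort("csf must be >= 0", class = "herbrisk_domain_error")
  }
  edi * csf
}

#' Classify a cancer-risk value into the conventional bands
#'
#' Risks below 1e-6 are negligible; risks between 1e-6 and 1e-4 (both
#' boundaries included) are acceptable; risks above 1e-4 indicate a
#' potential cancer risk.
#'
#' @param cr Numeric cancer risk value(s), >= 0.
#' @return A factor with levels `negligible`, `acceptable`,
#'   `potential_risk` (NA stays NA).
#' @export
#' @examples
#' classify_cancer_risk(c(1.9e-8, 1.12e-6, 2e-4))
classify_cancer_risk <- function(cr) {
  if (any(!is.na(cr) & cr < 0)) {
    rlang::abort("cancer risk must be >= 0", class = "herbrisk_domain_error")
  }
  labels <- c("negligible", "acceptable", "potential_risk")
  out <- rep(NA_character_, length(cr))
  out[!is.na(cr) & cr < 1e-6] <- "negligible"
  out[!is.na(cr) & cr >= 1e-6 & cr <= 1e-4] <- "acceptable"
  out[!is.na(cr) & cr > 1e-4] <- "potential_risk"
  factor(out, levels = labels)
}

#' Deterministic point-estimate risk table
#'
#' Runs the full ingestion risk chain on the replicate mean concentration
#' of every detected (sample, element) cell: EDI, THQ, and - for elements
#' with a cancer slope factor - CR with its risk band. Cells that are
#' entirely non-detect produce no rows, and samples with no detected
#' elements produce no hazard index.
#'
#' @inheritParams flag_nondetects
#' @param tox Toxicity reference tibble from [read_toxicity_reference()];
#'   every detected element must have a row (an element without one raises
#'   a configuration error naming it).
#' @param params An [exposure_parameters()] object.
#' @return A list of class `risk_tables` with
#'   \describe{
#'     \item{risk}{tibble: `sample_id`, `element`, `concentration`, `edi`,
#'       `thq`, `cr` (NA when no CSF), `cr_band`, `estimator`}
#'     \item{hazard_index}{tibble: `sample_id`, `hi`, `n_elements`,
#'       `elements` (comma-separated contributing elements)}
#'   }
#' @export
deterministic_risk_table <- function(ms, tox, params = exposure_parameters()) {
  ms <- as_measurement_set(ms)
  det <- ms[!ms$nondetect, , drop = FALSE]
  missing_tox <- setdiff(unique(det$element), tox$element)
  if (length(missing_tox) > 0) {
    rlang::abort(
      paste0("element(s) missing from toxicity reference: ",
             paste(sort(missing_tox), collapse = ", ")),
      class = "herbrisk_config_error"
    )
  }
  means <- det |>
    dplyr::group_by(.data$sample_id, .data$element) |>
    dplyr::summarise(concentration = mean(.data$concentration),
                     .groups = "drop") |>
    dplyr::arrange(.data$sample_id, .data$element)
  idx <- match(means$element, tox$element)
  risk <- means
  risk$edi <- estimated_daily_intake(means$concentration, params)
  risk$thq <- target_hazard_quotient(risk$edi, tox$rfd[idx])
  risk$cr <- ifelse(is.na(tox$csf[idx]), NA_real_,
                    cancer_risk(risk$edi, tox$csf[idx]))
  risk$cr_band <- classify_cancer_risk(risk$cr)
  risk$estimator <- "deterministic"
  hi <- risk |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      hi = hazard_index(.data$thq),
      n_elements = dplyr::n(),
      elements = paste(.data$element, collapse = ","),
      .groups = "drop"
    )
  structure(list(risk = risk, hazard_index = hi), class = "risk_tables")
}

#' @export
print.risk_tables <- function(x, ...) {
  cat(sprintf("<risk_tables> %d risk record(s), %d sample hazard index row(s)\n",
              nrow(x$risk), nrow(x$hazard_index)))
  print(x$risk, ...)
  print(x$hazard_index, ...)
  invisible(x)
}
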