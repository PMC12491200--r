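#' Monte Carlo simulation settings
#'
#' @param n_iterations Number of iterations, >= 100. Default 10,000.
#' @param seed Integer RNG seed; every run with the same seed and inputs is
#'   bit-reproducible.
#' @param percentiles Fractions in (0, 1) to report. Default `c(0.5, 0.95)`
#'   (P50 and P95).
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_iterations = 10000L, seed = 1L,
                      percentiles = c(0.5, 0.95)) {
  if (!is.numeric(n_iterations) || n_iterations < 100) {
    rlang::abort("n_iterations must be >= 100",
                 class = "herbrisk_validation_error")
  }
  if (any(percentiles <= 0 | percentiles >= 1)) {
    rlang::abort("percentiles must lie strictly in (0, 1)",
                 class = "herbrisk_validation_error")
  }
  structure(
    list(n_iterations = as.integer(n_iterations), seed = as.integer(seed),
         percentiles = sort(percentiles)),
    class = "mc_config"
  )
}

#' Draw concentrations from a zero-truncated normal distribution
#'
#' Draws from Normal(mean, sd) with negative values rejected and redrawn,
#' modelling measurement variability around the replicate mean while
#' keeping concentrations physically non-negative. With `sd = 0` every
#' draw equals the mean.
#'
#' @param mean Replicate mean concentration, mg/kg (>= 0).
#' @param sd Replicate standard deviation, mg/kg (>= 0).
#' @param n Number of draws.
#' @param seed Optional integer seed set before drawing.
#' @return Numeric vector of `n` non-negative draws.
#' @export
sample_concentrations <- function(mean, sd, n, seed = NULL) {
  if (!is.numeric(sd) || length(sd) != 1 || is.na(sd) || sd < 0) {
    rlang::abort("sd must be a single number >= 0",
                 class = "herbrisk_domain_error")
  }
  if (!is.numeric(mean) || length(mean) != 1 || is.na(mean) || mean < 0) {
    rlang::abort("mean must be a single number >= 0",
                 class = "herbrisk_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(rep(mean, n))
  draws <- stats::rnorm(n, mean, sd)
  neg <- which(draws < 0)
  while (length(neg) > 0) {
    draws[neg] <- stats::rnorm(length(neg), mean, sd)
    neg <- neg[draws[neg] < 0]
  }
  draws
}

#' Empirical percentile with linear interpolation
#'
#' The standard linear-interpolation quantile of the draws (type 7
#' convention, interpolating between adjacent order statistics).
#'
#' @param draws Non-empty numeric vector.
#' @param q Fraction(s) in `[0, 1]`.
#' @return The empirical quantile(s).
#' @export
percentile <- function(draws, q) {
  if (length(draws) == 0) {
    rlang::abort("cannot take a percentile of zero draws",
                 class = "herbrisk_insufficient_data_error")
  }
  unname(stats::quantile(draws, probs = q, type = 7, names = FALSE))
}

#' Probabilistic (Monte Carlo) risk assessment
#'
#' Propagates concentration uncertainty through the ingestion risk chain.
#' For every detected (sample, element) cell the replicate mean and SD
#' parameterise a zero-truncated normal; each iteration draws one
#' concentration per element, computes EDI, THQ and (where a CSF exists)
#' CR, and sums THQ across the sample's elements into a per-iteration
#' hazard index. Requested percentiles of each metric are then taken over
#' iterations - the HI is quantiled over its own per-iteration sums, not
#' assembled from per-element quantiles.
#'
#' @inheritParams deterministic_risk_table
#' @param cfg An [mc_config()] object.
#' @param keep_draws If `TRUE`, attach the per-iteration draw matrices as
#'   attribute `"draws"` (a list per sample with `conc`, `edi`, `thq`,
#'   `cr` matrices and the `hi` vector).
#' @return A tibble of class `prob_risk` with columns `sample_id`,
#'   `element` (`"HI"` for the hazard-index rows), `metric` (`EDI`,
#'   `THQ`, `CR` or `HI`), `percentile`, `value`.
#' @export
monte_carlo_risk <- function(ms, tox, params = exposure_parameters(),
                             cfg = mc_config(), keep_draws = FALSE) {
  stopifnot(inherits(cfg, "mc_config"))
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
  moments <- det |>
    dplyr::group_by(.data$sample_id, .data$element) |>
    dplyr::summarise(mean = mean(.data$concentration),
                     sd = if (dplyr::n() > 1) stats::sd(.data$concentration) else 0,
                     .groups = "drop") |>
    dplyr::arrange(.data$sample_id, .data$element)

  set.seed(cfg$seed)
  n <- cfg$n_iterations
  out <- list()
  draws_by_sample <- list()
  for (s in unique(moments$sample_id)) {
    cell <- moments[moments$sample_id == s, , drop = FALSE]
    conc <- vapply(seq_len(nrow(cell)), function(i) {
      sample_concentrations(cell$mean[i], cell$sd[i], n)
    }, double(n))
    conc <- matrix(conc, nrow = n,
                   dimnames = list(NULL, cell$element))
    edi <- estimated_daily_intake(conc, params)
    idx <- match(cell$element, tox$element)
    thq <- sweep(edi, 2, tox$rfd[idx], `/`)
    csf <- tox$csf[idx]
    cr <- sweep(edi, 2, ifelse(is.na(csf), NA_real_, csf), `*`)
    hi <- rowSums(thq)

    rows <- lapply(seq_len(nrow(cell)), function(i) {
      el <- cell$element[i]
      metrics <- list(EDI = edi[, i], THQ = thq[, i])
      if (!is.na(csf[i])) metrics$CR <- cr[, i]
      dplyr::bind_rows(lapply(names(metrics), function(mname) {
        tibble::tibble(
          sample_id = s, element = el, metric = mname,
          percentile = cfg$percentiles,
          value = percentile(metrics[[mname]], cfg$percentiles)
        )
      }))
    })
    hi_rows <- tibble::tibble(
      sample_id = s, element = "HI", metric = "HI",
      percentile = cfg$percentiles,
      value = percentile(hi, cfg$percentiles)
    )
    out[[s]] <- dplyr::bind_rows(c(rows, list(hi_rows)))
    if (keep_draws) {
      draws_by_sample[[s]] <- list(conc = conc, edi = edi, thq = thq,
                                   cr = cr, hi = hi)
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("prob_risk", class(res))
  if (keep_draws) attr(res, "draws") <- draws_by_sample
  res
}

#' Closed-form quantile of the zero-truncated normal
#'
#' Quantile of Normal(mean, sd) conditioned on being non-negative; the
#' distribution [sample_concentrations()] draws from. Used as an
#' independent check on simulated percentile ratios.
#'
#' @param q Fraction(s) in (0, 1).
#' @param mean,sd Parameters of the parent normal (`mean >= 0`, `sd > 0`).
#' @return The truncated-normal quantile(s).
#' @export
truncnorm_quantile <- function(q, mean, sd) {
  f0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(f0 + q * (1 - f0), mean, sd)
}
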