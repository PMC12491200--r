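#' Generate replicate elemental measurements with non-detects
#'
#' Emulates the design of a triplicate ICP-OES campaign: each
#' (sample, element) cell has a true mean and a coefficient of variation;
#' replicates are drawn from Normal(mean, mean * cv / 100) truncated at
#' zero by resampling. With probability `nd_probability` the entire cell is
#' emitted as non-detect - mirroring how instruments report an element as
#' "ND" for a sample rather than per replicate. CV-parameterised noise (as
#' opposed to an absolute SD) keeps fixtures realistic across the several
#' orders of magnitude that elemental concentrations span.
#'
#' @param spec A data frame with columns `sample_id`, `element`,
#'   `true_mean` (mg/kg, >= 0), `true_cv` (%, >= 0) and optionally
#'   `n_replicates` (default 3, >= 2) and `nd_probability` (default 0,
#'   in `[0, 1]`).
#' @param seed Integer seed for reproducibility.
#' @return A [as_measurement_set()] tibble.
#' @export
#' @examples
#' spec <- data.frame(sample_id = "A", element = "Mn",
#'                    true_mean = 1.49e-2, true_cv = 7.99)
#' generate_measurements(spec, seed = 1)
generate_measurements <- function(spec, seed = 1L) {
  spec <- tibble::as_tibble(spec)
  required <- c("sample_id", "element", "true_mean", "true_cv")
  missing_cols <- setdiff(required, names(spec))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("generator spec is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "herbrisk_schema_error")
  }
  if (!"n_replicates" %in% names(spec)) spec$n_replicates <- 3L
  if (!"nd_probability" %in% names(spec)) spec$nd_probability <- 0
  if (any(spec$true_mean < 0) || any(spec$true_cv < 0)) {
    rlang::abort("true_mean and true_cv must be >= 0",
                 class = "herbrisk_validation_error")
  }
  if (any(spec$n_replicates < 2)) {
    rlang::abort("n_replicates must be >= 2",
                 class = "herbrisk_validation_error")
  }
  if (any(spec$nd_probability < 0 | spec$nd_probability > 1)) {
    rlang::abort("nd_probability must lie in [0, 1]",
                 class = "herbrisk_validation_error")
  }
  set.seed(seed)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    n <- spec$n_replicates[i]
    nd <- stats::runif(1) < spec$nd_probability[i]
    if (nd) {
      conc <- rep(NA_real_, n)
    } else {
      sd <- spec$true_mean[i] * spec$true_cv[i] / 100
      conc <- sample_concentrations(spec$true_mean[i], sd, n)
    }
    tibble::tibble(
      sample_id = spec$sample_id[i], element = spec$element[i],
      replicate = seq_len(n), concentration = conc,
      nondetect = rep(nd, n)
    )
  })
  as_measurement_set(dplyr::bind_rows(rows))
}

#' Generate a calibration blank series
#'
#' Blank signal readings drawn from Normal(0, true_sd), paired with a
#' calibration slope, for exercising the 3-sigma LOD rule:
#' [compute_lod()] on the output is approximately `3 * true_sd / slope`
#' in expectation (the sample SD at small n is slightly downward biased).
#'
#' @param element Element label.
#' @param true_sd True standard deviation of the blank signal (>= 0).
#' @param slope Calibration slope, > 0.
#' @param n Number of blank readings, default 3.
#' @param seed Integer seed.
#' @return A list with `element`, `blank_signals`, `slope`.
#' @export
generate_blank_series <- function(element, true_sd, slope, n = 3L, seed = 1L) {
  if (!is.numeric(true_sd) || true_sd < 0) {
    rlang::abort("true_sd must be >= 0", class = "herbrisk_domain_error")
  }
  if (!is.numeric(slope) || slope <= 0) {
    rlang::abort("slope must be > 0", class = "herbrisk_domain_error")
  }
  if (n < 2) {
    rlang::abort("need at least 2 blank readings",
                 class = "herbrisk_validation_error")
  }
  set.seed(seed)
  list(element = element,
       blank_signals = stats::rnorm(n, 0, true_sd),
       slope = slope)
}

#' Generate a synthetic GC-MS identified-compound table
#'
#' Random peak areas are converted to relative abundances (summing to 100
#' per sample before masking); classes are drawn from a palette; a fraction
#' of (compound, sample) cells can be masked to absent, after which totals
#' fall strictly below 100.
#'
#' @param n_compounds Number of compounds, >= 1.
#' @param class_palette Non-empty character vector of class labels.
#' @param sample_ids Sample identifiers, default `c("A", "B", "C")`.
#' @param mask_prob Probability a (compound, sample) cell is absent.
#' @param seed Integer seed.
#' @return A long tibble shaped like [read_compound_table()] output.
#' @export
generate_compound_table <- function(n_compounds, class_palette,
                                    sample_ids = c("A", "B", "C"),
                                    mask_prob = 0, seed = 1L) {
  if (n_compounds < 1) {
    rlang::abort("n_compounds must be >= 1",
                 class = "herbrisk_validation_error")
  }
  if (length(class_palette) == 0) {
    rlang::abort("class_palette must not be empty",
                 class = "herbrisk_validation_error")
  }
  set.seed(seed)
  classes <- sample(class_palette, n_compounds, replace = TRUE)
  rt <- sort(stats::runif(n_compounds, 3, 46))
  wide <- tibble::tibble(
    record_id = seq_len(n_compounds),
    name = sprintf("compound_%02d", seq_len(n_compounds)),
    formula = sprintf("C%dH%d", 8 + seq_len(n_compounds),
                      18 + 2 * seq_len(n_compounds)),
    compound_class = classes,
    retention_time = rt
  )
  for (s in sample_ids) {
    areas <- stats::rlnorm(n_compounds, meanlog = 0, sdlog = 1)
    ab <- relative_abundance(areas)
    masked <- stats::runif(n_compounds) < mask_prob
    ab[masked] <- NA_real_
    wide[[s]] <- ab
  }
  tidyr::pivot_longer(wide, cols = dplyr::all_of(sample_ids),
                      names_to = "sample_id", values_to = "abundance")
}
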