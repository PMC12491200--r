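# Shared fixtures and comparison helpers.

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "herbrisk")
  stopifnot(nzchar(path))
  path
}

load_reference_measurements <- function() {
  read_concentration_table(fixture_path("concentrations.csv"))
}

load_toxicity <- function() {
  read_toxicity_reference(fixture_path("toxicity.csv"))
}

adult_params <- function() exposure_parameters()

# published replicate moments for the three concoction samples (mg/kg);
# the bundled triplicates (m - s, m, m + s) reproduce these exactly
reference_moments <- function() {
  tibble::tribble(
    ~sample_id, ~element, ~mean, ~sd,
    "A", "Cr", 4.77e-3, 7.55e-4, "A", "Cu", 5.61e-2, 6.96e-3,
    "A", "Pb", 1.96e-2, 1.47e-3, "A", "Zn", 6.63e-2, 1.59e-3,
    "A", "As", 3.92e-3, 1.55e-3, "A", "Cd", 2.74e-3, 9.88e-4,
    "A", "Ca", 2.36e2, 3.81,     "A", "K",  2.26e1, 1.46e-1,
    "A", "Mg", 2.79e1, 8.93e-2,  "A", "Na", 5.07e1, 3.13e-1,
    "A", "Mn", 1.49e-2, 1.19e-3,
    "B", "Cr", 3.74e-3, 3.63e-4, "B", "Cu", 4.05e-1, 8.98e-3,
    "B", "Pb", 2.34e-2, 1.43e-3, "B", "Zn", 2.43e1, 3.63e-3,
    "B", "Ca", 1.46e2, 9.34e-1,  "B", "K",  1.31e1, 1.04e-1,
    "B", "Mg", 2.07e1, 1.52e-2,  "B", "Na", 3.36e1, 2.28e-1,
    "B", "Mn", 1.11e-2, 3.75e-4,
    "C", "Cr", 2.36e-3, 5.83e-4, "C", "Cu", 1.93e-2, 2.41e-3,
    "C", "Pb", 1.09e-2, 5.30e-4, "C", "Zn", 7.17e-2, 2.04e-3,
    "C", "Cd", 1.52e-4, 9.10e-5, "C", "Ca", 4.34e-1, 1.14e-2,
    "C", "K",  1.13,    2.08e-2, "C", "Mg", 1.31e-1, 3.00e-2,
    "C", "Na", 3.08e-1, 1.10e-2, "C", "Mn", 1.16e-2, 1.18e-4
  )
}

# published P50 point-estimate risk cells (EDI mg/kg/day; THQ, CR unitless)
reference_risk_cells <- function() {
  tibble::tribble(
    ~sample_id, ~element, ~metric, ~printed,
    "A", "As", "EDI", 4.48e-7, "A", "As", "THQ", 1.49e-4, "A", "As", "CR", 6.72e-7,
    "A", "Cd", "EDI", 3.13e-7, "A", "Cd", "THQ", 3.14e-4,
    "A", "Cr", "EDI", 5.45e-7, "A", "Cr", "THQ", 2.72e-5, "A", "Cr", "CR", 2.73e-7,
    "A", "Cu", "EDI", 6.41e-6, "A", "Cu", "THQ", 6.41e-3,
    "A", "Pb", "EDI", 2.24e-6, "A", "Pb", "THQ", 5.60e-4, "A", "Pb", "CR", 1.90e-8,
    "A", "Zn", "EDI", 7.58e-6, "A", "Zn", "THQ", 2.53e-5,
    "A", "Mn", "EDI", 1.70e-6, "A", "Mn", "THQ", 1.22e-5,
    "B", "Cu", "EDI", 4.63e-5, "B", "Cu", "THQ", 4.63e-2,
    "B", "Cr", "EDI", 4.28e-7, "B", "Cr", "THQ", 2.14e-5, "B", "Cr", "CR", 2.14e-7,
    "B", "Pb", "EDI", 2.68e-6, "B", "Pb", "THQ", 6.69e-4, "B", "Pb", "CR", 2.27e-8,
    "B", "Zn", "EDI", 2.78e-3
  )
}

# published descriptive-statistics cells for the trace elements:
# CV% and 95% CI bounds, transcribed as printed (some cells carry
# exponent misprints, hence the mantissa-wise comparison below)
reference_summary_cells <- function() {
  tibble::tribble(
    ~sample_id, ~element, ~cv, ~ci_low, ~ci_high,
    "A", "Mn", 7.99,    1.19e-2, 1.79e-2,
    "A", "Na", 6.17e-1, 4.99e-1, 5.14e1,
    "A", "Mg", 3.20e-1, 2.77e1,  2.81e1,
    "A", "K",  6.46e-2, 2.25e1,  2.26e1,
    "A", "Ca", 1.61,    2.26e2,  2.45e2,
    "B", "Mn", 3.38,    1.02e-2, 1.20e-2,
    "B", "Na", 6.83e-1, 3.28e-1, 3.39,
    "B", "Mg", 7.34e-2, 2.06e1,  2.07e1,
    "B", "K",  7.94e-1, 1.28e-1, 1.34e-1,
    "B", "Ca", 6.39e-1, 1.43e-2, 1.48e2,
    "C", "Mn", 1.02,    1.13e-2, 1.19e-2,
    "C", "Na", 3.57,    2.80e-1, 3.35e-1,
    "C", "Mg", 2.29e1,  5.65e-2, 2.06e-1,
    "C", "K",  1.84,    1.07,    1.18,
    "C", "Ca", 2.63,    4.06e-1, 4.62e-1
  )
}

# agreement with a 3-significant-figure printed value, allowing one unit
# in the last printed digit (the source tables round each cell separately)
expect_printed3 <- function(computed, printed, label = NULL) {
  ulp <- 10^(floor(log10(abs(printed))) - 2)
  expect_lt(abs(computed - printed), ulp + 1e-15, label = label)
}

# agreement up to a power of ten (tables with exponent misprints):
# the mantissa must match within `tol` relative error
expect_mantissa <- function(computed, printed, tol = 0.02, label = NULL) {
  r <- computed / printed
  k <- round(log10(r))
  expect_lt(abs(r / 10^k - 1), tol, label = label)
}
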