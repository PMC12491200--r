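test_that("concentration draws respect the truncated-normal contract", {
  # degenerate spread: every draw equals the mean
  expect_equal(sample_concentrations(3.92e-3, 0, 50), rep(3.92e-3, 50))
  expect_error(sample_concentrations(1, -0.1, 10),
               class = "herbrisk_domain_error")

  draws <- sample_concentrations(3.92e-3, 1.55e-3, 10000, seed = 11)
  expect_true(all(draws >= 0))
  # empirical mean within 3 SE of the closed-form truncated-normal mean
  a <- 3.92e-3 / 1.55e-3
  m_trunc <- 3.92e-3 + 1.55e-3 * dnorm(a) / pnorm(a)
  expect_lt(abs(mean(draws) - m_trunc), 3 * 1.55e-3 / sqrt(10000))
  # ... which itself sits within the truncation shift of the parent mean
  expect_lt(abs(mean(draws) - 3.92e-3),
            3 * 1.55e-3 / sqrt(10000) + (m_trunc - 3.92e-3))

  # heavy truncation still yields only non-negative draws
  expect_true(all(sample_concentrations(1e-4, 1e-2, 5000, seed = 3) >= 0))

  # identical seed, identical draws
  expect_identical(sample_concentrations(1, 0.3, 100, seed = 5),
                   sample_concentrations(1, 0.3, 100, seed = 5))
})

test_that("percentiles interpolate linearly between order statistics", {
  expect_equal(percentile(c(1, 2, 3, 4, 5), 0.5), 3)
  expect_equal(percentile(rep(7, 20), c(0.1, 0.5, 0.99)), rep(7, 3))
  expect_error(percentile(numeric(0), 0.5),
               class = "herbrisk_insufficient_data_error")
  set.seed(21)
  u <- runif(10000)
  expect_lt(abs(percentile(u, 0.95) - 0.95), 0.02)
  # agrees with the type-7 convention
  expect_equal(percentile(u, c(0.5, 0.95)),
               unname(quantile(u, c(0.5, 0.95), type = 7)))
})

test_that("zero-spread fixtures collapse the simulation to the point estimate", {
  spec <- data.frame(
    sample_id = "A",
    element = c("As", "Cu", "Pb"),
    true_mean = c(3.92e-3, 5.61e-2, 1.96e-2),
    true_cv = 0
  )
  ms <- generate_measurements(spec, seed = 1)
  tox <- load_toxicity()
  det <- deterministic_risk_table(ms, tox, adult_params())
  mc <- monte_carlo_risk(ms, tox, adult_params(),
                         mc_config(n_iterations = 500, seed = 9))
  for (el in spec$element) {
    row <- det$risk[det$risk$element == el, ]
    for (pq in c(0.5, 0.95)) {
      expect_equal(
        mc$value[mc$element == el & mc$metric == "EDI" & mc$percentile == pq],
        row$edi)
      expect_equal(
        mc$value[mc$element == el & mc$metric == "THQ" & mc$percentile == pq],
        row$thq)
    }
  }
  hi <- mc$value[mc$metric == "HI"]
  expect_equal(hi, rep(det$hazard_index$hi, 2))
})

test_that("simulated percentiles are monotone, reproducible, and consistent
           with the truncated-normal quantiles", {
  ms <- load_reference_measurements()
  tox <- load_toxicity()
  ms_a <- ms[ms$sample_id == "A" & ms$element %in% tox$element, ]
  cfg <- mc_config(n_iterations = 10000, seed = 101)
  mc <- monte_carlo_risk(ms_a, tox, adult_params(), cfg, keep_draws = TRUE)

  # P95 >= P50 for every record
  wide <- tidyr::pivot_wider(mc, names_from = "percentile",
                             values_from = "value")
  expect_true(all(wide$`0.95` >= wide$`0.5`))

  # P50 EDI within 2% of the deterministic value (symmetric parent,
  # < 1% truncation mass for As)
  det <- deterministic_risk_table(ms_a, tox, adult_params())
  p50_as <- mc$value[mc$element == "As" & mc$metric == "EDI" &
                       mc$percentile == 0.5]
  expect_lt(abs(p50_as / det$risk$edi[det$risk$element == "As"] - 1), 0.02)

  # P95/P50 ratio matches the closed-form truncated-normal ratio within 5%
  p95_as <- mc$value[mc$element == "As" & mc$metric == "EDI" &
                       mc$percentile == 0.95]
  q <- truncnorm_quantile(c(0.5, 0.95), 3.92e-3, 1.55e-3)
  expect_lt(abs((p95_as / p50_as) / (q[2] / q[1]) - 1), 0.05)
  # ... and the normal approximation 1 + 1.645 * cv is close behind
  expect_lt(abs((p95_as / p50_as) / (1 + 1.645 * 1.55e-3 / 3.92e-3) - 1),
            0.05)

  # HI per iteration is exactly the row sum of the THQ draws
  draws <- attr(mc, "draws")$A
  expect_equal(draws$hi, rowSums(draws$thq), tolerance = 1e-15)

  # fixed seed -> bit-identical output
  mc2 <- monte_carlo_risk(ms_a, tox, adult_params(), cfg)
  expect_identical(mc$value, mc2$value)

  # a different seed moves the stochastic quantiles
  mc3 <- monte_carlo_risk(ms_a, tox, adult_params(),
                          mc_config(n_iterations = 10000, seed = 102))
  expect_false(identical(mc3$value, mc2$value))
  # ... but P50 stays within the Monte Carlo band of the point estimate
  p50_b <- mc3$value[mc3$element == "As" & mc3$metric == "EDI" &
                       mc3$percentile == 0.5]
  expect_lt(abs(p50_b / det$risk$edi[det$risk$element == "As"] - 1), 0.02)
})

test_that("simulation configuration is validated", {
  expect_error(mc_config(n_iterations = 10),
               class = "herbrisk_validation_error")
  expect_error(mc_config(percentiles = c(0, 0.5)),
               class = "herbrisk_validation_error")
})
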