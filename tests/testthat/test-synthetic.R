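test_that("generated measurements honour the generator contract", {
  spec <- data.frame(sample_id = "A", element = c("Mn", "Zn"),
                     true_mean = c(1.49e-2, 6.63e-2), true_cv = c(7.99, 0))
  ms <- generate_measurements(spec, seed = 4)
  expect_s3_class(ms, "measurement_set")
  expect_equal(nrow(ms), 6)
  # zero CV: identical replicates
  zn <- ms$concentration[ms$element == "Zn"]
  expect_equal(zn, rep(6.63e-2, 3))
  # reproducible under the same seed
  expect_identical(ms, generate_measurements(spec, seed = 4))
  expect_false(identical(ms$concentration,
                         generate_measurements(spec, seed = 5)$concentration))

  # nd_probability = 1: the whole cell is non-detect
  spec$nd_probability <- 1
  nd <- generate_measurements(spec, seed = 4)
  expect_true(all(nd$nondetect))
  expect_true(all(is.na(nd$concentration)))

  expect_error(generate_measurements(data.frame(sample_id = "A",
                                                element = "Mn",
                                                true_mean = -1,
                                                true_cv = 5)),
               class = "herbrisk_validation_error")
  expect_error(generate_measurements(transform(spec, n_replicates = 1)),
               class = "herbrisk_validation_error")
})

test_that("summaries recover the generator's parameters over many seeds", {
  true_mean <- 1.49e-2
  true_cv <- 7.99
  n_rep <- 1000
  spec <- data.frame(sample_id = sprintf("s%04d", seq_len(n_rep)),
                     element = "Mn", true_mean = true_mean,
                     true_cv = true_cv)
  ms <- generate_measurements(spec, seed = 2024)
  summ <- concentration_summary(ms)
  expect_equal(nrow(summ), n_rep)
  # grand mean within 3 SE of the truth (3 replicates x 1000 cells)
  true_sd <- true_mean * true_cv / 100
  se <- true_sd / sqrt(3 * n_rep)
  expect_lt(abs(mean(summ$mean) - true_mean), 3 * se)
  # average CV consistent with n = 3 sampling error: E[s] = c4 * sigma
  c4 <- sqrt(2 / 2) * gamma(3 / 2) / gamma(1)
  expect_lt(abs(mean(summ$cv_percent) / (c4 * true_cv) - 1), 0.05)
})

test_that("generated blank series feed the LOD rule correctly", {
  s0 <- generate_blank_series("Cd", true_sd = 0, slope = 2, seed = 1)
  expect_equal(compute_lod(s0), 0)
  expect_identical(generate_blank_series("Cd", 1e-5, 2, seed = 9),
                   generate_blank_series("Cd", 1e-5, 2, seed = 9))
  expect_error(generate_blank_series("Cd", 1e-5, slope = 0),
               class = "herbrisk_domain_error")

  # small-n recovery: with n = 6 blanks the mean LOD over 1,000 seeds is
  # within 10% of 3 * sd / slope (the sample SD is biased low by c4(n))
  true_sd <- 2.5e-5
  lods <- vapply(seq_len(1000), function(seed) {
    compute_lod(generate_blank_series("Cd", true_sd, slope = 2, n = 6,
                                      seed = seed))
  }, double(1))
  expect_lt(abs(mean(lods) / (3 * true_sd / 2) - 1), 0.10)

  # at n = 3 the downward bias matches the closed-form c4 factor
  lods3 <- vapply(seq_len(1000), function(seed) {
    compute_lod(generate_blank_series("Cd", true_sd, slope = 2, n = 3,
                                      seed = seed))
  }, double(1))
  c4_3 <- sqrt(2 / 2) * gamma(3 / 2) / gamma(1)
  expect_lt(abs(mean(lods3) / (c4_3 * 3 * true_sd / 2) - 1), 0.03)
})

test_that("generated compound tables close to 100% before masking", {
  one <- generate_compound_table(1, "Alkane", sample_ids = "A", seed = 1)
  expect_equal(one$abundance, 100)

  tbl <- generate_compound_table(25, c("Alkane", "Ester", "Ketone"),
                                 seed = 31)
  for (s in c("A", "B", "C")) {
    expect_equal(sum(tbl$abundance[tbl$sample_id == s]), 100,
                 tolerance = 1e-12)
  }

  masked <- generate_compound_table(25, c("Alkane", "Ester"),
                                    mask_prob = 0.2, seed = 31)
  for (s in c("A", "B", "C")) {
    tot <- aggregate_by_class(masked, s)$total_identified
    expect_lt(tot, 100)
  }
  expect_error(generate_compound_table(0, "Alkane"),
               class = "herbrisk_validation_error")
  expect_error(generate_compound_table(5, character(0)),
               class = "herbrisk_validation_error")
})

test_that("a zero-spread generated set reproduces the point-estimate block", {
  moments <- reference_moments()
  a <- moments[moments$sample_id == "A" &
                 moments$element %in% load_toxicity()$element, ]
  spec <- data.frame(sample_id = "A", element = a$element,
                     true_mean = a$mean, true_cv = 0)
  ms <- generate_measurements(spec, seed = 8)
  tox <- load_toxicity()
  det <- deterministic_risk_table(ms, tox, adult_params())
  cells <- reference_risk_cells()
  cells <- cells[cells$sample_id == "A", ]
  for (i in seq_len(nrow(cells))) {
    row <- det$risk[det$risk$element == cells$element[i], ]
    got <- switch(cells$metric[i], EDI = row$edi, THQ = row$thq,
                  CR = row$cr)
    expect_printed3(got, cells$printed[i],
                    label = paste(cells$element[i], cells$metric[i]))
  }
})
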