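test_that("trimming removes the first and last minute and composes additively", {
  tr <- linear_trace(duration = 900)
  trimmed <- trim_trace(tr, 60)
  expect_equal(range(trimmed$time), c(60, 840))
  expect_identical(trim_trace(tr, 0), tr)

  # composition: trim a then b equals a single trim of a + b
  once <- trim_trace(trim_trace(tr, 40), 20)
  both <- trim_trace(tr, 60)
  expect_equal(once$time, both$time)
  expect_equal(once$o2, both$o2)

  short <- linear_trace(duration = 100)
  expect_error(trim_trace(short, 60), class = "short_trace")
})

test_that("slope fitting matches the closed-form OLS oracle", {
  # noiseless linear input
  tr <- linear_trace(slope = -0.001, intercept = 8)
  fit <- fit_slope(tr)
  expect_equal(fit$slope, -0.001)
  expect_equal(fit$intercept, 8)
  expect_equal(fit$r_squared, 1)

  # noisy synthetic traces agree with the independent closed form
  set.seed(11)
  for (i in 1:5) {
    tt <- sort(sample(0:900, 200))
    y <- 8 - 4e-4 * tt + rnorm(200, 0, 0.02)
    fit <- fit_slope(o2_trace(tt, y))
    oracle <- ols_oracle(tt, y)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-12)
  }

  # constant trace: zero slope, R^2 reported as 0 by convention
  flat <- o2_trace(0:100, rep(7.5, 101))
  fit <- fit_slope(flat)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)

  expect_error(fit_slope(o2_trace(1, 8)), class = "degenerate_fit")
})

test_that("background interpolation is linear in elapsed time and clamps", {
  bp <- blank_pair("AC1", pre_rate = 0.10, post_rate = 0.30,
                   pre_time = 0, post_time = 1000)
  expect_equal(blank_rate_at(bp, 500), 0.20)
  expect_equal(blank_rate_at(bp, 250), 0.15)
  # clamped outside the measured span
  expect_equal(blank_rate_at(bp, -50), 0.10)
  expect_equal(blank_rate_at(bp, 2000), 0.30)

  # 25% of span with pre 0, post 0.4
  bp2 <- blank_pair("AC1", 0, 0.4, 100, 500)
  expect_equal(blank_rate_at(bp2, 200), 0.1)

  # constant blanks are constant at any t
  bp3 <- blank_pair("AC1", 0.15, 0.15, 0, 1000)
  expect_equal(blank_rate_at(bp3, c(0, 333, 1000)), rep(0.15, 3))

  # degenerate pair (equal times) returns pre_rate
  bp4 <- blank_pair("AC1", 0.12, 0.40, 500, 500)
  expect_equal(blank_rate_at(bp4, 500), 0.12)
})

test_that("mass-specific conversion applies volume, time and mass units", {
  spec <- chamber_spec("AC1", animal_mass = 60, volume = 0.560)  # V_eff 0.5 L
  expect_equal(spec$effective_volume, 0.5)
  fit <- structure(list(slope = -0.0005, intercept = 8, r_squared = 0.99,
                        n_points = 800, min_saturation_fraction = 0.95),
                   class = "slope_fit")
  rec <- mass_specific_rate(fit, spec, zero_blanks, t_mid = 450)
  expect_equal(rec$rate, 15.0)  # 0.0005 * 0.5 * 3600 * 1000 / 60
  expect_true(rec$qc_pass)

  fit0 <- fit
  fit0$slope <- 0
  expect_equal(mass_specific_rate(fit0, spec, zero_blanks, 450)$rate, 0)

  # rate is linear in slope magnitude at zero blank
  fit2 <- fit
  fit2$slope <- 2 * fit$slope
  expect_equal(mass_specific_rate(fit2, spec, zero_blanks, 450)$rate,
               2 * rec$rate)
})

test_that("quality gates flag low R2, low saturation, and negative rates", {
  spec <- chamber_spec("AC1", animal_mass = 60)
  fit <- structure(list(slope = -0.0005, intercept = 8, r_squared = 0.85,
                        n_points = 800, min_saturation_fraction = 0.95),
                   class = "slope_fit")
  rec <- mass_specific_rate(fit, spec, zero_blanks, 450)
  expect_false(rec$qc_pass)
  expect_equal(rec$qc_reasons, "LOW_R2")

  fit$r_squared <- 0.99
  fit$min_saturation_fraction <- 0.7
  rec <- mass_specific_rate(fit, spec, zero_blanks, 450)
  expect_equal(rec$qc_reasons, "LOW_SATURATION")

  # blank larger than the whole-chamber rate: value retained, flagged
  big_blank <- blank_pair("AC1", 5, 5, 0, 1000)
  fit$min_saturation_fraction <- 0.95
  rec <- mass_specific_rate(fit, spec, big_blank, 450)
  expect_false(rec$qc_pass)
  expect_match(rec$qc_reasons, "NEGATIVE_RATE")
  expect_lt(rec$rate, 0)  # not clipped
})

test_that("blank subtraction recovers the animal-only rate from mixed decline", {
  # a trace whose decline is animal + microbial, with the microbial component
  # fed back as the blank pair, must return the animal-only rate exactly
  spec <- chamber_spec("AC1", animal_mass = 60, volume = 0.560)
  animal_rate <- 12                                    # ug/g/h
  animal_mg_h <- animal_rate * 60 / 1000
  blank_mg_h <- 0.25
  slope <- -(animal_mg_h + blank_mg_h) / 0.5 / 3600
  tr <- linear_trace(slope = slope, intercept = 8)
  fit <- fit_slope(trim_trace(tr, 60))
  bp <- blank_pair("AC1", blank_mg_h, blank_mg_h, 0, 1000)
  rec <- mass_specific_rate(fit, spec, bp, 450)
  expect_equal(rec$rate, animal_rate, tolerance = 1e-9)
})

test_that("batch processing validates its input schema", {
  st <- simulate_study(seed = 3, n_per_ramp = 2, warm_end = 33, cold_end = 25)
  bad <- st$traces[, setdiff(names(st$traces), "o2_mg_per_l")]
  expect_error(process_traces(bad, st$metadata), class = "schema_error")
  expect_error(process_traces(bad, st$metadata), "o2_mg_per_l")
  expect_error(process_traces(st$traces[0, ], st$metadata),
               class = "empty_input")
  expect_error(
    process_traces(st$traces,
                   st$metadata[st$metadata$chamber_id != "W1", ]),
    class = "schema_error")
})
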