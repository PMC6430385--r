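test_that("profile aggregation computes per-temperature means and excludes QC failures", {
  recs <- data.frame(
    chamber_id = "A", cycle_id = 1:7,
    nominal_temperature = c(29, 29, 29, 31, 29, 31, 31),
    rate = c(10, 12, 14, 20, 99, 21, 22),
    qc_pass = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    qc_reasons = c("", "", "", "", "LOW_R2", "", ""),
    stringsAsFactors = FALSE)
  prof <- aggregate_profile(recs)
  r29 <- prof[prof$temperature == 29, ]
  expect_equal(r29$mean_rate, 12)
  expect_equal(r29$sd_rate, 2)
  expect_equal(r29$n, 3L)  # the failing record is not counted
  expect_equal(attr(prof, "excluded"), 1L)

  single <- aggregate_profile(recs[1, ])
  expect_equal(single$sd_rate, 0)
  expect_equal(single$flags, "N_EQ_1")

  expect_error(aggregate_profile(recs[0, ]), class = "empty_input")
  all_fail <- recs
  all_fail$qc_pass <- FALSE
  expect_error(aggregate_profile(all_fail), class = "empty_input")
})

test_that("window detection recovers the break temperatures of a noiseless profile", {
  prof <- paper_shaped_profile()
  win <- find_linear_window(prof)
  expect_equal(win$t_low, 22)
  expect_equal(win$t_high, 38)
  expect_equal(win$r_squared, 1, tolerance = 1e-12)
  expect_equal(win$slope, (33.2 - 2.2) / 16, tolerance = 1e-9)

  # an exactly linear stretch bounded by plateau and collapse keeps its ends
  # even when the plateau/collapse rows would pass a loose global R^2 gate
  prof2 <- make_profile(20:40, c(rep(5, 5), 5 + 2 * (1:12), 29 - 6 * (1:4)))
  win2 <- find_linear_window(prof2)
  expect_equal(win2$t_low, 24)
  expect_equal(win2$t_high, 36)

  flat <- make_profile(20:30, rep(7, 11))
  expect_error(find_linear_window(flat), class = "no_window")
})

test_that("extremes anchor to the window edges with diagnostic warnings", {
  prof <- paper_shaped_profile()
  win <- find_linear_window(prof)
  ext <- detect_extremes(prof, win)
  expect_equal(ext$TMMR, 33.2)
  expect_equal(ext$WT_crit, 38)
  expect_equal(ext$TSMR, 2.2)
  expect_equal(ext$CT_crit, 22)
  expect_length(ext$warnings, 0)

  # monotone increasing profile: the downturn was never observed
  mono <- make_profile(22:38, 2 + 2 * (0:16))
  wmono <- find_linear_window(mono)
  extm <- detect_extremes(mono, wmono)
  expect_true("CENSORED_PEAK" %in% extm$warnings)

  # plateau outlier beyond tolerance
  bump <- paper_shaped_profile()
  bump$mean_rate[bump$temperature == 19] <- 6
  bump$sd_rate <- 1
  extb <- detect_extremes(bump, find_linear_window(bump), plateau_tol = 1)
  expect_true("NO_PLATEAU" %in% extb$warnings)
})

test_that("aerobic scope is the TMMR - TSMR difference", {
  expect_equal(compute_tas(33.2, 2.2), 31)
  expect_equal(compute_tas(5, 5), 0)
  expect_equal(compute_tas(20, 5), 15)
  expect_error(compute_tas(2, 3), class = "bad_scope")
})

test_that("Q10 follows the van't Hoff form with its symmetries", {
  expect_equal(round(compute_q10(13.2, 33.2, 29, 38), 1), 2.8)
  expect_equal(round(compute_q10(2.2, 13.2, 22, 29), 1), 12.9)
  expect_equal(compute_q10(7, 7, 12, 30), 1)

  set.seed(5)
  for (i in 1:20) {
    r <- runif(2, 0.5, 40)
    tt <- sort(runif(2, 5, 45))
    q <- compute_q10(r[1], r[2], tt[1], tt[2])
    # endpoint-swap symmetry
    expect_equal(compute_q10(r[2], r[1], tt[2], tt[1]), q, tolerance = 1e-12)
    # scale invariance
    c0 <- runif(1, 0.1, 10)
    expect_equal(compute_q10(c0 * r[1], c0 * r[2], tt[1], tt[2]), q,
                 tolerance = 1e-12)
  }
  expect_error(compute_q10(0, 5, 20, 30), class = "bad_q10")
  expect_error(compute_q10(5, 5, 20, 20), class = "bad_q10")
})

test_that("the thermal optimum is the midpoint rate mapped through the window line", {
  win <- structure(list(t_low = 22, t_high = 38, slope = 2, intercept = -42,
                        r_squared = 1), class = "linear_window")
  opt <- thermal_optimum(30, 10, win)
  expect_equal(opt$r_mid, 20)
  expect_equal(opt$t_opt, 31.0)

  expect_equal(thermal_optimum(33.2, 2.2, win)$r_mid, 17.7)

  # degenerate scope clamps to the cold edge
  optd <- thermal_optimum(2, 2, win)
  expect_equal(optd$r_mid, 2)
  expect_equal(optd$t_opt, 22)

  # band spans acclimation temperature to t_opt
  expect_equal(opt$band$t_low, 29)
  expect_equal(opt$band$rate_low, -42 + 2 * 29)
})

test_that("shifting all profile rates shifts TMMR and TSMR but not TAS", {
  prof <- paper_shaped_profile()
  shift <- 7.5
  prof2 <- make_profile(prof$temperature, prof$mean_rate + shift)
  w1 <- find_linear_window(prof)
  w2 <- find_linear_window(prof2)
  e1 <- detect_extremes(prof, w1)
  e2 <- detect_extremes(prof2, w2)
  expect_equal(e2$TMMR, e1$TMMR + shift)
  expect_equal(e2$TSMR, e1$TSMR + shift)
  expect_equal(compute_tas(e2$TMMR, e2$TSMR), compute_tas(e1$TMMR, e1$TSMR))
})

test_that("the full analysis satisfies its internal identities", {
  st <- simulate_study(seed = 9)
  rates <- process_traces(st$traces, st$metadata)
  res <- thermal_window_analysis(rates)
  expect_equal(res$TAS, res$TMMR - res$TSMR)
  expect_gte(res$TMMR, res$TSMR)
  expect_true(res$CT_crit <= res$t_opt && res$t_opt <= res$WT_crit)
  expect_equal(res$r_mid, (res$TMMR + res$TSMR) / 2)
  js <- jsonlite::fromJSON(thermal_window_json(res))
  expect_equal(js$TAS, res$TAS)
})
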