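test_that("a periodic trace segments into one breath per cycle", {
  b <- segment_breaths(sine_trace(freq_hz = 2.5, duration_s = 10))
  expect_equal(nrow(b), 25)
  expect_true(all(abs(b$inst_rate_bpm - 150) < 2))
  # landmark ordering invariant
  expect_true(all(b$insp_onset_s < b$insp_peak_s))
  expect_true(all(b$insp_peak_s < b$exp_onset_s))
  expect_true(all(b$exp_onset_s <= b$exp_end_s))
})

test_that("degenerate traces yield an empty table with a warning", {
  flat <- tibble::tibble(time_s = seq(0, 5, by = 0.001), value = 3)
  expect_warning(b <- segment_breaths(flat), "constant")
  expect_equal(nrow(b), 0)
  short <- tibble::tibble(time_s = c(0, 0.001), value = c(0, 1))
  expect_warning(b2 <- segment_breaths(short), "short")
  expect_equal(nrow(b2), 0)
})

test_that("segmentation is scale invariant and time-shift equivariant", {
  sim <- sim_breath_trace(duration_s = 20, noise_sd = 0.05, seed = 5)
  b1 <- segment_breaths(sim$trace)
  scaled <- dplyr::mutate(sim$trace, value = value * 37)
  b2 <- segment_breaths(scaled)
  expect_equal(b2$insp_onset_s, b1$insp_onset_s)
  expect_equal(b2$insp_amplitude, 37 * b1$insp_amplitude)
  expect_equal(b2$exp_amplitude, 37 * b1$exp_amplitude)

  shifted <- dplyr::mutate(sim$trace, time_s = time_s + 100)
  b3 <- segment_breaths(shifted)
  expect_equal(b3$insp_onset_s, b1$insp_onset_s + 100)
  expect_equal(b3$duration_s, b1$duration_s)
})

test_that("segmentation recovers synthetic ground truth", {
  # exact count and onsets at zero noise
  sim <- sim_breath_trace(duration_s = 60, noise_sd = 0, seed = 1)
  b <- segment_breaths(sim$trace)
  expect_equal(nrow(b), length(sim$truth$breath_onsets_s))
  expect_true(all(abs(b$insp_onset_s - sim$truth$breath_onsets_s) < 0.02))

  # >= 95% of onsets within 20% of a breath period at 5% noise
  sim2 <- sim_breath_trace(duration_s = 60, noise_sd = 0.05, seed = 2)
  b2 <- segment_breaths(sim2$trace)
  period <- 60 / 150
  d <- vapply(sim2$truth$breath_onsets_s,
              function(o) min(abs(b2$insp_onset_s - o)), numeric(1))
  expect_gte(mean(d <= 0.2 * period), 0.95)
})

test_that("tidal volumes integrate inspiratory flow", {
  # rectangular inspiration: 1 ml/s for 0.2 s -> 0.2 ml
  t <- seq(0, 2.4, by = 1e-3)
  rect <- tibble::tibble(time_s = t,
                         value = ifelse((t - 0.5) %% 1 < 0.2 & t >= 0.5,
                                        1, -0.25))
  br <- segment_breaths(rect, kind = "flow")
  br <- compute_tidal_volumes(rect, br)
  expect_equal(br$tidal_volume_ml[1], 0.2, tolerance = 0.02)
  expect_equal(br$peak_insp_flow[1], 1, tolerance = 1e-6)

  # half-sine inspiration peak P width w -> 2 P w / pi
  sim <- sim_breath_trace(duration_s = 30, base_amplitude = 2.6,
                          kind = "flow", noise_sd = 0, seed = 1)
  b <- segment_breaths(sim$trace, kind = "flow")
  b <- compute_tidal_volumes(sim$trace, b)
  truth_tv <- sim$truth$breaths$tidal_volume_ml
  expect_equal(nrow(b), length(truth_tv))
  expect_true(all(abs(b$tidal_volume_ml - truth_tv) / truth_tv < 0.02))

  expect_error(compute_tidal_volumes(sim$trace, segment_breaths(sim$trace)),
               class = "reflexkit_error_kind")
})

test_that("eupneic filter removes out-of-range breaths and is idempotent", {
  b <- toy_breaths(exp_amp = rep(1, 6))
  b$tidal_volume_ml <- c(0.2, 2.5, 0.04, 0.3, 2, 0.05)
  b$inst_rate_bpm[4] <- 420
  res <- filter_eupneic(b)
  expect_equal(sort(res$breaths$breath), c(1, 5, 6))  # bounds inclusive
  excl <- setNames(res$exclusions$n_excluded, res$exclusions$rule)
  expect_equal(excl[["tv_max"]], 1)
  expect_equal(excl[["tv_min"]], 1)
  expect_equal(excl[["bpm_max"]], 1)
  expect_equal(excl[["total"]], 3)

  res2 <- filter_eupneic(res$breaths)
  expect_identical(res2$breaths, res$breaths)
  expect_equal(res2$exclusions$n_excluded, rep(0L, 4),
               ignore_attr = TRUE)

  # clean table passes untouched
  ok <- filter_eupneic(b[c(1, 5), ])
  expect_identical(ok$breaths, b[c(1, 5), ])
})

test_that("eupnea summaries average per-breath parameters over the window", {
  b <- toy_breaths(exp_amp = c(1, 1))
  b$tidal_volume_ml <- c(0.2, 0.3)
  b$inst_rate_bpm <- c(120, 180)
  s <- summarize_eupnea(b, c(0, 10), body_weight_g = 25)
  expect_equal(s$mean_tidal_volume_ml, 0.25)
  expect_equal(s$mean_rate_bpm, 150)
  expect_equal(s$minute_volume_ml_per_min, 0.25 * 150)
  expect_equal(s$tv_per_gram, 0.01)

  expect_error(summarize_eupnea(b, c(100, 110)),
               class = "reflexkit_error_window_outside")
  b10 <- toy_breaths(exp_amp = rep(1, 10))
  expect_error(summarize_eupnea(b10[c(1, 10), ], c(3, 5)),
               class = "reflexkit_error_window_empty")
})

test_that("minute volume is consistent on uniform synthetic breathing", {
  sim <- sim_breath_trace(duration_s = 30, base_amplitude = 2.6,
                          kind = "flow", noise_sd = 0, seed = 3)
  b <- compute_tidal_volumes(sim$trace, segment_breaths(sim$trace, kind = "flow"))
  s <- summarize_eupnea(b, c(0, 30))
  expect_equal(s$minute_volume_ml_per_min,
               s$mean_tidal_volume_ml * s$mean_rate_bpm)
})
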