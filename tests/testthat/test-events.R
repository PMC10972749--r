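test_that("amplitude-ratio rule uses a strict 50% threshold", {
  # 51% increase -> call; exactly 50% -> no call
  ev <- classify_events(toy_breaths(c(1, 1.51, 1)), "anaesthetized")
  expect_equal(ev$breath, 2)
  ev2 <- classify_events(toy_breaths(c(1, 1.50, 1)), "anaesthetized")
  expect_equal(nrow(ev2), 0)

  # plethysmography additionally requires the inspiratory ratio
  b <- toy_breaths(exp_amp = c(1, 1.6, 1), insp_amp = c(1, 1.2, 1))
  expect_equal(nrow(classify_events(b, "anaesthetized")), 1)
  expect_equal(nrow(classify_events(b, "plethysmography")), 0)
  b2 <- toy_breaths(exp_amp = c(1, 1.6, 1), insp_amp = c(1, 1.6, 1))
  expect_equal(nrow(classify_events(b2, "plethysmography")), 1)
})

test_that("too few breaths yields an empty call list with a warning", {
  expect_warning(ev <- classify_events(toy_breaths(c(1, 2)), "anaesthetized"),
                 "fewer than 3")
  expect_equal(nrow(ev), 0)
})

test_that("event calling is scale invariant", {
  b <- toy_breaths(c(1, 1.7, 1, 1, 1.2, 1))
  for (c_ in c(0.01, 1, 250)) {
    bc <- b
    bc$exp_amplitude <- b$exp_amplitude * c_
    bc$insp_amplitude <- b$insp_amplitude * c_
    expect_equal(classify_events(bc, "anaesthetized")$breath, 2)
  }
})

test_that("injected gasps and sighs are recovered and typed by context", {
  ep <- stimulus_protocol("compression", start_s = 15)  # window [15, 55)
  sim <- sim_breath_trace(duration_s = 90, gasp_times_s = c(18, 22, 26),
                          sigh_times_s = c(60, 75), epochs = ep,
                          gasp_gain = 2, noise_sd = 0, seed = 4)
  b <- segment_breaths(sim$trace)
  ev <- classify_events(b, "anaesthetized", ep)
  expect_equal(sum(ev$event_type == "gasp"), 3)
  expect_equal(sum(ev$event_type == "sigh"), 2)
  rec <- event_recovery(ev, sim$truth$events, tol_s = 0.4)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$precision, 1)
})

test_that("gasp frequency divides counts by the window in minutes", {
  ep5 <- stimulus_epochs("methacholine", 100, 105, 405)
  ev <- tibble::tibble(time_s = c(110, 200), event_type = "gasp")
  expect_equal(gasp_frequency(ev, ep5, "observation_window"), 2 / (305 / 60))

  ep10 <- stimulus_epochs("illumination", 100, 110, 140)
  ev1 <- tibble::tibble(time_s = 103, event_type = "gasp")
  expect_equal(gasp_frequency(ev1, ep10, "stimulus_window"), 6)
  expect_equal(gasp_frequency(ev1[0, ], ep10, "stimulus_window"), 0)

  # additivity over a partition of the observation window
  ev_many <- tibble::tibble(time_s = c(101, 104, 108, 112, 131),
                            event_type = "gasp")
  whole <- gasp_frequency(ev_many, ep10, "observation_window") * 40 / 60
  parts <- vapply(list(c(100, 110), c(110, 120), c(120, 140)), function(w) {
    sum(ev_many$time_s >= w[1] & ev_many$time_s < w[2])
  }, numeric(1))
  expect_equal(sum(parts), whole)
})

test_that("baseline normalization divides by the 10-s pre-stimulus mean", {
  b <- toy_breaths(exp_amp = rep(2, 30), period_s = 1)
  ep <- stimulus_epochs("compression", 15, 25)
  nb <- normalize_to_baseline(b, ep, features = "exp_amplitude")
  expect_true(all(nb$exp_amplitude_norm == 1))

  b2 <- b
  b2$inst_rate_bpm <- ifelse(in_window(b$insp_onset_s, 15, 25), 75, 150)
  nb2 <- normalize_to_baseline(b2, ep, features = "inst_rate_bpm")
  expect_equal(unique(nb2$inst_rate_bpm_norm[in_window(nb2$insp_onset_s, 15, 25)]),
               0.5)

  expect_error(normalize_to_baseline(b[b$insp_onset_s > 20, ], ep),
               class = "reflexkit_error_baseline")
})

test_that("compression attenuation is recovered through normalization", {
  ep <- stimulus_protocol("compression", start_s = 30)
  sim <- sim_breath_trace(duration_s = 60, epochs = ep,
                          compression_attenuation = 0.5, noise_sd = 0,
                          seed = 6)
  b <- segment_breaths(sim$trace)
  nb <- normalize_to_baseline(b, ep, features = "insp_amplitude")
  during <- nb$insp_amplitude_norm[in_window(nb$insp_onset_s, 30.5, 39.5)]
  expect_equal(mean(during), 0.5, tolerance = 0.05)
})

test_that("Hering-Breuer normalized rate handles apnoea, null and graded reflexes", {
  b <- toy_breaths(exp_amp = rep(1, 50), period_s = 0.4)
  ep <- stimulus_epochs("inflation", 10, 15)
  # apnoea: drop all breaths during inflation
  hb0 <- hering_breuer(b[!in_window(b$insp_onset_s, 10, 15), ], ep)
  expect_equal(hb0$normalized_rate, 0)
  # null reflex: unchanged breathing
  hb1 <- hering_breuer(b, ep)
  expect_equal(hb1$normalized_rate, 1, tolerance = 0.05)

  # synthetic rate halving
  epi <- stimulus_epochs("inflation", 30, 40, 70)
  epi$rate_scale <- 0.5
  sim <- sim_breath_trace(duration_s = 60, epochs = epi, noise_sd = 0,
                          seed = 2)
  hb <- hering_breuer(segment_breaths(sim$trace), epi)
  expect_equal(hb$normalized_rate, 0.5, tolerance = 0.1)

  expect_error(hering_breuer(b, ep, baseline_window = c(9, 12)),
               class = "reflexkit_error_baseline")
})

test_that("latency to first gasp is measured from epoch start", {
  ep <- stimulus_epochs("compression", 100, 110, 160)
  ev <- tibble::tibble(time_s = c(103, 120), event_type = "gasp")
  expect_equal(latency_to_first_gasp(ev, ep), 3)
  expect_true(is.na(latency_to_first_gasp(ev[0, ], ep)))

  sim <- sim_breath_trace(duration_s = 60,
                          epochs = stimulus_protocol("compression", 20),
                          gasp_times_s = 32, noise_sd = 0, seed = 8)
  b <- segment_breaths(sim$trace)
  evs <- classify_events(b, "anaesthetized", stimulus_protocol("compression", 20))
  expect_equal(latency_to_first_gasp(evs, stimulus_protocol("compression", 20)),
               12, tolerance = 0.4)
})

test_that("trial aggregation averages per animal then across animals", {
  df <- tibble::tibble(animal = c("a", "a", "a", "b", "b"),
                       v = c(1, 2, 3, 2, 6))
  agg <- aggregate_trials(df, v)
  expect_equal(sort(tidy(agg)$mean_value), c(2, 4))
  g <- glance(agg)
  expect_equal(g$mean, 3)
  expect_equal(g$sem, 1)  # sd(c(2,4))/sqrt(2)
  expect_equal(g$n_animals, 2)

  # invariant to trial order and to duplicating one animal's trials
  agg2 <- aggregate_trials(df[sample(nrow(df)), ], v)
  expect_equal(glance(agg2), g)
  dup <- dplyr::bind_rows(df, df[df$animal == "a", ])
  expect_equal(glance(aggregate_trials(dup, v))$mean, 3)

  expect_error(aggregate_trials(df[0, ], v),
               class = "reflexkit_error_empty")
})
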