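test_that("ROI extraction averages mask pixels per frame and channel", {
  # constant fields come back verbatim
  g <- array(10, c(4, 5, 3)); r <- array(20, c(4, 5, 3))
  lab <- matrix(0L, 4, 5); lab[1:2, 1:2] <- 1L; lab[3:4, 4:5] <- 2L
  tr <- extract_roi_traces(g, r, lab, sampling_rate_hz = 2)
  expect_equal(unique(tr$gcamp), 10)
  expect_equal(unique(tr$tdtomato), 20)
  expect_equal(sort(unique(tr$roi)), c(1, 2))
  expect_equal(unique(diff(tr$time_s[tr$roi == 1])), 0.5)

  # disjoint ROIs over distinct constant values separate cleanly
  g2 <- array(0, c(4, 5, 2))
  g2[1:2, 1:2, ] <- 10; g2[3:4, 4:5, ] <- 20
  tr2 <- extract_roi_traces(g2, g2, lab)
  expect_equal(unique(tr2$gcamp[tr2$roi == 1]), 10)
  expect_equal(unique(tr2$gcamp[tr2$roi == 2]), 20)

  # random stack equals a brute-force per-pixel average
  set.seed(99)
  g3 <- array(runif(4 * 5 * 6), c(4, 5, 6))
  tr3 <- extract_roi_traces(g3, g3, lab)
  for (f in 1:6) {
    expect_equal(tr3$gcamp[tr3$roi == 1][f],
                 mean(g3[, , f][lab == 1]))
  }

  # errors name the offending ROI
  expect_error(extract_roi_traces(g, r, list(a = cbind(10, 1))),
               "out-of-bounds", class = "reflexkit_error_mask")
  expect_error(extract_roi_traces(g, r, list(a = matrix(numeric(), 0, 2))),
               "empty", class = "reflexkit_error_mask")
  expect_error(
    extract_roi_traces(g, r, list(a = cbind(1, 1), b = cbind(1, 1))),
    "overlap", class = "reflexkit_error_mask")
})

test_that("unhealthy ROIs are flagged by low CV and high brightness", {
  # healthy ROIs fluctuate a few percent about baseline (noise 2 a.u. on a
  # ~100 a.u. baseline); unhealthy ROIs are constant and bright
  sim <- sim_calcium_session(n_rois = 30, duration_s = 60,
                             epochs = stimulus_epochs("compression", 30, 40),
                             noise_sd = 2, unhealthy_rois = c(3, 17),
                             seed = 21)
  fl <- exclude_unhealthy(sim$traces)
  expect_equal(fl$roi[fl$excluded_unhealthy], c(3, 17))
  # normal-variability ROI untouched
  expect_false(fl$excluded_unhealthy[fl$roi == 1])
})

test_that("ratiometric dF/F0 cancels shared envelopes and scales steps", {
  # equal channels -> dff identically 0
  tr <- tibble::tibble(roi = 1, time_s = seq(0, 59.5, by = 0.5),
                       gcamp = 100, tdtomato = 100)
  ep <- stimulus_epochs("compression", 30, 40)
  expect_true(all(ratiometric_dff(tr, ep)$dff == 0))

  # shared bleach envelope leaves dff unchanged
  sim <- sim_calcium_session(n_rois = 5, duration_s = 120,
                             epochs = stimulus_epochs("compression", 60, 70),
                             bleach_tau_s = 100, noise_sd = 0, seed = 1)
  d <- ratiometric_dff(sim$traces, sim$truth$epochs)
  expect_lt(max(abs(d$dff)), 1e-10)

  # GCaMP step 100 -> 150 against flat tdTomato gives peak dff 0.5
  tr2 <- tr
  tr2$gcamp <- ifelse(in_window(tr$time_s, 30, 35), 150, 100)
  d2 <- ratiometric_dff(tr2, ep)
  expect_equal(max(d2$dff), 0.5)

  # invariance under common positive scaling of both channels
  tr3 <- dplyr::mutate(tr2, gcamp = gcamp * 3.7, tdtomato = tdtomato * 3.7)
  expect_equal(ratiometric_dff(tr3, ep)$dff, d2$dff)

  expect_error(ratiometric_dff(dplyr::mutate(tr, tdtomato = 0), ep),
               class = "reflexkit_error_ratio")
  expect_error(ratiometric_dff(tr, stimulus_epochs("compression", 5, 10)),
               class = "reflexkit_error_baseline")
})

test_that("responsiveness uses the 3-s.d. session criterion", {
  # a slow ripple sets the session s.d.; an in-epoch peak at ~4 s.d. above
  # the session mean is responsive, one at ~2 s.d. is not
  t <- seq(0, 119.5, by = 0.5)
  ripple <- 0.01 * sin(2 * pi * t / 7)
  ripple_sd <- sd(ripple)
  mk <- function(peak_sd) {
    g <- 100 * (1 + ripple)
    g[t >= 62 & t < 63] <- 100 * (1 + peak_sd * ripple_sd)
    tibble::tibble(roi = 1, time_s = t, gcamp = g, tdtomato = 100)
  }
  ep <- stimulus_epochs("compression", 60, 70)
  hi <- score_responsiveness(mk(4), ep)
  lo <- score_responsiveness(mk(2), ep)
  expect_true(hi$responsive)
  expect_false(lo$responsive)

  # monotone: raising an in-window peak never deactivates a responsive ROI
  hi2 <- score_responsiveness(mk(8), ep)
  expect_true(hi2$responsive)
  expect_gt(hi2$response_magnitude, hi$response_magnitude)

  expect_error(score_responsiveness(mk(4), stimulus_epochs("x", 60, 500)),
               class = "reflexkit_error_epoch")
})

test_that("the pipeline recovers synthetic responders", {
  # exact recovery at zero noise
  sim0 <- sim_calcium_session(n_rois = 50,
                              responder_map = list(compression = 1:5,
                                                   inflation = 6:10),
                              noise_sd = 0, seed = 31)
  sc0 <- score_responsiveness(sim0$traces, sim0$truth$epochs)
  expect_equal(sc0$roi[sc0$epoch == "compression" & sc0$responsive], 1:5)
  expect_equal(sc0$roi[sc0$epoch == "inflation" & sc0$responsive], 6:10)

  # all 10 responders found at amplitude 10x noise-induced dff scale
  sim <- sim_calcium_session(n_rois = 100,
                             responder_map = list(compression = 1:10),
                             response_amplitude_dff = 1, noise_sd = 0.05,
                             seed = 32)
  sc <- score_responsiveness(sim$traces, sim$truth$epochs)
  called <- sc$roi[sc$epoch == "compression" & sc$responsive]
  expect_true(all(1:10 %in% called))  # zero false negatives
})

test_that("selectivity classes follow the Rc/Ri bounds", {
  mk_scores <- function(rc, ri, resp_c = TRUE, resp_i = TRUE) {
    tibble::tibble(
      roi = 1, epoch = c("compression", "inflation"),
      f0 = 1, response_magnitude = c(rc, ri),
      session_mean = 0, session_sd = 0.01,
      responsive = c(resp_c, resp_i))
  }
  cls <- function(...) classify_selectivity(mk_scores(...))$selectivity
  expect_equal(cls(3, 1), "compression_selective")    # Rc/Ri = 3
  expect_equal(cls(1, 1), "polymodal")                # Rc/Ri = 1
  expect_equal(cls(0.4, 1), "inflation_selective")    # Rc/Ri = 0.4
  # boundary ratios fall to polymodal (open selective intervals)
  expect_equal(cls(2, 1), "polymodal")
  expect_equal(cls(0.5, 1), "polymodal")
  expect_equal(cls(0.1, 1, resp_c = FALSE, resp_i = FALSE), "nonresponsive")
  # joint rescaling of (Rc, Ri) does not change the class
  expect_equal(cls(30, 10), "compression_selective")

  expect_error(
    classify_selectivity(mk_scores(1, 1)[1, ]),
    class = "reflexkit_error_epoch")
})

test_that("selectivity matches generator truth on a clean session", {
  sim <- demo_calcium(n_rois = 12)
  sc <- score_responsiveness(sim$traces, sim$truth$epochs)
  sel <- classify_selectivity(sc)
  expect_equal(sel$selectivity, sim$truth$selectivity)
})

test_that("tallies partition the cohort and derive percentages", {
  tl <- response_tally(91, 64, 29, 1119)
  expect_equal(tl$total, 1303)
  g <- glance(tl)
  expect_equal(g$any_compression, 120)
  expect_equal(g$any_compression_pct, 9.2)
  expect_equal(g$any_inflation, 93)
  expect_equal(g$any_inflation_pct, 7.1)
  expect_equal(g$compression_only_of_compression_pct, 75.8)
  expect_equal(g$both_of_compression_pct, 24.2)
  td <- tidy(tl)
  expect_equal(sum(td$count), 1303)

  # null cohort: all percentages zero except the neither category
  tl0 <- response_tally(0, 0, 0, 10)
  expect_equal(glance(tl0)$any_compression_pct, 0)
  expect_true(is.na(glance(tl0)$compression_only_of_compression_pct))
  expect_error(response_tally(0, 0, 0, 0), class = "reflexkit_error_tally")

  # from per-ROI flags
  flags <- tibble::tibble(compression = c(TRUE, TRUE, FALSE, FALSE),
                          inflation = c(FALSE, TRUE, TRUE, FALSE))
  tf <- tally_responses(flags)
  expect_equal(as.integer(tf$counts), c(1L, 1L, 1L, 1L))
  expect_error(
    tally_responses(tibble::tibble(compression = c(TRUE, NA),
                                   inflation = c(TRUE, TRUE))),
    class = "reflexkit_error_tally")
})
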