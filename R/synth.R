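#' Build a stimulus-epoch table
#'
#' Stimulus epochs are the time anchors for every reflex metric: an applied
#' challenge spans `[start_s, end_s)` and reflexes are scored out to
#' `observation_end_s`. All windows in the package are half-open.
#'
#' @param label Character vector of epoch labels (e.g. "compression",
#'   "inflation", "suction_low", "methacholine", "illumination", "cno").
#' @param start_s,end_s Epoch start/end in seconds (`start_s < end_s`).
#' @param observation_end_s End of the reflex observation window (defaults to
#'   `end_s`); must satisfy `end_s <= observation_end_s`.
#' @param meta Optional list of per-epoch metadata lists (target pressures,
#'   gas mixes, ...).
#' @return A tibble with columns `label`, `start_s`, `end_s`,
#'   `observation_end_s` and a `meta` list-column.
#' @export
#' @examples
#' stimulus_epochs("compression", 60, 70, 100)
stimulus_epochs <- function(label, start_s, end_s,
                            observation_end_s = end_s, meta = NULL) {
  if (any(!(start_s < end_s)) || any(!(end_s <= observation_end_s))) {
    rlang::abort("epochs require start_s < end_s <= observation_end_s",
                 class = "reflexkit_error_epoch")
  }
  if (is.null(meta)) meta <- rep(list(list()), length(label))
  tibble::tibble(
    label = as.character(label),
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    observation_end_s = as.numeric(observation_end_s),
    meta = meta
  )
}

#' Standard stimulus protocols
#'
#' Returns the epoch table for a named airway challenge with the standard
#' durations and observation windows: thoracic compression is ramped over 5 s
#' and held for 10 s; tracheal suction is applied for 5 s at -5 (low) or -10
#' (high) cmH2O; nebulized stimuli are delivered for 5 s and reflexes
#' monitored for the following 5 min; optogenetic illumination lasts 10 s;
#' ventilator-driven lung inflation (Hering-Breuer testing) lasts 10 s. For
#' compression/suction/illumination/inflation the observation window is the
#' stimulus plus 30 s.
#'
#' @param name One of `"compression"`, `"suction_low"`, `"suction_high"`,
#'   `"methacholine"`, `"optogenetic"`, `"cno"`, `"inflation"`.
#' @param start_s Stimulus onset in seconds (default 60).
#' @return A one-row epoch tibble (see [stimulus_epochs()]).
#' @export
#' @examples
#' stimulus_protocol("compression")
#' stimulus_protocol("methacholine", start_s = 120)
stimulus_protocol <- function(name, start_s = 60) {
  valid <- c("compression", "suction_low", "suction_high", "methacholine",
             "optogenetic", "cno", "inflation")
  if (length(name) != 1L || !name %in% valid) {
    rlang::abort(
      paste0("unknown protocol ", deparse(name), "; valid protocols: ",
             paste(valid, collapse = ", ")),
      class = "reflexkit_error_protocol")
  }
  switch(name,
    compression = stimulus_epochs(
      "compression", start_s, start_s + 10, start_s + 40,
      meta = list(list(ramp_s = 5, target_attenuation = c(0.4, 0.6)))),
    suction_low = stimulus_epochs(
      "suction_low", start_s, start_s + 5, start_s + 35,
      meta = list(list(target_pressure_cmh2o = -5))),
    suction_high = stimulus_epochs(
      "suction_high", start_s, start_s + 5, start_s + 35,
      meta = list(list(target_pressure_cmh2o = -10))),
    methacholine = stimulus_epochs(
      "methacholine", start_s, start_s + 5, start_s + 5 + 300,
      meta = list(list(dose_mg_ml = 10, nebulizer_duty = 0.5))),
    optogenetic = stimulus_epochs(
      "illumination", start_s, start_s + 10, start_s + 40,
      meta = list(list(wavelength_nm = 473))),
    cno = stimulus_epochs(
      "cno", start_s, start_s + 1, start_s + 1800,
      meta = list(list(dose_mg_kg = 3, analysis_delay_s = 420))),
    inflation = stimulus_epochs(
      "inflation", start_s, start_s + 10, start_s + 40,
      meta = list(list(flow_ml_min_g = c(10, 25))))
  )
}

# amplitude/rate multipliers applying to a breath starting at time t
epoch_scales <- function(t, epochs, compression_attenuation) {
  amp <- 1
  rate <- 1
  if (is.null(epochs) || !nrow(epochs)) return(c(amp = amp, rate = rate))
  has_amp <- "amplitude_scale" %in% names(epochs)
  has_rate <- "rate_scale" %in% names(epochs)
  hit <- which(in_window(t, epochs$start_s, epochs$end_s))
  for (i in hit) {
    if (has_amp && !is.na(epochs$amplitude_scale[i])) {
      amp <- amp * epochs$amplitude_scale[i]
    } else if (epochs$label[i] == "compression") {
      amp <- amp * (1 - compression_attenuation)
    }
    if (has_rate && !is.na(epochs$rate_scale[i])) {
      rate <- rate * epochs$rate_scale[i]
    }
  }
  c(amp = amp, rate = rate)
}

#' Simulate a respiratory trace with known breaths, gasps and sighs
#'
#' Generates eupnoeic breathing as a train of stereotyped breath cycles
#' (half-sine inspiration followed by a sharp exponential expiration), with
#' optional injected gasps/sighs (whole cycles scaled by `gasp_gain`),
#' stimulus epochs that attenuate cyclic amplitude (compression) or rescale
#' the breathing rate, and additive white Gaussian noise. Ground truth
#' (breath onsets, injected events, per-breath amplitudes and tidal volumes
#' for flow traces) is returned alongside the trace so downstream
#' segmentation and event calling can be validated exactly.
#'
#' Injected events must satisfy the gasp detection rule by construction, so
#' `gasp_gain` must exceed 1.5 (the >50% amplitude-increase threshold), and
#' two injected events may not fall within one breath period of each other.
#'
#' @param duration_s Trace duration (s).
#' @param sampling_rate_hz Sampling rate (Hz); pressure traces default 1 kHz.
#' @param base_rate_bpm Eupnoeic breathing rate (breaths/min).
#' @param base_amplitude Inspiratory amplitude in signal units (cmH2O for
#'   pressure, ml/s for flow).
#' @param exp_amplitude_frac Expiratory trough magnitude as a fraction of the
#'   inspiratory amplitude.
#' @param gasp_times_s,sigh_times_s Times (s) at which to inject augmented
#'   breaths; each is snapped to the nearest breath onset.
#' @param gasp_gain Amplitude multiplier for injected events (> 1.5).
#' @param noise_sd Additive Gaussian noise s.d. (signal units).
#' @param epochs Optional epoch tibble ([stimulus_epochs()]); may carry
#'   `amplitude_scale` / `rate_scale` columns. Breaths whose onset falls in a
#'   `"compression"` epoch are attenuated by `compression_attenuation`.
#' @param compression_attenuation Fractional reduction in cyclic amplitude
#'   during compression epochs, in `[0.4, 0.6]`.
#' @param kind `"pressure"` or `"flow"`; flow traces carry per-breath tidal
#'   volumes (ml) in the ground truth.
#' @param seed Integer seed; identical inputs give bit-identical outputs.
#' @return A list of class `"reflex_sim"` with elements `trace` (tibble
#'   `time_s`, `value`), and `truth` (list: `breath_onsets_s`, `breaths`
#'   tibble, `events` tibble, `epochs`, `params`).
#' @export
#' @examples
#' sim <- sim_breath_trace(duration_s = 10, base_rate_bpm = 150, seed = 1)
#' nrow(sim$trace)
#' length(sim$truth$breath_onsets_s)
sim_breath_trace <- function(duration_s = 60,
                             sampling_rate_hz = 1000,
                             base_rate_bpm = 150,
                             base_amplitude = 1,
                             exp_amplitude_frac = 0.8,
                             gasp_times_s = numeric(),
                             gasp_gain = 2,
                             sigh_times_s = numeric(),
                             noise_sd = 0,
                             epochs = NULL,
                             compression_attenuation = 0.5,
                             kind = c("pressure", "flow"),
                             seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0, sampling_rate_hz > 0, base_rate_bpm > 0,
            base_amplitude > 0, noise_sd >= 0)
  if (gasp_gain <= 1.5) {
    rlang::abort("gasp_gain must exceed 1.5 so injected events satisfy the >50% detection rule",
                 class = "reflexkit_error_synth")
  }
  if (!(compression_attenuation >= 0.4 && compression_attenuation <= 0.6)) {
    rlang::abort("compression_attenuation must lie in [0.4, 0.6]",
                 class = "reflexkit_error_synth")
  }
  ev_times <- c(gasp_times_s, sigh_times_s)
  ev_types <- c(rep("gasp", length(gasp_times_s)),
                rep("sigh", length(sigh_times_s)))
  if (any(ev_times < 0 | ev_times >= duration_s)) {
    rlang::abort("injected event times must lie within [0, duration_s)",
                 class = "reflexkit_error_synth")
  }
  period <- 60 / base_rate_bpm
  if (length(ev_times) > 1L) {
    st <- sort(ev_times)
    gap <- diff(st)
    if (any(gap < period)) {
      bad <- which(gap < period)[1]
      rlang::abort(
        sprintf("injected events at %.3f s and %.3f s are closer than one breath period (%.3f s)",
                st[bad], st[bad + 1], period),
        class = "reflexkit_error_synth")
    }
  }

  fs <- sampling_rate_hz
  n <- round(duration_s * fs)
  time_s <- (seq_len(n) - 1L) / fs

  # variable-rate breath onset grid
  onsets <- numeric(0)
  rate_scales <- numeric(0)
  t <- 0
  while (t < duration_s - 1e-9) {
    sc <- epoch_scales(t, epochs, compression_attenuation)
    if (sc[["rate"]] <= 0) {
      # apnoeic epoch: jump to the end of the first epoch covering t
      hit <- which(in_window(t, epochs$start_s, epochs$end_s))
      t <- max(epochs$end_s[hit])
      next
    }
    onsets <- c(onsets, t)
    rate_scales <- c(rate_scales, sc[["rate"]])
    t <- t + period / sc[["rate"]]
  }
  nb <- length(onsets)

  # event -> breath assignment (snap to nearest onset)
  gains <- rep(1, nb)
  ev_breath <- integer(length(ev_times))
  if (length(ev_times)) {
    for (k in seq_along(ev_times)) {
      ev_breath[k] <- which.min(abs(onsets - ev_times[k]))
    }
    if (anyDuplicated(ev_breath)) {
      rlang::abort("two injected events map to the same breath",
                   class = "reflexkit_error_synth")
    }
    gains[ev_breath] <- gasp_gain
  }

  amp_scales <- vapply(onsets, function(o)
    epoch_scales(o, epochs, compression_attenuation)[["amp"]], numeric(1))

  ti <- 0.3 * period              # inspiratory half-sine width
  tau_e <- 0.1 * period           # expiratory decay constant
  value <- numeric(n)
  insp_amp <- base_amplitude * gains * amp_scales
  exp_amp <- exp_amplitude_frac * insp_amp
  next_onset <- c(onsets[-1], duration_s)
  for (k in seq_len(nb)) {
    i0 <- floor(onsets[k] * fs) + 1L
    i1 <- min(n, ceiling(next_onset[k] * fs))
    if (i1 < i0) next
    tau <- time_s[i0:i1] - onsets[k]
    v <- ifelse(tau < ti,
                insp_amp[k] * sin(pi * tau / ti),
                -exp_amp[k] * exp(-(tau - ti) / tau_e))
    value[i0:i1] <- v
  }
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(n, 0, noise_sd) else
      withr::with_seed(seed, stats::rnorm(n, 0, noise_sd))
    value <- value + noise
  }

  breaths <- tibble::tibble(
    onset_s = onsets,
    gain = gains,
    insp_amplitude = insp_amp,
    exp_amplitude = exp_amp
  )
  if (kind == "flow") {
    breaths$tidal_volume_ml <- insp_amp * 2 * ti / pi
  }
  events <- tibble::tibble(
    time_s = if (length(ev_times)) onsets[ev_breath] else numeric(0),
    requested_time_s = as.numeric(ev_times),
    type = ev_types
  )
  structure(list(
    trace = tibble::tibble(time_s = time_s, value = value),
    truth = list(
      breath_onsets_s = onsets,
      breaths = breaths,
      events = events[order(events$time_s), , drop = FALSE],
      epochs = epochs,
      params = list(duration_s = duration_s, sampling_rate_hz = fs,
                    base_rate_bpm = base_rate_bpm,
                    base_amplitude = base_amplitude,
                    exp_amplitude_frac = exp_amplitude_frac,
                    gasp_gain = gasp_gain, noise_sd = noise_sd,
                    compression_attenuation = compression_attenuation,
                    kind = kind, seed = seed)
    )
  ), class = "reflex_sim")
}

#' Simulate a two-channel vagal ganglion calcium-imaging session
#'
#' Generates paired GCaMP/tdTomato ROI-by-time fluorescence with
#' stimulus-locked transients on the GCaMP channel of designated responder
#' ROIs, a shared exponential photobleaching envelope on both channels (so
#' the ratiometric pipeline cancels it), additive Gaussian noise, and
#' optional "unhealthy" ROIs with strong, unvarying GCaMP fluorescence.
#'
#' @param n_rois Number of ROIs (>= 1).
#' @param duration_s Session length (s).
#' @param sampling_rate_hz Frame rate (Hz); volumetric imaging defaults 2 Hz.
#' @param epochs Epoch tibble; transients lock to `start_s` of each epoch a
#'   ROI responds to. Defaults to a compression epoch at 60 s and an
#'   inflation epoch at 150 s (10 s each).
#' @param responder_map Named list mapping epoch labels to integer vectors of
#'   responding ROI ids, e.g. `list(compression = 1:10)`.
#' @param response_amplitude_dff Peak dF/F0 of evoked transients.
#' @param transient_rise_s,transient_decay_s Transient kinetics (s).
#' @param bleach_tau_s Photobleaching time constant (s); `Inf` disables.
#' @param gcamp_base,tdtomato_base Mean baseline fluorescence (a.u.); per-ROI
#'   levels vary uniformly within +/-20%.
#' @param noise_sd Additive noise s.d. (fluorescence units, per channel).
#' @param unhealthy_rois Integer ids of ROIs rendered constant and bright on
#'   the GCaMP channel.
#' @param seed Integer seed for reproducibility.
#' @return A list of class `"reflex_sim"`: `traces` (long tibble `roi`,
#'   `time_s`, `gcamp`, `tdtomato`), and `truth` (responders per epoch, true
#'   selectivity class per ROI, unhealthy ids, epochs, params).
#' @export
#' @examples
#' sim <- sim_calcium_session(n_rois = 5, responder_map = list(compression = 1:2),
#'                            seed = 1)
#' dplyr::count(sim$traces, roi)
sim_calcium_session <- function(n_rois = 100,
                                duration_s = 240,
                                sampling_rate_hz = 2,
                                epochs = NULL,
                                responder_map = list(),
                                response_amplitude_dff = 1,
                                transient_rise_s = 1,
                                transient_decay_s = 4,
                                bleach_tau_s = Inf,
                                gcamp_base = 100,
                                tdtomato_base = 100,
                                noise_sd = 0,
                                unhealthy_rois = integer(),
                                seed = NULL) {
  stopifnot(n_rois >= 1, duration_s > 0, sampling_rate_hz > 0, noise_sd >= 0)
  if (is.null(epochs)) {
    epochs <- stimulus_epochs(c("compression", "inflation"),
                              start_s = c(60, 150), end_s = c(70, 160),
                              observation_end_s = c(100, 190))
  }
  bad <- setdiff(names(responder_map), epochs$label)
  if (length(bad)) {
    rlang::abort(paste0("responder_map refers to unknown epoch label(s): ",
                        paste(bad, collapse = ", ")),
                 class = "reflexkit_error_synth")
  }
  if (length(unlist(responder_map)) &&
      any(!unlist(responder_map) %in% seq_len(n_rois))) {
    rlang::abort("responder_map contains ROI ids outside 1..n_rois",
                 class = "reflexkit_error_synth")
  }

  gen <- function() {
    n <- round(duration_s * sampling_rate_hz)
    time_s <- (seq_len(n) - 1L) / sampling_rate_hz
    bleach <- if (is.finite(bleach_tau_s)) exp(-time_s / bleach_tau_s) else rep(1, n)
    base_g <- gcamp_base * stats::runif(n_rois, 0.8, 1.2)
    base_r <- tdtomato_base * stats::runif(n_rois, 0.8, 1.2)

    kernel <- function(u) {
      k <- ifelse(u < 0, 0,
                  pmin(u / transient_rise_s, 1) *
                    exp(-pmax(u - transient_rise_s, 0) / transient_decay_s))
      response_amplitude_dff * k
    }
    dff_true <- matrix(0, n_rois, n)
    for (lab in names(responder_map)) {
      t0 <- epochs$start_s[match(lab, epochs$label)]
      for (r in responder_map[[lab]]) {
        dff_true[r, ] <- dff_true[r, ] + kernel(time_s - t0)
      }
    }
    g <- sweep((1 + dff_true), 1, base_g, `*`)
    g <- sweep(g, 2, bleach, `*`)
    r <- outer(base_r, bleach)
    if (noise_sd > 0) {
      g <- g + matrix(stats::rnorm(n_rois * n, 0, noise_sd), n_rois, n)
      r <- r + matrix(stats::rnorm(n_rois * n, 0, noise_sd), n_rois, n)
    }
    if (length(unhealthy_rois)) {
      g[unhealthy_rois, ] <- 3 * gcamp_base
    }
    g <- pmax(g, .Machine$double.eps)
    r <- pmax(r, .Machine$double.eps)
    tibble::tibble(
      roi = rep(seq_len(n_rois), each = n),
      time_s = rep(time_s, times = n_rois),
      gcamp = as.vector(t(g)),
      tdtomato = as.vector(t(r))
    )
  }
  traces <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())

  responders <- purrr::map(responder_map, ~ sort(unique(.x)))
  comp <- responders[["compression"]] %||% integer()
  infl <- responders[["inflation"]] %||% integer()
  selectivity <- vapply(seq_len(n_rois), function(r) {
    if (r %in% comp && r %in% infl) "polymodal"
    else if (r %in% comp) "compression_selective"
    else if (r %in% infl) "inflation_selective"
    else "nonresponsive"
  }, character(1))

  structure(list(
    traces = traces,
    truth = list(
      responders = responders,
      selectivity = selectivity,
      unhealthy_rois = sort(unique(as.integer(unhealthy_rois))),
      epochs = epochs,
      params = list(n_rois = n_rois, duration_s = duration_s,
                    sampling_rate_hz = sampling_rate_hz,
                    response_amplitude_dff = response_amplitude_dff,
                    bleach_tau_s = bleach_tau_s, noise_sd = noise_sd,
                    seed = seed)
    )
  ), class = "reflex_sim")
}

#' Simulate a multiunit nerve/EMG trace with stimulus-locked gain changes
#'
#' Produces a zero-mean spiky signal (background Gaussian noise plus random
#' sign spikes) whose rectified-integrated mean scales with a per-epoch gain
#' envelope; a serotonin reference epoch can be appended for normalization.
#' Ground truth records the gain of every epoch.
#'
#' @param duration_s Trace length (s).
#' @param sampling_rate_hz Sampling rate (Hz), default 2 kHz.
#' @param epochs Epoch tibble with a numeric `gain` column (multiplier on
#'   signal amplitude during `[start_s, end_s)`).
#' @param serotonin_onset_s Optional serotonin administration time (s); the
#'   gain applies over the following `serotonin_window_s`.
#' @param serotonin_gain Amplitude gain of the serotonin response.
#' @param serotonin_window_s Length of the serotonin response window (s).
#' @param spike_rate_hz Mean multiunit spike rate (> 0).
#' @param spike_amplitude Spike amplitude scale (signal units).
#' @param noise_sd Background noise s.d. (signal units).
#' @param seed Integer seed; fixed seed gives bit-identical regeneration.
#' @return A list of class `"reflex_sim"`: `trace` (tibble `time_s`,
#'   `value`) and `truth` (epoch gains, serotonin window/gain, params).
#' @export
#' @examples
#' ep <- stimulus_epochs("suction_low", 120, 125, 155)
#' ep$gain <- 1.5
#' sim <- sim_nerve_trace(duration_s = 300, epochs = ep,
#'                        serotonin_onset_s = 180, seed = 1)
sim_nerve_trace <- function(duration_s = 300,
                            sampling_rate_hz = 2000,
                            epochs = NULL,
                            serotonin_onset_s = NULL,
                            serotonin_gain = 3,
                            serotonin_window_s = 100,
                            spike_rate_hz = 300,
                            spike_amplitude = 1,
                            noise_sd = 0.1,
                            seed = NULL) {
  stopifnot(duration_s > 0, sampling_rate_hz > 0, spike_amplitude > 0)
  if (spike_rate_hz <= 0) {
    rlang::abort("baseline spike rate must be positive",
                 class = "reflexkit_error_synth")
  }
  if (!is.null(epochs) && nrow(epochs)) {
    if (is.null(epochs$gain)) {
      rlang::abort("nerve epochs need a numeric `gain` column",
                   class = "reflexkit_error_synth")
    }
    if (any(epochs$start_s < 0 | epochs$end_s > duration_s)) {
      rlang::abort("epoch outside trace duration",
                   class = "reflexkit_error_synth")
    }
  }
  fs <- sampling_rate_hz
  n <- round(duration_s * fs)
  time_s <- (seq_len(n) - 1L) / fs

  gen <- function() {
    w <- stats::rnorm(n, 0, noise_sd)
    p <- min(1, spike_rate_hz / fs)
    spk <- which(stats::runif(n) < p)
    w[spk] <- w[spk] +
      sample(c(-1, 1), length(spk), replace = TRUE) *
        spike_amplitude * abs(stats::rnorm(length(spk)))
    w
  }
  w <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())

  env <- rep(1, n)
  if (!is.null(epochs) && nrow(epochs)) {
    for (i in seq_len(nrow(epochs))) {
      idx <- in_window(time_s, epochs$start_s[i], epochs$end_s[i])
      env[idx] <- env[idx] * epochs$gain[i]
    }
  }
  sero <- NULL
  if (!is.null(serotonin_onset_s)) {
    idx <- in_window(time_s, serotonin_onset_s,
                     serotonin_onset_s + serotonin_window_s)
    env[idx] <- env[idx] * serotonin_gain
    sero <- list(onset_s = serotonin_onset_s, window_s = serotonin_window_s,
                 gain = serotonin_gain)
  }

  structure(list(
    trace = tibble::tibble(time_s = time_s, value = env * w),
    truth = list(
      epochs = epochs,
      serotonin = sero,
      params = list(duration_s = duration_s, sampling_rate_hz = fs,
                    spike_rate_hz = spike_rate_hz, noise_sd = noise_sd,
                    spike_amplitude = spike_amplitude, seed = seed)
    )
  ), class = "reflex_sim")
}

#' @export
print.reflex_sim <- function(x, ...) {
  what <- if (!is.null(x$traces)) "calcium session" else
    if (!is.null(x$truth$serotonin) || !is.null(x$truth$params$spike_rate_hz))
      "nerve trace" else "respiratory trace"
  cat("<reflex_sim>", what, "\n")
  if (!is.null(x$trace)) {
    cat("  samples:", nrow(x$trace), " span:",
        round(max(x$trace$time_s), 2), "s\n")
  }
  if (!is.null(x$traces)) {
    cat("  rois:", length(unique(x$traces$roi)),
        " frames:", length(unique(x$traces$time_s)), "\n")
  }
  invisible(x)
}
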