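# shared fixtures built in code

# minimal well-formed breath table with chosen amplitudes
toy_breaths <- function(exp_amp, insp_amp = exp_amp, period_s = 1,
                        kind = "pressure") {
  n <- length(exp_amp)
  onset <- (seq_len(n) - 1) * period_s
  tibble::tibble(
    breath = seq_len(n),
    insp_onset_s = onset,
    insp_peak_s = onset + 0.25 * period_s,
    exp_onset_s = onset + 0.5 * period_s,
    exp_end_s = onset + period_s,
    insp_amplitude = insp_amp,
    exp_amplitude = exp_amp,
    duration_s = rep(period_s, n),
    inst_rate_bpm = rep(60 / period_s, n),
    kind = kind
  )
}

# sinusoidal trace helper
sine_trace <- function(freq_hz = 2.5, duration_s = 10, fs = 1000, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  tibble::tibble(time_s = t, value = amp * sin(2 * pi * freq_hz * t))
}

# small calcium session with hand-set responder layout
demo_calcium <- function(n_rois = 20, noise_sd = 0, seed = 11, ...) {
  sim_calcium_session(
    n_rois = n_rois,
    responder_map = list(compression = 1:3, inflation = 4:6),
    noise_sd = noise_sd, seed = seed, ...)
}
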