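#' Rectify and integrate a multiunit nerve or EMG signal
#'
#' Digital equivalent of the hardware "leaky integrator" used on raw
#' multiunit recordings: the signal is rectified about its median (robust
#' to amplifier offset and spike asymmetry) and passed through a
#' first-order exponential moving average with time constant `tau_s`
#' (default 0.02 s, the EMG convention). The filter uses the exact
#' discretization `alpha = 1 - exp(-dt/tau)`, so a unit step in rectified
#' amplitude reaches `1 - exp(-1)` (~63.2%) of its asymptote at `t = tau`
#' exactly. Output has the same length and sampling rate as the input, and
#' scales linearly with input gain.
#'
#' @param trace Data frame with `time_s` and `value` columns (nerve or EMG
#'   signal, arbitrary units).
#' @param tau_s Integrator time constant (s); must be at least two sample
#'   intervals to be resolvable.
#' @return Tibble `time_s`, `value` holding the rectified-integrated
#'   signal.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' x <- data.frame(time_s = t, value = sin(400 * t))
#' yi <- integrate_signal(x, tau_s = 0.02)
integrate_signal <- function(trace, tau_s = 0.02) {
  check_trace_df(trace)
  if (tau_s <= 0) {
    rlang::abort("tau_s must be positive", class = "reflexkit_error_tau")
  }
  dt <- infer_dt(trace$time_s)
  if (tau_s < 2 * dt) {
    rlang::abort(sprintf(
      "tau_s = %g s is below the resolvable limit (2 samples = %g s)",
      tau_s, 2 * dt), class = "reflexkit_error_tau")
  }
  r <- abs(trace$value - stats::median(trace$value))
  a <- 1 - exp(-dt / tau_s)
  y <- stats::filter(a * r, 1 - a, method = "recursive",
                     init = 0)
  tibble::tibble(time_s = trace$time_s, value = as.numeric(y))
}

#' Percentage change of integrated activity from baseline
#'
#' Stimulus-induced responses are expressed as the percentage change of the
#' mean rectified-integrated activity in the stimulus window relative to a
#' pre-stimulus baseline window: `100 * (mean(stim) - mean(base)) /
#' mean(base)`. Windows are half-open `[start, end)`.
#'
#' @param integrated Integrated trace from [integrate_signal()].
#' @param stim_window,baseline_window Length-2 numeric windows (s); the
#'   baseline conventionally spans the 60 s before stimulus onset.
#' @return Percent change (numeric scalar).
#' @export
percent_change <- function(integrated, stim_window, baseline_window) {
  check_trace_df(integrated, "integrated")
  stopifnot(length(stim_window) == 2L, length(baseline_window) == 2L)
  t <- integrated$time_s
  rng <- range(t)
  for (wname in c("stim_window", "baseline_window")) {
    w <- get(wname)
    if (w[1] < rng[1] - 1e-9 || w[2] > rng[2] + infer_dt(t) + 1e-9) {
      rlang::abort(paste0(wname, " lies outside the trace"),
                   class = "reflexkit_error_window")
    }
  }
  m_base <- mean(integrated$value[in_window(t, baseline_window[1],
                                            baseline_window[2])])
  if (!is.finite(m_base) || m_base <= 0) {
    rlang::abort("baseline mean must be positive",
                 class = "reflexkit_error_baseline")
  }
  m_stim <- mean(integrated$value[in_window(t, stim_window[1],
                                            stim_window[2])])
  100 * (m_stim - m_base) / m_base
}

#' Normalize a stimulus response to the serotonin reference
#'
#' Whole-nerve responses vary with electrode contact and nerve health, so
#' each preparation is referenced to its response to intraperitoneal
#' serotonin, measured as the percent change of integrated activity over
#' the `window_s` (default 100 s) following administration. The normalized
#' response is `response_pct / serotonin_pct`, a dimensionless fraction of
#' the serotonin response.
#'
#' @param response_pct Stimulus percent change from [percent_change()].
#' @param serotonin_trace Integrated trace covering the serotonin trial
#'   (may be the same recording).
#' @param serotonin_onset_s Administration time (s).
#' @param window_s Serotonin response window length (s), default 100.
#' @param baseline_window Baseline for the serotonin percent change;
#'   defaults to the 60 s preceding administration.
#' @return One-row tibble: `pct_change_baseline`, `serotonin_pct_change`,
#'   `normalized`, and the serotonin window used.
#' @export
normalize_to_serotonin <- function(response_pct, serotonin_trace,
                                   serotonin_onset_s, window_s = 100,
                                   baseline_window = NULL) {
  if (is.null(baseline_window)) {
    baseline_window <- c(serotonin_onset_s - 60, serotonin_onset_s)
  }
  sero_pct <- percent_change(serotonin_trace,
                             c(serotonin_onset_s, serotonin_onset_s + window_s),
                             baseline_window)
  if (sero_pct <= 0) {
    rlang::abort("nonpositive serotonin response; reference trial unusable",
                 class = "reflexkit_error_serotonin")
  }
  tibble::tibble(
    pct_change_baseline = response_pct,
    serotonin_pct_change = sero_pct,
    normalized = response_pct / sero_pct,
    serotonin_window_start_s = serotonin_onset_s,
    serotonin_window_end_s = serotonin_onset_s + window_s
  )
}
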