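#' Segment a respiratory trace into breaths
#'
#' Detects individual respiratory cycles in a pressure or flow trace and
#' returns one row per breath with its landmark times and amplitudes. The
#' procedure is: (1) smooth with a centred moving average
#' (`smoothing_window_s`, default 0.02 s); (2) find inspiratory peaks whose
#' topographic prominence exceeds `prominence_frac` times the robust signal
#' range (2nd-98th percentile span of the smoothed trace); (3) place the
#' inspiratory onset at the last baseline crossing before each peak, the
#' expiratory onset at the first baseline crossing after it, and the breath
#' end at the next breath's onset (trace end for the last breath). The
#' baseline is the median of the smoothed trace. Amplitudes are nonnegative
#' magnitudes relative to that baseline: `insp_amplitude` from the peak,
#' `exp_amplitude` from the deepest trough before the next breath.
#'
#' All thresholds are relative, so segmentation is invariant to positive
#' rescaling of the trace and equivariant to time shifts. A constant or
#' too-short trace yields an empty table with a warning, not an error.
#'
#' @param trace Data frame with columns `time_s` (uniformly sampled,
#'   seconds) and `value` (cmH2O for pressure, ml/s for flow).
#' @param kind `"pressure"` or `"flow"`; recorded on the output and checked
#'   by volume-dependent downstream steps.
#' @param smoothing_window_s Moving-average window (s).
#' @param prominence_frac Peak prominence threshold as a fraction of the
#'   robust signal range.
#' @param min_breath_s Minimum breath period (s); peaks closer than this are
#'   merged keeping the higher (default 0.1 s, i.e. 600 breaths/min cap).
#' @return A tibble (one row per breath, indices contiguous from 1) with
#'   columns `breath`, `insp_onset_s`, `insp_peak_s`, `exp_onset_s`,
#'   `exp_end_s`, `insp_amplitude`, `exp_amplitude`, `duration_s`,
#'   `inst_rate_bpm`, and a `kind` column.
#' @export
#' @examples
#' t <- seq(0, 10, by = 1e-3)
#' breaths <- segment_breaths(data.frame(time_s = t,
#'                                       value = sin(2 * pi * 2.5 * t)))
#' nrow(breaths)                      # 25 cycles
#' round(mean(breaths$inst_rate_bpm)) # ~150 breaths/min
segment_breaths <- function(trace,
                            kind = c("pressure", "flow"),
                            smoothing_window_s = 0.02,
                            prominence_frac = 0.25,
                            min_breath_s = 0.1) {
  kind <- match.arg(kind)
  check_trace_df(trace)
  empty <- tibble::tibble(
    breath = integer(), insp_onset_s = numeric(), insp_peak_s = numeric(),
    exp_onset_s = numeric(), exp_end_s = numeric(),
    insp_amplitude = numeric(), exp_amplitude = numeric(),
    duration_s = numeric(), inst_rate_bpm = numeric(),
    kind = character())
  n <- nrow(trace)
  if (n < 4L) {
    rlang::warn("trace too short to segment; returning empty breath table")
    return(empty)
  }
  dt <- infer_dt(trace$time_s)
  fs <- 1 / dt
  x <- trace$value
  xs <- moving_average(x, round(smoothing_window_s * fs))
  baseline <- stats::median(xs)
  rng <- unname(diff(stats::quantile(xs, c(0.02, 0.98))))
  scale_floor <- max(abs(baseline), max(abs(xs)), 1) * 1e-12
  if (rng <= scale_floor) {
    rlang::warn("trace is (near-)constant; returning empty breath table")
    return(empty)
  }
  min_prom <- prominence_frac * rng
  peaks <- find_peaks(xs, min_prom = min_prom,
                      min_height = baseline + 0.5 * min_prom,
                      min_dist = max(1L, round(min_breath_s * fs)))
  if (length(peaks) < 1L) {
    rlang::warn("no respiratory cycles detected; returning empty breath table")
    return(empty)
  }

  np <- length(peaks)
  onset_i <- integer(np)
  expon_i <- integer(np)
  trough_i <- integer(np)
  prev_bound <- c(1L, peaks[-np])
  next_bound <- c(peaks[-1L], n)
  for (k in seq_len(np)) {
    p <- peaks[k]
    # inspiratory onset: last sample at/below the onset level before the
    # peak; the level sits 2% of the peak height above baseline so that a
    # slow expiratory recovery hugging the baseline is not mistaken for
    # early inspiration
    seg <- prev_bound[k]:p
    lvl <- baseline + 0.02 * (xs[p] - baseline)
    below <- seg[xs[seg] <= lvl]
    onset_i[k] <- if (length(below)) max(below) else seg[which.min(xs[seg])]
    # expiratory trough and onset between this peak and the next boundary
    seg2 <- p:next_bound[k]
    trough_i[k] <- seg2[which.min(xs[seg2])]
    below2 <- seg2[xs[seg2] <= baseline]
    below2 <- below2[below2 > p]
    expon_i[k] <- if (length(below2)) min(below2) else trough_i[k]
  }

  t0 <- trace$time_s[1]
  tm <- function(i) trace$time_s[i]
  exp_end_i <- c(onset_i[-1L], n)
  ok <- onset_i < peaks & peaks < expon_i & expon_i <= exp_end_i
  onset_i <- onset_i[ok]; peaks <- peaks[ok]
  expon_i <- expon_i[ok]; trough_i <- trough_i[ok]
  exp_end_i <- c(onset_i[-1L], n)
  np <- length(peaks)
  if (!np) {
    rlang::warn("no well-formed respiratory cycles detected; returning empty breath table")
    return(empty)
  }

  duration <- c(diff(tm(onset_i)), tm(exp_end_i[np]) - tm(onset_i[np]))
  duration <- pmax(duration, dt)
  tibble::tibble(
    breath = seq_len(np),
    insp_onset_s = tm(onset_i),
    insp_peak_s = tm(peaks),
    exp_onset_s = tm(expon_i),
    exp_end_s = tm(exp_end_i),
    insp_amplitude = xs[peaks] - baseline,
    exp_amplitude = pmax(baseline - xs[trough_i], 0),
    duration_s = duration,
    inst_rate_bpm = 60 / duration,
    kind = kind
  )
}

#' Compute per-breath tidal volumes from a flow trace
#'
#' For pneumotachograph (flow) traces, the tidal volume of each breath is
#' the time integral of inspiratory flow over the inspiratory phase
#' `[insp_onset_s, exp_onset_s)` (trapezoidal rule; ml/s integrated over s
#' gives ml), and `peak_insp_flow` is the maximum flow in that phase.
#' Pressure traces carry no volume calibration: their amplitude serves as a
#' volume proxy and this function refuses them.
#'
#' @param trace Flow trace (`time_s`, `value` in ml/s).
#' @param breaths Breath table from [segment_breaths()] on the same trace
#'   with `kind == "flow"`.
#' @return `breaths` with `tidal_volume_ml` and `peak_insp_flow` columns.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' fl <- data.frame(time_s = t, value = ifelse(t < 0.2, 1, 0))
#' # rectangular 1 ml/s x 0.2 s inspiration integrates to 0.2 ml
compute_tidal_volumes <- function(trace, breaths) {
  check_trace_df(trace)
  if (!nrow(breaths)) {
    breaths$tidal_volume_ml <- numeric(0)
    breaths$peak_insp_flow <- numeric(0)
    return(breaths)
  }
  if (!all(breaths$kind == "flow")) {
    rlang::abort("tidal volumes require a flow trace (kind = \"flow\")",
                 class = "reflexkit_error_kind")
  }
  tv <- numeric(nrow(breaths))
  pif <- numeric(nrow(breaths))
  for (k in seq_len(nrow(breaths))) {
    idx <- which(trace$time_s >= breaths$insp_onset_s[k] &
                   trace$time_s < breaths$exp_onset_s[k])
    if (length(idx) < 2L) {
      tv[k] <- 0; pif[k] <- 0
      next
    }
    v <- pmax(trace$value[idx], 0)  # inspiratory (positive) flow only
    tv[k] <- pracma::trapz(trace$time_s[idx], v)
    pif[k] <- max(v)
  }
  breaths$tidal_volume_ml <- tv
  breaths$peak_insp_flow <- pif
  breaths
}

#' Default eupneic filter bounds
#'
#' Bounds excluding respiratory events outside typical adult mouse
#' breathing: tidal volume above 2 ml or below 0.05 ml, or instantaneous
#' rate above 400 breaths/min. Bounds are inclusive for retention (a breath
#' at exactly 2 ml is kept; exclusion applies strictly beyond the bound).
#'
#' @param tv_max_ml,tv_min_ml Tidal-volume bounds (ml).
#' @param bpm_max Maximum instantaneous rate (breaths/min).
#' @return A list of class `"eupnea_filter_config"`.
#' @export
eupnea_filter_config <- function(tv_max_ml = 2, tv_min_ml = 0.05,
                                 bpm_max = 400) {
  stopifnot(tv_min_ml < tv_max_ml, bpm_max > 0)
  structure(list(tv_max_ml = tv_max_ml, tv_min_ml = tv_min_ml,
                 bpm_max = bpm_max),
            class = "eupnea_filter_config")
}

#' Filter a breath table to eupneic breaths
#'
#' Removes breaths outside the configured tidal-volume and rate bounds and
#' reports how many each rule removed. The filter is pure and idempotent.
#' Tidal-volume rules apply only when the table carries a
#' `tidal_volume_ml` column (flow traces); rate filtering always applies.
#'
#' @param breaths Breath table.
#' @param cfg Bounds from [eupnea_filter_config()].
#' @return A list with `breaths` (retained rows, indices preserved) and
#'   `exclusions`, a tibble counting removals per rule (`tv_max`, `tv_min`,
#'   `bpm_max`) plus distinct breaths removed.
#' @export
#' @examples
#' cfg <- eupnea_filter_config()
filter_eupneic <- function(breaths, cfg = eupnea_filter_config()) {
  stopifnot(inherits(cfg, "eupnea_filter_config"))
  has_tv <- "tidal_volume_ml" %in% names(breaths)
  tv <- if (has_tv) breaths$tidal_volume_ml else rep(NA_real_, nrow(breaths))
  bad_tv_max <- has_tv & !is.na(tv) & tv > cfg$tv_max_ml
  bad_tv_min <- has_tv & !is.na(tv) & tv < cfg$tv_min_ml
  bad_bpm <- breaths$inst_rate_bpm > cfg$bpm_max
  bad <- bad_tv_max | bad_tv_min | bad_bpm
  list(
    breaths = breaths[!bad, , drop = FALSE],
    exclusions = tibble::tibble(
      rule = c("tv_max", "tv_min", "bpm_max", "total"),
      n_excluded = c(sum(bad_tv_max), sum(bad_tv_min), sum(bad_bpm), sum(bad))
    )
  )
}

#' Summarize eupneic breathing over a time window
#'
#' Averages respiratory parameters over breaths whose inspiratory onset
#' falls in the half-open window `[start, end)`. Minute volume is the
#' product of mean tidal volume and mean rate; volume-dependent measures
#' are additionally normalized to body weight when one is supplied.
#'
#' @param breaths Breath table (typically after [filter_eupneic()]).
#' @param window Numeric length-2 vector `c(start_s, end_s)`.
#' @param body_weight_g Optional animal body weight in grams.
#' @return One-row tibble: `n_breaths`, `mean_tidal_volume_ml`,
#'   `mean_rate_bpm`, `minute_volume_ml_per_min`, `body_weight_g`,
#'   `tv_per_gram`, `minute_volume_per_gram`.
#' @export
#' @examples
#' # two breaths of 0.2 and 0.3 ml at 120 and 180 breaths/min average to
#' # 0.25 ml and 150 breaths/min
summarize_eupnea <- function(breaths, window, body_weight_g = NULL) {
  stopifnot(is.numeric(window), length(window) == 2L, window[1] < window[2])
  if (!nrow(breaths)) {
    rlang::abort("breath table is empty", class = "reflexkit_error_window")
  }
  span <- range(breaths$insp_onset_s)
  sel <- breaths[in_window(breaths$insp_onset_s, window[1], window[2]), ,
                 drop = FALSE]
  if (!nrow(sel)) {
    if (window[2] <= span[1] || window[1] > span[2]) {
      rlang::abort("window lies outside the span of the breath table",
                   class = "reflexkit_error_window_outside")
    }
    rlang::abort("no breaths fall in the requested window",
                 class = "reflexkit_error_window_empty")
  }
  mean_tv <- if ("tidal_volume_ml" %in% names(sel))
    mean(sel$tidal_volume_ml) else NA_real_
  mean_rate <- mean(sel$inst_rate_bpm)
  mv <- mean_tv * mean_rate
  bw <- if (is.null(body_weight_g)) NA_real_ else body_weight_g
  tibble::tibble(
    n_breaths = nrow(sel),
    mean_tidal_volume_ml = mean_tv,
    mean_rate_bpm = mean_rate,
    minute_volume_ml_per_min = mv,
    body_weight_g = bw,
    tv_per_gram = mean_tv / bw,
    minute_volume_per_gram = mv / bw
  )
}
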