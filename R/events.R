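#' Classify gasps and sighs from a breath table
#'
#' Flags augmented breaths by the >50% amplitude-ratio rule and types them
#' by stimulus context. Under the `"anaesthetized"` rule (tracheal or
#' oesophageal pressure recordings) a breath is called when its expiratory
#' amplitude exceeds 1.5 times that of both the previous and the subsequent
#' breath (strict inequality; a ratio of exactly 1.5 is not a call). Under
#' the `"plethysmography"` rule the same must additionally hold for the
#' inspiratory amplitude. Calls whose inspiratory onset falls inside a
#' stimulus window (`[start_s, observation_end_s)` of any epoch) are typed
#' `"gasp"`; calls outside any stimulus context are typed `"sigh"` - the
#' amplitude rule is identical, context is the only separator.
#'
#' The first and last breaths have no two neighbours and are never callable;
#' fewer than 3 breaths yields an empty result with a warning. Because only
#' amplitude ratios enter the rule, calling is scale invariant.
#'
#' @param breaths Breath table from [segment_breaths()].
#' @param rule `"anaesthetized"` (expiration only) or `"plethysmography"`
#'   (inspiration and expiration).
#' @param epochs Optional epoch tibble; `NULL` types every call as a sigh.
#' @param threshold Fractional amplitude increase required (default 0.5).
#' @return A tibble with one row per called breath: `breath`, `time_s`
#'   (inspiratory onset), `event_type`, the four neighbour amplitude ratios
#'   (`insp_ratio_prev`, `insp_ratio_next`, `exp_ratio_prev`,
#'   `exp_ratio_next`) and `in_epoch` (epoch label or `"none"`).
#' @export
#' @examples
#' b <- tibble::tibble(
#'   breath = 1:3, insp_onset_s = 0:2, insp_peak_s = 0:2 + 0.1,
#'   exp_onset_s = 0:2 + 0.2, exp_end_s = 0:2 + 0.9,
#'   insp_amplitude = c(1, 1.6, 1), exp_amplitude = c(1, 1.6, 1),
#'   duration_s = rep(1, 3), inst_rate_bpm = rep(60, 3), kind = "pressure")
#' classify_events(b, rule = "anaesthetized")
classify_events <- function(breaths,
                            rule = c("anaesthetized", "plethysmography"),
                            epochs = NULL,
                            threshold = 0.5) {
  rule <- match.arg(rule)
  empty <- tibble::tibble(
    breath = integer(), time_s = numeric(), event_type = character(),
    insp_ratio_prev = numeric(), insp_ratio_next = numeric(),
    exp_ratio_prev = numeric(), exp_ratio_next = numeric(),
    in_epoch = character())
  nb <- nrow(breaths)
  if (nb < 3L) {
    rlang::warn("fewer than 3 breaths; no events can be called")
    return(empty)
  }
  i <- 2:(nb - 1L)
  thr <- 1 + threshold
  exp_amp <- breaths$exp_amplitude
  insp_amp <- breaths$insp_amplitude
  exp_prev <- exp_amp[i] / exp_amp[i - 1L]
  exp_next <- exp_amp[i] / exp_amp[i + 1L]
  insp_prev <- insp_amp[i] / insp_amp[i - 1L]
  insp_next <- insp_amp[i] / insp_amp[i + 1L]
  call <- exp_prev > thr & exp_next > thr
  if (rule == "plethysmography") {
    call <- call & insp_prev > thr & insp_next > thr
  }
  idx <- i[call]
  if (!length(idx)) return(empty)
  t_ev <- breaths$insp_onset_s[idx]
  in_epoch <- rep("none", length(idx))
  if (!is.null(epochs) && nrow(epochs)) {
    for (k in seq_along(idx)) {
      hit <- which(in_window(t_ev[k], epochs$start_s,
                             epochs$observation_end_s))
      if (length(hit)) in_epoch[k] <- epochs$label[hit[1]]
    }
  }
  tibble::tibble(
    breath = breaths$breath[idx],
    time_s = t_ev,
    event_type = ifelse(in_epoch == "none", "sigh", "gasp"),
    insp_ratio_prev = insp_prev[call],
    insp_ratio_next = insp_next[call],
    exp_ratio_prev = exp_prev[call],
    exp_ratio_next = exp_next[call],
    in_epoch = in_epoch
  )
}

#' Gasp frequency over a stimulus or observation window
#'
#' Counts gasp calls in the chosen half-open window of an epoch and divides
#' by the window length in minutes. `"stimulus_window"` uses
#' `[start_s, end_s)` (e.g. gasps per minute of optogenetic illumination);
#' `"observation_window"` uses `[start_s, observation_end_s)` (e.g. the
#' 5-min watch after a nebulized stimulus). Counts over a partition of a
#' window sum to the total, so the measure is additive.
#'
#' @param events Event table from [classify_events()].
#' @param epoch One-row epoch tibble.
#' @param denominator `"observation_window"` or `"stimulus_window"`.
#' @return Gasps per minute (numeric scalar, >= 0).
#' @export
#' @examples
#' ep <- stimulus_epochs("illumination", 100, 110, 140)
#' ev <- tibble::tibble(time_s = 103, event_type = "gasp")
#' gasp_frequency(ev, ep, "stimulus_window")  # 1 gasp / (10/60) min = 6
gasp_frequency <- function(events, epoch,
                           denominator = c("observation_window",
                                           "stimulus_window")) {
  denominator <- match.arg(denominator)
  stopifnot(nrow(epoch) == 1L)
  end <- if (denominator == "stimulus_window") epoch$end_s else
    epoch$observation_end_s
  len_min <- (end - epoch$start_s) / 60
  if (len_min <= 0) {
    rlang::abort("epoch window has zero length", class = "reflexkit_error_window")
  }
  n <- sum(events$event_type == "gasp" &
             in_window(events$time_s, epoch$start_s, end))
  n / len_min
}

#' Normalize per-breath features to a pre-stimulus baseline
#'
#' Divides each chosen per-breath feature by the mean of that feature over
#' breaths whose inspiratory onsets fall in the 10-s window immediately
#' before stimulus onset (`[start_s - baseline_s, start_s)`). A feature that
#' is constant throughout normalizes to 1 everywhere.
#'
#' @param breaths Breath table.
#' @param epoch One-row epoch tibble (or any list with `start_s`).
#' @param features Character vector of feature columns to normalize
#'   (default the amplitude and rate columns present).
#' @param baseline_s Baseline length in seconds (default 10).
#' @return `breaths` with an added `<feature>_norm` column per feature.
#' @export
normalize_to_baseline <- function(breaths, epoch,
                                  features = NULL, baseline_s = 10) {
  start <- epoch$start_s[1]
  if (is.null(features)) {
    features <- intersect(
      c("insp_amplitude", "exp_amplitude", "inst_rate_bpm",
        "tidal_volume_ml", "peak_insp_flow"),
      names(breaths))
  }
  base <- breaths[in_window(breaths$insp_onset_s, start - baseline_s, start), ,
                  drop = FALSE]
  if (!nrow(base)) {
    rlang::abort(sprintf("no breaths in the %g-s baseline before stimulus onset",
                         baseline_s),
                 class = "reflexkit_error_baseline")
  }
  for (f in features) {
    m <- mean(base[[f]])
    breaths[[paste0(f, "_norm")]] <- breaths[[f]] / m
  }
  breaths
}

#' Hering-Breuer inspiratory reflex quantification
#'
#' Compares the breathing rate during a lung-inflation epoch with the rate
#' over a pre-inflation baseline. Rates are breath counts per window length;
#' an apnoeic inflation window (no breaths) therefore gives a normalized
#' rate of 0, and an absent reflex gives 1.
#'
#' @param breaths Breath table.
#' @param inflation_epoch One-row epoch tibble for the inflation
#'   (`[start_s, end_s)`, typically 10 s).
#' @param baseline_window Length-2 numeric `c(start, end)`; defaults to the
#'   10 s immediately preceding inflation.
#' @return One-row tibble: `baseline_rate_bpm`, `inflation_rate_bpm`,
#'   `normalized_rate`, and the windows used.
#' @export
hering_breuer <- function(breaths, inflation_epoch, baseline_window = NULL) {
  stopifnot(nrow(inflation_epoch) == 1L)
  s <- inflation_epoch$start_s
  e <- inflation_epoch$end_s
  if (is.null(baseline_window)) baseline_window <- c(s - 10, s)
  if (baseline_window[2] > s) {
    rlang::abort("baseline window must precede the inflation epoch",
                 class = "reflexkit_error_baseline")
  }
  n_base <- sum(in_window(breaths$insp_onset_s,
                          baseline_window[1], baseline_window[2]))
  if (n_base == 0L) {
    rlang::abort("no breaths in the baseline window",
                 class = "reflexkit_error_baseline")
  }
  base_rate <- 60 * n_base / diff(baseline_window)
  n_inf <- sum(in_window(breaths$insp_onset_s, s, e))
  inf_rate <- 60 * n_inf / (e - s)
  tibble::tibble(
    baseline_rate_bpm = base_rate,
    inflation_rate_bpm = inf_rate,
    normalized_rate = inf_rate / base_rate,
    baseline_start_s = baseline_window[1],
    baseline_end_s = baseline_window[2],
    inflation_start_s = s,
    inflation_end_s = e
  )
}

#' Latency from stimulus onset to the first gasp
#'
#' @param events Event table from [classify_events()].
#' @param epoch One-row epoch tibble; gasps are sought in
#'   `[start_s, observation_end_s)`.
#' @return Seconds from epoch start to the first gasp, or `NA` if none.
#' @export
#' @examples
#' ep <- stimulus_epochs("compression", 100, 110, 140)
#' ev <- tibble::tibble(time_s = 103, event_type = "gasp")
#' latency_to_first_gasp(ev, ep)  # 3
latency_to_first_gasp <- function(events, epoch) {
  stopifnot(nrow(epoch) == 1L)
  g <- events$time_s[events$event_type == "gasp" &
                       in_window(events$time_s, epoch$start_s,
                                 epoch$observation_end_s)]
  if (!length(g)) return(NA_real_)
  min(g) - epoch$start_s
}

#' Aggregate trial values to per-animal means and a group summary
#'
#' Implements the per-animal averaging convention used for group
#' comparisons: each animal contributes the mean of its trials, and the
#' group is summarized as the mean of animal means with the s.e.m. computed
#' across animals (sample s.d. / sqrt(n animals)). Results are invariant to
#' trial order and to duplicating an animal's trial list.
#'
#' @param data Data frame with one row per trial.
#' @param value Column of trial values (tidy-eval).
#' @param animal Column identifying the animal (tidy-eval, default
#'   `animal`).
#' @return Object of class `"trial_means"`; [generics::tidy()] returns the
#'   per-animal means, [generics::glance()] the one-row group summary
#'   (`mean`, `sem`, `n_animals`, `n_trials`).
#' @export
#' @examples
#' df <- tibble::tibble(animal = c("a", "a", "a", "b"),
#'                      gasps_per_min = c(1, 2, 3, 4))
#' glance(aggregate_trials(df, gasps_per_min))
aggregate_trials <- function(data, value, animal = animal) {
  value <- rlang::enquo(value)
  animal <- rlang::enquo(animal)
  if (!nrow(data)) {
    rlang::abort("no trials to aggregate", class = "reflexkit_error_empty")
  }
  per_animal <- data |>
    dplyr::group_by(!!animal) |>
    dplyr::summarise(mean_value = mean(!!value), n_trials = dplyr::n(),
                     .groups = "drop")
  group <- tibble::tibble(
    mean = mean(per_animal$mean_value),
    sem = stats::sd(per_animal$mean_value) / sqrt(nrow(per_animal)),
    n_animals = nrow(per_animal),
    n_trials = sum(per_animal$n_trials)
  )
  structure(list(per_animal = per_animal, group = group),
            class = "trial_means")
}

#' @export
print.trial_means <- function(x, ...) {
  cat("<trial_means> ", x$group$n_animals, " animals, ",
      x$group$n_trials, " trials\n", sep = "")
  cat("  group mean ", signif(x$group$mean, 4), " +/- ",
      signif(x$group$sem, 4), " (s.e.m.)\n", sep = "")
  invisible(x)
}

#' @rdname aggregate_trials
#' @param x A `trial_means` object.
#' @param ... Unused.
#' @export
tidy.trial_means <- function(x, ...) x$per_animal

#' @rdname aggregate_trials
#' @export
glance.trial_means <- function(x, ...) x$group

#' Score recovery of injected events against ground truth
#'
#' Matches called events to ground-truth events greedily by time (each
#' truth event matches at most one call of the same type within
#' `tol_s`) and reports sensitivity (matched / injected) and precision
#' (matched / called). Used to validate the detector against synthetic
#' recordings.
#'
#' @param events Event table from [classify_events()].
#' @param truth_events Ground-truth event tibble with `time_s` and `type`
#'   (as produced by [sim_breath_trace()]).
#' @param tol_s Matching tolerance in seconds (typically one breath
#'   period).
#' @param match_type Require event types to agree (default `TRUE`).
#' @return One-row tibble: `n_true`, `n_called`, `n_matched`,
#'   `sensitivity`, `precision`.
#' @export
event_recovery <- function(events, truth_events, tol_s,
                           match_type = TRUE) {
  n_true <- nrow(truth_events)
  n_called <- nrow(events)
  used <- rep(FALSE, n_called)
  matched <- 0L
  for (k in seq_len(n_true)) {
    ok <- !used & abs(events$time_s - truth_events$time_s[k]) <= tol_s
    if (match_type) ok <- ok & events$event_type == truth_events$type[k]
    hit <- which(ok)
    if (length(hit)) {
      used[hit[which.min(abs(events$time_s[hit] -
                               truth_events$time_s[k]))]] <- TRUE
      matched <- matched + 1L
    }
  }
  tibble::tibble(
    n_true = n_true,
    n_called = n_called,
    n_matched = matched,
    sensitivity = if (n_true) matched / n_true else NA_real_,
    precision = if (n_called) matched / n_called else NA_real_
  )
}
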