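#' Read a two-column trace CSV
#'
#' Traces are exchanged as CSV with the exact header `time_s,value`, a
#' strictly increasing and uniform time column, and numeric values. The
#' sampling rate is inferred from the median time step; any step deviating
#' from it by more than 1% is rejected as non-uniform sampling.
#'
#' @param path File path.
#' @return Tibble with columns `time_s`, `value`.
#' @export
read_trace_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(trimws(hdr), c("time_s", "value"))) {
    rlang::abort("trace CSV must have header `time_s,value`",
                 class = "reflexkit_error_header")
  }
  df <- suppressWarnings(readr::read_csv(path, col_types = "dd",
                                         progress = FALSE))
  if (nrow(readr::problems(df)) > 0 || anyNA(df$time_s) || anyNA(df$value)) {
    rlang::abort("trace CSV contains non-numeric or missing rows",
                 class = "reflexkit_error_numeric")
  }
  if (nrow(df) >= 3L) {
    dt <- diff(df$time_s)
    med <- stats::median(dt)
    if (med <= 0 || any(abs(dt - med) > 0.01 * med)) {
      rlang::abort("trace CSV has non-uniform sampling (steps deviate > 1% from the median)",
                   class = "reflexkit_error_sampling")
    }
  }
  tibble::as_tibble(df)
}

#' Write a trace CSV
#'
#' Writes `time_s,value` CSV that [read_trace_csv()] round-trips exactly
#' (shortest round-trip numeric representation).
#'
#' @param trace Data frame with `time_s` and `value`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  check_trace_df(trace)
  readr::write_csv(trace[c("time_s", "value")], path, progress = FALSE)
  invisible(path)
}

#' Read / write stimulus-epoch JSON
#'
#' Epoch tables serialize as a JSON array of objects with fields `label`,
#' `start_s`, `end_s`, `observation_end_s` and a free-form `meta` object;
#' round-trips are lossless for the tabular fields.
#'
#' @param path File path.
#' @return For `read_epochs_json()`, an epoch tibble (see
#'   [stimulus_epochs()]).
#' @export
read_epochs_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  stimulus_epochs(
    label = vapply(raw, function(e) e$label, character(1)),
    start_s = vapply(raw, function(e) e$start_s, numeric(1)),
    end_s = vapply(raw, function(e) e$end_s, numeric(1)),
    observation_end_s = vapply(raw, function(e)
      e$observation_end_s %||% e$end_s, numeric(1)),
    meta = lapply(raw, function(e) e$meta %||% list())
  )
}

#' @rdname read_epochs_json
#' @param epochs Epoch tibble.
#' @export
write_epochs_json <- function(epochs, path) {
  out <- lapply(seq_len(nrow(epochs)), function(i) {
    list(label = epochs$label[i],
         start_s = epochs$start_s[i],
         end_s = epochs$end_s[i],
         observation_end_s = epochs$observation_end_s[i],
         meta = if (!is.null(epochs$meta)) epochs$meta[[i]] else list())
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Analysis run configuration
#'
#' Collects every threshold and window of the pipeline in one object whose
#' defaults reproduce the standard analysis exactly: the >50% event
#' amplitude rule, the 3-s.d. calcium responsiveness criterion, Rc/Ri
#' selectivity bounds 2 and 0.5, 20-s F0 window, 10-s pre-stimulus
#' baseline, eupneic bounds (tidal volume 0.05-2 ml, 400 breaths/min),
#' integrator tau 0.02 s, 100-s serotonin window, 5-s response lag, and
#' half-up percentage rounding to 1 decimal. Serializes losslessly to JSON.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `"reflex_config"`.
#' @export
#' @examples
#' cfg <- reflex_config(seed = 7)
#' cfg$event_threshold
reflex_config <- function(...) {
  defaults <- list(
    event_threshold = 0.5,
    sd_threshold = 3,
    rcri_lower = 0.5,
    rcri_upper = 2,
    f0_window_s = 20,
    baseline_window_s = 10,
    tv_max_ml = 2,
    tv_min_ml = 0.05,
    bpm_max = 400,
    tau_s = 0.02,
    serotonin_window_s = 100,
    response_lag_s = 5,
    smoothing_window_s = 0.02,
    prominence_frac = 0.25,
    pct_digits = 1,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    rlang::abort(paste0("unknown config field(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "reflexkit_error_config")
  }
  defaults[names(dots)] <- dots
  structure(defaults, class = "reflex_config")
}

#' @rdname reflex_config
#' @param config A `reflex_config` object.
#' @param path File path.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "reflex_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname reflex_config
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$seed <- as.integer(raw$seed)
  do.call(reflex_config, raw)
}

#' Write a summary table or tally to CSV or JSON
#'
#' Serializes results with deterministic column order; JSON output embeds
#' the full run configuration for provenance. A `response_tally` is written
#' as its one-row [generics::glance()] summary joined with the per-category
#' breakdown; plain data frames are written as-is. Identical inputs produce
#' byte-identical files.
#'
#' @param x A data frame or [response_tally()] object.
#' @param path Destination path.
#' @param format `"csv"` or `"json"`.
#' @param config Run configuration recorded in JSON output.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path, format = c("csv", "json"),
                          config = reflex_config()) {
  format <- match.arg(format)
  tbl <- if (inherits(x, "response_tally")) {
    wide <- tidy(x) |>
      tidyr::pivot_wider(names_from = "category",
                         values_from = c("count", "pct"))
    dplyr::bind_cols(glance(x), wide)
  } else {
    as.data.frame(x)
  }
  tbl <- tbl[, sort(names(tbl)), drop = FALSE]
  if (format == "csv") {
    readr::write_csv(tibble::as_tibble(tbl), path, progress = FALSE)
  } else {
    jsonlite::write_json(list(config = unclass(config), results = tbl),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Serialize a simulated dataset's ground truth
#'
#' Every generated dataset travels with its ground truth so downstream
#' recovery can be checked later; `write_ground_truth_json()` stores the
#' `truth` element of a [sim_breath_trace()], [sim_calcium_session()] or
#' [sim_nerve_trace()] result (onsets, injected events, responder sets,
#' epoch gains, generating parameters) as JSON.
#'
#' @param sim A `reflex_sim` object, or its `truth` list.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(sim, path) {
  truth <- if (inherits(sim, "reflex_sim")) sim$truth else sim
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
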