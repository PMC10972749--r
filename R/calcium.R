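#' Extract ROI traces from a two-channel image stack
#'
#' Averages pixel fluorescence over each region of interest, per frame and
#' per channel. ROIs are delineated on the (stable) red channel in practice;
#' here they are supplied either as an integer label matrix (0 =
#' background) or as a named list of pixel coordinate matrices (two columns:
#' row, column, 1-based) which may not overlap.
#'
#' @param gcamp,tdtomato Numeric arrays of dimension `height x width x
#'   frames` with identical dimensions.
#' @param masks Integer label matrix (`height x width`) or a named list of
#'   two-column pixel coordinate matrices.
#' @param sampling_rate_hz Frame rate (Hz) used to construct `time_s`.
#' @return Long tibble with columns `roi`, `time_s`, `gcamp`, `tdtomato`.
#' @export
#' @examples
#' st <- array(10, c(4, 4, 3)); st2 <- array(20, c(4, 4, 3))
#' lab <- matrix(0L, 4, 4); lab[1:2, 1:2] <- 1L
#' extract_roi_traces(st, st2, lab, sampling_rate_hz = 2)
extract_roi_traces <- function(gcamp, tdtomato, masks, sampling_rate_hz = 1) {
  if (!identical(dim(gcamp), dim(tdtomato)) || length(dim(gcamp)) != 3L) {
    rlang::abort("gcamp and tdtomato must be h x w x frames arrays of identical shape",
                 class = "reflexkit_error_stack")
  }
  h <- dim(gcamp)[1]; w <- dim(gcamp)[2]; nf <- dim(gcamp)[3]

  if (is.matrix(masks) && is.numeric(masks)) {
    if (!identical(dim(masks), c(h, w))) {
      rlang::abort("label mask dimensions must match the frame dimensions",
                   class = "reflexkit_error_mask")
    }
    ids <- sort(setdiff(unique(as.integer(masks)), 0L))
    if (!length(ids)) {
      rlang::abort("label mask contains no ROIs", class = "reflexkit_error_mask")
    }
    pix <- lapply(ids, function(id) which(masks == id))
    names(pix) <- as.character(ids)
  } else if (is.list(masks)) {
    if (is.null(names(masks)) || any(names(masks) == "")) {
      rlang::abort("pixel-list masks must be a named list",
                   class = "reflexkit_error_mask")
    }
    pix <- lapply(names(masks), function(id) {
      coords <- masks[[id]]
      if (!length(coords)) {
        rlang::abort(paste0("ROI ", id, " has an empty mask"),
                     class = "reflexkit_error_mask")
      }
      coords <- matrix(as.integer(coords), ncol = 2)
      if (any(coords[, 1] < 1L | coords[, 1] > h |
                coords[, 2] < 1L | coords[, 2] > w)) {
        rlang::abort(paste0("ROI ", id, " has out-of-bounds pixels"),
                     class = "reflexkit_error_mask")
      }
      (coords[, 2] - 1L) * h + coords[, 1]
    })
    names(pix) <- names(masks)
    all_pix <- unlist(pix)
    if (anyDuplicated(all_pix)) {
      rlang::abort("ROI masks overlap", class = "reflexkit_error_mask")
    }
    ids <- names(masks)
  } else {
    rlang::abort("masks must be a label matrix or a named list of pixel coordinates",
                 class = "reflexkit_error_mask")
  }

  gm <- matrix(gcamp, h * w, nf)
  rm_ <- matrix(tdtomato, h * w, nf)
  time_s <- (seq_len(nf) - 1L) / sampling_rate_hz
  purrr::map2_dfr(pix, ids, function(idx, id) {
    tibble::tibble(
      roi = rep(if (is.character(id)) id else as.integer(id), nf),
      time_s = time_s,
      gcamp = colMeans(gm[idx, , drop = FALSE]),
      tdtomato = colMeans(rm_[idx, , drop = FALSE])
    )
  })
}

#' Flag unhealthy ROIs by strong, unvarying GCaMP fluorescence
#'
#' Cells that are saturated or dying show distinctively bright and nearly
#' constant GCaMP signal; such ROIs are excluded before response analysis.
#' An ROI is flagged when its GCaMP coefficient of variation falls below
#' `cv_threshold` AND its mean GCaMP exceeds the `level_quantile` quantile
#' of ROI means.
#'
#' @param traces Long ROI trace tibble (`roi`, `time_s`, `gcamp`,
#'   `tdtomato`).
#' @param cv_threshold Coefficient-of-variation cut (default 0.01).
#' @param level_quantile Brightness quantile an unhealthy ROI must exceed
#'   (default 0.9).
#' @return Tibble `roi`, `mean_gcamp`, `cv_gcamp`, `excluded_unhealthy`.
#' @export
exclude_unhealthy <- function(traces, cv_threshold = 0.01,
                              level_quantile = 0.9) {
  stats_tbl <- traces |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(mean_gcamp = mean(.data$gcamp),
                     cv_gcamp = stats::sd(.data$gcamp) / mean(.data$gcamp),
                     .groups = "drop")
  lvl <- stats::quantile(stats_tbl$mean_gcamp, level_quantile, names = FALSE)
  stats_tbl$excluded_unhealthy <-
    stats_tbl$cv_gcamp < cv_threshold & stats_tbl$mean_gcamp > lvl
  stats_tbl
}

# per-ROI baseline ratio over [t0 - f0_window_s, t0); errors if the window
# is not fully covered by the session
roi_f0 <- function(traces, t0, f0_window_s) {
  if (t0 - f0_window_s < min(traces$time_s) - 1e-9) {
    rlang::abort(sprintf(
      "insufficient baseline: need %g s of data before stimulus onset at %g s",
      f0_window_s, t0), class = "reflexkit_error_baseline")
  }
  traces |>
    dplyr::filter(in_window(.data$time_s, t0 - f0_window_s, t0)) |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(f0 = mean(.data$gcamp / .data$tdtomato),
                     .groups = "drop")
}

#' Ratiometric dF/F0 traces
#'
#' Computes the ratio R(t) = GCaMP(t) / tdTomato(t) per ROI, which cancels
#' any multiplicative factor shared by both channels (photobleaching,
#' motion-induced brightness changes, expression level), then expresses it
#' as a fractional change `(R - F0) / F0` about the baseline F0, the mean
#' ratio over the 20 s preceding the first stimulus epoch.
#'
#' @param traces Long ROI trace tibble; both channels must be positive.
#' @param epochs Epoch tibble; F0 is anchored to the first epoch's
#'   `start_s`. If `NULL`, F0 uses the first `f0_window_s` of the session.
#' @param f0_window_s Baseline window length (s), default 20.
#' @return Tibble `roi`, `time_s`, `ratio`, `f0`, `dff` covering the whole
#'   session.
#' @export
#' @examples
#' tr <- tibble::tibble(roi = 1, time_s = 0:29, gcamp = 100, tdtomato = 100)
#' all(ratiometric_dff(tr, f0_window_s = 20)$dff == 0)
ratiometric_dff <- function(traces, epochs = NULL, f0_window_s = 20) {
  if (any(traces$tdtomato <= 0)) {
    rlang::abort("tdTomato values must be positive for ratiometric normalization",
                 class = "reflexkit_error_ratio")
  }
  t0 <- if (!is.null(epochs) && nrow(epochs)) min(epochs$start_s) else
    min(traces$time_s) + f0_window_s
  f0_tbl <- roi_f0(traces, t0, f0_window_s)
  traces |>
    dplyr::mutate(ratio = .data$gcamp / .data$tdtomato) |>
    dplyr::left_join(f0_tbl, by = "roi") |>
    dplyr::mutate(dff = (.data$ratio - .data$f0) / .data$f0) |>
    dplyr::select("roi", "time_s", "ratio", "f0", "dff")
}

#' Score stimulus responsiveness of each ROI
#'
#' For every ROI and epoch, the response magnitude is the peak dF/F0 over
#' `[start_s, end_s + response_lag_s)`, computed against an F0 re-estimated
#' from the 20 s immediately preceding that epoch (tolerating slow drift
#' between epochs). An ROI is coded responsive to an epoch when that
#' magnitude is at least `sd_threshold` standard deviations above the mean
#' of its session-wide dF/F0 trace (and strictly above the mean, which
#' guards the degenerate all-flat case).
#'
#' Increasing an in-window peak can never turn a responsive ROI
#' nonresponsive for that epoch when session statistics are held fixed.
#'
#' @param traces Long ROI trace tibble.
#' @param epochs Epoch tibble; every epoch must lie inside the session.
#' @param f0_window_s Per-epoch baseline window (s), default 20.
#' @param response_lag_s Extension of the response window past epoch offset
#'   to capture offset-peaking transients (s), default 5.
#' @param sd_threshold Responsiveness criterion in session s.d. units,
#'   default 3.
#' @return Tibble with one row per ROI x epoch: `roi`, `epoch`, `f0`,
#'   `response_magnitude`, `session_mean`, `session_sd`, `responsive`.
#' @export
score_responsiveness <- function(traces, epochs, f0_window_s = 20,
                                 response_lag_s = 5, sd_threshold = 3) {
  stopifnot(!is.null(epochs), nrow(epochs) >= 1L)
  t_min <- min(traces$time_s); t_max <- max(traces$time_s)
  if (any(epochs$start_s < t_min | epochs$end_s > t_max + 1e-9)) {
    rlang::abort("epoch lies outside the imaging session",
                 class = "reflexkit_error_epoch")
  }
  session <- ratiometric_dff(traces, epochs, f0_window_s) |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(session_mean = mean(.data$dff),
                     session_sd = stats::sd(.data$dff), .groups = "drop")

  per_epoch <- purrr::map_dfr(seq_len(nrow(epochs)), function(i) {
    f0_tbl <- roi_f0(traces, epochs$start_s[i], f0_window_s)
    traces |>
      dplyr::filter(in_window(.data$time_s, epochs$start_s[i],
                              epochs$end_s[i] + response_lag_s)) |>
      dplyr::left_join(f0_tbl, by = "roi") |>
      dplyr::group_by(.data$roi) |>
      dplyr::summarise(
        f0 = .data$f0[1],
        response_magnitude = max((.data$gcamp / .data$tdtomato - .data$f0) /
                                   .data$f0),
        .groups = "drop") |>
      dplyr::mutate(epoch = epochs$label[i], .after = "roi")
  })
  per_epoch |>
    dplyr::left_join(session, by = "roi") |>
    dplyr::mutate(responsive =
      .data$response_magnitude >= .data$session_mean +
        sd_threshold * .data$session_sd &
      .data$response_magnitude > .data$session_mean)
}

#' Classify stimulus selectivity from compression/inflation responses
#'
#' For each ROI responsive to at least one of the two mechanical stimuli,
#' the selectivity ratio Rc/Ri (peak dF/F0 response to compression over
#' that to inflation) assigns a class: compression-selective when
#' Rc/Ri > 2, inflation-selective when Rc/Ri < 0.5, polymodal for the
#' interior. Ratios exactly at a boundary fall to polymodal (the open
#' selective intervals exclude them). ROIs responsive to neither stimulus
#' are `nonresponsive` with an undefined ratio. The classification depends
#' only on the ratio, hence is invariant to joint rescaling of (Rc, Ri).
#'
#' @param scores Output of [score_responsiveness()] containing both
#'   stimulus epochs.
#' @param compression_label,inflation_label Epoch labels of the two
#'   stimuli.
#' @param lower,upper Rc/Ri class bounds (defaults 0.5 and 2).
#' @return Tibble per ROI: `roi`, `rc`, `ri`, `responsive_compression`,
#'   `responsive_inflation`, `rc_ri`, `selectivity`.
#' @export
classify_selectivity <- function(scores,
                                 compression_label = "compression",
                                 inflation_label = "inflation",
                                 lower = 0.5, upper = 2) {
  need <- c(compression_label, inflation_label)
  if (!all(need %in% scores$epoch)) {
    rlang::abort(paste0("scores lack response magnitudes for epoch(s): ",
                        paste(setdiff(need, scores$epoch), collapse = ", ")),
                 class = "reflexkit_error_epoch")
  }
  wide <- scores |>
    dplyr::filter(.data$epoch %in% need) |>
    dplyr::select("roi", "epoch", "response_magnitude", "responsive") |>
    tidyr::pivot_wider(names_from = "epoch",
                       values_from = c("response_magnitude", "responsive"))
  rc <- wide[[paste0("response_magnitude_", compression_label)]]
  ri <- wide[[paste0("response_magnitude_", inflation_label)]]
  resp_c <- wide[[paste0("responsive_", compression_label)]]
  resp_i <- wide[[paste0("responsive_", inflation_label)]]
  any_resp <- resp_c | resp_i
  # a negative peak dF/F0 means no response at all; floor at 0 so the ratio
  # saturates (Inf / 0) instead of flipping sign
  rc_ri <- ifelse(any_resp, pmax(rc, 0) / pmax(ri, 0), NA_real_)
  selectivity <- dplyr::case_when(
    !any_resp ~ "nonresponsive",
    rc_ri > upper ~ "compression_selective",
    rc_ri < lower ~ "inflation_selective",
    .default = "polymodal"
  )
  tibble::tibble(
    roi = wide$roi, rc = rc, ri = ri,
    responsive_compression = resp_c,
    responsive_inflation = resp_i,
    rc_ri = rc_ri, selectivity = selectivity
  )
}

#' Build a responder tally from category counts
#'
#' Constructs the population accounting used for imaging cohorts: counts of
#' neurons responsive to only compression, only inflation, both, or
#' neither, together with derived any-stimulus counts and percentages
#' (half-up rounding). The four categories must partition the cohort.
#'
#' @param compression_only,inflation_only,both,neither Category counts.
#' @param digits Decimal places for percentages (default 1).
#' @return Object of class `"response_tally"`. [generics::tidy()] gives a
#'   per-category tibble; [generics::glance()] a one-row summary with the
#'   derived any-compression / any-inflation counts, their cohort
#'   percentages, and the conditional split of compression responders into
#'   stretch-insensitive and dual responders.
#' @export
#' @examples
#' tl <- response_tally(91, 64, 29, 1119)
#' glance(tl)$any_compression_pct  # 9.2
response_tally <- function(compression_only, inflation_only, both, neither,
                           digits = 1) {
  counts <- c(compression_only = compression_only,
              inflation_only = inflation_only,
              both = both, neither = neither)
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("category counts must be nonnegative integers",
                 class = "reflexkit_error_tally")
  }
  total <- sum(counts)
  if (total == 0) {
    rlang::abort("empty cohort", class = "reflexkit_error_tally")
  }
  any_c <- compression_only + both
  any_i <- inflation_only + both
  structure(list(
    counts = counts,
    total = total,
    digits = digits,
    pct = pct_of(counts, total, digits),
    any_compression = any_c,
    any_inflation = any_i,
    any_compression_pct = pct_of(any_c, total, digits),
    any_inflation_pct = pct_of(any_i, total, digits),
    compression_only_of_compression_pct =
      if (any_c > 0) pct_of(compression_only, any_c, digits) else NA_real_,
    both_of_compression_pct =
      if (any_c > 0) pct_of(both, any_c, digits) else NA_real_
  ), class = "response_tally")
}

#' Tally responder categories across a cohort
#'
#' Cross-tabulates per-ROI compression/inflation responsiveness flags into
#' the four-way partition (only compression, only inflation, both,
#' neither) and derives cohort percentages. Accepts the output of
#' [classify_selectivity()] or any data frame with logical
#' `compression`/`inflation` (or `responsive_compression` /
#' `responsive_inflation`) columns.
#'
#' @param flags Per-ROI data frame of responsiveness flags.
#' @param digits Decimal places for percentages.
#' @return A [response_tally()] object.
#' @export
tally_responses <- function(flags, digits = 1) {
  cc <- flags[["responsive_compression"]] %||% flags[["compression"]]
  ii <- flags[["responsive_inflation"]] %||% flags[["inflation"]]
  if (is.null(cc) || is.null(ii) || !is.logical(cc) || !is.logical(ii) ||
      anyNA(cc) || anyNA(ii)) {
    rlang::abort("flags need complete logical compression and inflation columns so categories partition the cohort",
                 class = "reflexkit_error_tally")
  }
  response_tally(sum(cc & !ii), sum(!cc & ii), sum(cc & ii), sum(!cc & !ii),
                 digits = digits)
}

#' @export
print.response_tally <- function(x, ...) {
  cat("<response_tally> ", x$total, " neurons\n", sep = "")
  lbl <- c("only compression", "only inflation", "both", "neither")
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-16s %5d (%s%%)\n", lbl[i], x$counts[i],
                format(x$pct[i])))
  }
  invisible(x)
}

#' @rdname response_tally
#' @param x A `response_tally` object.
#' @param ... Unused.
#' @export
tidy.response_tally <- function(x, ...) {
  tibble::tibble(
    category = names(x$counts),
    count = as.integer(x$counts),
    pct = unname(x$pct)
  )
}

#' @rdname response_tally
#' @export
glance.response_tally <- function(x, ...) {
  tibble::tibble(
    total = x$total,
    any_compression = x$any_compression,
    any_compression_pct = x$any_compression_pct,
    any_inflation = x$any_inflation,
    any_inflation_pct = x$any_inflation_pct,
    compression_only_of_compression_pct = x$compression_only_of_compression_pct,
    both_of_compression_pct = x$both_of_compression_pct
  )
}
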