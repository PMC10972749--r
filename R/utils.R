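#' Round half away from zero
#'
#' Cohort percentages in reports are rounded half-up (so 5.0505% of a cohort
#' prints as 5.1%), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a cohort
#'
#' Converts a count/total pair into a percentage with half-up rounding, the
#' convention used for all population tallies (e.g. 120 of 1,303 neurons
#' -> 9.2).
#'
#' @param count Number of members in the category.
#' @param total Cohort size (> 0).
#' @param digits Decimal places (default 1; use 0 where integer percentages
#'   are reported).
#' @return Percentage on the 0-100 scale.
#' @export
#' @examples
#' pct_of(120, 1303)
#' pct_of(130, 209, digits = 0)
pct_of <- function(count, total, digits = 1) {
  stopifnot(is.numeric(count), is.numeric(total), all(total > 0))
  round_half_up(100 * count / total, digits)
}

# half-open window membership [start, end)
in_window <- function(t, start, end) {
  t >= start & t < end
}

# sampling interval / rate inferred from a time column
infer_dt <- function(time_s) {
  if (length(time_s) < 2) {
    rlang::abort("need at least 2 samples to infer a sampling rate",
                 class = "reflexkit_error_trace")
  }
  stats::median(diff(time_s))
}

infer_fs <- function(time_s) 1 / infer_dt(time_s)

check_trace_df <- function(x, arg = "trace") {
  if (!is.data.frame(x) || !all(c("time_s", "value") %in% names(x))) {
    rlang::abort(
      paste0("`", arg, "` must be a data frame with columns time_s and value"),
      class = "reflexkit_error_trace")
  }
  if (!all(is.finite(x$value))) {
    rlang::abort("trace values must be finite", class = "reflexkit_error_trace")
  }
  invisible(x)
}

# centred moving average with shrinking windows at the edges (cumsum-based)
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L || length(x) < 2L) return(x)
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local maxima with a topographic-prominence filter.
# Returns integer indices of retained peaks, in increasing order.
# min_height applies to the raw value; min_dist (samples) keeps the higher of
# any two peaks closer than that.
find_peaks <- function(x, min_prom, min_height = -Inf, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  dx <- diff(x)
  s <- sign(dx)
  # carry sign through plateaus so flat-topped peaks register once;
  # a leading flat segment keeps sign 0
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  idx <- cummax(ifelse(nz, seq_along(s), 0L))
  s <- ifelse(idx == 0L, 0, s[pmax(idx, 1L)])
  cand <- which(s[-length(s)] > 0 & s[-1] < 0) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))

  prominence <- function(i) {
    h <- x[i]
    # walk left to the previous strictly-higher sample, tracking the valley
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }
  prom <- vapply(cand, prominence, numeric(1))
  keep <- cand[prom >= min_prom]
  if (length(keep) > 1L && min_dist > 1L) {
    ord <- keep[order(x[keep], decreasing = TRUE)]
    taken <- integer(0)
    for (i in ord) {
      if (!length(taken) || all(abs(taken - i) >= min_dist)) {
        taken <- c(taken, i)
      }
    }
    keep <- sort(taken)
  }
  keep
}
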