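# Interval series shared by the heart-rate (RR, ms) and respiration
# (breath-to-breath, s) feature modules. Unfilled gaps in the source grid
# break the series into segments; successive differences are never taken
# across a break.

#' Construct an interval series
#'
#' @param intervals Positive numeric intervals (RR in ms, breath-to-breath
#'   in s).
#' @param times Wall-clock times (s since midnight) of the source samples;
#'   defaults to an index-based clock.
#' @param segments Integer segment labels; successive differences are only
#'   formed inside a segment.
#' @param unit `"ms"` or `"s"`.
#' @param source_step Grid step (s) of the source signal, used for
#'   wall-clock segmentation statistics.
#' @return An object of class `interval_series`.
#' @export
interval_series <- function(intervals, times = NULL, segments = NULL,
                            unit = c("ms", "s"), source_step = 1) {
  unit <- match.arg(unit)
  intervals <- as.numeric(intervals)
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("intervals must be finite and > 0", call. = FALSE)
  }
  n <- length(intervals)
  if (is.null(times)) times <- (seq_len(n) - 1) * source_step
  if (is.null(segments)) segments <- rep(1L, n)
  stopifnot(length(times) == n, length(segments) == n)
  structure(list(intervals = intervals, times = as.numeric(times),
                 segments = as.integer(segments), unit = unit,
                 source_step = source_step),
            class = "interval_series")
}

#' @export
print.interval_series <- function(x, ...) {
  cat("<interval_series>", length(x$intervals), "intervals (", x$unit, "),",
      length(unique(x$segments)), "segment(s)\n")
  invisible(x)
}

# Successive differences within segments only.
successive_diffs <- function(is) {
  same <- is$segments[-1] == is$segments[-length(is$segments)]
  diff(is$intervals)[same]
}

# Poincare point pairs (x_i, y_i) = (I_i, I_{i+1}) within segments.
poincare_points <- function(is) {
  n <- length(is$intervals)
  if (n < 2) return(list(x = numeric(), y = numeric()))
  same <- is$segments[-1] == is$segments[-n]
  list(x = is$intervals[-n][same], y = is$intervals[-1][same])
}

# Derive an interval series from a preprocessed regular signal by pointwise
# inversion of the rate. Present runs become segments.
intervals_from_rate <- function(signal, numerator, unit) {
  stopifnot(signal$is_regular)
  keep <- !is.na(signal$values)
  v <- signal$values[keep]
  if (length(v) == 0) {
    return(interval_series(numeric(0), unit = unit,
                           source_step = signal$grid_step))
  }
  if (any(v <= 0)) stop("rate values must be > 0 to derive intervals",
                        call. = FALSE)
  seg <- cumsum(c(1L, as.integer(diff(which(keep)) > 1)))
  interval_series(numerator / v, times = signal$timestamps[keep],
                  segments = seg, unit = unit,
                  source_step = signal$grid_step)
}

#' Derive the beat-to-beat (RR) interval series from a heart-rate signal
#'
#' Each present heart-rate sample (bpm) is inverted to an RR interval,
#' `RR = 60000 / HR` milliseconds, preserving order. Runs of present samples
#' separated by unfilled gaps become separate segments; successive
#' differences are never taken across a gap.
#'
#' @param hr A preprocessed regular heart-rate [ts_signal()].
#' @return An [interval_series()] in milliseconds.
#' @export
derive_bbi <- function(hr) {
  stopifnot(hr$kind %in% c("heart_rate", "bbi"))
  if (hr$kind == "bbi") {
    keep <- !is.na(hr$values)
    seg <- cumsum(c(1L, as.integer(diff(which(keep)) > 1)))
    return(interval_series(hr$values[keep], times = hr$timestamps[keep],
                           segments = seg, unit = "ms",
                           source_step = hr$grid_step))
  }
  intervals_from_rate(hr, 60000, "ms")
}

#' Derive the breath-to-breath interval series from a respiration-rate signal
#'
#' Each present respiration-rate sample (breaths/min) is inverted to a
#' breath-to-breath interval, `BB = 60 / rate` seconds.
#'
#' @param resp A preprocessed regular respiration-rate [ts_signal()].
#' @return An [interval_series()] in seconds.
#' @export
derive_bb <- function(resp) {
  stopifnot(resp$kind == "respiration_rate")
  intervals_from_rate(resp, 60, "s")
}
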