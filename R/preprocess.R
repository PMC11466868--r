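# Preprocessing: retime -> detect gaps -> bounded linear fill -> moving-average
# denoise. Instantaneous signals run all four stages; cumulative counters are
# retimed (sum semantics) only.

# Grid covering the signal: full day [0, 86400) for daytime kinds, the observed
# span rounded outward to the grid for nocturnal kinds (SpO2, respiration are
# collected only during sleep; filling a whole day of absent values would be
# meaningless).
grid_for <- function(signal, grid_step) {
  info <- kind_info(signal$kind)
  if (info$nocturnal && length(signal$timestamps) > 0) {
    lo <- floor(min(signal$timestamps) / grid_step) * grid_step
    hi <- ceiling(max(signal$timestamps) / grid_step) * grid_step
    hi <- min(hi, 86400 - grid_step)
    seq(lo, hi, by = grid_step)
  } else {
    seq(0, 86400 - grid_step, by = grid_step)
  }
}

#' Retime an irregular signal onto a uniform grid
#'
#' Each raw sample is assigned to its nearest grid point (ties, a sample
#' exactly halfway between two grid points, go to the earlier one). Each grid
#' point takes the arithmetic mean of its assigned samples for instantaneous
#' kinds, or their sum for cumulative kinds (per-interval increments). Grid
#' points with no assigned sample are absent (`NA`). The original data are
#' thereby preserved, only translated to the constant time grid.
#'
#' @param signal A [ts_signal()] (irregular or already regular).
#' @param grid_step Grid step in seconds; defaults to the kind's nominal step.
#' @return A regular [ts_signal()] on the grid.
#' @export
retime <- function(signal, grid_step = NULL) {
  info <- kind_info(signal$kind)
  if (is.null(grid_step)) grid_step <- info$nominal_step
  stopifnot(grid_step > 0)
  grid <- grid_for(signal, grid_step)
  out <- rep(NA_real_, length(grid))
  if (length(signal$timestamps) == 0) {
    warning("empty input signal; returning all-absent grid", call. = FALSE)
  } else {
    rel <- signal$timestamps - grid[1]
    j0 <- floor(rel / grid_step)
    frac <- rel - j0 * grid_step
    idx <- j0 + (frac > grid_step / 2)      # tie (== step/2) -> earlier point
    idx <- pmin(pmax(idx, 0), length(grid) - 1) + 1
    f <- if (info$aggregation == "cumulative") sum else mean
    agg <- tapply(signal$values, idx, f)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  sig <- ts_signal(signal$kind, grid, out, is_regular = TRUE,
                   grid_step = grid_step, day = signal$day)
  attr(sig, "daily_total") <- attr(signal, "daily_total")
  sig
}

#' Detect gaps in a regular signal
#'
#' Finds maximal runs of consecutive absent grid points and classifies each as
#' fillable or not: a gap is fillable when its duration does not exceed the
#' kind's maximum gap (60 s for heart rate and beat-to-beat intervals, 120 s
#' for SpO2, 300 s for respiration rate; cumulative counters are never
#' filled) and it has present neighbours on both sides (runs touching the grid
#' boundary are reported but never fillable).
#'
#' @param signal A regular [ts_signal()].
#' @param max_gap Maximum fillable gap duration (s); defaults to the kind's
#'   registry value. `NA` disables filling.
#' @return A list of gap segments, each a list with `start`, `end`,
#'   `duration` (s), `n_missing`, `fillable`.
#' @export
detect_gaps <- function(signal, max_gap = NULL) {
  stopifnot(signal$is_regular)
  if (is.null(max_gap)) max_gap <- kind_info(signal$kind)$max_gap
  miss <- is.na(signal$values)
  if (!any(miss)) return(list())
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gaps <- list()
  step <- signal$grid_step
  n <- length(signal$values)
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    dur <- (i1 - i0 + 1) * step
    boundary <- i0 == 1 || i1 == n
    gaps[[length(gaps) + 1]] <- list(
      start = signal$timestamps[i0],
      end = signal$timestamps[i0] + dur,
      duration = dur,
      n_missing = as.integer(i1 - i0 + 1),
      fillable = !boundary && !is.na(max_gap) && dur <= max_gap,
      i0 = i0, i1 = i1
    )
  }
  gaps
}

#' Fill fillable gaps by linear interpolation
#'
#' Every fillable gap is replaced by the straight line between the last
#' present value before and the first present value after the gap;
#' non-fillable gaps are left absent. Originally present values are never
#' touched.
#'
#' @param signal A regular [ts_signal()].
#' @param gaps Gap list from [detect_gaps()] on the same signal.
#' @return The signal with fillable gaps interpolated; the number of filled
#'   points is recorded in the `n_filled` attribute.
#' @export
fill_gaps <- function(signal, gaps) {
  stopifnot(signal$is_regular)
  v <- signal$values
  n_filled <- 0L
  for (g in gaps) {
    if (any(!is.na(v[g$i0:g$i1]))) {
      stop("gap list inconsistent with signal: values present inside gap",
           call. = FALSE)
    }
    if (!g$fillable) next
    left <- v[g$i0 - 1]; right <- v[g$i1 + 1]
    if (is.na(left) || is.na(right)) {
      stop("gap list inconsistent with signal: absent neighbour", call. = FALSE)
    }
    k <- g$n_missing
    v[g$i0:g$i1] <- left + (right - left) * seq_len(k) / (k + 1)
    n_filled <- n_filled + k
  }
  out <- ts_signal(signal$kind, signal$timestamps, v, is_regular = TRUE,
                   grid_step = signal$grid_step, day = signal$day)
  attr(out, "daily_total") <- attr(signal, "daily_total")
  attr(out, "n_filled") <- n_filled
  out
}

#' Centred moving-average denoising
#'
#' Smooths a regular signal with a centred moving average of odd width.
#' Absent values stay absent and act as hard window boundaries: the window
#' never averages across an unfilled gap, and at series edges or next to a
#' gap it shrinks to the available samples. Width 1 is the identity.
#'
#' @param signal A regular [ts_signal()].
#' @param window Odd integer window width in samples (default 3).
#' @return The smoothed signal, same length.
#' @export
denoise <- function(signal, window = 3) {
  stopifnot(signal$is_regular)
  if (window < 1 || window %% 2 != 1) {
    stop("window must be an odd integer >= 1", call. = FALSE)
  }
  if (window == 1) return(signal)
  h <- (window - 1) %/% 2
  v <- signal$values
  out <- v
  miss <- is.na(v)
  if (any(!miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(!r$values)) {
      seg <- v[starts[k]:ends[k]]
      L <- length(seg)
      cs <- cumsum(c(0, seg))
      i <- seq_len(L)
      lo <- pmax(1, i - h); hi <- pmin(L, i + h)
      out[starts[k]:ends[k]] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    }
  }
  res <- ts_signal(signal$kind, signal$timestamps, out, is_regular = TRUE,
                   grid_step = signal$grid_step, day = signal$day)
  attr(res, "daily_total") <- attr(signal, "daily_total")
  res
}

#' Preprocess one signal-day
#'
#' Composes the full signal-conditioning chain for the kind: retiming onto
#' the uniform grid, gap detection, bounded linear gap filling and
#' moving-average denoising for instantaneous kinds; retiming only (sum
#' semantics, no filling, no smoothing) for cumulative counters.
#'
#' @param signal A [ts_signal()] (typically irregular, from [read_signal()]).
#' @param config A [pipeline_config()].
#' @return A list with `signal` (the cleaned regular [ts_signal()]) and
#'   `report` (raw/grid/filled counts, the gap list, window used).
#' @export
preprocess <- function(signal, config = pipeline_config()) {
  info <- kind_info(signal$kind)
  n_raw <- length(signal$values)
  step <- unname(config$grid_step[signal$kind])
  reg <- retime(signal, step)
  if (info$aggregation == "cumulative") {
    gaps <- detect_gaps(reg, max_gap = NA)   # reported, never filled
    report <- list(n_raw = n_raw, n_grid = length(reg$values), gaps = gaps,
                   n_filled = 0L,
                   n_unfilled = sum(vapply(gaps, `[[`, 0L, "n_missing")),
                   denoise_window_used = 1L)
    return(list(signal = reg, report = report))
  }
  gaps <- detect_gaps(reg, max_gap = unname(config$max_gap[signal$kind]))
  filled <- fill_gaps(reg, gaps)
  n_filled <- attr(filled, "n_filled")
  smoothed <- denoise(filled, config$denoise_window)
  report <- list(
    n_raw = n_raw, n_grid = length(reg$values), gaps = gaps,
    n_filled = n_filled,
    n_unfilled = sum(vapply(gaps, `[[`, 0L, "n_missing")) - n_filled,
    denoise_window_used = config$denoise_window
  )
  list(signal = smoothed, report = report)
}
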