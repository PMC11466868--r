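#' Signal kind registry
#'
#' The pipeline handles seven wearable health streams, each with a fixed
#' aggregation semantic and a nominal sampling step: heart rate and
#' beat-to-beat interval at 15 s, nocturnal SpO2 and respiration rate at 60 s,
#' and cumulative step/calorie counters at 15 min. Intensity minutes is a
#' daily summary scalar that is passed through untouched.
#'
#' @return A data.frame with one row per signal kind: `kind`, `aggregation`
#'   (`"cumulative"`, `"instantaneous"` or `"summary"`), `nominal_step`
#'   (seconds), `max_gap` (largest gap duration in seconds that linear
#'   interpolation may fill; `NA` means gap filling is skipped), physiological
#'   plausibility bounds `lo`/`hi`, and `nocturnal` (whether the stream covers
#'   only the sleep window rather than the full day).
#' @export
signal_kinds <- function() {
  data.frame(
    kind = c("steps", "calories", "intensity_minutes", "heart_rate",
             "bbi", "spo2", "respiration_rate"),
    aggregation = c("cumulative", "cumulative", "summary", "instantaneous",
                    "instantaneous", "instantaneous", "instantaneous"),
    nominal_step = c(900, 900, 86400, 15, 15, 60, 60),
    max_gap = c(NA, NA, NA, 60, 60, 120, 300),
    lo = c(0, 0, 0, 20, 60000 / 250, 50, 4),
    hi = c(Inf, Inf, 1440, 250, 60000 / 20, 100, 60),
    nocturnal = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Look up the registry row for one signal kind
#' @param kind Signal kind name (see [signal_kinds()]).
#' @return A one-row list of kind properties.
#' @keywords internal
kind_info <- function(kind) {
  reg <- signal_kinds()
  i <- match(kind, reg$kind)
  if (is.na(i)) {
    stop("unknown signal kind: '", kind, "' (expected one of ",
         paste(reg$kind, collapse = ", "), ")", call. = FALSE)
  }
  as.list(reg[i, ])
}

#' Construct a timestamped value stream for one signal and one day
#'
#' A `ts_signal` holds one signal kind over one calendar day. Timestamps are
#' seconds since local midnight of that day. Irregular signals carry only the
#' observed samples; regular signals live on a uniform grid where missing grid
#' points are explicit `NA` values.
#'
#' @param kind Signal kind name (see [signal_kinds()]).
#' @param timestamps Numeric, strictly increasing, seconds since local
#'   midnight, within `[0, 86400)`.
#' @param values Numeric, same length. `NA` allowed only in regular signals
#'   (absent grid points).
#' @param is_regular Logical: does the signal live on a uniform grid?
#' @param grid_step Grid step in seconds; required iff `is_regular`.
#' @param day Optional day identifier (e.g. `"2023-05-01"`).
#' @return An object of class `ts_signal`.
#' @export
ts_signal <- function(kind, timestamps, values, is_regular = FALSE,
                      grid_step = NULL, day = NA_character_) {
  kind_info(kind)  # validates kind
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values)) {
    stop("timestamps and values must have equal length", call. = FALSE)
  }
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0)) {
    bad <- which(diff(timestamps) <= 0)[1] + 1L
    stop("timestamps not strictly increasing at row ", bad, call. = FALSE)
  }
  if (any(timestamps < 0 | timestamps >= 86400)) {
    stop("timestamps must lie in [0, 86400) seconds since midnight",
         call. = FALSE)
  }
  if (!is_regular && anyNA(values)) {
    stop("irregular signals cannot contain NA values", call. = FALSE)
  }
  if (is_regular) {
    if (is.null(grid_step) || grid_step <= 0) {
      stop("regular signals need a positive grid_step", call. = FALSE)
    }
    if (length(timestamps) > 1) {
      off <- (timestamps - timestamps[1]) / grid_step
      if (any(abs(off - round(off)) > 1e-9)) {
        stop("regular signal timestamps must be multiples of grid_step apart",
             call. = FALSE)
      }
    }
  } else {
    grid_step <- NULL
  }
  structure(
    list(kind = kind, timestamps = timestamps, values = values,
         is_regular = is_regular, grid_step = grid_step, day = day),
    class = "ts_signal"
  )
}

#' @export
print.ts_signal <- function(x, ...) {
  n <- length(x$values)
  na <- sum(is.na(x$values))
  cat("<ts_signal> kind:", x$kind,
      if (x$is_regular) sprintf("regular (step %gs)", x$grid_step) else "irregular",
      "\n  samples:", n, if (na > 0) sprintf("(%d absent)", na) else "",
      "\n  span:", if (n > 0) sprintf("%.0f..%.0f s since midnight",
                                      min(x$timestamps), max(x$timestamps)) else "empty",
      "\n")
  invisible(x)
}

#' @export
summary.ts_signal <- function(object, ...) {
  v <- object$values[!is.na(object$values)]
  cat("Signal:", object$kind, "| n =", length(object$values),
      "| present =", length(v), "\n")
  if (length(v) > 0) print(summary(v))
  invisible(object)
}

#' @export
plot.ts_signal <- function(x, ...) {
  plot(x$timestamps / 3600, x$values, type = if (x$is_regular) "l" else "p",
       xlab = "Hours since midnight", ylab = x$kind, main = x$kind, ...)
  invisible(x)
}

# Present (non-absent) samples of a signal as (timestamps, values).
present_samples <- function(signal) {
  keep <- !is.na(signal$values)
  list(timestamps = signal$timestamps[keep], values = signal$values[keep])
}
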