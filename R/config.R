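#' Pipeline configuration
#'
#' All tunables of the preprocessing and feature-extraction pipeline in one
#' object. Defaults follow the study protocol: per-signal grid steps of 15 s
#' (heart rate, beat-to-beat), 60 s (SpO2, respiration rate) and 900 s
#' (steps, calories); maximum fillable gap durations of 60 s (heart rate,
#' beat-to-beat), 120 s (SpO2) and 300 s (respiration rate) with no gap
#' filling for the cumulative counters; a 3-sample moving-average window; a
#' 90% desaturation threshold; and the standard VLF/LF/HF spectral bands.
#'
#' @param grid_step Named numeric: per-kind grid step (s).
#' @param max_gap Named numeric: per-kind maximum fillable gap duration (s);
#'   `NA` disables gap filling for that kind.
#' @param denoise_window Odd integer >= 1; width (samples) of the centred
#'   moving average. 1 disables smoothing.
#' @param desat_threshold Desaturation threshold (% SpO2).
#' @param spectral_bands List of `c(lo, hi)` band edges in Hz; must be
#'   ordered and non-overlapping.
#' @param resample_rate Uniform resampling rate (Hz) for spectral analysis of
#'   the breath-interval tachogram.
#' @param welch_nperseg,welch_overlap Welch segment length (samples) and
#'   fractional overlap.
#' @param entropy_m Embedding dimension for ApEn/SampEn.
#' @param entropy_r Tolerance as a fraction of the series SD.
#' @param dfa_short,dfa_long Scale ranges (samples) for the short- and
#'   long-term DFA regimes.
#' @param mfdfa_q Moment orders for multifractal DFA (0 excluded).
#' @param baseline_window Width (s) of the rolling window whose lowest mean
#'   locates the baseline heart rate.
#' @param mx_offset Offset x (percentage points below the median) for the
#'   SpO2 Mx feature.
#' @param delta_epoch Epoch length (s) for the SpO2 Delta Index.
#' @param rng_seed Integer seed used by stochastic helpers.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_step = NULL,
                            max_gap = NULL,
                            denoise_window = 3,
                            desat_threshold = 90,
                            spectral_bands = list(VLF = c(0, 0.04),
                                                  LF = c(0.04, 0.15),
                                                  HF = c(0.15, 0.4)),
                            resample_rate = 4,
                            welch_nperseg = 256,
                            welch_overlap = 0.5,
                            entropy_m = 2,
                            entropy_r = 0.2,
                            dfa_short = c(4, 16),
                            dfa_long = c(16, 64),
                            mfdfa_q = setdiff(-5:5, 0),
                            baseline_window = 1800,
                            mx_offset = 1,
                            delta_epoch = 12,
                            rng_seed = 1L) {
  reg <- signal_kinds()
  gs <- stats::setNames(reg$nominal_step, reg$kind)
  mg <- stats::setNames(reg$max_gap, reg$kind)
  if (!is.null(grid_step)) gs[names(grid_step)] <- grid_step
  if (!is.null(max_gap)) mg[names(max_gap)] <- max_gap
  if (denoise_window < 1 || denoise_window %% 2 != 1) {
    stop("denoise_window must be an odd integer >= 1", call. = FALSE)
  }
  edges <- do.call(rbind, spectral_bands)
  if (any(edges[, 2] <= edges[, 1])) stop("each band needs lo < hi", call. = FALSE)
  if (nrow(edges) > 1 && any(edges[-1, 1] < edges[-nrow(edges), 2] - 1e-12)) {
    stop("spectral bands must be ordered and non-overlapping", call. = FALSE)
  }
  bad <- !is.na(mg) & mg < gs[names(mg)]
  if (any(bad)) {
    stop("max_gap must be >= grid_step for: ",
         paste(names(mg)[bad], collapse = ", "), call. = FALSE)
  }
  if (any(mfdfa_q == 0)) stop("mfdfa_q must exclude 0", call. = FALSE)
  structure(
    list(grid_step = gs, max_gap = mg,
         denoise_window = as.integer(denoise_window),
         desat_threshold = desat_threshold,
         spectral_bands = spectral_bands,
         resample_rate = resample_rate,
         welch_nperseg = as.integer(welch_nperseg),
         welch_overlap = welch_overlap,
         entropy_m = as.integer(entropy_m), entropy_r = entropy_r,
         dfa_short = dfa_short, dfa_long = dfa_long, mfdfa_q = mfdfa_q,
         baseline_window = baseline_window,
         mx_offset = mx_offset, delta_epoch = delta_epoch,
         rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  grid steps (s):",
      paste(names(x$grid_step), x$grid_step, sep = "=", collapse = ", "), "\n")
  cat("  max fillable gap (s):",
      paste(names(x$max_gap), x$max_gap, sep = "=", collapse = ", "), "\n")
  cat("  denoise window:", x$denoise_window, "samples\n")
  cat("  desaturation threshold:", x$desat_threshold, "%\n")
  invisible(x)
}

#' Read a pipeline configuration from JSON
#'
#' The JSON object mirrors [pipeline_config()] field for field; absent fields
#' keep their defaults.
#'
#' @param path Path to a JSON file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$spectral_bands)) {
    raw$spectral_bands <- lapply(raw$spectral_bands, as.numeric)
  }
  do.call(pipeline_config, raw)
}
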