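# Nocturnal pulse-oximetry features: distributional summaries, the Delta
# Index, and desaturation-event metrics (events are maximal runs of samples
# below the 90% threshold). Integrals use left-rectangle quadrature on the
# uniform grid; recording time spans first to last present sample plus one
# grid step.

#' SpO2 distributional summary features
#'
#' Mean, median, minimum, sample SD, range, 90th percentile (linear
#' interpolation), number of zero crossings of the mean-centred signal, and
#' Mx, the percentage of samples at least `x` percentage points below the
#' median (default offset 1).
#'
#' @param spo2 A preprocessed regular SpO2 [ts_signal()].
#' @param config A [pipeline_config()].
#' @return Named list: `AV`, `MED`, `Min`, `SD`, `RG`, `P`, `Mx`, `ZC`.
#' @export
spo2_summary <- function(spo2, config = pipeline_config()) {
  v <- present_samples(spo2)$values
  out <- list(AV = NA_real_, MED = NA_real_, Min = NA_real_, SD = NA_real_,
              RG = NA_real_, P = NA_real_, Mx = NA_real_, ZC = NA_real_)
  if (length(v) == 0) return(out)
  out$AV <- mean(v)
  out$MED <- stats::median(v)
  out$Min <- min(v)
  out$SD <- sample_sd(v)
  out$RG <- max(v) - min(v)
  out$P <- unname(stats::quantile(v, 0.9, type = 7))
  out$Mx <- 100 * mean(v <= out$MED - config$mx_offset)
  s <- sign(v - mean(v))
  s <- s[s != 0]
  out$ZC <- if (length(s) >= 2) sum(s[-1] != s[-length(s)]) else 0
  out
}

#' Delta Index of an SpO2 signal
#'
#' The classic oximetry variability measure: the mean absolute difference
#' between consecutive short-epoch means (12 s epochs by default, aligned to
#' the series start). Empty epochs are skipped; only consecutive non-empty
#' epochs are paired.
#'
#' @param spo2 A preprocessed regular SpO2 [ts_signal()].
#' @param epoch Epoch length in seconds.
#' @return The Delta Index, or `NA` with fewer than two non-empty epochs.
#' @export
delta_index <- function(spo2, epoch = 12) {
  p <- present_samples(spo2)
  if (length(p$values) == 0) return(NA_real_)
  id <- floor((p$timestamps - p$timestamps[1]) / epoch)
  means <- as.numeric(tapply(p$values, id, mean))
  if (length(means) < 2) return(NA_real_)
  mean(abs(diff(means)))
}

#' Desaturation events and event metrics
#'
#' Segments the night into desaturation events, maximal runs of present
#' samples strictly below the threshold (90% by default), and computes:
#' CT, the percentage of recording time spent below the threshold; CA, the
#' integral of the deficit below the threshold normalized by recording time;
#' AOD100 and AODmax, the area under the event curve using 100% or the
#' recording maximum as baseline, normalized by recording time; ODI, the
#' number of events per recording hour, reported as the floored integer with
#' the unrounded rate in the metadata; and POD, events as a percentage of
#' present samples.
#'
#' @param spo2 A preprocessed regular SpO2 [ts_signal()].
#' @param threshold Desaturation threshold (% SpO2).
#' @return List with `events` (data.frame: start, end, duration_s,
#'   min_value, area_below_threshold) and `features` (named list `CT`, `CA`,
#'   `AOD100`, `AODmax`, `ODI`, `POD`), plus `metadata` with the unrounded
#'   ODI rate and the recording time.
#' @export
desaturation_metrics <- function(spo2, threshold = 90) {
  stopifnot(spo2$is_regular)
  keep <- !is.na(spo2$values)
  feats <- list(CA = NA_real_, CT = NA_real_, POD = NA_real_,
                AODmax = NA_real_, AOD100 = NA_real_, ODI = NA_real_)
  empty_events <- data.frame(start = numeric(), end = numeric(),
                             duration_s = numeric(), min_value = numeric(),
                             area_below_threshold = numeric())
  if (!any(keep)) {
    return(list(events = empty_events, features = feats,
                metadata = list(odi_rate = NA_real_, recording_time_s = 0)))
  }
  step <- spo2$grid_step
  t <- spo2$timestamps[keep]; v <- spo2$values[keep]
  rec_time <- (t[length(t)] - t[1]) + step
  below <- v < threshold

  # maximal runs of sub-threshold present samples; unfilled holes in the
  # grid break a run (an event never spans missing time)
  events <- empty_events
  if (any(below)) {
    jump <- c(FALSE, diff(t) > step)
    run_id <- cumsum(c(TRUE, below[-1] != below[-length(below)]) | jump)
    for (g in unique(run_id[below])) {
      sel <- which(run_id == g)
      i0 <- sel[1]; i1 <- sel[length(sel)]
      events <- rbind(events, data.frame(
        start = t[i0], end = t[i1] + step,
        duration_s = (i1 - i0 + 1) * step,
        min_value = min(v[i0:i1]),
        area_below_threshold = sum(threshold - v[i0:i1]) * step))
    }
  }
  n_events <- nrow(events)
  in_event <- below
  feats$CT <- 100 * sum(below) * step / rec_time
  feats$CA <- sum(pmax(0, threshold - v)) * step / rec_time
  feats$AOD100 <- sum(100 - v[in_event]) * step / rec_time
  feats$AODmax <- sum(pmax(0, max(v) - v[in_event])) * step / rec_time
  odi_rate <- n_events / (rec_time / 3600)
  feats$ODI <- floor(odi_rate)
  feats$POD <- 100 * n_events / length(v)
  list(events = events, features = feats,
       metadata = list(odi_rate = odi_rate, recording_time_s = rec_time))
}

#' Full SpO2 feature record
#'
#' @param spo2 A preprocessed regular SpO2 [ts_signal()].
#' @param config A [pipeline_config()].
#' @return A [feature_record()]; the desaturation event table is attached as
#'   the `events` attribute.
#' @export
spo2_features <- function(spo2, config = pipeline_config()) {
  feats <- spo2_summary(spo2, config)
  feats$DI <- delta_index(spo2, config$delta_epoch)
  desat <- desaturation_metrics(spo2, config$desat_threshold)
  feats <- c(feats, desat$features)
  rec <- feature_record(spo2$kind, spo2$day, feats,
                        metadata = c(list(n_samples = sum(!is.na(spo2$values))),
                                     desat$metadata))
  attr(rec, "events") <- desat$events
  rec
}
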