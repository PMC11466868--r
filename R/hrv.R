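# Heart-rate and beat-to-beat interval features: daily summaries and trend
# terms of the rate itself, the time-domain HRV catalogue, Poincare geometry,
# heart-rate asymmetry, and fragmentation indices.
#
# Variance conventions: reported SDNN-family summaries use the sample SD
# (n-1); inside the Poincare identities the population convention is used, so
# that SD1 = RMSSD/sqrt(2) and SD1^2 + SD2^2 = 2*sigma^2(RR) hold exactly.

sample_sd <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_
pop_var <- function(x) mean((x - mean(x))^2)

#' Daily heart-rate summary and trend features
#'
#' Computes mean, SD, extremes and their times of day (first occurrence on
#' ties, seconds since midnight), the baseline heart rate (median over the
#' 30-minute window with the lowest rolling mean), and the linear/quadratic
#' trend terms of an ordinary least-squares quadratic fit of heart rate on
#' time, together with its coefficient of determination (defined as 0 for a
#' constant series).
#'
#' @param hr A preprocessed regular heart-rate [ts_signal()].
#' @param config A [pipeline_config()].
#' @return Named list of features `HR_Mean`, `HR_SD`, `HR_Max`, `HR_Min`,
#'   `HR_Max_Time`, `HR_Min_Time`, `HR_Baseline`, `HR_Trend_Linear`,
#'   `HR_Trend_Quadratic`, `HR_Trend_R2`.
#' @export
hr_summary <- function(hr, config = pipeline_config()) {
  p <- present_samples(hr)
  v <- p$values; t <- p$timestamps
  out <- list(HR_Baseline = NA_real_, HR_Max = NA_real_, HR_Min = NA_real_,
              HR_Mean = NA_real_, HR_SD = NA_real_, HR_Max_Time = NA_real_,
              HR_Min_Time = NA_real_, HR_Trend_Linear = NA_real_,
              HR_Trend_Quadratic = NA_real_, HR_Trend_R2 = NA_real_)
  if (length(v) == 0) return(out)
  out$HR_Mean <- mean(v)
  out$HR_SD <- sample_sd(v)
  out$HR_Max <- max(v); out$HR_Min <- min(v)
  out$HR_Max_Time <- t[which.max(v)]
  out$HR_Min_Time <- t[which.min(v)]
  out$HR_Baseline <- hr_baseline(t, v, config$baseline_window)
  if (length(v) >= 3) {
    fit <- stats::lm(v ~ t + I(t^2))
    cf <- stats::coef(fit)
    out$HR_Trend_Linear <- unname(cf["t"])
    out$HR_Trend_Quadratic <- unname(cf["I(t^2)"])
    tss <- sum((v - mean(v))^2)
    out$HR_Trend_R2 <- if (tss == 0) 0 else 1 - sum(stats::resid(fit)^2) / tss
  }
  out
}

# Baseline: slide a wall-clock window over the present samples, find the
# window with the lowest mean, report the median inside it.
hr_baseline <- function(t, v, width) {
  best_mean <- Inf; best <- stats::median(v)
  for (i in seq_along(t)) {
    in_win <- t >= t[i] & t < t[i] + width
    m <- mean(v[in_win])
    if (m < best_mean) {
      best_mean <- m
      best <- stats::median(v[in_win])
    }
  }
  best
}

#' Time-domain HRV features
#'
#' The standard catalogue computed on an RR interval series: MeanNN, SDNN,
#' RMSSD, SDSD, coefficient-of-variation forms, robust statistics (median,
#' scaled MAD, IQR), pNN50/pNN20, the HRV triangular index (1/128 s
#' histogram), and the segment statistics SDANN / SDNNI over 1, 2 and 5
#' minute wall-clock segments (standard deviation of segment means; mean of
#' segment standard deviations). Segments spanning less than half their
#' nominal length are discarded.
#'
#' @param bbi An [interval_series()] in ms (see [derive_bbi()]).
#' @return Named list of features.
#' @export
hrv_time_domain <- function(bbi) {
  rr <- bbi$intervals
  d <- successive_diffs(bbi)
  out <- list(MeanNN = NA_real_, SDNN = NA_real_, RMSSD = NA_real_,
              SDSD = NA_real_, CVNN = NA_real_, CVSD = NA_real_,
              MedianNN = NA_real_, MadNN = NA_real_, HCVNN = NA_real_,
              IQRNN = NA_real_, pNN50 = NA_real_, pNN20 = NA_real_,
              HTI = NA_real_, TiNN = NA_real_,
              SDANN1 = NA_real_, SDANN2 = NA_real_, SDANN5 = NA_real_,
              SDNNI1 = NA_real_, SDNNI2 = NA_real_, SDNNI5 = NA_real_)
  if (length(rr) < 2) return(out)
  out$MeanNN <- mean(rr)
  out$SDNN <- sample_sd(rr)
  out$MedianNN <- stats::median(rr)
  out$MadNN <- stats::mad(rr)               # median abs deviation * 1.4826
  out$HCVNN <- if (out$MedianNN > 0) out$MadNN / out$MedianNN else NA_real_
  out$IQRNN <- stats::IQR(rr)
  out$CVNN <- out$SDNN / out$MeanNN
  bw <- 1000 / 128                          # 1/128 s histogram bin (ms)
  out$HTI <- length(rr) / max(table(floor(rr / bw)))
  if (length(d) >= 1) {
    out$RMSSD <- sqrt(mean(d^2))
    out$SDSD <- sample_sd(d)
    out$CVSD <- out$RMSSD / out$MeanNN
    out$pNN50 <- 100 * mean(abs(d) > 50)
    out$pNN20 <- 100 * mean(abs(d) > 20)
  }
  for (k in c(1, 2, 5)) {
    seg <- segment_stats(bbi, k * 60)
    out[[paste0("SDANN", k)]] <- seg$sdann
    out[[paste0("SDNNI", k)]] <- seg$sdnni
  }
  out
}

# Non-overlapping wall-clock segments aligned to the series start; segments
# covering less than half the nominal length are dropped.
segment_stats <- function(bbi, seg_len) {
  t <- bbi$times
  id <- floor((t - t[1]) / seg_len)
  means <- c(); sds <- c()
  for (g in unique(id)) {
    sel <- id == g
    span <- max(t[sel]) - min(t[sel]) + bbi$source_step
    if (span < seg_len / 2) next
    means <- c(means, mean(bbi$intervals[sel]))
    if (sum(sel) >= 2) sds <- c(sds, stats::sd(bbi$intervals[sel]))
  }
  list(sdann = if (length(means) >= 2) stats::sd(means) else NA_real_,
       sdnni = if (length(sds) >= 1) mean(sds) else NA_real_)
}

#' Poincare plot geometry
#'
#' SD1 and SD2 are the dispersions of the lagged point cloud
#' (RR_i, RR_{i+1}) perpendicular to and along the line of identity.
#' SD1^2 = mean(d^2)/2 on the successive differences (so SD1 equals
#' RMSSD/sqrt(2) exactly) and SD2^2 = 2*sigma^2(RR) - SD1^2 (population
#' variance, floored at 0). CSI and CVI are the ratio and log10 product of
#' the ellipse axes L = 4*SD2, T = 4*SD1; the modified CSI is L^2/T.
#'
#' @param bbi An [interval_series()].
#' @return Named list: `SD1`, `SD2`, `SD1SD2`, `CSI`, `CVI`, `CSI_Modified`.
#' @export
poincare <- function(bbi) {
  out <- list(SD1 = NA_real_, SD2 = NA_real_, SD1SD2 = NA_real_,
              CSI = NA_real_, CVI = NA_real_, CSI_Modified = NA_real_)
  if (length(bbi$intervals) < 3) return(out)
  d <- successive_diffs(bbi)
  if (length(d) < 1) return(out)
  sd1 <- sqrt(mean(d^2) / 2)
  sd2 <- sqrt(max(0, 2 * pop_var(bbi$intervals) - sd1^2))
  out$SD1 <- sd1; out$SD2 <- sd2
  out$SD1SD2 <- if (sd2 > 0) sd1 / sd2 else NA_real_
  if (sd1 > 0) {
    L <- 4 * sd2; T <- 4 * sd1
    out$CSI <- L / T
    out$CSI_Modified <- L^2 / T
    out$CVI <- if (sd2 > 0) log10(L * T) else NA_real_
  }
  out
}

#' Heart-rate asymmetry indices
#'
#' Classifies Poincare points by the sign of the successive difference
#' (above the line of identity: deceleration; below: acceleration) and
#' computes Guzik's index (share of perpendicular distance), the slope index
#' (share of angular deviation from 45 degrees), the area index (share of
#' sector area, 0.5*r^2*|theta - 45deg|), Porta's index (share of points
#' below), and the variance decomposition into deceleration/acceleration
#' contributions at short term (SD1d/SD1a), long term (SD2d/SD2a, with
#' zero-difference points split half and half) and in total (SDNNd/SDNNa,
#' with SDNNx^2 = (SD1x^2 + SD2x^2)/2), plus the relative contributions
#' C1d/C1a, C2d/C2a, Cd/Ca which sum to 1 pairwise by construction.
#'
#' @param bbi An [interval_series()].
#' @return Named list of asymmetry features.
#' @export
hra_asymmetry <- function(bbi) {
  out <- list(GI = NA_real_, SI = NA_real_, AI = NA_real_, PI = NA_real_,
              SD1d = NA_real_, SD1a = NA_real_, C1d = NA_real_, C1a = NA_real_,
              SD2d = NA_real_, SD2a = NA_real_, C2d = NA_real_, C2a = NA_real_,
              SDNNd = NA_real_, SDNNa = NA_real_, Cd = NA_real_, Ca = NA_real_)
  pts <- poincare_points(bbi)
  x <- pts$x; y <- pts$y
  m <- length(x)
  if (m < 2) return(out)
  d <- y - x
  dec <- d > 0; acc <- d < 0; zero <- d == 0

  if (any(dec | acc)) {
    # perpendicular distances, angular deviations, sector areas
    dist <- abs(d) / sqrt(2)
    theta <- atan2(y, x) - pi / 4                 # signed deviation from LI
    r2 <- x^2 + y^2
    area <- 0.5 * r2 * abs(theta)
    off <- dec | acc
    out$GI <- 100 * sum(dist[dec]) / sum(dist[off])
    out$SI <- 100 * sum(abs(theta[dec])) / sum(abs(theta[off]))
    out$AI <- 100 * sum(area[dec]) / sum(area[off])
    out$PI <- 100 * sum(acc) / sum(off)
  }

  sd1d2 <- sum(d[dec]^2) / (2 * m)
  sd1a2 <- sum(d[acc]^2) / (2 * m)
  out$SD1d <- sqrt(sd1d2); out$SD1a <- sqrt(sd1a2)
  if (sd1d2 + sd1a2 > 0) {
    out$C1d <- sd1d2 / (sd1d2 + sd1a2)
    out$C1a <- 1 - out$C1d
  }

  dall <- (x + y - mean(x) - mean(y)) / sqrt(2)   # along-LI distance to centroid
  sd2d2 <- (sum(dall[dec]^2) + 0.5 * sum(dall[zero]^2)) / m
  sd2a2 <- (sum(dall[acc]^2) + 0.5 * sum(dall[zero]^2)) / m
  out$SD2d <- sqrt(sd2d2); out$SD2a <- sqrt(sd2a2)
  if (sd2d2 + sd2a2 > 0) {
    out$C2d <- sd2d2 / (sd2d2 + sd2a2)
    out$C2a <- 1 - out$C2d
  }

  sdnnd2 <- (sd1d2 + sd2d2) / 2
  sdnna2 <- (sd1a2 + sd2a2) / 2
  out$SDNNd <- sqrt(sdnnd2); out$SDNNa <- sqrt(sdnna2)
  if (sdnnd2 + sdnna2 > 0) {
    out$Cd <- sdnnd2 / (sdnnd2 + sdnna2)
    out$Ca <- 1 - out$Cd
  }
  out
}

#' Fragmentation indices of the RR series
#'
#' Statistics of the sign structure of the successive differences: PIP (the
#' percentage of consecutive difference pairs whose sign inverts), IALS
#' (inverse of the mean length of maximal constant-sign acceleration or
#' deceleration runs), PSS (percentage of differences belonging to runs
#' shorter than 3), and PAS (percentage of NN intervals inside alternation
#' segments of at least 4 intervals). Zero differences inherit the previous
#' non-zero sign; leading zeros are dropped.
#'
#' @param bbi An [interval_series()].
#' @return Named list: `PIP`, `IALS`, `PSS`, `PAS`.
#' @export
fragmentation <- function(bbi) {
  out <- list(PIP = NA_real_, IALS = NA_real_, PSS = NA_real_, PAS = NA_real_)
  d <- successive_diffs(bbi)
  s <- sign(d)
  # zeros inherit the previous non-zero sign; leading zeros dropped
  nz <- s != 0
  if (!any(nz)) return(out)
  first <- which(nz)[1]
  s <- s[first:length(s)]
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- s[i - 1]
  m <- length(s)
  if (m < 2) return(out)
  changes <- sum(s[-1] != s[-m])
  out$PIP <- 100 * changes / (m - 1)
  runs <- rle(s)$lengths
  out$IALS <- 1 / mean(runs)
  out$PSS <- 100 * sum(runs[runs < 3]) / m
  # alternation segments: maximal stretches where the sign flips every step;
  # a stretch of L differences covers L+1 NN intervals
  flip <- s[-1] != s[-m]
  alt_runs <- rle(flip)
  n_nn <- length(bbi$intervals)
  covered <- logical(n_nn)
  pos <- cumsum(c(1, alt_runs$lengths))
  for (k in seq_along(alt_runs$lengths)) {
    if (!alt_runs$values[k]) next
    L <- alt_runs$lengths[k] + 1              # differences in the stretch
    if (L + 1 < 4) next
    i0 <- first + pos[k] - 1                  # first NN index of the stretch
    covered[i0:(i0 + L)] <- TRUE
  }
  out$PAS <- 100 * sum(covered) / n_nn
  out
}

#' Full heart-rate / beat-to-beat feature record
#'
#' Runs the complete heart-rate catalogue on a preprocessed signal: daily
#' summaries and trends of the rate, then the time-domain, Poincare,
#' asymmetry and fragmentation features of the derived RR series. TiNN is
#' reported as null (not computed).
#'
#' @param hr A preprocessed regular heart-rate [ts_signal()].
#' @param config A [pipeline_config()].
#' @return A [feature_record()].
#' @export
hrv_features <- function(hr, config = pipeline_config()) {
  feats <- hr_summary(hr, config)
  p <- present_samples(hr)
  rr_names <- c("MeanNN", "SDNN", "RMSSD", "SDSD", "CVNN", "CVSD",
                "MedianNN", "MadNN", "HCVNN", "IQRNN", "pNN50", "pNN20",
                "HTI", "TiNN", "SDANN1", "SDANN2", "SDANN5",
                "SDNNI1", "SDNNI2", "SDNNI5",
                "SD1", "SD2", "SD1SD2", "CSI", "CVI", "CSI_Modified",
                "GI", "SI", "AI", "PI",
                "SD1d", "SD1a", "C1d", "C1a", "SD2d", "SD2a", "C2d", "C2a",
                "SDNNd", "SDNNa", "Cd", "Ca",
                "PIP", "IALS", "PSS", "PAS")
  if (length(p$values) >= 2 && all(p$values > 0)) {
    bbi <- derive_bbi(hr)
    rr_feats <- c(hrv_time_domain(bbi), poincare(bbi),
                  hra_asymmetry(bbi), fragmentation(bbi))
  } else {
    rr_feats <- stats::setNames(
      rep(list(NA_real_), length(rr_names)), rr_names)
  }
  feats <- c(feats, rr_feats[rr_names])
  feature_record(hr$kind, hr$day, feats,
                 metadata = list(n_samples = sum(!is.na(hr$values))))
}
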