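# Respiration-rate features on the breath-to-breath interval series:
# time-domain statistics, Welch band powers of the interval tachogram,
# Poincare geometry, approximate/sample entropy, and mono- and multifractal
# detrended fluctuation analysis.

as_intervals <- function(x) {
  if (inherits(x, "interval_series")) x$intervals else as.numeric(x)
}

#' Time-domain breath-to-breath statistics
#'
#' @param bb An [interval_series()] in seconds (see [derive_bb()]) or a
#'   numeric interval vector.
#' @return Named list: `Mean`, `Var` (sample), `SDBB`, `RMSSD`, `SDSD`.
#' @export
resp_time_domain <- function(bb) {
  out <- list(Mean = NA_real_, Var = NA_real_, SDBB = NA_real_,
              RMSSD = NA_real_, SDSD = NA_real_)
  x <- as_intervals(bb)
  if (length(x) < 2) return(out)
  d <- if (inherits(bb, "interval_series")) successive_diffs(bb) else diff(x)
  out$Mean <- mean(x)
  out$Var <- stats::var(x)
  out$SDBB <- stats::sd(x)
  if (length(d) >= 1) {
    out$RMSSD <- sqrt(mean(d^2))
    out$SDSD <- sample_sd(d)
  }
  out
}

#' Welch power spectral density
#'
#' Mean modified periodogram over Hann-tapered, mean-detrended, overlapping
#' segments; one-sided density so that the integral over frequency
#' approximates the series variance.
#'
#' @param x Numeric series (uniformly sampled).
#' @param fs Sampling rate (Hz).
#' @param nperseg Segment length in samples (clipped to the largest power of
#'   two not exceeding the series length).
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @return List with `freq` (Hz) and `psd` (units^2/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 256, overlap = 0.5) {
  n <- length(x)
  stopifnot(n >= 8)
  nperseg <- min(nperseg, 2^floor(log2(n)))
  step <- max(1, floor(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  k <- 0:(nperseg - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / nperseg))       # periodic Hann
  scale <- fs * sum(w^2)
  nf <- nperseg %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    y <- stats::fft(w * (seg - mean(seg)))
    p <- (Mod(y)^2 / scale)[1:nf]
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]             # one-sided
    acc <- acc + p
  }
  list(freq = (0:(nf - 1)) * fs / nperseg, psd = acc / length(starts))
}

band_power <- function(freq, psd, lo, hi) {
  df <- freq[2] - freq[1]
  sum(psd[freq >= lo & freq < hi]) * df
}

#' Spectral band powers of the breath-to-breath tachogram
#'
#' The interval series is laid out over cumulative breath time, linearly
#' interpolated onto a uniform grid (4 Hz by default), and its Welch power
#' spectral density is integrated over the VLF (0-0.04 Hz), LF
#' (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands. Normalized powers divide by
#' total power = VLF + LF + HF.
#'
#' @param bb An [interval_series()] or numeric interval vector (seconds).
#' @param config A [pipeline_config()] (band edges, resample rate, Welch
#'   parameters).
#' @return Named list: `VLF`, `LF`, `HF`, `LFHF`, `LFn`, `HFn`, plus
#'   `total_power`.
#' @export
resp_spectral <- function(bb, config = pipeline_config()) {
  out <- list(VLF = NA_real_, LF = NA_real_, HF = NA_real_, LFHF = NA_real_,
              LFn = NA_real_, HFn = NA_real_, total_power = NA_real_)
  x <- as_intervals(bb)
  if (length(x) < 4) return(out)
  tau <- cumsum(x) - x[1]                     # breath occurrence times
  fs <- config$resample_rate
  grid <- seq(0, tau[length(tau)], by = 1 / fs)
  if (length(grid) < 64) return(out)
  xs <- stats::approx(tau, x, xout = grid)$y
  xs <- xs - mean(xs)
  spec <- welch_psd(xs, fs, config$welch_nperseg, config$welch_overlap)
  bands <- config$spectral_bands
  out$VLF <- band_power(spec$freq, spec$psd, bands$VLF[1], bands$VLF[2])
  out$LF <- band_power(spec$freq, spec$psd, bands$LF[1], bands$LF[2])
  out$HF <- band_power(spec$freq, spec$psd, bands$HF[1], bands$HF[2])
  out$total_power <- out$VLF + out$LF + out$HF
  if (out$HF > 0) out$LFHF <- out$LF / out$HF
  if (out$total_power > 0) {
    out$LFn <- out$LF / out$total_power
    out$HFn <- out$HF / out$total_power
  }
  out
}

#' Poincare geometry of the breath-to-breath series
#'
#' Same geometry as the heart-rate module ([poincare()]); the reported ratio
#' is `SD2SD1 = SD2/SD1` (long- over short-term variability).
#'
#' @param bb An [interval_series()] or numeric interval vector.
#' @return Named list: `SD1`, `SD2`, `SD2SD1`.
#' @export
resp_poincare <- function(bb) {
  if (!inherits(bb, "interval_series")) {
    bb <- interval_series(bb, unit = "s")
  }
  g <- poincare(bb)
  list(SD1 = g$SD1, SD2 = g$SD2,
       SD2SD1 = if (!is.na(g$SD1) && g$SD1 > 0) g$SD2 / g$SD1 else NA_real_)
}

#' Approximate and sample entropy
#'
#' Template-matching entropies under the Chebyshev distance with tolerance
#' `r_frac` times the series SD. Approximate entropy includes self-matches
#' (`Phi_m - Phi_{m+1}` of mean log match fractions); sample entropy excludes
#' them (`-log(A/B)`).
#'
#' @param bb An [interval_series()] or numeric vector.
#' @param m Embedding dimension.
#' @param r_frac Tolerance as a fraction of the sample SD.
#' @return Named list: `ApEn`, `SampEn`.
#' @export
entropy_features <- function(bb, m = 2, r_frac = 0.2) {
  x <- as_intervals(bb)
  out <- list(ApEn = NA_real_, SampEn = NA_real_)
  n <- length(x)
  if (n < 2 * (m + 1)) return(out)
  r <- r_frac * stats::sd(x)
  if (!is.finite(r)) return(out)
  # constant series: every template matches; both entropies are 0
  D <- abs(outer(x, x, "-"))

  cheb_counts <- function(mm) {
    nt <- n - mm + 1
    M <- D[1:nt, 1:nt, drop = FALSE]
    if (mm > 1) {
      for (k in 1:(mm - 1)) M <- pmax(M, D[1:nt + k, 1:nt + k, drop = FALSE])
    }
    M <= r
  }

  # ApEn: self-matches included, template sets of full length
  phi <- function(mm) {
    C <- rowSums(cheb_counts(mm)) / (n - mm + 1)
    mean(log(C))
  }
  out$ApEn <- phi(m) - phi(m + 1)

  # SampEn: self-matches excluded, both lengths over the first n-m templates
  nt <- n - m
  Mm <- cheb_counts(m)[1:nt, 1:nt, drop = FALSE]
  Mm1 <- cheb_counts(m + 1)
  B <- sum(Mm) - nt                       # minus self-matches
  A <- sum(Mm1) - nrow(Mm1)
  if (B > 0 && A > 0) out$SampEn <- -log(A / B)
  if (B > 0 && A == 0) out$SampEn <- NA_real_
  out
}

# Per-window RMS of linearly detrended profile segments at one scale.
dfa_window_rms <- function(profile, scale) {
  nwin <- floor(length(profile) / scale)
  if (nwin < 1) return(numeric(0))
  i <- seq_len(scale)
  sxx <- sum((i - mean(i))^2)
  vapply(seq_len(nwin), function(w) {
    y <- profile[((w - 1) * scale + 1):(w * scale)]
    b <- sum((i - mean(i)) * (y - mean(y))) / sxx
    res <- y - (mean(y) + b * (i - mean(i)))
    sqrt(mean(res^2))
  }, 0)
}

dfa_scales <- function(lo, hi, n_scales = 10) {
  unique(round(exp(seq(log(lo), log(hi), length.out = n_scales))))
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-centred series, splits the profile into
#' non-overlapping windows of each scale, removes a least-squares line per
#' window, and regresses the log RMS fluctuation on log scale. `alpha1`
#' uses the short-term regime (scales 4-16 by default), `alpha2` the
#' long-term regime (16-64). A regime needs at least four times its maximum
#' scale in samples, else its exponent is `NA`; an exactly detrendable
#' (degenerate) series also yields `NA`.
#'
#' Plain first-order DFA overestimates the exponent of short-range series at
#' the smallest scales (for white noise the expected squared fluctuation is
#' sigma^2 (s^2-4)/(15 s), not sigma^2 s/15, which inflates the 4-16 slope
#' to about 0.6). The fluctuation function is therefore rescaled by the
#' exact white-noise factor s/sqrt(s^2-4) (modified DFA), so an uncorrelated
#' series recovers 0.5 on average while long-range scaling is asymptotically
#' untouched.
#'
#' @param bb An [interval_series()] or numeric vector.
#' @param short_scales,long_scales Two-element scale ranges (samples).
#' @return Named list: `alpha1`, `alpha2`.
#' @export
dfa <- function(bb, short_scales = c(4, 16), long_scales = c(16, 64)) {
  x <- as_intervals(bb)
  fit_alpha <- function(range) {
    if (length(x) < 4 * range[2]) return(NA_real_)
    profile <- cumsum(x - mean(x))
    scales <- dfa_scales(range[1], range[2])
    F <- vapply(scales, function(s) {
      r <- dfa_window_rms(profile, s)
      # finite-size rescaling: exact white-noise expectation at scale s
      sqrt(mean(r^2)) * s / sqrt(s^2 - 4)
    }, 0)
    ok <- F > 0
    if (sum(ok) < 3) return(NA_real_)
    unname(stats::coef(stats::lm(log(F[ok]) ~ log(scales[ok])))[2])
  }
  list(alpha1 = fit_alpha(short_scales), alpha2 = fit_alpha(long_scales))
}

#' Multifractal detrended fluctuation analysis
#'
#' Generalizes DFA over moment orders `q`: the q-th order fluctuation
#' function is the q-mean of per-window RMS residuals, its log-log slope
#' gives the generalized exponent h(q), and the Legendre transform
#' tau(q) = q h(q) - 1 yields singularity exponents alpha = dtau/dq (central
#' finite differences) and dimensions f(alpha) = q alpha - tau. For each
#' regime the width and centre of the singularity spectrum are reported:
#' ExpRange/ExpMean over alpha and DimRange/DimMean over f(alpha).
#'
#' @param bb An [interval_series()] or numeric vector.
#' @param q_values Moment orders (0 excluded; handled by log-averaging is
#'   not needed for the reported summaries).
#' @param short_scales,long_scales Scale ranges as in [dfa()].
#' @return Named list with `alpha1_ExpRange`, `alpha1_ExpMean`,
#'   `alpha1_DimRange`, `alpha1_DimMean` and the `alpha2_*` counterparts.
#' @export
mfdfa <- function(bb, q_values = setdiff(-5:5, 0),
                  short_scales = c(4, 16), long_scales = c(16, 64)) {
  x <- as_intervals(bb)
  out <- list(alpha1_ExpRange = NA_real_, alpha1_ExpMean = NA_real_,
              alpha1_DimRange = NA_real_, alpha1_DimMean = NA_real_,
              alpha2_ExpRange = NA_real_, alpha2_ExpMean = NA_real_,
              alpha2_DimRange = NA_real_, alpha2_DimMean = NA_real_)
  regime <- function(range) {
    if (length(x) < 4 * range[2]) return(NULL)
    profile <- cumsum(x - mean(x))
    scales <- dfa_scales(range[1], range[2])
    rms_by_scale <- lapply(scales, function(s) dfa_window_rms(profile, s))
    hq <- vapply(q_values, function(q) {
      Fq <- vapply(rms_by_scale, function(r) {
        if (any(r == 0) && q < 0) return(NA_real_)
        mean(r^q)^(1 / q)
      }, 0)
      ok <- is.finite(Fq) & Fq > 0
      if (sum(ok) < 3) return(NA_real_)
      unname(stats::coef(stats::lm(log(Fq[ok]) ~ log(scales[ok])))[2])
    }, 0)
    ok <- is.finite(hq)
    if (sum(ok) < 3) return(NULL)
    q <- q_values[ok]; h <- hq[ok]
    tau <- q * h - 1
    nq <- length(q)
    alpha <- numeric(nq)
    alpha[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
    alpha[nq] <- (tau[nq] - tau[nq - 1]) / (q[nq] - q[nq - 1])
    if (nq > 2) {
      for (i in 2:(nq - 1)) {
        alpha[i] <- (tau[i + 1] - tau[i - 1]) / (q[i + 1] - q[i - 1])
      }
    }
    f <- q * alpha - tau
    list(ExpRange = max(alpha) - min(alpha), ExpMean = mean(alpha),
         DimRange = max(f) - min(f), DimMean = mean(f))
  }
  r1 <- regime(short_scales)
  r2 <- regime(long_scales)
  if (!is.null(r1)) {
    out$alpha1_ExpRange <- r1$ExpRange; out$alpha1_ExpMean <- r1$ExpMean
    out$alpha1_DimRange <- r1$DimRange; out$alpha1_DimMean <- r1$DimMean
  }
  if (!is.null(r2)) {
    out$alpha2_ExpRange <- r2$ExpRange; out$alpha2_ExpMean <- r2$ExpMean
    out$alpha2_DimRange <- r2$DimRange; out$alpha2_DimMean <- r2$DimMean
  }
  out
}

#' Full respiration-rate feature record
#'
#' Derives the breath-to-breath interval series and runs the whole
#' respiration catalogue: time-domain statistics, spectral band powers,
#' Poincare geometry, entropies, and (multifractal) DFA for the short- and
#' long-term regimes.
#'
#' @param resp A preprocessed regular respiration-rate [ts_signal()].
#' @param config A [pipeline_config()].
#' @return A [feature_record()].
#' @export
resp_features <- function(resp, config = pipeline_config()) {
  p <- present_samples(resp)
  nms <- c("Mean", "Var", "SDBB", "RMSSD", "SDSD",
           "VLF", "LF", "HF", "LFHF", "LFn", "HFn", "total_power",
           "SD1", "SD2", "SD2SD1", "ApEn", "SampEn",
           "DFA_alpha1", "DFA_alpha2",
           "alpha1_ExpRange", "alpha2_ExpRange",
           "alpha1_ExpMean", "alpha2_ExpMean",
           "alpha1_DimRange", "alpha2_DimRange",
           "alpha1_DimMean", "alpha2_DimMean")
  if (length(p$values) < 2 || any(p$values <= 0)) {
    feats <- stats::setNames(rep(list(NA_real_), length(nms)), nms)
    return(feature_record(resp$kind, resp$day, feats,
                          metadata = list(n_samples = length(p$values))))
  }
  bb <- derive_bb(resp)
  a <- dfa(bb, config$dfa_short, config$dfa_long)
  feats <- c(resp_time_domain(bb),
             resp_spectral(bb, config),
             resp_poincare(bb),
             entropy_features(bb, config$entropy_m, config$entropy_r),
             list(DFA_alpha1 = a$alpha1, DFA_alpha2 = a$alpha2),
             mfdfa(bb, config$mfdfa_q, config$dfa_short, config$dfa_long))
  feature_record(resp$kind, resp$day, feats[nms],
                 metadata = list(
                   n_samples = length(p$values),
                   resample_rate_hz = config$resample_rate,
                   welch_nperseg = config$welch_nperseg,
                   welch_overlap = config$welch_overlap))
}
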