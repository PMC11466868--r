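# Seeded generators for wearable-like daily streams with known ground truth:
# a circadian heart-rate day with AR(1) noise, nocturnal SpO2 with planted
# desaturation events, nocturnal respiration rate (optionally with an
# embedded low-frequency oscillation in the breath-to-breath sequence), and
# cumulative step/calorie counters, plus spike/gap artifact injection.

#' Specification of a synthetic wearable day
#'
#' Collects all generative parameters. Defaults emulate a typical adult day:
#' resting-to-active heart rate around 70 bpm with a 10 bpm circadian swing
#' and autocorrelated (AR(1)) sensor noise; an 8 h night of SpO2 around 96%
#' with occasional desaturation events dropping below the 90% threshold; a
#' nocturnal respiration rate around 14 breaths/min; and step counts from
#' random active bouts. Artifact rates follow the kinds of defects seen in
#' wrist-worn recordings: brief additive spikes (sensor pressure/motion) and
#' dropout gaps whose durations are log-uniform across the fillable /
#' non-fillable boundary so both gap-filling branches occur.
#'
#' @param rng_seed Integer seed; fixed seed gives identical output.
#' @param hr_baseline,hr_amplitude,hr_phase Circadian heart-rate model (bpm,
#'   bpm, s of peak time offset).
#' @param hr_ar,hr_noise_sd AR(1) coefficient and innovation SD (bpm).
#' @param night_start,night_end Sleep window (s since midnight).
#' @param spo2_baseline,spo2_noise_sd SpO2 level and noise (%).
#' @param desat_rate,desat_depth,desat_duration Desaturation events per
#'   hour, depth (%) and duration (s).
#' @param resp_baseline,resp_noise_sd Respiration rate level and noise
#'   (breaths/min).
#' @param resp_lf_freq,resp_lf_amp Optional embedded oscillation in the
#'   breath-to-breath sequence (Hz, s).
#' @param bout_rate,bout_steps Active bouts per hour and mean steps per
#'   active 15-min interval.
#' @param spike_rate,spike_amplitude Spikes per hour and additive amplitude.
#' @param gap_rate,gap_duration_range Gaps per hour; durations drawn
#'   log-uniformly from this range (s).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(rng_seed = 1L,
                           hr_baseline = 70, hr_amplitude = 10,
                           hr_phase = 54000, hr_ar = 0.8, hr_noise_sd = 2,
                           night_start = 0, night_end = 28800,
                           spo2_baseline = 96, spo2_noise_sd = 0.4,
                           desat_rate = 0.5, desat_depth = 8,
                           desat_duration = 180,
                           resp_baseline = 14, resp_noise_sd = 0.5,
                           resp_lf_freq = 0, resp_lf_amp = 0,
                           bout_rate = 1, bout_steps = 400,
                           spike_rate = 1, spike_amplitude = 40,
                           gap_rate = 1, gap_duration_range = c(30, 600)) {
  spec <- as.list(environment())
  rates <- c(desat_rate, bout_rate, spike_rate, gap_rate)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

# Scoped RNG: run code under a derived seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

ar1_noise <- function(n, coef, sd) {
  innov <- stats::rnorm(n, 0, sd)
  as.numeric(stats::filter(innov, coef, method = "recursive"))
}

#' Generate a synthetic heart-rate day
#'
#' 15 s grid over the full day: baseline + circadian sinusoid + AR(1) noise,
#' clipped to 30-200 bpm. The `ground_truth` attribute records the
#' configured mean, the clean series and the location of its maximum.
#'
#' @param spec A [synthetic_spec()].
#' @return An irregular [ts_signal()] (ready for [retime()]).
#' @export
generate_hr_day <- function(spec = synthetic_spec()) {
  with_seed(spec$rng_seed, {
    t <- seq(0, 86400 - 15, by = 15)
    clean <- spec$hr_baseline +
      spec$hr_amplitude * sin(2 * pi * (t - spec$hr_phase + 21600) / 86400)
    hr <- clean + ar1_noise(length(t), spec$hr_ar, spec$hr_noise_sd)
    hr <- pmin(200, pmax(30, hr))
    sig <- ts_signal("heart_rate", t, hr, is_regular = FALSE)
    attr(sig, "ground_truth") <- list(
      true_mean = spec$hr_baseline,
      clean = clean,
      max_time = t[which.max(hr)])
    sig
  })
}

#' Generate a synthetic nocturnal SpO2 stream
#'
#' 60 s grid over the sleep window: baseline + Gaussian noise, with a
#' Poisson number of planted desaturation events (rate per hour) during
#' which the level drops by the configured depth. Event windows are kept
#' disjoint and separated so they remain distinct after preprocessing; the
#' exact windows are returned in the `ground_truth` attribute.
#'
#' @param spec A [synthetic_spec()].
#' @param n_events Optionally force the event count instead of drawing it.
#' @return An irregular [ts_signal()].
#' @export
generate_spo2_night <- function(spec = synthetic_spec(), n_events = NULL) {
  with_seed(spec$rng_seed + 1L, {
    t <- seq(spec$night_start, spec$night_end - 60, by = 60)
    hours <- (spec$night_end - spec$night_start) / 3600
    v <- spec$spo2_baseline + stats::rnorm(length(t), 0, spec$spo2_noise_sd)
    if (is.null(n_events)) n_events <- stats::rpois(1, spec$desat_rate * hours)
    events <- list()
    if (n_events > 0) {
      len <- ceiling(spec$desat_duration / 60)
      # place events on an exclusion grid so they stay disjoint and separated
      slots <- seq(2, length(t) - len - 1, by = len + 4)
      n_events <- min(n_events, length(slots))
      starts <- sort(sample(slots, n_events))
      for (s in starts) {
        idx <- s:(s + len - 1)
        v[idx] <- v[idx] - spec$desat_depth
        events[[length(events) + 1]] <- list(
          start = t[s], end = t[s + len - 1] + 60, n_samples = len)
      }
    }
    v <- pmin(100, pmax(55, v))
    sig <- ts_signal("spo2", t, v, is_regular = FALSE)
    attr(sig, "ground_truth") <- list(n_events = n_events, events = events,
                                      baseline = spec$spo2_baseline)
    sig
  })
}

#' Generate a synthetic nocturnal respiration-rate stream
#'
#' 60 s grid over the sleep window. The generative model lives on the
#' breath-to-breath interval sequence: a constant interval
#' `60/resp_baseline` plus optional sinusoidal oscillation (for spectral
#' tests) plus noise, converted back to a rate.
#'
#' @param spec A [synthetic_spec()].
#' @return An irregular [ts_signal()].
#' @export
generate_resp_night <- function(spec = synthetic_spec()) {
  with_seed(spec$rng_seed + 2L, {
    t <- seq(spec$night_start, spec$night_end - 60, by = 60)
    bb0 <- 60 / spec$resp_baseline
    tau <- (t - t[1]) * bb0 / 60            # approximate breath-time axis
    bb <- bb0 + spec$resp_lf_amp * sin(2 * pi * spec$resp_lf_freq * tau)
    rate <- 60 / bb + stats::rnorm(length(t), 0, spec$resp_noise_sd)
    rate <- pmin(59, pmax(5, rate))
    sig <- ts_signal("respiration_rate", t, rate, is_regular = FALSE)
    attr(sig, "ground_truth") <- list(true_rate = spec$resp_baseline)
    sig
  })
}

#' Generate a synthetic cumulative counter day
#'
#' 15 min grid of non-negative increments from Poisson-placed active bouts;
#' returned as a running total (as the device exports it), so
#' [read_signal()] / [retime()] semantics can be exercised end to end.
#'
#' @param spec A [synthetic_spec()].
#' @param kind `"steps"` or `"calories"`.
#' @param as_increments Return per-interval increments instead of running
#'   totals.
#' @return An irregular [ts_signal()]; `daily_total` attribute holds the
#'   final running total.
#' @export
generate_cumulative_day <- function(spec = synthetic_spec(),
                                    kind = c("steps", "calories"),
                                    as_increments = TRUE) {
  kind <- match.arg(kind)
  with_seed(spec$rng_seed + 3L, {
    t <- seq(0, 86400 - 900, by = 900)
    n <- length(t)
    active <- stats::rbinom(n, 1, min(1, spec$bout_rate * 900 / 3600))
    inc <- active * stats::rpois(n, spec$bout_steps)
    if (kind == "calories") inc <- round(inc * 0.04 + 1)  # resting burn
    values <- if (as_increments) inc else cumsum(inc)
    sig <- ts_signal(kind, t, values, is_regular = FALSE)
    attr(sig, "daily_total") <- sum(inc)
    attr(sig, "ground_truth") <- list(daily_total = sum(inc))
    sig
  })
}

#' Inject spike and gap artifacts into a clean signal
#'
#' Adds a Poisson number of additive spikes and deletes a Poisson number of
#' sample runs (gaps) with log-uniform durations, emulating sensor pressure
#' peaks and non-wear dropouts. The exact injected artifacts are returned
#' so recovery can be checked against ground truth.
#'
#' @param signal A clean irregular [ts_signal()].
#' @param spec A [synthetic_spec()].
#' @return List with `signal` (corrupted) and `log` (data.frames `spikes`
#'   and `gaps`).
#' @export
inject_artifacts <- function(signal, spec = synthetic_spec()) {
  with_seed(spec$rng_seed + 4L, {
    t <- signal$timestamps; v <- signal$values
    span_h <- if (length(t) > 1) (max(t) - min(t)) / 3600 else 0
    n_spikes <- stats::rpois(1, spec$spike_rate * span_h)
    spikes <- data.frame(time = numeric(), amplitude = numeric())
    if (n_spikes > 0 && length(t) > 0) {
      idx <- sort(sample(seq_along(t), min(n_spikes, length(t))))
      v[idx] <- v[idx] + spec$spike_amplitude
      spikes <- data.frame(time = t[idx], amplitude = spec$spike_amplitude)
    }
    n_gaps <- stats::rpois(1, spec$gap_rate * span_h)
    gaps <- data.frame(start = numeric(), duration = numeric())
    drop <- rep(FALSE, length(t))
    if (n_gaps > 0 && length(t) > 2) {
      r <- spec$gap_duration_range
      for (k in seq_len(n_gaps)) {
        dur <- exp(stats::runif(1, log(r[1]), log(r[2])))
        start <- stats::runif(1, min(t), max(t) - dur)
        drop <- drop | (t >= start & t < start + dur)
        gaps <- rbind(gaps, data.frame(start = start, duration = dur))
      }
    }
    out <- ts_signal(signal$kind, t[!drop], v[!drop], is_regular = FALSE,
                     day = signal$day)
    attr(out, "ground_truth") <- attr(signal, "ground_truth")
    list(signal = out, log = list(spikes = spikes, gaps = gaps))
  })
}
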