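make_hr_signal <- function(v, step = 15) {
  ts_signal("heart_rate", seq(0, by = step, length.out = length(v)), v,
            is_regular = TRUE, grid_step = step)
}

test_that("beat-to-beat intervals are the inverted heart rate", {
  bbi <- derive_bbi(make_hr_signal(c(60, 72, 100)))
  expect_equal(bbi$intervals, c(1000, 60000 / 72, 600))
  expect_error(derive_bbi(make_hr_signal(c(60, 0, 70))), "> 0")

  # constant heart rate gives zero variability downstream
  td <- hrv_time_domain(derive_bbi(make_hr_signal(rep(75, 50))))
  expect_equal(td$RMSSD, 0)
  expect_equal(td$SDNN, 0)
})

test_that("unfilled gaps break the series into segments", {
  v <- c(60, 61, NA, NA, NA, NA, NA, 62, 63)
  bbi <- derive_bbi(make_hr_signal(v))
  expect_equal(length(unique(bbi$segments)), 2)
  expect_length(wearsig:::successive_diffs(bbi), 2)   # never across the break
})

test_that("heart-rate summary recovers exact polynomial trends", {
  t <- seq(0, 86400 - 15, by = 15)
  hr <- ts_signal("heart_rate", t, 60 + 0.001 * t, is_regular = TRUE,
                  grid_step = 15)
  s <- hr_summary(hr)
  expect_equal(s$HR_Trend_Linear, 0.001, tolerance = 1e-9)
  expect_equal(s$HR_Trend_Quadratic, 0, tolerance = 1e-12)
  expect_equal(s$HR_Trend_R2, 1, tolerance = 1e-9)

  const <- hr_summary(make_hr_signal(rep(70, 100)))
  expect_equal(const$HR_Mean, 70)
  expect_equal(const$HR_SD, 0)
  expect_equal(const$HR_Max, 70)
  expect_equal(const$HR_Min, 70)
  expect_equal(const$HR_Trend_R2, 0)       # zero explained variance
})

test_that("extreme times report the first occurrence in day seconds", {
  t <- seq(0, 86400 - 15, by = 15)
  v <- rep(70, length(t))
  v[t == 81045] <- 99
  v[t == 81060] <- 99                       # tie: first occurrence wins
  v[t == 6315] <- 56
  hr <- ts_signal("heart_rate", t, v, is_regular = TRUE, grid_step = 15)
  s <- hr_summary(hr)
  expect_equal(s$HR_Max_Time, 81045)
  expect_equal(s$HR_Min_Time, 6315)
  expect_true(s$HR_Baseline >= s$HR_Min && s$HR_Baseline <= s$HR_Mean)
})

test_that("time-domain features match direct formulas on simple series", {
  td <- hrv_time_domain(interval_series(c(800, 800, 800)))
  expect_equal(td$SDNN, 0); expect_equal(td$RMSSD, 0)
  expect_equal(td$pNN50, 0); expect_equal(td$CVNN, 0)

  td <- hrv_time_domain(interval_series(c(800, 860)))
  expect_equal(td$RMSSD, 60)
  expect_equal(td$pNN50, 100)
})

test_that("every time-domain feature equals the brute-force oracle", {
  for (seed in 1:20) {
    rr <- make_rr(500, seed)
    bbi <- interval_series(rr, times = seq(0, by = 15,
                                           length.out = length(rr)),
                           source_step = 15)
    got <- hrv_time_domain(bbi)
    want <- o_hrv_time(rr)
    for (nm in names(want)) {
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-9, label = nm)
    }
  }
})

test_that("SDANN/SDNNI use wall-clock segments and need enough data", {
  rr <- make_rr(400, 3)                     # 100 min at 15 s
  bbi <- interval_series(rr, times = seq(0, by = 15, length.out = 400),
                         source_step = 15)
  td <- hrv_time_domain(bbi)
  # independent segmentation: 1-min segments of 4 intervals each
  mseg <- matrix(rr, nrow = 4)
  expect_equal(td$SDANN1, sd(colMeans(mseg)), tolerance = 1e-9)
  expect_equal(td$SDNNI1, mean(apply(mseg, 2, sd)), tolerance = 1e-9)

  short <- interval_series(rr[1:8], times = seq(0, by = 15, length.out = 8),
                           source_step = 15)
  expect_true(is.na(hrv_time_domain(short)$SDANN5))  # < two 5-min segments
})

test_that("Poincare geometry matches the rotated-cloud oracle and identities", {
  for (seed in 1:20) {
    rr <- make_rr(300, seed + 100)
    bbi <- interval_series(rr)
    g <- poincare(bbi)
    td <- hrv_time_domain(bbi)
    expect_equal(g$SD1, o_sd1_rotated(rr), tolerance = 1e-9)
    expect_equal(g$SD1, td$RMSSD / sqrt(2), tolerance = 1e-9)
    # SD1^2 + SD2^2 = 2 * population variance of the intervals
    expect_equal(g$SD1^2 + g$SD2^2,
                 2 * mean((rr - mean(rr))^2), tolerance = 1e-9)
    expect_equal(g$CSI, g$SD2 / g$SD1, tolerance = 1e-12)
    expect_equal(g$CVI, log10(16 * g$SD1 * g$SD2), tolerance = 1e-12)
    expect_equal(g$CSI_Modified, 4 * g$SD2^2 / g$SD1, tolerance = 1e-9)
  }

  alt <- interval_series(rep(c(800, 900), 10))
  expect_equal(poincare(alt)$SD1, 100 / sqrt(2), tolerance = 1e-9)

  ramp <- interval_series(800 + 2 * (1:50))
  g <- poincare(ramp)
  expect_lt(g$SD1 / g$SD2, 0.05)            # colinear cloud hugs the LI
})

test_that("asymmetry indices are 50 on mirror-symmetric clouds", {
  # every (x, y) has its mirror (y, x): alternating up/down by equal steps,
  # odd interval count so ascending and descending points pair up exactly
  rr <- c(rep(c(800, 850), 30), 800)
  a <- hra_asymmetry(interval_series(rr))
  expect_equal(a$GI, 50, tolerance = 1e-9)
  expect_equal(a$SI, 50, tolerance = 1e-9)
  expect_equal(a$AI, 50, tolerance = 1e-9)
  expect_equal(a$PI, 50, tolerance = 1e-9)
})

test_that("deceleration/acceleration contributions sum to one", {
  for (seed in 1:20) {
    rr <- make_rr(300, seed + 200)
    a <- hra_asymmetry(interval_series(rr))
    expect_equal(a$C1d + a$C1a, 1, tolerance = 1e-12)
    expect_equal(a$C2d + a$C2a, 1, tolerance = 1e-12)
    expect_equal(a$Cd + a$Ca, 1, tolerance = 1e-12)
    # short-term decomposition recomposes SD1 exactly
    g <- poincare(interval_series(rr))
    expect_equal(a$SD1d^2 + a$SD1a^2, g$SD1^2, tolerance = 1e-9)
  }
})

test_that("Guzik's index equals the point-by-point geometric oracle", {
  for (seed in 1:20) {
    rr <- make_rr(200, seed + 300)
    a <- hra_asymmetry(interval_series(rr))
    expect_equal(a$GI, o_gi(rr), tolerance = 1e-9)
  }
})

test_that("fragmentation handles monotone and alternating extremes", {
  inc <- interval_series(800 + 5 * (1:40))   # strictly increasing
  f <- fragmentation(inc)
  expect_equal(f$PIP, 0)
  expect_equal(f$IALS, 1 / 39)
  expect_equal(f$PSS, 0)
  expect_equal(f$PAS, 0)

  alt <- interval_series(rep(c(800, 850), 25))
  f <- fragmentation(alt)
  expect_equal(f$PIP, 100)
  expect_equal(f$PAS, 100)

  flat <- fragmentation(interval_series(rep(800, 20)))
  expect_true(is.na(flat$PIP) && is.na(flat$PAS))
})

test_that("fragmentation matches the run-length-encoding oracle", {
  for (seed in 1:20) {
    set.seed(seed + 400)
    rr <- 800 + 10 * cumsum(sample(c(-1, 1), 500, replace = TRUE))
    f <- fragmentation(interval_series(rr))
    want <- o_fragmentation(rr)
    expect_equal(f$PIP, want$PIP, tolerance = 1e-9)
    expect_equal(f$IALS, want$IALS, tolerance = 1e-9)
    expect_equal(f$PSS, want$PSS, tolerance = 1e-9)
    expect_equal(f$PAS, want$PAS, tolerance = 1e-9)
  }
})

test_that("percentage features stay in range and pNN50 <= pNN20", {
  for (seed in 1:10) {
    rr <- make_rr(300, seed + 500)
    td <- hrv_time_domain(interval_series(rr))
    expect_lte(td$pNN50, td$pNN20)
    a <- hra_asymmetry(interval_series(rr))
    f <- fragmentation(interval_series(rr))
    pct <- c(td$pNN50, td$pNN20, a$GI, a$SI, a$AI, a$PI, f$PIP, f$PSS, f$PAS)
    expect_true(all(pct >= 0 & pct <= 100))
    sds <- c(td$SDNN, td$RMSSD, td$SDSD, a$SD1d, a$SD1a, a$SD2d, a$SD2a)
    expect_true(all(sds >= 0))
  }
})

test_that("rank statistics are shuffle-invariant, sequence statistics are not", {
  rr <- make_rr(300, 11)
  set.seed(12)
  shuffled <- sample(rr)
  a <- hrv_time_domain(interval_series(rr))
  b <- hrv_time_domain(interval_series(shuffled))
  expect_equal(a$MeanNN, b$MeanNN)
  expect_equal(a$SDNN, b$SDNN)
  expect_equal(a$MedianNN, b$MedianNN)
  expect_equal(a$IQRNN, b$IQRNN)
  expect_false(isTRUE(all.equal(a$RMSSD, b$RMSSD)))
})

test_that("the full record carries every catalogue feature exactly once", {
  spec <- synthetic_spec(rng_seed = 5)
  pp <- preprocess(generate_hr_day(spec))
  rec <- hrv_features(pp$signal)
  expected <- c("HR_Baseline", "HR_Max", "HR_Min", "HR_Mean", "HR_SD",
                "HR_Max_Time", "HR_Min_Time", "HR_Trend_Linear",
                "HR_Trend_Quadratic", "HR_Trend_R2",
                "MeanNN", "SDNN", "SDANN1", "SDANN2", "SDANN5",
                "SDNNI1", "SDNNI2", "SDNNI5", "RMSSD", "SDSD",
                "CVNN", "CVSD", "MedianNN", "MadNN", "HCVNN", "IQRNN",
                "pNN50", "pNN20", "HTI", "TiNN",
                "SD1", "SD2", "SD1SD2", "CSI", "CVI", "CSI_Modified",
                "PIP", "IALS", "PSS", "PAS", "GI", "SI", "AI", "PI",
                "SD1d", "SD1a", "C1d", "C1a", "SD2d", "SD2a", "C2d", "C2a",
                "SDNNd", "SDNNa", "Cd", "Ca")
  expect_setequal(names(rec$features), expected)
  expect_true(is.na(rec$features$TiNN))     # reported but never computed
})
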