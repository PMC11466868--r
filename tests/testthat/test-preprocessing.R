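test_that("retiming averages the nearest raw points onto the grid", {
  sig <- ts_signal("heart_rate", c(14, 16), c(70, 74))
  reg <- retime(sig, 15)
  expect_true(reg$is_regular)
  expect_equal(reg$values[reg$timestamps == 15], 72)
  expect_equal(sum(!is.na(reg$values)), 1)
  expect_equal(length(reg$values), 86400 / 15)
})

test_that("retiming sums cumulative increments mapped to the same grid point", {
  sig <- ts_signal("steps", c(890, 905), c(10, 20))
  reg <- retime(sig, 900)
  expect_equal(reg$values[reg$timestamps == 900], 30)
  expect_equal(sum(reg$values, na.rm = TRUE), 30)   # mass conserved
})

test_that("points already on the grid pass through unchanged", {
  t <- seq(0, 86400 - 15, by = 15)
  set.seed(1)
  v <- runif(length(t), 60, 100)
  reg <- retime(ts_signal("heart_rate", t, v), 15)
  expect_equal(reg$values, v)
  expect_equal(reg$timestamps, t)
})

test_that("retiming matches the brute-force nearest-point oracle, ties to earlier", {
  for (seed in 1:5) {
    set.seed(seed)
    t <- sort(runif(300, 0, 86400 - 1))
    v <- runif(300, 60, 100)
    reg <- retime(ts_signal("heart_rate", t, v), 15)
    expect_equal(reg$values, o_retime(t, v, reg$timestamps), tolerance = 1e-12)
  }
  # exact halfway tie goes to the earlier grid point
  reg <- retime(ts_signal("heart_rate", c(7.5, 22.5), c(100, 50)), 15)
  expect_equal(reg$values[reg$timestamps == 0], 100)
  expect_equal(reg$values[reg$timestamps == 15], 50)
})

test_that("cumulative retiming conserves totals exactly under any grid", {
  for (seed in 1:5) {
    set.seed(seed)
    t <- sort(sample(seq(0, 86399), 50))
    v <- rpois(50, 40)
    reg <- retime(ts_signal("steps", t, v), 900)
    expect_identical(sum(reg$values, na.rm = TRUE), as.numeric(sum(v)))
  }
})

test_that("gap detection applies the per-signal duration limits", {
  # respiration: 4 missing minutes (240 s) is fillable (limit 300 s)
  t <- seq(0, 600 - 60, by = 60)
  v <- c(16, 15, NA, NA, NA, NA, 14, 15, 16, 15)
  resp <- ts_signal("respiration_rate", t, v, is_regular = TRUE, grid_step = 60)
  g <- detect_gaps(resp)
  expect_length(g, 1)
  expect_equal(g[[1]]$duration, 240)
  expect_equal(g[[1]]$n_missing, 4L)
  expect_true(g[[1]]$fillable)

  # heart rate: 5 missing 15 s points (75 s) exceeds the 60 s limit
  t <- seq(0, 150 - 15, by = 15)
  v <- c(70, 71, NA, NA, NA, NA, NA, 72, 71, 70)
  hr <- ts_signal("heart_rate", t, v, is_regular = TRUE, grid_step = 15)
  g <- detect_gaps(hr)
  expect_length(g, 1)
  expect_equal(g[[1]]$duration, 75)
  expect_false(g[[1]]$fillable)

  # fully present signal has no gaps
  full <- ts_signal("heart_rate", t, seq(70, 79), is_regular = TRUE,
                    grid_step = 15)
  expect_length(detect_gaps(full), 0)
})

test_that("gap segments are disjoint, maximal, and cover all absent points", {
  set.seed(7)
  n <- 400
  v <- runif(n, 60, 100)
  v[sample(n, 120)] <- NA
  sig <- ts_signal("heart_rate", seq(0, by = 15, length.out = n), v,
                   is_regular = TRUE, grid_step = 15)
  g <- detect_gaps(sig)
  covered <- unlist(lapply(g, function(x) x$i0:x$i1))
  expect_identical(sort(covered), which(is.na(v)))    # union == absent set
  expect_identical(anyDuplicated(covered), 0L)        # disjoint
  for (x in g) {                                      # maximal
    if (x$i0 > 1) expect_false(is.na(v[x$i0 - 1]))
    if (x$i1 < n) expect_false(is.na(v[x$i1 + 1]))
  }
})

test_that("boundary gaps are reported but never fillable", {
  v <- c(NA, NA, 96, 95, NA, 96, NA)
  sig <- ts_signal("spo2", seq(0, by = 60, length.out = 7), v,
                   is_regular = TRUE, grid_step = 60)
  g <- detect_gaps(sig)
  expect_length(g, 3)
  expect_false(g[[1]]$fillable)     # touches start
  expect_true(g[[2]]$fillable)
  expect_false(g[[3]]$fillable)     # touches end
})

test_that("fillable gaps are filled exactly linearly, others untouched", {
  sp <- ts_signal("spo2", seq(0, 180, 60), c(96, NA, NA, 93),
                  is_regular = TRUE, grid_step = 60)
  filled <- fill_gaps(sp, detect_gaps(sp))
  expect_equal(filled$values, c(96, 95, 94, 93))

  hr <- ts_signal("heart_rate", seq(0, 150, 15),
                  c(70, 71, NA, NA, NA, NA, NA, NA, NA, NA, 72),
                  is_regular = TRUE, grid_step = 15)
  g <- detect_gaps(hr)
  expect_false(g[[1]]$fillable)     # 135 s > 60 s
  filled <- fill_gaps(hr, g)
  expect_identical(filled$values, hr$values)

  # both neighbours equal -> constant interpolation
  sp2 <- ts_signal("spo2", seq(0, 180, 60), c(90, NA, NA, 90),
                   is_regular = TRUE, grid_step = 60)
  expect_equal(fill_gaps(sp2, detect_gaps(sp2))$values, rep(90, 4))
})

test_that("filling only writes inside gaps and stays within neighbour bounds", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    v <- runif(n, 85, 100)
    holes <- sample(3:(n - 3), 30)
    v[holes] <- NA
    sig <- ts_signal("spo2", seq(0, by = 60, length.out = n), v,
                     is_regular = TRUE, grid_step = 60)
    g <- detect_gaps(sig)
    filled <- fill_gaps(sig, g)
    present <- !is.na(v)
    expect_identical(filled$values[present], v[present])  # bit-identical
    for (x in g) {
      if (!x$fillable) next
      lo <- min(v[x$i0 - 1], v[x$i1 + 1])
      hi <- max(v[x$i0 - 1], v[x$i1 + 1])
      expect_true(all(filled$values[x$i0:x$i1] >= lo - 1e-12))
      expect_true(all(filled$values[x$i0:x$i1] <= hi + 1e-12))
    }
  }
})

test_that("denoising equals the brute-force windowed mean with edge shrinkage", {
  sig <- ts_signal("heart_rate", seq(0, 60, 15), c(1, 2, 9, 2, 1),
                   is_regular = TRUE, grid_step = 15)
  expect_equal(denoise(sig, 3)$values, c(1.5, 4, 13 / 3, 4, 1.5))

  for (seed in 1:20) {
    set.seed(seed)
    n <- 100
    v <- runif(n, 50, 150)
    v[sample(n, 15)] <- NA
    sig <- ts_signal("heart_rate", seq(0, by = 15, length.out = n), v,
                     is_regular = TRUE, grid_step = 15)
    for (w in c(3, 5)) {
      expect_equal(denoise(sig, w)$values, o_movmean(v, w), tolerance = 1e-12)
    }
  }
})

test_that("denoising fixes constants, commutes with shifts, preserves length", {
  const <- ts_signal("heart_rate", seq(0, 45, 15), rep(70, 4),
                     is_regular = TRUE, grid_step = 15)
  expect_equal(denoise(const, 3)$values, rep(70, 4))

  set.seed(3)
  v <- runif(50, 60, 100)
  sig <- ts_signal("heart_rate", seq(0, by = 15, length.out = 50), v,
                   is_regular = TRUE, grid_step = 15)
  shifted <- ts_signal("heart_rate", sig$timestamps, v + 11,
                       is_regular = TRUE, grid_step = 15)
  expect_equal(denoise(shifted, 3)$values, denoise(sig, 3)$values + 11)
  expect_length(denoise(sig, 5)$values, 50)

  expect_identical(denoise(sig, 1)$values, v)       # window 1 is identity
  expect_error(denoise(sig, 4), "odd")
})

test_that("preprocess composes the stages and reports the audit trail", {
  set.seed(21)
  t <- seq(0, 86400 - 15, by = 15)
  v <- 70 + 5 * sin(2 * pi * t / 86400) + rnorm(length(t), 0, 1)
  drop <- t >= 3600 & t < 3645                     # 45 s gap (3 points)
  sig <- ts_signal("heart_rate", t[!drop], v[!drop])
  cfg <- pipeline_config()
  res <- preprocess(sig, cfg)

  # equals the hand-composed stage calls
  manual <- denoise(fill_gaps(retime(sig, 15),
                              detect_gaps(retime(sig, 15), 60)), 3)
  expect_equal(res$signal$values, manual$values)
  expect_equal(res$report$n_filled, 3L)
  expect_equal(res$report$n_raw, sum(!drop))
  expect_false(anyNA(res$signal$values))

  # the spike-free gap region is now linear-interpolated then smoothed
  expect_true(all(!is.na(res$signal$values[t %in% c(3600, 3615, 3630)])))
})

test_that("cumulative streams skip filling and smoothing", {
  set.seed(4)
  t <- seq(0, 86400 - 900, by = 900)
  v <- rpois(length(t), 30)
  keep <- seq_along(t)[-c(10, 11)]
  sig <- ts_signal("steps", t[keep], v[keep])
  res <- preprocess(sig)
  expect_equal(res$report$n_filled, 0L)
  expect_equal(res$report$denoise_window_used, 1L)
  expect_identical(res$signal$values, retime(sig, 900)$values)
  expect_equal(sum(res$signal$values, na.rm = TRUE), sum(v[keep]))
})

test_that("an empty stream preprocesses to an all-absent grid", {
  sig <- ts_signal("heart_rate", numeric(0), numeric(0))
  expect_warning(res <- preprocess(sig), "empty")
  expect_equal(res$report$n_raw, 0)
  expect_true(all(is.na(res$signal$values)))
})
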