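# Brute-force reference implementations, deliberately naive (explicit loops,
# direct formulas) and independent of the package internals.

# Nearest-grid-point retiming: for every raw sample scan all grid points,
# assign to the closest (ties to the earlier), then aggregate per cell.
o_retime <- function(timestamps, values, grid, aggregate = mean) {
  cells <- vector("list", length(grid))
  for (i in seq_along(timestamps)) {
    dists <- abs(grid - timestamps[i])
    j <- which(dists == min(dists))[1]          # earlier grid point on ties
    cells[[j]] <- c(cells[[j]], values[i])
  }
  out <- rep(NA_real_, length(grid))
  for (j in seq_along(grid)) {
    if (length(cells[[j]]) > 0) out[j] <- aggregate(cells[[j]])
  }
  out
}

# Centred moving mean with shrinking windows; NA values are hard boundaries.
o_movmean <- function(v, window) {
  h <- (window - 1) %/% 2
  out <- v
  for (i in seq_along(v)) {
    if (is.na(v[i])) next
    lo <- i; hi <- i
    while (lo > 1 && lo > i - h && !is.na(v[lo - 1])) lo <- lo - 1
    while (hi < length(v) && hi < i + h && !is.na(v[hi + 1])) hi <- hi + 1
    out[i] <- mean(v[lo:hi])
  }
  out
}

# Direct-formula time-domain HRV statistics on a single-segment RR series.
o_hrv_time <- function(rr) {
  n <- length(rr)
  d <- rr[-1] - rr[-n]
  mu <- sum(rr) / n
  sdnn <- sqrt(sum((rr - mu)^2) / (n - 1))
  rmssd <- sqrt(sum(d^2) / length(d))
  med <- stats::median(rr)
  madnn <- stats::median(abs(rr - med)) * 1.4826
  q <- o_quantile7(rr, 0.75) - o_quantile7(rr, 0.25)
  counts <- table(floor(rr / (1000 / 128)))
  list(MeanNN = mu, SDNN = sdnn, RMSSD = rmssd,
       SDSD = sqrt(sum((d - mean(d))^2) / (length(d) - 1)),
       CVNN = sdnn / mu, CVSD = rmssd / mu,
       MedianNN = med, MadNN = madnn, HCVNN = madnn / med,
       IQRNN = q,
       pNN50 = 100 * sum(abs(d) > 50) / length(d),
       pNN20 = 100 * sum(abs(d) > 20) / length(d),
       HTI = n / max(counts))
}

# Type-7 quantile by hand.
o_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
}

# SD1 via explicit 45-degree rotation of the lagged point cloud (uncentred
# RMS perpendicular to the identity line).
o_sd1_rotated <- function(rr) {
  x <- rr[-length(rr)]; y <- rr[-1]
  u <- (y - x) / sqrt(2)
  sqrt(mean(u^2))
}

# Guzik's index by point-by-point perpendicular distances.
o_gi <- function(rr) {
  x <- rr[-length(rr)]; y <- rr[-1]
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    d <- abs(y[i] - x[i]) / sqrt(2)
    if (y[i] > x[i]) num <- num + d
    if (y[i] != x[i]) den <- den + d
  }
  100 * num / den
}

# Fragmentation indices by explicit run-length encoding of the sign sequence
# (zeros inherit the previous sign, leading zeros dropped).
o_fragmentation <- function(rr) {
  d <- diff(rr)
  s <- sign(d)
  while (length(s) > 0 && s[1] == 0) s <- s[-1]
  offset <- length(d) - length(s)            # dropped leading zeros
  if (length(s) == 0) return(NULL)
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- s[i - 1]
  m <- length(s)
  # runs
  runs <- c(); cur <- 1
  for (i in seq_len(m - 1) + 1) {
    if (s[i] == s[i - 1]) cur <- cur + 1 else { runs <- c(runs, cur); cur <- 1 }
  }
  runs <- c(runs, cur)
  changes <- 0
  for (i in 2:m) if (s[i] != s[i - 1]) changes <- changes + 1
  short <- 0
  for (r in runs) if (r < 3) short <- short + r
  # alternation segments on the flip sequence
  flips <- s[-1] != s[-m]
  covered <- rep(FALSE, length(rr))
  i <- 1
  while (i <= length(flips)) {
    if (flips[i]) {
      j <- i
      while (j < length(flips) && flips[j + 1]) j <- j + 1
      L <- j - i + 2                          # differences in the stretch
      if (L + 1 >= 4) {
        first_nn <- offset + i                # NN index before difference i
        covered[first_nn:(first_nn + L)] <- TRUE
      }
      i <- j + 1
    } else i <- i + 1
  }
  list(PIP = 100 * changes / (m - 1),
       IALS = 1 / mean(runs),
       PSS = 100 * short / m,
       PAS = 100 * sum(covered) / length(rr))
}

# Delta Index by explicit epoch bucketing and pairing.
o_delta_index <- function(times, values, epoch) {
  ids <- floor((times - times[1]) / epoch)
  means <- c()
  for (g in sort(unique(ids))) means <- c(means, mean(values[ids == g]))
  s <- 0
  for (k in 2:length(means)) s <- s + abs(means[k] - means[k - 1])
  s / (length(means) - 1)
}

# O(n^2) template-counting entropies, scalar loops throughout.
o_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logs <- numeric(nt)
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt) {
        dmax <- 0
        for (k in 0:(mm - 1)) dmax <- max(dmax, abs(x[i + k] - x[j + k]))
        if (dmax <= r) cnt <- cnt + 1
      }
      logs[i] <- log(cnt / nt)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

o_sampen <- function(x, m, r) {
  n <- length(x)
  count_matches <- function(mm) {
    nt <- n - m                               # same template count both lengths
    cnt <- 0
    for (i in 1:nt) for (j in 1:nt) {
      if (i == j) next
      dmax <- 0
      for (k in 0:(mm - 1)) dmax <- max(dmax, abs(x[i + k] - x[j + k]))
      if (dmax <= r) cnt <- cnt + 1
    }
    cnt
  }
  B <- count_matches(m); A <- count_matches(m + 1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Seeded RR fixture: lognormal-ish intervals around 850 ms.
make_rr <- function(n, seed) {
  set.seed(seed)
  850 + cumsum(rnorm(n, 0, 5)) * 0.1 + rnorm(n, 0, 30)
}
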