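# Naive, loop-based reimplementation of the 178-value feature extractor.
# Deliberately unvectorized and independent of the package internals (its
# own DFT, its own moment sums) so it can serve as an oracle.

oracleMean <- function(v) {
  s <- 0
  for (e in v) s <- s + e
  s / length(v)
}

oracleMoments <- function(v) {
  n <- length(v)
  m <- oracleMean(v)
  s2 <- s3 <- s4 <- 0
  for (e in v) {
    d <- e - m
    s2 <- s2 + d^2; s3 <- s3 + d^3; s4 <- s4 + d^4
  }
  m2 <- s2 / n
  if (m2 == 0) return(c(m, 0, 0, 0))
  c(m, sqrt(m2), (s3 / n) / m2^1.5, (s4 / n) / m2^2 - 3)
}

oracleRms <- function(v) {
  s <- 0
  for (e in v) s <- s + e^2
  sqrt(s / length(v))
}

# centered boxcar with reflected ends; even kernels extend one point right
oracleSmooth <- function(v, k) {
  n <- length(v)
  left <- (k - 1) %/% 2
  out <- numeric(n)
  for (i in 1:n) {
    acc <- 0
    for (j in (i - left):(i - left + k - 1)) {
      jj <- j
      if (jj < 1) jj <- 1 - jj
      if (jj > n) jj <- 2 * n + 1 - jj
      acc <- acc + v[jj]
    }
    out[i] <- acc / k
  }
  out
}

oracleHistogram <- function(v) {
  n <- length(v)
  m <- oracleMean(v)
  m2 <- 0
  for (e in v) m2 <- m2 + (e - m)^2
  s <- sqrt(m2 / n)
  counts <- numeric(9)
  w <- 8 / 9
  for (e in v) {
    z <- if (s == 0) 0 else (e - m) / s
    b <- 1
    while (b < 9 && z >= -4 + b * w) b <- b + 1
    if (z >= 4) b <- 9
    counts[b] <- counts[b] + 1
  }
  counts
}

oracleDftMagnitudes <- function(v, nBins = 32) {
  n <- length(v)
  out <- numeric(nBins)
  for (k in 0:(nBins - 1)) {
    re <- im <- 0
    for (t in 0:(n - 1)) {
      ang <- -2 * pi * k * t / n
      re <- re + v[t + 1] * cos(ang)
      im <- im + v[t + 1] * sin(ang)
    }
    out[k + 1] <- sqrt(re^2 + im^2)
  }
  out
}

oracleFeatures <- function(clip) {
  x <- clip[, 1]; y <- clip[, 2]; z <- clip[, 3]
  axes <- list(x, y, z)
  mom <- lapply(axes, oracleMoments)
  jerk <- lapply(axes, function(v) oracleMoments(diff(v)))
  means <- sapply(mom, `[`, 1)
  n <- nrow(clip)
  norms <- cp <- acp <- NULL
  normSum <- 0
  cpSum <- acpSum <- c(0, 0, 0)
  for (i in 1:n) {
    normSum <- normSum + sqrt(x[i]^2 + y[i]^2 + z[i]^2)
    p <- c(x[i] * y[i], x[i] * z[i], y[i] * z[i])
    cpSum <- cpSum + p
    acpSum <- acpSum + abs(p)
  }
  c(means, abs(means),
    sapply(mom, `[`, 2), sapply(mom, `[`, 3), sapply(mom, `[`, 4),
    sapply(jerk, `[`, 1), sapply(jerk, `[`, 2),
    sapply(jerk, `[`, 3), sapply(jerk, `[`, 4),
    sapply(axes, oracleRms),
    sapply(axes, function(v) oracleRms(oracleSmooth(v, 5))),
    sapply(axes, function(v) oracleRms(oracleSmooth(v, 10))),
    sapply(axes, min), sapply(axes, max),
    sapply(axes, function(v) min(abs(v))),
    sapply(axes, function(v) max(abs(v))),
    unlist(lapply(axes, oracleHistogram)),
    unlist(lapply(axes, oracleDftMagnitudes)),
    normSum / n, cpSum / n, acpSum / n)
}
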