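# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: quantiles by sorting, Gaussian masses via pnorm, peak
# enumeration by brute force, distances by explicit pairwise arithmetic,
# ellipse membership re-derived from the ellipse equation.

# percentile by direct sort (oracle for basal scaling)
oraclePercentile <- function(v, p) {
  s <- sort(v)
  s[max(1, ceiling(p / 100 * length(s)))]
}

# mass of A * exp(-(x-mu)^2 / (2 sigma^2)) over [lo, hi] via pnorm
oracleGaussMass <- function(A, mu, sigma, lo, hi) {
  A * sigma * sqrt(2 * pi) * (pnorm(hi, mu, sigma) - pnorm(lo, mu, sigma))
}

# all strict local maxima by brute-force neighbour comparison
oracleLocalMaxima <- function(v) {
  which(vapply(seq_along(v), function(i)
    i > 1 && i < length(v) && v[i] > v[i - 1] && v[i] > v[i + 1],
    logical(1)))
}

# mixture mean/SD by high-resolution numerical moments of the density
oracleMixtureMoments <- function(A, mu, sigma) {
  x <- seq(min(mu) - 8 * max(sigma), max(mu) + 8 * max(sigma),
           length.out = 20001)
  d <- rowSums(vapply(seq_along(A), function(i)
    A[i] * exp(-(x - mu[i])^2 / (2 * sigma[i]^2)), numeric(length(x))))
  w <- d / sum(d)
  m <- sum(w * x)
  c(mean = m, sd = sqrt(sum(w * x^2) - m^2))
}

# per-interval speeds by explicit pairwise distances over consecutive frames
oracleIntervalSpeeds <- function(trackDf) {
  out <- numeric(0)
  for (cell in unique(trackDf$cell)) {
    d <- trackDf[trackDf$cell == cell, ]
    d <- d[order(d$frame), ]
    for (i in seq_len(nrow(d) - 1)) {
      if (d$frame[i + 1] - d$frame[i] == 1)
        out <- c(out, sqrt((d$x[i + 1] - d$x[i])^2 +
                           (d$y[i + 1] - d$y[i])^2))
    }
  }
  out
}

# ellipse membership straight from the ellipse inequality
oracleMembership <- function(nuclei, regions) {
  vapply(seq_len(nrow(nuclei)), function(i) {
    hit <- which(((nuclei$x[i] - regions$cx) / regions$a)^2 +
                 ((nuclei$y[i] - regions$cy) / regions$b)^2 <= 1)
    if (length(hit)) regions$region[hit[1]] else 0L
  }, numeric(1))
}

# closed-form Hertz inversion at a single sampled point
oracleHertzInvert <- function(force, delta, halfAngle = 35, nu = 0.5) {
  force * pi * (1 - nu^2) / (2 * tan(halfAngle * pi / 180) * delta^2) / 1e-3
}

# rotate/translate all track positions rigidly
rigidMotion <- function(df, angle, dx, dy) {
  co <- cos(angle); si <- sin(angle)
  data.frame(cell = df$cell, frame = df$frame,
             x = co * df$x - si * df$y + dx,
             y = si * df$x + co * df$y + dy)
}

# noiseless two-peak profile built directly from the formula
cleanProfile <- function(A1 = 100, mu1 = 8, s1 = 1.2, A2 = 100, mu2 = 17,
                         s2 = 1.2, baseline = 0, spacing = 0.1, n = 256,
                         green = NULL) {
  x <- seq(0, by = spacing, length.out = n)
  red <- baseline + A1 * exp(-(x - mu1)^2 / (2 * s1^2)) +
    A2 * exp(-(x - mu2)^2 / (2 * s2^2))
  if (is.null(green)) green <- rep(0, n)
  LineScanProfile(x, red, green)
}
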