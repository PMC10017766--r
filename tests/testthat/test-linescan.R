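test_that("basal scaling zeroes a constant channel and preserves peak height", {
  x <- seq(0, 10, by = 0.1)
  p <- LineScanProfile(x, red = rep(7, length(x)), green = rep(7, length(x)))
  s <- scaleToBasal(p)
  expect_equal(redChannel(s), rep(0, length(x)))
  # baseline 10, peak max 30 -> scaled max 20
  q <- cleanProfile(A1 = 20, mu1 = 5, s1 = 0.8, A2 = 20, mu2 = 15, s2 = 0.8,
                    baseline = 10, n = 220, green = rep(1, 220))
  expect_equal(max(redChannel(scaleToBasal(q))), 20, tolerance = 1e-6)
})

test_that("constant-zero channels pass through with a warning flag", {
  x <- seq(0, 10, by = 0.1)
  p <- LineScanProfile(x, red = rep(1, length(x)), green = rep(0, length(x)))
  expect_warning(s <- scaleToBasal(p), "constant zero")
  expect_true("constant-channel-green" %in% scanFlags(s))
  expect_equal(greenChannel(s), rep(0, length(x)))
})

test_that("default basal estimate lands within one noise SD of the truth", {
  for (s in 1:10) {
    p <- simulateLineScan(seed = s)
    tr <- groundTruth(p)
    scaled <- scaleToBasal(p)
    # recovered basal = what was subtracted from the red channel
    basal <- max(redChannel(p) - redChannel(scaled))
    expect_lt(abs(basal - tr$baseline), tr$noiseSd)
  }
  # the percentile path matches the sort-based oracle
  p <- simulateLineScan(seed = 1)
  scaled <- scaleToBasal(p, basalPercentile = 5)
  basal <- max(redChannel(p) - redChannel(scaled))
  expect_equal(basal, quantile(redChannel(p), 0.05, names = FALSE),
               tolerance = 1e-9)
  expect_lt(abs(basal - oraclePercentile(redChannel(p), 5)),
            diff(range(redChannel(p))) / 100)
})

test_that("smoothing is zero-phase: null, peak-preserving and symmetric", {
  x <- seq(0, 20, by = 0.1)
  z <- LineScanProfile(x, red = rep(0, length(x)), green = rep(0, length(x)))
  expect_equal(redChannel(smoothProfile(z)), rep(0, length(x)))
  g <- cleanProfile(A1 = 100, mu1 = 10, s1 = 1.5, A2 = 0.001, mu2 = 17,
                    s2 = 1, n = 256)
  sm <- smoothProfile(g)
  peakAt <- scanPosition(sm)[which.max(redChannel(sm))]
  expect_lt(abs(peakAt - 10), 0.1 + 1e-9)
  # mirror-symmetric two-peak input -> mirror-symmetric output
  n <- 257
  xs <- seq(0, by = 0.1, length.out = n)
  v <- exp(-(xs - 9.3)^2 / 2) + exp(-(xs - (max(xs) - 9.3))^2 / 2)
  ps <- LineScanProfile(xs, v, v)
  out <- redChannel(smoothProfile(ps))
  expect_equal(out, rev(out), tolerance = 1e-6)
})

test_that("smoothing rejects profiles too short for filtfilt", {
  x <- seq(0, 3.4, by = 0.1)  # 35 samples, passes class validity
  p <- LineScanProfile(x, red = rep(1, 35), green = rep(1, 35))
  expect_error(smoothProfile(p, filterOrder = 12), "too short")
})

test_that("two-peak detection matches brute-force enumeration", {
  p <- cleanProfile(A1 = 50, mu1 = 5, s1 = 1, A2 = 50, mu2 = 15, s2 = 1)
  pk <- findTwoPeaks(p)
  expect_equal(pk$position, c(5, 15), tolerance = 0.1)

  # three peaks, heights 10/50/40 at 3/8/17 -> the 50 and 40 peaks win
  x <- seq(0, by = 0.1, length.out = 256)
  v <- 10 * exp(-(x - 3)^2 / 0.5) + 50 * exp(-(x - 8)^2 / 0.5) +
    40 * exp(-(x - 17)^2 / 0.5)
  p3 <- LineScanProfile(x, v, v)
  pk3 <- findTwoPeaks(p3)
  expect_equal(pk3$position, c(8, 17), tolerance = 0.1)
  # oracle: enumerate maxima, rank by height
  idx <- oracleLocalMaxima(v)
  top2 <- sort(x[idx[order(-v[idx])][1:2]])
  expect_equal(pk3$position, top2, tolerance = 1e-9)
})

test_that("a single peak raises the no-distinct-BM error", {
  p <- cleanProfile(A1 = 100, mu1 = 10, s1 = 1.5, A2 = 0, mu2 = 17, s2 = 1)
  expect_error(findTwoPeaks(p), "no distinct basement membrane")
})

test_that("exact gauss1 data recover parameters at machine precision", {
  p <- cleanProfile(A1 = 100, mu1 = 10, s1 = 1.5, A2 = 0.001, mu2 = 20,
                    s2 = 0.5, n = 256)
  f <- fitPeak(p, center = 10)
  expect_identical(f@modelOrder, 1L)
  expect_equal(f@amplitude, 100, tolerance = 1e-6)
  expect_equal(f@effectiveMean, 10, tolerance = 1e-6)
  expect_equal(f@effectiveSd, 1.5, tolerance = 1e-6)
})

test_that("exact gauss2 data select the double model", {
  x <- seq(0, by = 0.1, length.out = 256)
  v <- 100 * exp(-(x - 9.5)^2 / (2 * 0.64)) +
    100 * exp(-(x - 10.5)^2 / (2 * 0.64))
  p <- LineScanProfile(x, v, rep(0, 256))
  f <- fitPeak(p, center = 10)
  expect_identical(f@modelOrder, 2L)
  # oracle: exact-RSS comparison — gauss1 cannot reproduce a two-mean sum
  expect_gt(f@selectionScore, 2)
})

test_that("effective SD of a symmetric gauss2 equals sqrt(sigma^2 + d^2)", {
  # moments computed from component parameters against a numerical oracle
  A <- c(80, 80); mu <- c(9.4, 10.6); sg <- c(0.7, 0.7)
  m <- ecmscan:::mixtureMoments(A, mu, sg)
  expect_equal(unname(m["sd"]), sqrt(0.7^2 + 0.6^2), tolerance = 1e-12)
  o <- oracleMixtureMoments(A, mu, sg)
  expect_equal(unname(m["mean"]), unname(o["mean"]), tolerance = 1e-4)
  expect_equal(unname(m["sd"]), unname(o["sd"]), tolerance = 1e-3)
})

test_that("segment points follow mean +/- 2 SD with the midpoint overlap rule", {
  mkfit <- function(mu, sd) new("GaussianPeakFit", modelOrder = 1L,
                                amplitude = 1, mean = mu, sd = sd,
                                effectiveMean = mu, effectiveSd = sd,
                                rss = 0, selectionScore = 0)
  sp <- segmentPoints(mkfit(10, 1), mkfit(15, 1), span = c(0, 25))
  expect_equal(unname(segmentValues(sp)), c(8, 12, 13, 17))
  sp2 <- segmentPoints(mkfit(5, 1), mkfit(15, 2), span = c(0, 25))
  expect_equal(unname(segmentValues(sp2)), c(3, 7, 11, 19))
  ov <- segmentPoints(mkfit(5, 2), mkfit(8, 2), span = c(0, 25))
  expect_equal(unname(segmentValues(ov))[2:3], c(6.5, 6.5))
  expect_true(ov@noDistinctIM)
  expect_error(segmentPoints(mkfit(2, 1.5), mkfit(8, 2), span = c(0, 25)),
               "exceeds scan")
})

test_that("region abundance integrates rectangles and Gaussians correctly", {
  pts <- new("SegmentPoints", s1 = 2, s2 = 6, s3 = 10, s4 = 14)
  x <- seq(0, by = 0.1, length.out = 200)
  zero <- LineScanProfile(x, rep(0, 200), rep(0, 200))
  abZero <- regionAbundance(zero, pts, "red")
  expect_equal(unname(abundances(abZero)[1:4]), rep(0, 4))

  pulse <- ifelse(x >= 2 & x <= 6, 10, 0)
  pp <- LineScanProfile(x, pulse, pulse)
  expect_equal(abundances(regionAbundance(pp, pts, "red"))[["bmLeft"]], 40,
               tolerance = 1e-9)

  # clean Gaussian over mu +/- 2 sigma vs erf closed form, 0.1 um spacing
  A <- 120; mu <- 8; sg <- 1.2
  g <- cleanProfile(A1 = A, mu1 = mu, s1 = sg, A2 = 0, mu2 = 17, s2 = 1)
  gp <- new("SegmentPoints", s1 = mu - 2 * sg, s2 = mu + 2 * sg,
            s3 = 20, s4 = 24)
  got <- abundances(regionAbundance(g, gp, "red"))[["bmLeft"]]
  expect_equal(got, 0.9545 * A * sg * sqrt(2 * pi), tolerance = 0.005)
  expect_equal(got, oracleGaussMass(A, mu, sg, mu - 2 * sg, mu + 2 * sg),
               tolerance = 0.005)
})

test_that("abundance regions partition the total integral exactly", {
  p <- simulateLineScan(seed = 21)
  r <- analyzeLineScan(p)
  for (ch in c("red", "green")) {
    a <- abundances(r)[[ch]]
    sv <- segmentValues(r)
    prof <- r@profile
    total <- ecmscan:::trapzOver(scanPosition(prof), slot(prof, ch),
                                 sv[["s1"]], sv[["s4"]])
    expect_equal(a[["bmLeft"]] + a[["im"]] + a[["bmRight"]], total,
                 tolerance = 1e-9)
  }
})

test_that("abundances are scale-equivariant and segment points red-derived", {
  p <- simulateLineScan(seed = 22)
  r1 <- analyzeLineScan(p)
  p2 <- LineScanProfile(scanPosition(p), redChannel(p),
                        3 * greenChannel(p), truth = groundTruth(p))
  r2 <- analyzeLineScan(p2)
  expect_equal(segmentValues(r2), segmentValues(r1), tolerance = 1e-9)
  expect_equal(abundances(r2)$green[["bmTotal"]],
               3 * abundances(r1)$green[["bmTotal"]], tolerance = 1e-6)
  expect_equal(abundances(r2)$stoichiometry, 3 * abundances(r1)$stoichiometry,
               tolerance = 1e-6)
})

test_that("a fitted gauss1 holds 95.45% of its own mass in its window", {
  p <- simulateLineScan(seed = 23)
  r <- analyzeLineScan(p)
  f <- r@leftFit
  if (f@modelOrder == 1L) {
    inWin <- oracleGaussMass(f@amplitude, f@mean, f@sd,
                             f@effectiveMean - 2 * f@effectiveSd,
                             f@effectiveMean + 2 * f@effectiveSd)
    total <- f@amplitude * f@sd * sqrt(2 * pi)
    expect_gte(inWin / total, 0.954)
    expect_lte(inWin / total, 0.955)
  } else succeed("double model selected; covered by the mass criterion test")
})

test_that("stoichiometry is the green/red BM ratio with sane errors", {
  p <- simulateLineScan(seed = 24)
  r <- analyzeLineScan(p)
  ab <- abundances(r)
  expect_equal(ab$stoichiometry,
               ab$green[["bmTotal"]] / ab$red[["bmTotal"]])
  expect_error(stoichiometry(new("RegionAbundance", bmLeft = 0, im = 0,
                                 bmRight = 0, bmTotal = 0,
                                 peakBmIntensity = 0),
                             r@greenAbundance), "stoichiometry undefined")
})

test_that("noise-free synthetic profiles recover closed-form abundances", {
  p <- simulateLineScan(noiseSd = 0, seed = 31)
  r <- analyzeLineScan(p)
  tr <- linescanTruthAbundance(groundTruth(p))
  ab <- abundances(r)
  expect_equal(ab$red[["bmTotal"]], tr$red[["bmTotal"]], tolerance = 0.01)
  expect_equal(ab$green[["bmTotal"]], tr$green[["bmTotal"]],
               tolerance = 0.01)
  # the zero-phase filter widens the fitted window slightly, shaving the IM
  # plateau at both edges; 3% bounds that systematic effect
  expect_equal(ab$green[["im"]], tr$green[["im"]], tolerance = 0.03)
  expect_equal(ab$stoichiometry, tr$stoichiometry, tolerance = 0.01)
})

test_that("a synthetic profile without IM signal recovers the BM fraction", {
  p <- simulateLineScan(greenBmFraction = 0.8, greenImLevel = 0,
                        noiseSd = 0, seed = 32)
  r <- analyzeLineScan(p)
  expect_equal(abundances(r)$stoichiometry, 0.8, tolerance = 0.01)
})

test_that("single-peak profiles fail with the stage name attached", {
  x <- seq(0, by = 0.1, length.out = 256)
  v <- 10 + 100 * exp(-(x - 12)^2 / (2 * 1.44))
  p <- LineScanProfile(x, v, v)
  expect_error(analyzeLineScan(p), "\\[peaks\\].*basement membrane")
})

test_that("region sampling is uniform, seeded and errors when exhausted", {
  cand <- letters[1:10]
  expect_identical(sort(sampleRegions(cand, 10, seed = 1)), sort(cand))
  expect_identical(sampleRegions(cand, 4, seed = 5),
                   sampleRegions(cand, 4, seed = 5))
  expect_error(sampleRegions(cand, 11, seed = 1), "cannot sample")
  # inclusion frequency ~ n/N (hypergeometric expectation)
  hits <- integer(10); names(hits) <- cand
  for (s in 1:600) {
    drawn <- sampleRegions(cand, 3, seed = s)
    hits[drawn] <- hits[drawn] + 1L
  }
  expect_true(all(abs(hits / 600 - 0.3) < 0.08))
})
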