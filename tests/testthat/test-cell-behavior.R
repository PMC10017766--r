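test_that("interval speeds follow pairwise Euclidean displacement", {
  still <- TrackSet(data.frame(cell = "a", frame = 0:5, x = 2, y = 3))
  expect_equal(intervalSpeeds(still)$speed, rep(0, 5))

  # 3-4-5 steps
  tr <- data.frame(cell = "b", frame = 0:4,
                   x = 3 * (0:4), y = 4 * (0:4))
  expect_equal(intervalSpeeds(TrackSet(tr))$speed, rep(5, 4))

  ts <- simulateTracks(nCells = 8, frames = 30, seed = 2)
  got <- intervalSpeeds(ts)
  expect_equal(sort(got$speed), sort(oracleIntervalSpeeds(trackData(ts))),
               tolerance = 1e-12)
})

test_that("gaps yield no speed entry for the missing interval", {
  tr <- data.frame(cell = "c", frame = c(0, 1, 3, 4), x = c(0, 1, 5, 6),
                   y = 0)
  sp <- intervalSpeeds(TrackSet(tr))
  expect_equal(nrow(sp), 2)  # 0->1 and 3->4 only
  expect_equal(sp$frame, c(0, 3))
})

test_that("group mean speed aggregates per cell then across cells", {
  tr <- rbind(data.frame(cell = "a", frame = 0:10, x = 4 * (0:10), y = 0),
              data.frame(cell = "b", frame = 0:10, x = 6 * (0:10), y = 0))
  ms <- meanSpeed(TrackSet(tr))
  expect_equal(ms@meanSpeed, 5)
  expect_equal(ms@sdSpeed, sqrt(2))

  still <- TrackSet(data.frame(cell = rep(c("a", "b"), each = 4),
                               frame = rep(0:3, 2), x = 1, y = 1))
  ms0 <- meanSpeed(still)
  expect_equal(ms0@meanSpeed, 0)
  expect_equal(ms0@sdSpeed, 0)
  expect_error(meanSpeed(TrackSet(tr), window = c(50, 50)), "empty")
})

test_that("group speed recovers the generator's speed scale", {
  ts <- simulateTracks(nCells = 200, frames = 30, speedMean = 6,
                       speedSd = 1, dropoutRate = 0, seed = 6)
  ms <- meanSpeed(ts)
  expect_lt(abs(ms@meanSpeed - 6), 0.2)
  # oracle: stats on the stored true step lengths
  expect_equal(ms@meanSpeed,
               mean(vapply(groundTruth(ts)$stepLengths, mean, numeric(1))),
               tolerance = 1e-9)
})

test_that("total displacement sums 90 intervals over 15 h and excludes gaps", {
  tr <- data.frame(cell = "a", frame = 0:90, x = 5 * (0:90), y = 0)
  d <- totalDisplacement(TrackSet(tr), duration = 900)
  expect_equal(d$displacement$pathLength, 450)

  short <- TrackSet(rbind(tr, data.frame(cell = "b", frame = 0:50,
                                         x = 0, y = 0)))
  d2 <- totalDisplacement(short, duration = 900)
  expect_equal(d2$displacement$cell, "a")
  expect_equal(d2$excluded$cell, "b")
  expect_match(d2$excluded$reason, "incomplete")
})

test_that("path length dominates net displacement (triangle inequality)", {
  ts <- simulateTracks(nCells = 25, frames = 91, persistence = 0.3,
                       dropoutRate = 0, seed = 13)
  d <- totalDisplacement(ts)
  expect_true(all(d$displacement$pathLength >=
                  d$displacement$netDisplacement - 1e-9))
})

test_that("motility statistics are rigid-motion invariant", {
  ts <- simulateTracks(nCells = 10, frames = 40, dropoutRate = 0, seed = 19)
  moved <- TrackSet(rigidMotion(trackData(ts), angle = 0.83, dx = 120,
                                dy = -40), interval = 10, nFrames = 40)
  expect_equal(meanSpeed(moved)@meanSpeed, meanSpeed(ts)@meanSpeed,
               tolerance = 1e-9)
  a <- totalDisplacement(ts, 390)$displacement
  b <- totalDisplacement(moved, 390)$displacement
  expect_equal(b$pathLength, a$pathLength, tolerance = 1e-9)
  expect_equal(b$netDisplacement, a$netDisplacement, tolerance = 1e-9)
})

test_that("windowed mean speed lies between disjoint sub-window means", {
  ts <- simulateTracks(nCells = 6, frames = 60, dropoutRate = 0, seed = 23)
  m1 <- meanSpeed(ts, window = c(0, 300))@meanSpeed
  m2 <- meanSpeed(ts, window = c(300, 600))@meanSpeed
  mall <- meanSpeed(ts, window = c(0, 600))@meanSpeed
  expect_gte(mall, min(m1, m2) - 1e-9)
  expect_lte(mall, max(m1, m2) + 1e-9)
})

test_that("adhesion retention is the post/pre percentage", {
  expect_equal(adhesionPercent(100, 25), 25)
  expect_equal(adhesionPercent(100, 2), 2)
  expect_equal(adhesionPercent(200, 128), 64)
  expect_error(adhesionPercent(0, 5), "positive")
  flagged <- adhesionPercent(10, 12)
  expect_equal(as.numeric(flagged), 120)
  expect_identical(attr(flagged, "flag"), "post > pre")
})

test_that("fusion efficiency applies the >= 3 nuclei rule", {
  regions <- data.frame(region = 1L, cx = 50, cy = 50, a = 30, b = 10)
  inTube <- data.frame(x = c(45, 50, 55), y = 50)
  free <- data.frame(x = seq(200, 260, by = 10), y = 200)
  f <- new("FusionField", nuclei = rbind(inTube, free), regions = regions,
           fieldSize = c(300, 300))
  fe <- fusionEfficiency(f)
  expect_equal(fe$fusionIndex, 30)
  expect_equal(fe$classification$kind, "myotube")

  # a 2-nucleus region is a myocyte: denominator only
  f2 <- new("FusionField", nuclei = rbind(inTube[1:2, ],
                                          data.frame(x = seq(10, 80, by = 10),
                                                     y = 250)),
            regions = regions, fieldSize = c(300, 300))
  fe2 <- fusionEfficiency(f2)
  expect_equal(fe2$fusionIndex, 0)
  expect_equal(fe2$classification$kind, "myocyte")
})

test_that("boundary nuclei count as inside their region", {
  regions <- data.frame(region = 1L, cx = 50, cy = 50, a = 20, b = 10)
  nuclei <- data.frame(x = c(70, 50, 50, 200), y = c(50, 60, 50, 200))
  f <- new("FusionField", nuclei = nuclei, regions = regions,
           fieldSize = c(300, 300))
  fe <- fusionEfficiency(f)
  expect_equal(fe$membership, c(1, 1, 1, 0))
  expect_equal(fe$fusionIndex, 75)
})

test_that("pipeline fusion index equals generator truth across random fields", {
  for (s in 1:20) {
    f <- simulateFusionField(seed = s)
    fe <- fusionEfficiency(f)
    expect_identical(fe$membership, groundTruth(f)$membership)
    expect_equal(fe$fusionIndex, groundTruth(f)$fusionIndex)
    # independent oracle: re-derive membership from the ellipse equation,
    # count nuclei per region, apply the >= 3 rule
    om <- oracleMembership(f@nuclei, f@regions)
    counts <- table(om[om > 0])
    tubes <- as.integer(names(counts)[counts >= 3])
    expect_equal(fe$fusionIndex, 100 * mean(om %in% tubes))
  }
})

test_that("adding nuclei moves the fusion index in the documented direction", {
  f <- simulateFusionField(nMyotubes = 3, nMyocytes = 2, nMononuclear = 15,
                           seed = 29)
  fe <- fusionEfficiency(f)
  tube <- f@regions[f@regions$region == 1, ]
  plus <- new("FusionField",
              nuclei = rbind(f@nuclei, data.frame(x = tube$cx, y = tube$cy)),
              regions = f@regions, fieldSize = f@fieldSize)
  expect_gt(fusionEfficiency(plus)$fusionIndex, fe$fusionIndex)
  bg <- c(1, 1)  # field corner, outside every region by construction margins
  minus <- new("FusionField",
               nuclei = rbind(f@nuclei, data.frame(x = bg[1], y = bg[2])),
               regions = f@regions, fieldSize = f@fieldSize)
  feMinus <- fusionEfficiency(minus)
  expect_lt(feMinus$fusionIndex, fe$fusionIndex)
  expect_gte(feMinus$fusionIndex, 0)
  expect_lte(fusionEfficiency(plus)$fusionIndex, 100)
})

test_that("the rasterized label mask agrees with analytic membership", {
  f <- simulateFusionField(nMyotubes = 2, nMyocytes = 1, nMononuclear = 5,
                           seed = 31)
  mask <- rasterizeFusionField(f, pixelSize = 0.5)
  nuc <- f@nuclei
  maskMember <- vapply(seq_len(nrow(nuc)), function(i) {
    col <- pmin(pmax(ceiling(nuc$x[i] / 0.5), 1), ncol(mask))
    row <- pmin(pmax(ceiling(nuc$y[i] / 0.5), 1), nrow(mask))
    mask[row, col]
  }, integer(1))
  analytic <- groundTruth(f)$membership
  # pixelation can flip only nuclei within half a pixel of a boundary
  agree <- mean(maskMember == analytic)
  expect_gte(agree, 0.9)
})
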