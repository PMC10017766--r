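test_that("the Sneddon prefactor responds to geometry and Poisson ratio", {
  cone <- TipModel(35, 0.5)
  expect_equal(hertzPrefactor(cone),
               (2 / pi) * tan(35 * pi / 180) / (1 - 0.25))
  pyr <- TipModel(35, 0.5, geometry = "pyramid")
  expect_equal(hertzPrefactor(pyr) / hertzPrefactor(cone),
               (pi / (2 * sqrt(2))))
  expect_error(TipModel(95), "halfAngle")
  expect_error(TipModel(35, 0.7), "poissonRatio")
})

test_that("contact detection lands within two samples of the truth", {
  fc <- simulateForceCurve(noiseSd = 0, seed = 1)
  ct <- detectContactPoint(fc)
  spacing <- median(abs(diff(fc@approach$separation)))
  expect_lt(abs(ct$contactPoint - groundTruth(fc)$contactPoint),
            2 * spacing + 1e-12)
})

test_that("a flat zero-force curve yields a no-contact error", {
  sep <- seq(3, 0, length.out = 100)
  flat <- new("ForceCurve",
              approach = data.frame(separation = sep, force = rep(0, 100)),
              retract = data.frame(separation = numeric(),
                                   force = numeric()))
  expect_error(detectContactPoint(flat), "no contact")
})

test_that("baseline tilt is removed before contact detection", {
  devs <- vapply(1:25, function(s) {
    fc <- simulateForceCurve(noiseSd = 0.05, baselineTilt = 0.2, seed = s)
    detectContactPoint(fc)$contactPoint - groundTruth(fc)$contactPoint
  }, numeric(1))
  # detection crosses after true contact by construction; it must not be
  # thrown off by the tilt
  expect_lt(median(abs(devs)), 0.25)
})

test_that("noiseless Hertz curves recover E across three decades", {
  for (E in c(1e3, 1e4, 1e5)) {
    fc <- simulateForceCurve(youngModulus = E, noiseSd = 0, seed = 1)
    m <- fitHertzSneddon(fc)
    expect_equal(youngModulus(m), E, tolerance = 1e-3)
    # oracle: closed-form inversion at the deepest sampled point
    app <- fc@approach
    deepest <- which.min(app$separation)
    delta <- groundTruth(fc)$contactPoint - app$separation[deepest]
    expect_equal(oracleHertzInvert(app$force[deepest], delta), E,
                 tolerance = 1e-6)
  }
})

test_that("fitted E is linear in force and invariant to separation shifts", {
  fc <- simulateForceCurve(youngModulus = 8e3, noiseSd = 0, seed = 2)
  m <- fitHertzSneddon(fc)
  doubled <- new("ForceCurve",
                 approach = transform(fc@approach, force = 2 * force),
                 retract = fc@retract, triggerForce = fc@triggerForce * 2,
                 speed = fc@speed, springConstant = fc@springConstant)
  m2 <- fitHertzSneddon(doubled)
  expect_equal(youngModulus(m2), 2 * youngModulus(m), tolerance = 1e-6)

  shifted <- new("ForceCurve",
                 approach = transform(fc@approach,
                                      separation = separation + 5),
                 retract = fc@retract, triggerForce = fc@triggerForce,
                 speed = fc@speed, springConstant = fc@springConstant)
  m3 <- fitHertzSneddon(shifted)
  expect_equal(m3@contactPoint, m@contactPoint + 5, tolerance = 1e-6)
  expect_equal(youngModulus(m3), youngModulus(m), tolerance = 1e-6)
})

test_that("the incompressible limit scales E by exactly (1 - nu^2)", {
  fc <- simulateForceCurve(youngModulus = 1e4, noiseSd = 0, seed = 3)
  eHalf <- youngModulus(fitHertzSneddon(fc, TipModel(35, 0.5)))
  eZero <- youngModulus(fitHertzSneddon(fc, TipModel(35, 0)))
  expect_equal(eHalf / eZero, 0.75, tolerance = 1e-9)
})

test_that("a curve with no indentation region cannot be fitted", {
  sep <- seq(5, 2, length.out = 120)
  # contact nominally at 1 um: every sample is pre-contact
  flatHertz <- new("ForceCurve",
                   approach = data.frame(separation = sep,
                                         force = rnorm(120, 0, 1e-4)),
                   retract = data.frame(separation = numeric(),
                                        force = numeric()))
  expect_error(
    fitHertzSneddon(flatHertz,
                    contact = list(contactPoint = 2,
                                   baseline = c(0, 0), noiseSd = 1e-4)),
    "fewer than 10|no contact")
})

test_that("rupture force reads the adhesion dip magnitude", {
  fc <- simulateForceCurve(adhesionDepth = 2, noiseSd = 0, seed = 4)
  # the anti-extreme-value moving average attenuates the dip by < 0.5%
  expect_equal(ruptureForce(fc), 2, tolerance = 5e-3)

  # monotone non-negative retraction -> 0
  sep <- seq(3, 0, length.out = 200)
  fc0 <- new("ForceCurve",
             approach = data.frame(separation = sep, force = pmax(1 - sep, 0)),
             retract = data.frame(separation = sep, force = pmax(1 - sep, 0)))
  expect_equal(ruptureForce(fc0), 0)
})

test_that("rupture force tracks truth within three noise SDs", {
  for (s in 1:20) {
    fc <- simulateForceCurve(adhesionDepth = 1.5, noiseSd = 0.05, seed = s)
    expect_lt(abs(ruptureForce(fc) - 1.5), 3 * 0.05)
  }
})

test_that("batch summaries aggregate mean and SD per group", {
  mk <- function(E, rf) new("MechanicsResult", youngModulus = E,
                            contactPoint = 1, fitRange = c(0, 1), rss = 0,
                            ruptureForce = rf, tip = TipModel())
  one <- afmBatchSummary(list(mk(1e4, 1)))
  expect_equal(one$meanE, 1e4)
  expect_equal(one$sdE, 0)
  two <- afmBatchSummary(list(mk(1e4, 1), mk(2e4, 3)))
  expect_equal(two$meanE, 1.5e4)
  expect_equal(two$sdE, sqrt(sum((c(1, 2) * 1e4 - 1.5e4)^2)))
  expect_equal(two$meanRupture, 2)
  grouped <- afmBatchSummary(list(mk(1e4, 1), mk(2e4, 3), mk(3e4, 2)),
                             grouping = c("wt", "wt", "mdx"))
  expect_equal(nrow(grouped), 2)
  expect_error(afmBatchSummary(list()), "no results")
})

test_that("noisy group means concentrate around the true modulus", {
  curves <- lapply(1:30, function(s)
    simulateForceCurve(youngModulus = 8e3, noiseSd = 0.3, nSamples = 600,
                       seed = s))
  res <- lapply(curves, fitHertzSneddon)
  s <- afmBatchSummary(res)
  expect_lt(abs(s$meanE - 8e3) / 8e3, 0.05)
})
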