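#' Simulate an endomysial two-channel line-scan profile
#'
#' Generates the red (laminin alpha-2) channel as two Gaussian basement-
#' membrane peaks over a constant baseline with additive Gaussian noise, and
#' the green (co-stained component) channel as a configurable fraction of the
#' BM peaks plus a constant level on the interstitial-matrix interval. The
#' full generating parameter set is stored as ground truth on the returned
#' profile, so every downstream quantity (segment points, per-region
#' abundances, stoichiometry) has a closed form.
#'
#' The green channel is
#' `green(x) = greenBmFraction * (peak1(x) + peak2(x)) + greenImLevel * 1[IM]`
#' where the IM interval is `[mu1 + 2*sigma1, mu2 - 2*sigma2]` of the true red
#' peaks, plus noise.
#'
#' @param peak1Center,peak2Center true BM peak centres, um.
#' @param peak1Sd,peak2Sd true peak SDs, um.
#' @param peak1Amplitude,peak2Amplitude true peak amplitudes, intensity.
#' @param baseline red-channel constant baseline intensity.
#' @param greenBmFraction fraction in [0, 1] of the red BM peaks reproduced in
#'   the green channel.
#' @param greenImLevel green intensity on the IM interval.
#' @param noiseSd additive Gaussian noise SD (both channels).
#' @param spacing sample spacing, um.
#' @param nSamples number of samples.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return A [LineScanProfile-class] with `truth` carrying all parameters plus
#'   the noiseless channels (`redClean`, `greenClean`).
#' @examples
#' p <- simulateLineScan(seed = 1)
#' p
#' @export
simulateLineScan <- function(peak1Center = 8, peak1Sd = 1.2,
                             peak1Amplitude = 120,
                             peak2Center = 17, peak2Sd = 1.2,
                             peak2Amplitude = 110,
                             baseline = 10,
                             greenBmFraction = 0.6, greenImLevel = 30,
                             noiseSd = 5, spacing = 0.1, nSamples = 256,
                             seed = NULL) {
  if (peak1Amplitude <= 0 || peak2Amplitude <= 0)
    stopf("peak amplitudes must be positive")
  if (peak1Sd <= 0 || peak2Sd <= 0) stopf("peak SDs must be positive")
  if (noiseSd < 0) stopf("noiseSd must be non-negative")
  if (greenBmFraction < 0 || greenBmFraction > 1)
    stopf("greenBmFraction must lie in [0, 1]")
  if (peak1Center + 2 * peak1Sd >= peak2Center - 2 * peak2Sd)
    stopf(paste("overlapping peak windows: peak1Center + 2*peak1Sd (%.3f)",
                "must fall left of peak2Center - 2*peak2Sd (%.3f)"),
          peak1Center + 2 * peak1Sd, peak2Center - 2 * peak2Sd)
  x <- seq(0, by = spacing, length.out = nSamples)
  span <- x[nSamples]
  if (peak1Center - 2 * peak1Sd < 0 || peak2Center + 2 * peak2Sd > span)
    stopf("both peaks (mean +/- 2 SD) must lie inside the sampled span [0, %.3f]",
          span)

  bm <- gaussBump(x, peak1Amplitude, peak1Center, peak1Sd) +
    gaussBump(x, peak2Amplitude, peak2Center, peak2Sd)
  redClean <- baseline + bm
  imLo <- peak1Center + 2 * peak1Sd
  imHi <- peak2Center - 2 * peak2Sd
  greenClean <- greenBmFraction * bm +
    greenImLevel * as.numeric(x >= imLo & x <= imHi)

  withSeed(seed, {
    red <- redClean + stats::rnorm(nSamples, 0, noiseSd)
    green <- greenClean + stats::rnorm(nSamples, 0, noiseSd)
  })
  truth <- list(
    peak1Center = peak1Center, peak1Sd = peak1Sd,
    peak1Amplitude = peak1Amplitude,
    peak2Center = peak2Center, peak2Sd = peak2Sd,
    peak2Amplitude = peak2Amplitude,
    baseline = baseline, greenBmFraction = greenBmFraction,
    greenImLevel = greenImLevel, noiseSd = noiseSd,
    spacing = spacing, nSamples = nSamples, seed = seed,
    redClean = redClean, greenClean = greenClean
  )
  LineScanProfile(x, pmax(red, 0), pmax(green, 0), truth = truth)
}

#' Closed-form region abundances for a synthetic line scan
#'
#' Analytic basal-subtracted areas of the generated channels over the true
#' basement-membrane windows (`mu +/- 2*sigma`) and the interstitial interval,
#' using the Gaussian error function. These are the ground-truth targets the
#' segmentation pipeline is expected to recover.
#'
#' @param truth the `truth` list of a profile from [simulateLineScan()].
#' @return A list with numeric vectors `red` and `green`, each with elements
#'   `bmLeft`, `im`, `bmRight`, `bmTotal`, and `stoichiometry`.
#' @export
linescanTruthAbundance <- function(truth) {
  gaussMass <- function(A, mu, sigma, lo, hi) {
    A * sigma * sqrt(2 * pi) / 2 *
      (pracma::erf((hi - mu) / (sigma * sqrt(2))) -
       pracma::erf((lo - mu) / (sigma * sqrt(2))))
  }
  s <- c(truth$peak1Center - 2 * truth$peak1Sd,
         truth$peak1Center + 2 * truth$peak1Sd,
         truth$peak2Center - 2 * truth$peak2Sd,
         truth$peak2Center + 2 * truth$peak2Sd)
  bmArea <- function(lo, hi) {
    gaussMass(truth$peak1Amplitude, truth$peak1Center, truth$peak1Sd, lo, hi) +
      gaussMass(truth$peak2Amplitude, truth$peak2Center, truth$peak2Sd, lo, hi)
  }
  red <- c(bmLeft = bmArea(s[1], s[2]), im = bmArea(s[2], s[3]),
           bmRight = bmArea(s[3], s[4]))
  red["bmTotal"] <- red[["bmLeft"]] + red[["bmRight"]]
  green <- truth$greenBmFraction *
    c(bmLeft = bmArea(s[1], s[2]), im = bmArea(s[2], s[3]),
      bmRight = bmArea(s[3], s[4]))
  green["im"] <- green[["im"]] + truth$greenImLevel * (s[3] - s[2])
  green["bmTotal"] <- green[["bmLeft"]] + green[["bmRight"]]
  list(red = red, green = green,
       stoichiometry = unname(green["bmTotal"] / red["bmTotal"]))
}

#' Simulate per-location peak intensities for a remodeling experiment
#'
#' Emulates the paired imaging design behind the remodeling index: a control
#' myoscaffold (no cells) and a cell-seeded myoscaffold, each measured at
#' `nLocations` endomysial locations. Per-location variability is
#' multiplicative lognormal. The noise is parameterized on the per-location
#' remodeling ratio: ratios are drawn lognormal with mean `remodelingFactor`
#' and coefficient of variation `cv`, and treated intensities are
#' `controlMean / ratio`, so the stored ratios average exactly to the factor
#' being simulated.
#'
#' @param controlMean mean control peak intensity.
#' @param remodelingFactor true remodeling ratio (>= 1); 1 means no
#'   remodeling.
#' @param cv coefficient of variation of the lognormal location noise (>= 0).
#' @param nLocations number of endomysial locations per condition (the
#'   reference imaging design uses 20 per x20 image).
#' @param seed integer seed.
#' @return A list with [IntensitySet-class] elements `control` and `treated`
#'   and a `truth` list (including the per-location `ratios`).
#' @export
simulateRemodelingField <- function(controlMean = 100, remodelingFactor = 1,
                                    cv = 0.2, nLocations = 20, seed = NULL) {
  if (cv < 0) stopf("cv must be non-negative")
  if (remodelingFactor < 1) stopf("remodelingFactor must be >= 1")
  if (nLocations < 1) stopf("nLocations must be >= 1")
  if (controlMean <= 0) stopf("controlMean must be positive")
  s2 <- log(1 + cv^2)
  withSeed(seed, {
    controlNoise <- stats::rlnorm(nLocations, -s2 / 2, sqrt(s2))
    ratios <- stats::rlnorm(nLocations, log(remodelingFactor) - s2 / 2,
                            sqrt(s2))
  })
  control <- controlMean * controlNoise
  treated <- controlMean / ratios
  list(
    control = IntensitySet(control, condition = "myoscaffold"),
    treated = IntensitySet(treated, condition = "myoscaffold + cells"),
    truth = list(controlMean = controlMean,
                 remodelingFactor = remodelingFactor, cv = cv,
                 nLocations = nLocations, seed = seed, ratios = ratios)
  )
}

#' Simulate fixed-interval cell tracks as persistent random walks
#'
#' Each cell walks with per-interval step lengths drawn
#' `Normal(speedMean, speedSd)` (truncated at zero) and a heading that turns
#' by `Normal(0, (1 - persistence) * pi)` radians each interval, so
#' `persistence = 1` gives straight-line motion and `persistence = 0` an
#' uncorrelated random walk. With probability `dropoutRate` a cell's track is
#' truncated at a random interior frame and flagged incomplete, mimicking
#' cells that leave the field of view.
#'
#' @param nCells number of cells.
#' @param frames number of frames (>= 2); 91 frames at a 10-minute interval
#'   cover the 15-hour analysis window (90 intervals).
#' @param interval imaging interval TI in minutes (default 10).
#' @param speedMean,speedSd step-length distribution, um per interval.
#' @param persistence directional persistence in [0, 1].
#' @param dropoutRate probability a track is incomplete.
#' @param fieldSize length-2 numeric; cells start uniformly in this box (um).
#' @param seed integer seed.
#' @return A [TrackSet-class]; `truth` stores the parameters and the exact
#'   per-cell step lengths actually taken (`stepLengths`).
#' @export
simulateTracks <- function(nCells = 20, frames = 91, interval = 10,
                           speedMean = 6.21, speedSd = 1.5,
                           persistence = 0.7, dropoutRate = 0.1,
                           fieldSize = c(500, 500), seed = NULL) {
  if (frames < 2) stopf("frames must be >= 2")
  if (interval <= 0) stopf("interval must be positive")
  if (persistence < 0 || persistence > 1)
    stopf("persistence must lie in [0, 1]")
  if (dropoutRate < 0 || dropoutRate > 1)
    stopf("dropoutRate must lie in [0, 1]")
  withSeed(seed, {
    rows <- vector("list", nCells)
    stepLengths <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      nFramesI <- frames
      if (dropoutRate > 0 && stats::runif(1) < dropoutRate && frames > 2)
        nFramesI <- sample(2:(frames - 1), 1)
      theta <- stats::runif(1, 0, 2 * pi)
      x <- numeric(nFramesI); y <- numeric(nFramesI)
      x[1] <- stats::runif(1, 0, fieldSize[1])
      y[1] <- stats::runif(1, 0, fieldSize[2])
      steps <- numeric(max(nFramesI - 1, 0))
      for (k in seq_len(nFramesI - 1)) {
        theta <- theta + stats::rnorm(1, 0, (1 - persistence) * pi)
        L <- max(0, stats::rnorm(1, speedMean, speedSd))
        steps[k] <- L
        x[k + 1] <- x[k] + L * cos(theta)
        y[k + 1] <- y[k] + L * sin(theta)
      }
      rows[[i]] <- data.frame(cell = sprintf("cell%03d", i),
                              frame = seq_len(nFramesI) - 1L, x = x, y = y)
      stepLengths[[i]] <- steps
    }
  })
  names(stepLengths) <- sprintf("cell%03d", seq_len(nCells))
  truth <- list(nCells = nCells, frames = frames, interval = interval,
                speedMean = speedMean, speedSd = speedSd,
                persistence = persistence, dropoutRate = dropoutRate,
                seed = seed, stepLengths = stepLengths)
  TrackSet(do.call(rbind, rows), interval = interval, nFrames = frames,
           truth = truth)
}

# uniform point inside an axis-aligned ellipse, by rejection from its bbox
runifEllipse <- function(n, cx, cy, a, b) {
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    px <- stats::runif(n, -a, a); py <- stats::runif(n, -b, b)
    ok <- (px / a)^2 + (py / b)^2 <= 1
    take <- min(sum(ok), n - got)
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      out[(got + 1):(got + take), ] <- cbind(cx + px[idx], cy + py[idx])
      got <- got + take
    }
  }
  out
}

#' Simulate a fusion-scoring field of nuclei and alpha-actinin+ regions
#'
#' Places non-overlapping axis-aligned elliptical regions representing
#' myotubes (elongated, >= 3 nuclei each) and myocytes (small, 1-2 nuclei),
#' plus free mononuclear cells in the background. Overlap is avoided by
#' bounding-box rejection with bounded retries. The exact fusion index,
#' nuclei-in-myotubes over all nuclei, is stored as ground truth.
#'
#' @param nMyotubes,nMyocytes,nMononuclear region/cell counts (>= 0).
#' @param nucleiLambda Poisson rate of extra nuclei per myotube beyond the
#'   minimum of 3 (so a myotube has `3 + Poisson(nucleiLambda)` nuclei).
#' @param fieldSize length-2 numeric, field width and height in um.
#' @param maxTries placement retries per region before giving up.
#' @param seed integer seed.
#' @return A [FusionField-class]; `truth` stores `fusionIndex` (percent),
#'   per-nucleus region membership and per-region nucleus counts.
#' @export
simulateFusionField <- function(nMyotubes = 8, nucleiLambda = 4,
                                nMyocytes = 5, nMononuclear = 40,
                                fieldSize = c(500, 500), maxTries = 2000,
                                seed = NULL) {
  if (nMyotubes < 0 || nMyocytes < 0 || nMononuclear < 0)
    stopf("all counts must be >= 0")
  withSeed(seed, {
    nRegions <- nMyotubes + nMyocytes
    regions <- data.frame(region = integer(), cx = numeric(), cy = numeric(),
                          a = numeric(), b = numeric(),
                          kind = character())
    for (i in seq_len(nRegions)) {
      isTube <- i <= nMyotubes
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        a <- if (isTube) stats::runif(1, 50, 90) else stats::runif(1, 12, 20)
        b <- if (isTube) stats::runif(1, 8, 14) else stats::runif(1, 6, 10)
        if (2 * a > fieldSize[1] || 2 * b > fieldSize[2]) next
        cx <- stats::runif(1, a, fieldSize[1] - a)
        cy <- stats::runif(1, b, fieldSize[2] - b)
        # conservative non-overlap: axis-aligned bounding boxes must not touch
        clash <- nrow(regions) > 0 &&
          any(abs(regions$cx - cx) < regions$a + a &
              abs(regions$cy - cy) < regions$b + b)
        if (!clash) {
          regions <- rbind(regions, data.frame(
            region = i, cx = cx, cy = cy, a = a, b = b,
            kind = if (isTube) "myotube" else "myocyte"))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("field %g x %g um too small to place %d non-overlapping regions",
              fieldSize[1], fieldSize[2], nRegions)
    }
    nuclei <- data.frame(x = numeric(), y = numeric())
    membership <- integer()
    regionNuclei <- integer(nRegions)
    for (i in seq_len(nRegions)) {
      r <- regions[regions$region == i, ]
      k <- if (r$kind == "myotube") 3L + stats::rpois(1, nucleiLambda)
           else sample(1:2, 1)
      pts <- runifEllipse(k, r$cx, r$cy, r$a, r$b)
      nuclei <- rbind(nuclei, data.frame(x = pts[, 1], y = pts[, 2]))
      membership <- c(membership, rep(i, k))
      regionNuclei[i] <- k
    }
    got <- 0L
    while (got < nMononuclear) {
      px <- stats::runif(1, 0, fieldSize[1])
      py <- stats::runif(1, 0, fieldSize[2])
      inside <- nrow(regions) > 0 &&
        any(((px - regions$cx) / regions$a)^2 +
            ((py - regions$cy) / regions$b)^2 <= 1)
      if (!inside) {
        nuclei <- rbind(nuclei, data.frame(x = px, y = py))
        membership <- c(membership, 0L)
        got <- got + 1L
      }
    }
  })
  nTotal <- nrow(nuclei)
  if (nTotal == 0) stopf("field contains no nuclei")
  myotubeIds <- regions$region[regions$kind == "myotube"]
  inTubes <- sum(regionNuclei[myotubeIds])
  truth <- list(
    fusionIndex = 100 * inTubes / nTotal,
    membership = membership, regionNuclei = regionNuclei,
    nMyotubes = nMyotubes, nMyocytes = nMyocytes,
    nMononuclear = nMononuclear, seed = seed
  )
  new("FusionField", nuclei = nuclei,
      regions = regions[, c("region", "cx", "cy", "a", "b")],
      fieldSize = as.numeric(fieldSize), truth = truth)
}

#' Simulate an AFM force curve with Hertzian contact and adhesion
#'
#' The approach segment follows the conical Hertz-Sneddon relation
#' `F = (2/pi) * tan(alpha) * E / (1 - nu^2) * delta^2` for indentation
#' `delta = contactPoint - separation > 0` (zero force before contact) with
#' additive Gaussian force noise, truncated where the noiseless force reaches
#' the trigger force. The retraction mirrors the approach in the contact
#' region and carries a Gaussian-shaped adhesion dip of depth `adhesionDepth`
#' just past the contact point before pull-off.
#'
#' Units: E in Pa, separations in um, forces in nN
#' (`F[nN] = 1e-3 * C * E[Pa] * delta[um]^2`).
#'
#' @param youngModulus true Young's modulus, Pa.
#' @param tipHalfAngle cone half-angle, degrees.
#' @param poissonRatio sample Poisson ratio (0.5 = incompressible limit).
#' @param contactPoint separation at contact, um.
#' @param triggerForce acquisition trigger, nN (> 0, default 3).
#' @param adhesionDepth adhesion-dip depth, nN (>= 0).
#' @param noiseSd Gaussian force-noise SD, nN.
#' @param approachSpeed probe speed, um/s (metadata, default 2).
#' @param baselineTilt slope of a linear baseline artefact, nN/um (default 0).
#' @param nSamples samples per segment (default 2000, the order of a 2 kHz
#'   capture at 2 um/s over the ~1 s approach).
#' @param preContactRange um of free travel before contact.
#' @param seed integer seed.
#' @return A [ForceCurve-class] with `truth` carrying all parameters.
#' @export
simulateForceCurve <- function(youngModulus = 10e3, tipHalfAngle = 35,
                               poissonRatio = 0.5, contactPoint = 1,
                               triggerForce = 3, adhesionDepth = 1.5,
                               noiseSd = 0.05, approachSpeed = 2,
                               baselineTilt = 0, nSamples = 2000,
                               preContactRange = 1.5, seed = NULL) {
  if (youngModulus <= 0) stopf("youngModulus must be positive")
  if (triggerForce <= 0) stopf("triggerForce must be positive")
  if (adhesionDepth < 0) stopf("adhesionDepth must be non-negative")
  if (noiseSd < 0) stopf("noiseSd must be non-negative")
  C <- hertzPrefactor(TipModel(tipHalfAngle, poissonRatio))
  deltaMax <- sqrt(triggerForce / (1e-3 * C * youngModulus))
  sMin <- contactPoint - deltaMax
  sMax <- contactPoint + preContactRange
  sep <- seq(sMax, sMin, length.out = nSamples)  # acquisition order
  delta <- pmax(contactPoint - sep, 0)
  hertz <- 1e-3 * C * youngModulus * delta^2
  tilt <- baselineTilt * (sep - sMax)
  dipCenter <- contactPoint + 0.3
  dipWidth <- 0.12
  retSep <- sort(unique(c(sep, dipCenter)), decreasing = FALSE)  # pull-away order
  retDelta <- pmax(contactPoint - retSep, 0)
  retHertz <- 1e-3 * C * youngModulus * retDelta^2
  dip <- -adhesionDepth * exp(-(retSep - dipCenter)^2 / (2 * dipWidth^2)) *
    as.numeric(retSep >= contactPoint)
  retTilt <- baselineTilt * (retSep - sMax)
  withSeed(seed, {
    appForce <- hertz + tilt + stats::rnorm(length(sep), 0, noiseSd)
    retForce <- retHertz + dip + retTilt +
      stats::rnorm(length(retSep), 0, noiseSd)
  })
  truth <- list(youngModulus = youngModulus, tipHalfAngle = tipHalfAngle,
                poissonRatio = poissonRatio, contactPoint = contactPoint,
                triggerForce = triggerForce, adhesionDepth = adhesionDepth,
                noiseSd = noiseSd, approachSpeed = approachSpeed,
                baselineTilt = baselineTilt, seed = seed)
  new("ForceCurve",
      approach = data.frame(separation = sep, force = appForce),
      retract = data.frame(separation = retSep, force = retForce),
      triggerForce = triggerForce, speed = approachSpeed,
      springConstant = 0.02, truth = truth)
}
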