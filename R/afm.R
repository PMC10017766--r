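#' Hertz-Sneddon front factor for a tip model
#'
#' For a conical indenter of half-angle alpha on an elastic half-space of
#' Poisson ratio nu, `F = C * E * delta^2` with
#' `C = (2/pi) * tan(alpha) / (1 - nu^2)` (Sneddon). For a four-sided
#' pyramid the Bilodeau front factor `tan(alpha) / (sqrt(2) * (1 - nu^2))`
#' is used instead; the two geometries differ only by this constant.
#'
#' @param tip a [TipModel-class].
#' @return The prefactor `C` (units 1/Pa per nN/um^2 handled by callers).
#' @export
hertzPrefactor <- function(tip) {
  stopifnot(is(tip, "TipModel"))
  a <- tip@halfAngle * pi / 180
  base <- switch(tip@geometry,
                 cone = (2 / pi) * tan(a),
                 pyramid = tan(a) / sqrt(2))
  base / (1 - tip@poissonRatio^2)
}

#' Detect the contact point of an approach force curve
#'
#' Fits a least-squares baseline line over the first `baselineFraction` of
#' the approach (the samples farthest from the surface), then reports the
#' separation of the first sample whose baseline-corrected force exceeds
#' `k` times the baseline noise SD for `m` consecutive samples.
#'
#' @param curve a [ForceCurve-class] with a non-empty approach segment.
#' @param k noise-SD multiple for the detection threshold (default 5).
#' @param m consecutive samples required above threshold (default 5).
#' @param baselineFraction fraction of the segment used for the baseline fit
#'   (default 0.3).
#' @return A list with `contactPoint` (um), `baseline` (coefficients of the
#'   baseline line) and `noiseSd`.
#' @export
detectContactPoint <- function(curve, k = 5, m = 5, baselineFraction = 0.3) {
  stopifnot(is(curve, "ForceCurve"))
  app <- curve@approach
  if (!nrow(app)) stopf("approach segment is empty")
  app <- app[order(-app$separation), ]  # acquisition order: far to near
  n <- nrow(app)
  nb <- max(10L, floor(baselineFraction * n))
  bl <- stats::lm(force ~ separation, data = app[seq_len(nb), ])
  corrected <- app$force -
    stats::predict(bl, newdata = app["separation"])
  noiseSd <- stats::sd(stats::resid(bl))
  thr <- k * max(noiseSd, 1e-9)
  above <- corrected > thr
  hit <- NA_integer_
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= m) { hit <- i - m + 1L; break }
  }
  if (is.na(hit))
    stopf("no contact detected: baseline-corrected force never exceeds %.3g nN for %d consecutive samples",
          thr, m)
  list(contactPoint = app$separation[hit],
       baseline = stats::coef(bl), noiseSd = noiseSd)
}

#' Fit the Hertz-Sneddon model to an approach curve
#'
#' Least-squares fit of `F = C * E * delta^2` (delta = contactPoint -
#' separation) to the approach forces. The recorded approach segment is the
#' `0 < F <= triggerForce` fit range by construction, since acquisition
#' stops at the trigger. With `refineContact = TRUE` (the default) the
#' baseline line, the contact point and E are co-estimated in a single
#' nonlinear least-squares model `F = b0 + b1*s + C*E*max(cp - s, 0)^2`
#' over the whole segment: threshold-crossing contact detection is
#' systematically late on noisy curves, and a separately fitted far-field
#' baseline extrapolates its uncertainty across the contact region, either
#' of which biases E; the joint fit reaches the estimator's information
#' bound. With `FALSE` the detected contact and baseline are held fixed and
#' E has a closed-form linear solution.
#'
#' @param curve a [ForceCurve-class].
#' @param tip a [TipModel-class] (default cone, 35 degrees, nu = 0.5).
#' @param refineContact logical; co-refine the contact point (default TRUE).
#' @param contact optional result of [detectContactPoint()]; detected if
#'   missing.
#' @return A [MechanicsResult-class] (rupture force NA; see
#'   [ruptureForce()]).
#' @examples
#' fc <- simulateForceCurve(youngModulus = 1e4, noiseSd = 0, seed = 1)
#' fitHertzSneddon(fc)
#' @export
fitHertzSneddon <- function(curve, tip = TipModel(), refineContact = TRUE,
                            contact = NULL) {
  stopifnot(is(curve, "ForceCurve"), is(tip, "TipModel"))
  if (is.null(contact)) contact <- detectContactPoint(curve)
  app <- curve@approach[order(-curve@approach$separation), ]
  corrected <- app$force -
    (contact$baseline[1] + contact$baseline[2] * app$separation)
  C <- hertzPrefactor(tip)
  cp0 <- contact$contactPoint
  trig <- curve@triggerForce
  # no re-filtering on the noisy measured force: the recorded segment is the
  # trigger-bounded range, and censoring on measured F would drop the
  # highest-leverage samples asymmetrically and bias E
  if (refineContact) {
    d <- data.frame(s = app$separation, f = app$force)
    if (sum(d$s < cp0) < 10)
      stopf("fewer than 10 samples in the indentation fit range")
    fit <- try(minpack.lm::nlsLM(
      f ~ b0 + b1 * s + 1e-3 * C * E * pmax(cp - s, 0)^2,
      data = d,
      start = list(b0 = unname(contact$baseline[1]),
                   b1 = unname(contact$baseline[2]),
                   E = 1000, cp = cp0),
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error"))
      stopf("Hertz-Sneddon fit failed: %s", attr(fit, "condition")$message)
    cf <- stats::coef(fit)
    E <- cf[["E"]]; cp <- cf[["cp"]]
    rss <- sum(stats::resid(fit)^2)
    delta <- pmax(cp - d$s, 0)
  } else {
    cp <- cp0
    delta <- pmax(cp - app$separation, 0)
    sel <- delta > 0
    if (sum(sel) < 10)
      stopf("fewer than 10 samples in the indentation fit range")
    # F = (1e-3 * C * E) * delta^2 is linear in E
    E <- sum(corrected[sel] * delta[sel]^2) / (1e-3 * C * sum(delta[sel]^4))
    rss <- sum((corrected[sel] - 1e-3 * C * E * delta[sel]^2)^2)
    delta <- delta[sel]
  }
  if (!is.finite(E) || E <= 0)
    stopf("fitted Young's modulus non-positive (E = %.3g Pa, rss = %.3g)",
          E, rss)
  new("MechanicsResult", youngModulus = unname(E),
      contactPoint = unname(cp),
      fitRange = range(delta[delta > 0]),
      rss = rss, ruptureForce = NA_real_, tip = tip)
}

#' Peak rupture force of a retraction curve
#'
#' Magnitude of the deepest adhesive (negative) excursion of the
#' baseline-corrected retraction force; zero when no excursion falls below
#' the detection threshold of `k` times the baseline noise SD. The baseline
#' is a least-squares line over the `baselineFraction` of samples farthest
#' from the surface (post pull-off).
#'
#' @param curve a [ForceCurve-class] with a non-empty retract segment.
#' @param k detection threshold in baseline noise SDs (default 3).
#' @param baselineFraction fraction of far-field samples for the baseline
#'   (default 0.3).
#' @return Rupture force in nN (>= 0).
#' @export
ruptureForce <- function(curve, k = 3, baselineFraction = 0.3) {
  stopifnot(is(curve, "ForceCurve"))
  ret <- curve@retract
  if (!nrow(ret)) stopf("retract segment is empty")
  ret <- ret[order(-ret$separation), ]  # far field first
  nb <- max(10L, floor(baselineFraction * nrow(ret)))
  base <- ret[seq_len(nb), ]
  # the adhesion dip can leak into the far field on shallow curves; reject
  # strongly negative residuals (the dip is one-sided) and refit
  for (i in 1:5) {
    bl <- stats::lm(force ~ separation, data = base)
    rs <- stats::resid(bl)
    keep <- rs > -2.5 * stats::sd(rs)
    if (all(keep) || sum(keep) < 10) break
    base <- base[keep, , drop = FALSE]
  }
  corrected <- ret$force - stats::predict(bl, newdata = ret["separation"])
  noiseSd <- stats::sd(stats::resid(bl))
  # the raw minimum of a long noisy segment carries an extreme-value bias of
  # a few noise SDs; a moving average much narrower than any physical
  # adhesion dip suppresses it without attenuating the dip depth
  w <- max(5L, round(nrow(ret) / 100))
  smoothed <- stats::filter(corrected, rep(1 / w, w), sides = 2)
  low <- min(smoothed, na.rm = TRUE)
  if (low < -k * max(noiseSd / sqrt(w), 1e-9)) abs(low) else 0
}

#' Analyze one force curve end to end
#'
#' Contact detection, Hertz-Sneddon modulus fit on the approach, and rupture
#' force on the retraction, in one call.
#'
#' @inheritParams fitHertzSneddon
#' @return A [MechanicsResult-class] with the rupture force filled in.
#' @export
analyzeForceCurve <- function(curve, tip = TipModel(),
                              refineContact = TRUE) {
  res <- fitHertzSneddon(curve, tip, refineContact)
  rf <- if (nrow(curve@retract)) ruptureForce(curve) else NA_real_
  new("MechanicsResult", youngModulus = res@youngModulus,
      contactPoint = res@contactPoint, fitRange = res@fitRange,
      rss = res@rss, ruptureForce = rf, tip = tip)
}

#' Group summary of mechanics results
#'
#' Mean +/- SD of Young's modulus and rupture force per group. Aggregation
#' is per curve within each group; when curves come from multiple samples,
#' pass per-sample means as the results to aggregate per sample first.
#'
#' @param results list of [MechanicsResult-class] objects.
#' @param grouping character or factor, one group label per result.
#' @return A data.frame with columns `group`, `n`, `meanE`, `sdE` (Pa),
#'   `meanRupture`, `sdRupture` (nN).
#' @export
afmBatchSummary <- function(results, grouping = rep("all", length(results))) {
  if (!length(results)) stopf("no results to summarize")
  if (length(grouping) != length(results))
    stopf("grouping must have one label per result")
  E <- vapply(results, youngModulus, numeric(1))
  R <- vapply(results, ruptureForceValue, numeric(1))
  g <- as.character(grouping)
  out <- lapply(split(seq_along(results), g), function(idx) {
    if (!length(idx)) stopf("empty group")
    data.frame(group = g[idx[1]], n = length(idx),
               meanE = mean(E[idx]),
               sdE = if (length(idx) > 1) stats::sd(E[idx]) else 0,
               meanRupture = mean(R[idx], na.rm = TRUE),
               sdRupture = if (length(idx) > 1)
                 stats::sd(R[idx], na.rm = TRUE) else 0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
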