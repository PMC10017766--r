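#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' LineScanProfile: a two-channel endomysial intensity trace
#'
#' Holds one fluorescence line scan drawn across an endomysial span: a strictly
#' increasing position axis (micrometres) and two intensity channels. By
#' convention the red channel carries the basement-membrane marker (laminin
#' alpha-2) whose two peaks define the segmentation, and the green channel
#' carries the co-stained ECM component that is quantified on the red-derived
#' segment points.
#'
#' @slot position numeric, micrometres, strictly increasing, roughly uniform.
#' @slot red numeric, non-negative intensities, same length as position.
#' @slot green numeric, non-negative intensities, same length as position.
#' @slot truth list of generator ground-truth parameters when the profile is
#'   synthetic (see [simulateLineScan()]); `NULL` for measured data.
#' @slot flags character vector of processing flags accumulated by the
#'   pipeline (e.g. `"constant-channel"` after basal scaling of a flat trace).
#'
#' @seealso [LineScanProfile()], [analyzeLineScan()]
#' @export
setClass("LineScanProfile",
  representation(
    position = "numeric",
    red      = "numeric",
    green    = "numeric",
    truth    = "listOrNULL",
    flags    = "character"
  ),
  prototype(truth = NULL, flags = character())
)

setValidity("LineScanProfile", function(object) {
  msg <- character()
  n <- length(object@position)
  if (n < 32L)
    msg <- c(msg, "a line scan needs at least 32 samples")
  if (length(object@red) != n || length(object@green) != n)
    msg <- c(msg, "red and green must have the same length as position")
  if (anyNA(object@position) || anyNA(object@red) || anyNA(object@green))
    msg <- c(msg, "missing values are not allowed")
  else {
    if (any(diff(object@position) <= 0))
      msg <- c(msg, "position must be strictly increasing")
    if (any(object@red < 0) || any(object@green < 0))
      msg <- c(msg, "intensities must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LineScanProfile
#'
#' @param position numeric vector of positions in micrometres.
#' @param red,green numeric intensity vectors, same length as `position`.
#' @param truth optional list of generator ground truth.
#' @param flags optional character vector of processing flags.
#' @return A [LineScanProfile-class] object.
#' @examples
#' x <- seq(0, 25, by = 0.1)
#' p <- LineScanProfile(x, red = exp(-(x - 8)^2) + exp(-(x - 17)^2),
#'                      green = rep(0.1, length(x)))
#' @export
LineScanProfile <- function(position, red, green, truth = NULL,
                            flags = character()) {
  new("LineScanProfile", position = as.numeric(position),
      red = as.numeric(red), green = as.numeric(green),
      truth = truth, flags = flags)
}

#' GaussianPeakFit: a fitted single or double Gaussian peak model
#'
#' Result of fitting one basement-membrane peak with a single (`gauss1`) or
#' double (`gauss2`) Gaussian, selected by BIC. For a double model the
#' effective mean and SD are the first and second moments of the mixture
#' density implied by the components (weights proportional to amplitude times
#' SD, i.e. to component area).
#'
#' @slot modelOrder integer, 1 or 2.
#' @slot amplitude,mean,sd numeric vectors of per-component parameters
#'   (length `modelOrder`), intensities / micrometres.
#' @slot effectiveMean,effectiveSd numeric scalars, micrometres; feed the
#'   mean +/- 2 SD segment points.
#' @slot rss residual sum of squares of the selected fit.
#' @slot selectionScore BIC(gauss1) - BIC(gauss2); values above the selection
#'   threshold favour the double model.
#' @export
setClass("GaussianPeakFit",
  representation(
    modelOrder     = "integer",
    amplitude      = "numeric",
    mean           = "numeric",
    sd             = "numeric",
    effectiveMean  = "numeric",
    effectiveSd    = "numeric",
    rss            = "numeric",
    selectionScore = "numeric"
  )
)

setValidity("GaussianPeakFit", function(object) {
  msg <- character()
  k <- object@modelOrder
  if (!k %in% c(1L, 2L)) msg <- c(msg, "modelOrder must be 1 or 2")
  if (length(object@amplitude) != k || length(object@mean) != k ||
      length(object@sd) != k)
    msg <- c(msg, "component parameter vectors must have length modelOrder")
  if (any(object@sd <= 0)) msg <- c(msg, "component SDs must be positive")
  if (object@effectiveSd <= 0) msg <- c(msg, "effectiveSd must be positive")
  if (length(msg)) msg else TRUE
})

#' SegmentPoints: the four positions bounding BM and IM regions
#'
#' The four segment points derived from the left and right basement-membrane
#' peak fits: `s1 = mu_L - 2*sigma_L`, `s2 = mu_L + 2*sigma_L`,
#' `s3 = mu_R - 2*sigma_R`, `s4 = mu_R + 2*sigma_R` (effective parameters).
#' BM regions are `[s1,s2]` and `[s3,s4]`; the IM region is `[s2,s3]`. When
#' the two windows overlap, the midpoint of the overlap is assigned to both
#' `s2` and `s3` and the result is flagged as having no distinct IM.
#'
#' @slot s1,s2,s3,s4 numeric positions in micrometres, `s1 < s2 <= s3 < s4`.
#' @slot noDistinctIM logical; `TRUE` when the BM windows overlapped.
#' @export
setClass("SegmentPoints",
  representation(s1 = "numeric", s2 = "numeric", s3 = "numeric",
                 s4 = "numeric", noDistinctIM = "logical"),
  prototype(noDistinctIM = FALSE)
)

setValidity("SegmentPoints", function(object) {
  if (!(object@s1 < object@s2 && object@s2 <= object@s3 &&
        object@s3 < object@s4))
    "segment points must satisfy s1 < s2 <= s3 < s4"
  else TRUE
})

#' RegionAbundance: per-region area-under-curve abundances
#'
#' Trapezoidal integrals of one basal-scaled channel over the left BM, IM and
#' right BM regions, in intensity-times-micrometre units.
#'
#' @slot bmLeft,im,bmRight numeric, intensity * um.
#' @slot bmTotal numeric, `bmLeft + bmRight`.
#' @slot peakBmIntensity numeric, channel maximum within the two BM windows.
#' @export
setClass("RegionAbundance",
  representation(bmLeft = "numeric", im = "numeric", bmRight = "numeric",
                 bmTotal = "numeric", peakBmIntensity = "numeric")
)

setValidity("RegionAbundance", function(object) {
  msg <- character()
  if (any(c(object@bmLeft, object@im, object@bmRight) < -1e-9))
    msg <- c(msg, "abundances must be non-negative")
  if (abs(object@bmTotal - (object@bmLeft + object@bmRight)) >
      1e-9 * max(1, abs(object@bmTotal)))
    msg <- c(msg, "bmTotal must equal bmLeft + bmRight")
  if (length(msg)) msg else TRUE
})

#' SegmentationResult: full output of one line-scan analysis
#'
#' @slot profile the basal-scaled, smoothed [LineScanProfile-class] the
#'   segmentation operated on (all intermediates retained for audit).
#' @slot leftFit,rightFit [GaussianPeakFit-class] for each BM peak.
#' @slot points [SegmentPoints-class].
#' @slot redAbundance,greenAbundance [RegionAbundance-class]; the green
#'   abundances are computed on the red-derived segment points.
#' @slot stoichiometry numeric; green BM abundance over red BM abundance.
#' @slot parameters list of the algorithm parameters used, for provenance.
#' @export
setClass("SegmentationResult",
  representation(
    profile        = "LineScanProfile",
    leftFit        = "GaussianPeakFit",
    rightFit       = "GaussianPeakFit",
    points         = "SegmentPoints",
    redAbundance   = "RegionAbundance",
    greenAbundance = "RegionAbundance",
    stoichiometry  = "numeric",
    parameters     = "list"
  )
)

#' IntensitySet: per-location peak intensities for one condition
#'
#' @slot condition character label, e.g. `"myoscaffold"` (control) or
#'   `"myoscaffold + cells"` (treated).
#' @slot locationId character or integer-like location labels.
#' @slot peakIntensity numeric, positive, one value per endomysial location.
#' @export
setClass("IntensitySet",
  representation(condition = "character", locationId = "character",
                 peakIntensity = "numeric")
)

setValidity("IntensitySet", function(object) {
  msg <- character()
  n <- length(object@peakIntensity)
  if (n < 1L) msg <- c(msg, "at least one location is required")
  if (length(object@locationId) != n)
    msg <- c(msg, "locationId and peakIntensity lengths differ")
  if (anyNA(object@peakIntensity) || any(!is.finite(object@peakIntensity)) ||
      any(object@peakIntensity <= 0))
    msg <- c(msg, "peak intensities must be finite and positive")
  if (length(msg)) msg else TRUE
})

#' Construct an IntensitySet
#' @param peakIntensity numeric vector of positive per-location intensities.
#' @param condition single character condition label.
#' @param locationId optional location labels; defaults to `loc1, loc2, ...`.
#' @return An [IntensitySet-class].
#' @export
IntensitySet <- function(peakIntensity,
                         condition = "myoscaffold",
                         locationId = NULL) {
  if (is.null(locationId))
    locationId <- paste0("loc", seq_along(peakIntensity))
  new("IntensitySet", condition = condition,
      locationId = as.character(locationId),
      peakIntensity = as.numeric(peakIntensity))
}

#' RemodelingIndexResult: per-location remodeling indices and summary
#'
#' @slot ri numeric vector, one remodeling index per treated location.
#' @slot meanRI,sdRI numeric summary over locations (mean +/- SD).
#' @slot nLocations integer.
#' @slot orientation character, `"control/treated"` or `"treated/control"`.
#' @export
setClass("RemodelingIndexResult",
  representation(ri = "numeric", meanRI = "numeric", sdRI = "numeric",
                 nLocations = "integer", orientation = "character")
)

#' TrackSet: fixed-interval cell trajectories
#'
#' Cell tracks sampled at a fixed imaging interval (TI, default 10 minutes).
#' Stored long-form: one row per observed (cell, frame) pair.
#'
#' @slot tracks data.frame with columns `cell` (character), `frame`
#'   (integer, 0-based, strictly increasing within cell), `x`, `y`
#'   (micrometres).
#' @slot interval numeric, minutes per frame step.
#' @slot nFrames integer, number of frames in the analysis window; a track is
#'   complete when observed in every frame `0 .. nFrames - 1`.
#' @slot complete named logical, per-cell completeness flags.
#' @slot truth list of generator ground truth for synthetic tracks, else NULL.
#' @export
setClass("TrackSet",
  representation(tracks = "data.frame", interval = "numeric",
                 nFrames = "integer", complete = "logical",
                 truth = "listOrNULL"),
  prototype(truth = NULL)
)

setValidity("TrackSet", function(object) {
  msg <- character()
  tr <- object@tracks
  need <- c("cell", "frame", "x", "y")
  if (!all(need %in% names(tr)))
    msg <- c(msg, "tracks needs columns cell, frame, x, y")
  else {
    if (anyNA(tr$x) || anyNA(tr$y) || any(!is.finite(tr$x)) ||
        any(!is.finite(tr$y)))
      msg <- c(msg, "positions must be finite")
    bad <- vapply(split(tr$frame, tr$cell),
                  function(f) any(diff(f) <= 0), logical(1))
    if (any(bad))
      msg <- c(msg, "frames must be strictly increasing within each cell")
  }
  if (object@interval <= 0) msg <- c(msg, "interval must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a TrackSet from a long-form data frame
#'
#' @param tracks data.frame with columns `cell`, `frame`, `x`, `y`.
#' @param interval minutes per frame (default 10, the imaging TI).
#' @param nFrames analysis-window length in frames; defaults to
#'   `max(frame) + 1`.
#' @param truth optional generator ground truth.
#' @return A [TrackSet-class]; per-cell completeness flags are computed.
#' @export
TrackSet <- function(tracks, interval = 10, nFrames = NULL, truth = NULL) {
  tracks <- as.data.frame(tracks)
  tracks$cell <- as.character(tracks$cell)
  tracks$frame <- as.integer(tracks$frame)
  tracks <- tracks[order(tracks$cell, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  if (is.null(nFrames)) nFrames <- max(tracks$frame) + 1L
  nFrames <- as.integer(nFrames)
  complete <- vapply(split(tracks$frame, tracks$cell), function(f)
    length(f) == nFrames && identical(range(f), c(0L, nFrames - 1L)),
    logical(1))
  new("TrackSet", tracks = tracks, interval = as.numeric(interval),
      nFrames = as.integer(nFrames), complete = complete, truth = truth)
}

#' MotilitySummary: group-level motility statistics
#'
#' @slot perCell data.frame with per-cell mean speed (um/TI), number of
#'   intervals, path length and net displacement (um) and completeness.
#' @slot meanSpeed,sdSpeed numeric, group mean +/- SD of per-cell mean speeds.
#' @slot interval numeric, minutes per frame.
#' @export
setClass("MotilitySummary",
  representation(perCell = "data.frame", meanSpeed = "numeric",
                 sdSpeed = "numeric", interval = "numeric")
)

#' FusionField: nuclei and alpha-actinin-positive regions
#'
#' A field of view for fusion-efficiency scoring: nucleus centroids plus
#' labeled alpha-actinin-positive regions, modelled as axis-aligned ellipses.
#' Regions with >= 3 member nuclei are myotubes; regions with 1-2 nuclei are
#' myocytes whose nuclei count only in the denominator.
#'
#' @slot nuclei data.frame with columns `x`, `y` (micrometres).
#' @slot regions data.frame with columns `region` (integer label), `cx`,
#'   `cy` (centre), `a`, `b` (semi-axes, micrometres).
#' @slot fieldSize numeric length-2, field width and height in micrometres.
#' @slot truth list with the generator's exact fusion index for synthetic
#'   fields, else NULL.
#' @export
setClass("FusionField",
  representation(nuclei = "data.frame", regions = "data.frame",
                 fieldSize = "numeric", truth = "listOrNULL"),
  prototype(truth = NULL)
)

setValidity("FusionField", function(object) {
  msg <- character()
  if (!all(c("x", "y") %in% names(object@nuclei)))
    msg <- c(msg, "nuclei needs columns x, y")
  if (nrow(object@regions) &&
      !all(c("region", "cx", "cy", "a", "b") %in% names(object@regions)))
    msg <- c(msg, "regions needs columns region, cx, cy, a, b")
  if (nrow(object@regions) &&
      (any(object@regions$a <= 0) || any(object@regions$b <= 0)))
    msg <- c(msg, "ellipse semi-axes must be positive")
  if (length(msg)) msg else TRUE
})

#' ForceCurve: one AFM approach/retract force-separation record
#'
#' @slot approach data.frame with columns `separation` (um, decreasing toward
#'   and past contact in acquisition order) and `force` (nN).
#' @slot retract data.frame, same columns, retraction segment.
#' @slot triggerForce numeric, nN (acquisition trigger, default 3).
#' @slot speed numeric, um/s approach/retract speed (default 2).
#' @slot springConstant numeric, N/m probe spring constant.
#' @slot truth list of generator ground truth for synthetic curves, else NULL.
#' @export
setClass("ForceCurve",
  representation(approach = "data.frame", retract = "data.frame",
                 triggerForce = "numeric", speed = "numeric",
                 springConstant = "numeric", truth = "listOrNULL"),
  prototype(truth = NULL, triggerForce = 3, speed = 2, springConstant = 0.02)
)

setValidity("ForceCurve", function(object) {
  msg <- character()
  for (seg in c("approach", "retract")) {
    d <- slot(object, seg)
    if (!nrow(d)) next
    if (!all(c("separation", "force") %in% names(d)))
      msg <- c(msg, sprintf("%s needs columns separation, force", seg))
    else {
      if (nrow(d) < 50L)
        msg <- c(msg, sprintf("%s segment needs >= 50 samples", seg))
      if (any(!is.finite(d$force)))
        msg <- c(msg, sprintf("%s forces must be finite", seg))
    }
  }
  if (length(msg)) msg else TRUE
})

#' TipModel: indenter geometry for the Hertz-Sneddon relation
#'
#' The pyramidal probe is modelled as an equivalent cone of half-angle
#' `halfAngle`; the conical Sneddon relation is
#' `F = (2/pi) * tan(alpha) * E / (1 - nu^2) * delta^2`. A four-sided-pyramid
#' front factor (`geometry = "pyramid"`, factor `tan(alpha)/sqrt(2)` after
#' Bilodeau) is selectable because vendor conventions differ by this constant.
#'
#' @slot geometry character, `"cone"` or `"pyramid"`.
#' @slot halfAngle numeric, degrees, in (0, 90).
#' @slot poissonRatio numeric in [0, 0.5]; 0.5 is the incompressible limit.
#' @export
setClass("TipModel",
  representation(geometry = "character", halfAngle = "numeric",
                 poissonRatio = "numeric"),
  prototype(geometry = "cone", halfAngle = 35, poissonRatio = 0.5)
)

setValidity("TipModel", function(object) {
  msg <- character()
  if (!object@geometry %in% c("cone", "pyramid"))
    msg <- c(msg, "geometry must be 'cone' or 'pyramid'")
  if (object@halfAngle <= 0 || object@halfAngle >= 90)
    msg <- c(msg, "halfAngle must be in (0, 90) degrees")
  if (object@poissonRatio < 0 || object@poissonRatio > 0.5)
    msg <- c(msg, "poissonRatio must be in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Construct a TipModel
#' @param halfAngle cone half-angle in degrees (default 35).
#' @param poissonRatio sample Poisson ratio (default 0.5, incompressible).
#' @param geometry `"cone"` (Sneddon) or `"pyramid"` (Bilodeau front factor).
#' @return A [TipModel-class].
#' @export
TipModel <- function(halfAngle = 35, poissonRatio = 0.5, geometry = "cone") {
  new("TipModel", geometry = geometry, halfAngle = halfAngle,
      poissonRatio = poissonRatio)
}

#' MechanicsResult: Young's modulus and rupture force for one curve
#'
#' @slot youngModulus numeric, Pa.
#' @slot contactPoint numeric, um (separation at contact).
#' @slot fitRange numeric length-2, indentation interval (um) used in the fit.
#' @slot rss numeric, residual sum of squares of the Hertz fit (nN^2).
#' @slot ruptureForce numeric, nN, >= 0; NA when no retraction was analyzed.
#' @slot tip the [TipModel-class] used.
#' @export
setClass("MechanicsResult",
  representation(youngModulus = "numeric", contactPoint = "numeric",
                 fitRange = "numeric", rss = "numeric",
                 ruptureForce = "numeric", tip = "TipModel")
)

setValidity("MechanicsResult", function(object) {
  msg <- character()
  if (length(object@youngModulus) && !is.na(object@youngModulus) &&
      object@youngModulus <= 0)
    msg <- c(msg, "youngModulus must be positive")
  if (length(object@ruptureForce) && !is.na(object@ruptureForce) &&
      object@ruptureForce < 0)
    msg <- c(msg, "ruptureForce must be non-negative")
  if (length(msg)) msg else TRUE
})
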