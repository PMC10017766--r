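#' Accessors for ecmscan classes
#'
#' Small accessor generics so user code never reaches into slots directly.
#'
#' @param object an ecmscan S4 object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scanPosition", function(object) standardGeneric("scanPosition"))
#' @rdname accessors
#' @export
setGeneric("redChannel", function(object) standardGeneric("redChannel"))
#' @rdname accessors
#' @export
setGeneric("greenChannel", function(object) standardGeneric("greenChannel"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("scanFlags", function(object) standardGeneric("scanFlags"))
#' @rdname accessors
#' @export
setGeneric("segmentValues", function(object) standardGeneric("segmentValues"))
#' @rdname accessors
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("peakIntensities", function(object) standardGeneric("peakIntensities"))
#' @rdname accessors
#' @export
setGeneric("trackData", function(object) standardGeneric("trackData"))
#' @rdname accessors
#' @export
setGeneric("isComplete", function(object) standardGeneric("isComplete"))
#' @rdname accessors
#' @export
setGeneric("youngModulus", function(object) standardGeneric("youngModulus"))
#' @rdname accessors
#' @export
setGeneric("ruptureForceValue", function(object) standardGeneric("ruptureForceValue"))

setMethod("scanPosition", "LineScanProfile", function(object) object@position)
setMethod("redChannel", "LineScanProfile", function(object) object@red)
setMethod("greenChannel", "LineScanProfile", function(object) object@green)
setMethod("groundTruth", "LineScanProfile", function(object) object@truth)
setMethod("groundTruth", "TrackSet", function(object) object@truth)
setMethod("groundTruth", "FusionField", function(object) object@truth)
setMethod("groundTruth", "ForceCurve", function(object) object@truth)
setMethod("scanFlags", "LineScanProfile", function(object) object@flags)

setMethod("segmentValues", "SegmentPoints", function(object)
  c(s1 = object@s1, s2 = object@s2, s3 = object@s3, s4 = object@s4))
setMethod("segmentValues", "SegmentationResult", function(object)
  segmentValues(object@points))

setMethod("abundances", "RegionAbundance", function(object)
  c(bmLeft = object@bmLeft, im = object@im, bmRight = object@bmRight,
    bmTotal = object@bmTotal, peakBmIntensity = object@peakBmIntensity))
setMethod("abundances", "SegmentationResult", function(object)
  list(red = abundances(object@redAbundance),
       green = abundances(object@greenAbundance),
       stoichiometry = object@stoichiometry))

setMethod("peakIntensities", "IntensitySet", function(object)
  stats::setNames(object@peakIntensity, object@locationId))

setMethod("trackData", "TrackSet", function(object) object@tracks)
setMethod("isComplete", "TrackSet", function(object) object@complete)

setMethod("youngModulus", "MechanicsResult", function(object)
  object@youngModulus)
setMethod("ruptureForceValue", "MechanicsResult", function(object)
  object@ruptureForce)

setMethod("show", "LineScanProfile", function(object) {
  n <- length(object@position)
  cat(sprintf(
    "LineScanProfile: %d samples over [%.2f, %.2f] um (spacing ~%.3g um)\n",
    n, object@position[1], object@position[n],
    stats::median(diff(object@position))))
  cat(sprintf("  red:   max %.4g   green: max %.4g\n",
              max(object@red), max(object@green)))
  if (!is.null(object@truth)) cat("  synthetic (ground truth attached)\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "GaussianPeakFit", function(object) {
  cat(sprintf("GaussianPeakFit (gauss%d): effective mean %.3f um, sd %.3f um\n",
              object@modelOrder, object@effectiveMean, object@effectiveSd))
  cat(sprintf("  rss %.4g, BIC score (gauss1 - gauss2) %.2f\n",
              object@rss, object@selectionScore))
  invisible(NULL)
})

setMethod("show", "SegmentPoints", function(object) {
  cat(sprintf("SegmentPoints: s1=%.3f s2=%.3f s3=%.3f s4=%.3f um%s\n",
              object@s1, object@s2, object@s3, object@s4,
              if (object@noDistinctIM) "  [no distinct IM]" else ""))
  invisible(NULL)
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult\n")
  show(object@points)
  r <- abundances(object@redAbundance)
  g <- abundances(object@greenAbundance)
  cat(sprintf("  red   BM %.4g I*um, IM %.4g I*um\n", r[["bmTotal"]], r[["im"]]))
  cat(sprintf("  green BM %.4g I*um, IM %.4g I*um\n", g[["bmTotal"]], g[["im"]]))
  cat(sprintf("  stoichiometry (green/red BM): %.4g\n", object@stoichiometry))
  invisible(NULL)
})

setMethod("show", "IntensitySet", function(object) {
  cat(sprintf("IntensitySet '%s': %d locations, mean peak intensity %.4g\n",
              object@condition, length(object@peakIntensity),
              mean(object@peakIntensity)))
  invisible(NULL)
})

setMethod("show", "RemodelingIndexResult", function(object) {
  cat(sprintf("RemodelingIndexResult (%s): RI = %.3g +/- %.3g (n = %d)\n",
              object@orientation, object@meanRI, object@sdRI,
              object@nLocations))
  invisible(NULL)
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d cells, %d frames at TI = %g min (%d complete)\n",
              length(unique(object@tracks$cell)), object@nFrames,
              object@interval, sum(object@complete)))
  invisible(NULL)
})

setMethod("show", "MotilitySummary", function(object) {
  cat(sprintf("MotilitySummary: mean speed %.3g +/- %.3g um/TI (%d cells)\n",
              object@meanSpeed, object@sdSpeed, nrow(object@perCell)))
  invisible(NULL)
})

setMethod("show", "FusionField", function(object) {
  cat(sprintf("FusionField: %d nuclei, %d regions in %g x %g um field\n",
              nrow(object@nuclei), nrow(object@regions),
              object@fieldSize[1], object@fieldSize[2]))
  if (!is.null(object@truth))
    cat(sprintf("  synthetic (true fusion index %.4g%%)\n",
                object@truth$fusionIndex))
  invisible(NULL)
})

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf(
    "ForceCurve: approach %d pts, retract %d pts; trigger %g nN, %g um/s\n",
    nrow(object@approach), nrow(object@retract), object@triggerForce,
    object@speed))
  if (!is.null(object@truth))
    cat(sprintf("  synthetic (E = %.4g Pa)\n", object@truth$youngModulus))
  invisible(NULL)
})

setMethod("show", "TipModel", function(object) {
  cat(sprintf("TipModel: %s, half-angle %g deg, nu = %g\n",
              object@geometry, object@halfAngle, object@poissonRatio))
  invisible(NULL)
})

setMethod("show", "MechanicsResult", function(object) {
  cat(sprintf(
    "MechanicsResult: E = %.4g kPa, contact at %.3f um, rupture %.3g nN\n",
    object@youngModulus / 1000, object@contactPoint, object@ruptureForce))
  invisible(NULL)
})
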