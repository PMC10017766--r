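#' Remodeling index of a cell-seeded versus control myoscaffold
#'
#' The remodeling index (RI) compares peak ECM fluorescence in a control
#' myoscaffold (no cells) to a cell-seeded one: values near 1 indicate
#' minimal remodeling, larger values extensive degradation. Because control
#' and treated sections are different physical samples, locations cannot be
#' paired; each treated location is therefore referenced against the control
#' mean: `RI_i = mean(control) / treated_i` (orientation
#' `"control/treated"`, the default). The inverse orientation is available
#' behind a flag.
#'
#' @param control,treated [IntensitySet-class] objects of per-location peak
#'   intensities.
#' @param orientation `"control/treated"` (default) or `"treated/control"`.
#' @return A [RemodelingIndexResult-class] with per-location RIs and their
#'   mean +/- SD.
#' @examples
#' f <- simulateRemodelingField(remodelingFactor = 5.4, seed = 2)
#' remodelingIndex(f$control, f$treated)
#' @export
remodelingIndex <- function(control, treated,
                            orientation = c("control/treated",
                                            "treated/control")) {
  stopifnot(is(control, "IntensitySet"), is(treated, "IntensitySet"))
  orientation <- match.arg(orientation)
  tv <- treated@peakIntensity
  if (any(tv <= 0)) stopf("treated intensities must be positive")
  ref <- mean(control@peakIntensity)
  ri <- if (orientation == "control/treated") ref / tv else tv / ref
  new("RemodelingIndexResult", ri = unname(ri), meanRI = mean(ri),
      sdRI = if (length(ri) > 1) stats::sd(ri) else 0,
      nLocations = length(ri), orientation = orientation)
}

#' Percent reduction of fluorescence intensity over time
#'
#' `100 * (intensityT0 - intensityT) / intensityT0`; negative when the
#' intensity increased.
#'
#' @param intensityT0 intensity at the reference time (> 0).
#' @param intensityT intensity at the later time.
#' @return Percent reduction (may be negative).
#' @examples
#' percentReduction(100, 83)  # 17
#' @export
percentReduction <- function(intensityT0, intensityT) {
  if (any(intensityT0 <= 0)) stopf("intensityT0 must be positive")
  100 * (intensityT0 - intensityT) / intensityT0
}
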