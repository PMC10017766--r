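#' Per-interval speeds of tracked cells
#'
#' Speed over each observed interval is the Euclidean displacement between
#' consecutive observed positions, in micrometres per imaging interval
#' (um/TI). Gaps (missing frames) yield no speed entry: a displacement
#' spanning more than one frame step is not a per-interval speed.
#'
#' @param tracks a [TrackSet-class].
#' @return A data.frame with columns `cell`, `frame` (the interval's starting
#'   frame) and `speed` (um/TI).
#' @export
intervalSpeeds <- function(tracks) {
  stopifnot(is(tracks, "TrackSet"))
  tr <- tracks@tracks
  out <- lapply(split(tr, tr$cell), function(d) {
    if (nrow(d) < 2)
      stopf("cell '%s' has fewer than 2 frames", d$cell[1])
    df <- diff(d$frame)
    step <- sqrt(diff(d$x)^2 + diff(d$y)^2)
    keep <- df == 1L
    data.frame(cell = d$cell[1], frame = d$frame[-nrow(d)][keep],
               speed = step[keep])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group mean speed over a time window
#'
#' Per-cell mean speed over all intervals whose starting time falls in the
#' half-open window `[from, to)` (minutes), then the group mean +/- SD across
#' cells.
#'
#' @param tracks a [TrackSet-class].
#' @param window numeric length-2, window in minutes (default the full
#'   observation span).
#' @return A [MotilitySummary-class].
#' @export
meanSpeed <- function(tracks, window = NULL) {
  stopifnot(is(tracks, "TrackSet"))
  ti <- tracks@interval
  spanMax <- tracks@nFrames * ti
  if (is.null(window)) window <- c(0, spanMax)
  if (window[2] <= window[1]) stopf("empty time window")
  if (window[1] < 0 || window[1] >= spanMax)
    stopf("window start outside the observation span [0, %g) min", spanMax)
  sp <- intervalSpeeds(tracks)
  t0 <- sp$frame * ti
  sp <- sp[t0 >= window[1] & t0 < window[2], , drop = FALSE]
  if (!nrow(sp)) stopf("no intervals fall inside the window")
  perCell <- aggregate(speed ~ cell, sp, function(v)
    c(meanSpeed = mean(v), nIntervals = length(v)))
  perCell <- data.frame(cell = perCell$cell,
                        meanSpeed = perCell$speed[, "meanSpeed"],
                        nIntervals = perCell$speed[, "nIntervals"])
  perCell$complete <- tracks@complete[perCell$cell]
  new("MotilitySummary", perCell = perCell,
      meanSpeed = mean(perCell$meanSpeed),
      sdSpeed = if (nrow(perCell) > 1) stats::sd(perCell$meanSpeed) else 0,
      interval = ti)
}

#' Total displacement over the first hours of imaging
#'
#' Cumulative path length (sum of consecutive-interval Euclidean steps) over
#' the first `floor(duration / TI)` intervals, restricted to cells with
#' complete tracks over that window; incomplete tracks are reported as
#' structured exclusions, never silently dropped. Net start-to-end
#' displacement over the same window is reported as a secondary column.
#'
#' @param tracks a [TrackSet-class].
#' @param duration analysis window in minutes (default 900, i.e. 15 h; at
#'   TI = 10 min that is exactly 90 intervals).
#' @return A list with `displacement` (data.frame: `cell`, `pathLength`,
#'   `netDisplacement`, um) and `excluded` (data.frame: `cell`, `reason`).
#' @export
totalDisplacement <- function(tracks, duration = 900) {
  stopifnot(is(tracks, "TrackSet"))
  ti <- tracks@interval
  nInt <- floor(duration / ti)
  if (nInt < 1) stopf("duration shorter than one imaging interval")
  tr <- tracks@tracks
  res <- list(); exc <- list()
  for (d in split(tr, tr$cell)) {
    cell <- d$cell[1]
    need <- 0:nInt
    have <- d$frame
    if (!all(need %in% have)) {
      exc[[cell]] <- data.frame(cell = cell,
                                reason = sprintf(
                                  "incomplete track: frames %d-%d required, %d observed",
                                  0L, nInt, sum(have <= nInt)))
      next
    }
    dd <- d[d$frame <= nInt, ]
    dd <- dd[order(dd$frame), ]
    path <- sum(sqrt(diff(dd$x)^2 + diff(dd$y)^2))
    net <- sqrt((dd$x[nrow(dd)] - dd$x[1])^2 + (dd$y[nrow(dd)] - dd$y[1])^2)
    res[[cell]] <- data.frame(cell = cell, pathLength = path,
                              netDisplacement = net)
  }
  bind <- function(l, cols) if (length(l)) {
    b <- do.call(rbind, l); rownames(b) <- NULL; b
  } else stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))),
                         cols)
  list(displacement = bind(res, c("cell", "pathLength", "netDisplacement")),
       excluded = bind(exc, c("cell", "reason")))
}

#' Adhesion retention percentage
#'
#' Percentage of cells remaining adherent after dissociation, relative to
#' the adherent count before: `100 * postCount / preCount`.
#'
#' @param preCount adherent cells before dissociation (> 0).
#' @param postCount adherent cells after dissociation (>= 0).
#' @return Percent retained, with attribute `flag = "post > pre"` when more
#'   cells were counted after than before.
#' @examples
#' adhesionPercent(100, 25)  # 25
#' @export
adhesionPercent <- function(preCount, postCount) {
  if (preCount <= 0) stopf("preCount must be positive")
  if (postCount < 0) stopf("postCount must be non-negative")
  out <- 100 * postCount / preCount
  if (postCount > preCount) attr(out, "flag") <- "post > pre"
  out
}

# nucleus-in-ellipse membership; boundary counts as inside. Returns 0 for
# background, else the region label of the first containing region.
regionMembership <- function(nuclei, regions) {
  vapply(seq_len(nrow(nuclei)), function(i) {
    if (!nrow(regions)) return(0L)
    inside <- ((nuclei$x[i] - regions$cx) / regions$a)^2 +
      ((nuclei$y[i] - regions$cy) / regions$b)^2 <= 1
    if (any(inside)) as.integer(regions$region[which(inside)[1]]) else 0L
  }, integer(1))
}

#' Myotube fusion efficiency
#'
#' Classifies each alpha-actinin-positive region by its nucleus count:
#' regions holding at least 3 nuclei are myotubes, regions with 1-2 nuclei
#' are myocytes. Fusion efficiency is the percentage of all nuclei in the
#' field that reside in myotubes; myocyte nuclei count in the denominator
#' only. Nucleus-to-region membership is centroid-inside-ellipse with
#' boundary points counted as inside.
#'
#' @param field a [FusionField-class].
#' @return A list with `fusionIndex` (percent), `classification` (data.frame:
#'   `region`, `nNuclei`, `kind`), and `membership` (integer per nucleus,
#'   0 = background).
#' @examples
#' f <- simulateFusionField(seed = 3)
#' fusionEfficiency(f)$fusionIndex
#' @export
fusionEfficiency <- function(field) {
  stopifnot(is(field, "FusionField"))
  nTotal <- nrow(field@nuclei)
  if (nTotal == 0) stopf("field contains no nuclei")
  member <- regionMembership(field@nuclei, field@regions)
  counts <- table(factor(member[member > 0],
                         levels = field@regions$region))
  classification <- data.frame(
    region = as.integer(names(counts)),
    nNuclei = as.integer(counts))
  classification$kind <- ifelse(classification$nNuclei >= 3, "myotube",
                                ifelse(classification$nNuclei >= 1,
                                       "myocyte", "empty"))
  tubeRegions <- classification$region[classification$kind == "myotube"]
  inTubes <- sum(member %in% tubeRegions)
  list(fusionIndex = 100 * inTubes / nTotal,
       classification = classification, membership = member)
}

#' Rasterize a fusion field into a label mask
#'
#' Renders the elliptical regions into an integer label matrix (row = y,
#' column = x) at the given pixel size, for the image-based code path. Pixels
#' are labelled by the first region containing their centre; background is 0.
#'
#' @param field a [FusionField-class].
#' @param pixelSize pixel edge length in um (default 1).
#' @return Integer matrix of region labels.
#' @export
rasterizeFusionField <- function(field, pixelSize = 1) {
  stopifnot(is(field, "FusionField"))
  nx <- ceiling(field@fieldSize[1] / pixelSize)
  ny <- ceiling(field@fieldSize[2] / pixelSize)
  xc <- (seq_len(nx) - 0.5) * pixelSize
  yc <- (seq_len(ny) - 0.5) * pixelSize
  lab <- matrix(0L, nrow = ny, ncol = nx)
  for (i in seq_len(nrow(field@regions))) {
    r <- field@regions[i, ]
    cols <- which(abs(xc - r$cx) <= r$a)
    rows <- which(abs(yc - r$cy) <= r$b)
    for (rr in rows) {
      inside <- ((xc[cols] - r$cx) / r$a)^2 + ((yc[rr] - r$cy) / r$b)^2 <= 1
      lab[rr, cols[inside]][lab[rr, cols[inside]] == 0L] <- as.integer(r$region)
    }
  }
  lab
}
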