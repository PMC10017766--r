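# delimiter auto-detection between comma and tab on the first data line
sniffDelim <- function(path) {
  line <- readLines(path, n = 1)
  if (grepl("\t", line)) "\t" else ","
}

readDelimAuto <- function(path) {
  delim <- sniffDelim(path)
  first <- strsplit(readLines(path, n = 1), delim, fixed = TRUE)[[1]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(first))))
  utils::read.table(path, sep = delim, header = hasHeader,
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' Read a plot-profile table as a LineScanProfile
#'
#' Reads the delimited-text dialect of ImageJ "plot profile" exports:
#' comma- or tab-separated, with an `X,Y`-style header or unnamed numeric
#' columns. Two columns are read as (position, red); three as (position,
#' red, green). A calibration factor converts pixel positions to
#' micrometres.
#'
#' @param path file path.
#' @param columnMap optional named character vector mapping
#'   `position`/`red`/`green` to file column names.
#' @param calibration um per position unit (default 1; set to the pixel size
#'   when positions are in pixels).
#' @return A [LineScanProfile-class].
#' @export
readProfileCsv <- function(path, columnMap = NULL, calibration = 1) {
  d <- readDelimAuto(path)
  if (!is.null(columnMap)) {
    need <- c("position", "red", "green")
    if (!all(need %in% names(columnMap)))
      stopf("columnMap must name position, red and green columns")
    d <- d[, columnMap[need]]
  } else if (ncol(d) == 2) {
    d$green <- 0
  } else if (ncol(d) >= 3) {
    d <- d[, 1:3]
  } else stopf("profile file needs at least 2 columns")
  names(d) <- c("position", "red", "green")
  for (cn in names(d)) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stopf("non-numeric or missing %s value at data row %d of %s",
            cn, bad[1], path)
    d[[cn]] <- v
  }
  mono <- diff(d$position)
  if (any(mono <= 0))
    stopf("positions not strictly increasing at data row %d of %s",
          which(mono <= 0)[1] + 1L, path)
  LineScanProfile(d$position * calibration, d$red, d$green)
}

#' Write a LineScanProfile as CSV
#' @param profile a [LineScanProfile-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeProfileCsv <- function(profile, path) {
  stopifnot(is(profile, "LineScanProfile"))
  utils::write.csv(data.frame(position = profile@position,
                              red = profile@red, green = profile@green),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an Imaris-style track export as a TrackSet
#'
#' @param path file path (comma or tab delimited).
#' @param columnMap named character vector mapping `cell`, `time`, `x`, `y`
#'   to file column names (default the Imaris export names `TrackID`,
#'   `Time`, `PositionX`, `PositionY`).
#' @param interval imaging interval TI in minutes (default 10). `time`
#'   values are accepted either as frame indices or as minutes (multiples of
#'   the interval) and re-indexed to TI units.
#' @param nFrames analysis-window length in frames (default: inferred).
#' @return A [TrackSet-class] with completeness flags computed.
#' @export
readTracksCsv <- function(path,
                          columnMap = c(cell = "TrackID", time = "Time",
                                        x = "PositionX", y = "PositionY"),
                          interval = 10, nFrames = NULL) {
  d <- readDelimAuto(path)
  need <- c("cell", "time", "x", "y")
  if (!all(need %in% names(columnMap)))
    stopf("columnMap must name cell, time, x and y columns")
  if (!all(columnMap[need] %in% names(d)))
    stopf("missing columns in %s: %s", path,
          paste(setdiff(columnMap[need], names(d)), collapse = ", "))
  d <- d[, columnMap[need]]
  names(d) <- need
  for (cn in c("time", "x", "y")) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stopf("non-numeric or missing %s value at data row %d of %s",
            cn, bad[1], path)
    d[[cn]] <- v
  }
  tvals <- sort(unique(d$time))
  step <- if (length(tvals) > 1) min(diff(tvals)) else 1
  frame <- if (isTRUE(all.equal(step, interval))) round(d$time / interval)
           else round(d$time - min(d$time))
  TrackSet(data.frame(cell = as.character(d$cell),
                      frame = as.integer(frame), x = d$x, y = d$y),
           interval = interval, nFrames = nFrames)
}

#' Write a TrackSet as CSV (Imaris-style column names)
#' @param tracks a [TrackSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTracksCsv <- function(tracks, path) {
  stopifnot(is(tracks, "TrackSet"))
  tr <- tracks@tracks
  utils::write.csv(data.frame(TrackID = tr$cell,
                              Time = tr$frame * tracks@interval,
                              PositionX = tr$x, PositionY = tr$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column force-curve segment CSV
#'
#' Expects a `separation,force` table per segment, with optional `#`-prefixed
#' metadata header lines (`# key: value`, e.g. spring constant).
#'
#' @param approachPath,retractPath file paths; `retractPath` may be `NULL`.
#' @param triggerForce,speed acquisition metadata (defaults 3 nN, 2 um/s).
#' @return A [ForceCurve-class].
#' @export
readForceCurveCsv <- function(approachPath, retractPath = NULL,
                              triggerForce = 3, speed = 2) {
  readSeg <- function(p) {
    d <- readDelimAuto(p)
    if (ncol(d) < 2) stopf("force segment file needs 2 columns: %s", p)
    d <- d[, 1:2]
    names(d) <- c("separation", "force")
    d
  }
  app <- readSeg(approachPath)
  ret <- if (is.null(retractPath))
    data.frame(separation = numeric(), force = numeric())
  else readSeg(retractPath)
  new("ForceCurve", approach = app, retract = ret,
      triggerForce = triggerForce, speed = speed, springConstant = 0.02)
}

#' Write a ForceCurve's segments as CSV files
#' @param curve a [ForceCurve-class].
#' @param approachPath,retractPath output paths.
#' @return invisibly, the approach path.
#' @export
writeForceCurveCsv <- function(curve, approachPath, retractPath = NULL) {
  stopifnot(is(curve, "ForceCurve"))
  utils::write.csv(curve@approach, approachPath, row.names = FALSE)
  if (!is.null(retractPath) && nrow(curve@retract))
    utils::write.csv(curve@retract, retractPath, row.names = FALSE)
  invisible(approachPath)
}

#' Read a long-format intensity table into IntensitySets
#'
#' Expects columns `condition`, `location_id`, `peak_intensity` (extra
#' columns ignored).
#'
#' @param path file path.
#' @return A named list of [IntensitySet-class], one per condition.
#' @export
readIntensityCsv <- function(path) {
  d <- readDelimAuto(path)
  need <- c("condition", "location_id", "peak_intensity")
  if (!all(need %in% names(d)))
    stopf("intensity file needs columns %s", paste(need, collapse = ", "))
  lapply(split(d, d$condition), function(s)
    IntensitySet(s$peak_intensity, condition = s$condition[1],
                 locationId = s$location_id))
}

validateConfig <- function(config) {
  defaults <- list(
    seed = 1L, outputDir = "ecmscan-output",
    basalPercentile = NULL, filterOrder = 3, cutoffFraction = 0.2,
    minSeparation = NULL, halfWidth = 3.5, bicThreshold = 2,
    nProfiles = 20, remodelingFactor = 5.4, cv = 0.2, nLocations = 20,
    nCells = 20, frames = 91, interval = 10, speedMean = 6.21,
    speedSd = 1.5, persistence = 0.7, dropoutRate = 0.1,
    windowMinutes = 900,
    tipHalfAngle = 35, poissonRatio = 0.5, nCurves = 20,
    youngModulus = 10e3, adhesionDepth = 1.5, forceNoiseSd = 0.05
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("config: unknown field(s) %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!is.null(cfg$basalPercentile) &&
      (cfg$basalPercentile < 0 || cfg$basalPercentile >= 100))
    stopf("config: basalPercentile must lie in [0, 100)")
  if (cfg$cutoffFraction <= 0 || cfg$cutoffFraction >= 1)
    stopf("config: cutoffFraction must lie in (0, 1)")
  if (cfg$poissonRatio < 0 || cfg$poissonRatio > 0.5)
    stopf("config: poissonRatio must lie in [0, 0.5]")
  if (cfg$interval <= 0) stopf("config: interval must be positive")
  cfg
}

#' Run the simulate-and-analyze pipeline from a config
#'
#' Drives every stage on synthetic data: line-scan generation and
#' segmentation, remodeling-index recovery, track motility, fusion scoring
#' and force-curve mechanics. All randomness derives from `config$seed`;
#' rerunning with the same config yields byte-identical output files. Every
#' output CSV/JSON embeds the parameter set, and a plain-text log records
#' per-stage counts and exclusions (profiles rejected for lacking distinct
#' basement-membrane peaks are listed with their reason, never dropped
#' silently).
#'
#' @param config a named list, or the path of a YAML file holding one;
#'   unknown fields are rejected by validation, missing fields take
#'   documented defaults.
#' @return Invisibly, a list with the per-stage results and the paths of the
#'   files written.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validateConfig(config)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  # line scans
  seeds <- cfg$seed * 1000L + seq_len(cfg$nProfiles)
  profiles <- lapply(seeds, function(s) simulateLineScan(seed = s))
  rows <- list(); excluded <- list()
  for (i in seq_along(profiles)) {
    res <- tryCatch(
      analyzeLineScan(profiles[[i]], cfg$basalPercentile, cfg$filterOrder,
                      cfg$cutoffFraction, cfg$minSeparation, cfg$halfWidth,
                      cfg$bicThreshold),
      error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(profile = i, reason = conditionMessage(res))
      next
    }
    ab <- abundances(res)
    for (ch in c("red", "green")) {
      a <- ab[[ch]]
      rows[[length(rows) + 1L]] <- data.frame(
        profile_id = i, channel = ch,
        bm_left = a[["bmLeft"]], im = a[["im"]],
        bm_right = a[["bmRight"]], bm_total = a[["bmTotal"]],
        peak_intensity = a[["peakBmIntensity"]],
        stoichiometry = ab$stoichiometry,
        no_distinct_im = res@points@noDistinctIM)
    }
  }
  linescanTab <- do.call(rbind, rows)
  utils::write.csv(linescanTab,
                   file.path(cfg$outputDir, "linescan_abundance.csv"),
                   row.names = FALSE)
  note("linescan: %d profiles analyzed, %d excluded",
       cfg$nProfiles - length(excluded), length(excluded))
  if (length(excluded)) {
    excTab <- do.call(rbind, excluded)
    utils::write.csv(excTab, file.path(cfg$outputDir,
                                       "linescan_exclusions.csv"),
                     row.names = FALSE)
    for (j in seq_len(nrow(excTab)))
      note("linescan exclusion: profile %d: %s",
           excTab$profile[j], excTab$reason[j])
  }

  # remodeling index
  field <- simulateRemodelingField(remodelingFactor = cfg$remodelingFactor,
                                   cv = cfg$cv, nLocations = cfg$nLocations,
                                   seed = cfg$seed + 101L)
  ri <- remodelingIndex(field$control, field$treated)
  utils::write.csv(data.frame(location = seq_len(ri@nLocations),
                              ri = ri@ri),
                   file.path(cfg$outputDir, "remodeling_index.csv"),
                   row.names = FALSE)
  note("remodeling: mean RI %.4g +/- %.4g over %d locations",
       ri@meanRI, ri@sdRI, ri@nLocations)

  # motility
  tracks <- simulateTracks(nCells = cfg$nCells, frames = cfg$frames,
                           interval = cfg$interval,
                           speedMean = cfg$speedMean, speedSd = cfg$speedSd,
                           persistence = cfg$persistence,
                           dropoutRate = cfg$dropoutRate,
                           seed = cfg$seed + 202L)
  ms <- meanSpeed(tracks)
  disp <- totalDisplacement(tracks, duration = cfg$windowMinutes)
  utils::write.csv(ms@perCell, file.path(cfg$outputDir, "motility.csv"),
                   row.names = FALSE)
  utils::write.csv(disp$displacement,
                   file.path(cfg$outputDir, "displacement.csv"),
                   row.names = FALSE)
  note("motility: %d cells, mean speed %.4g um/TI; displacement computed for %d complete tracks, %d excluded",
       cfg$nCells, ms@meanSpeed, nrow(disp$displacement),
       nrow(disp$excluded))
  for (j in seq_len(nrow(disp$excluded)))
    note("displacement exclusion: %s: %s",
         disp$excluded$cell[j], disp$excluded$reason[j])

  # fusion
  fusion <- simulateFusionField(seed = cfg$seed + 303L)
  fe <- fusionEfficiency(fusion)
  utils::write.csv(fe$classification,
                   file.path(cfg$outputDir, "fusion_regions.csv"),
                   row.names = FALSE)
  note("fusion: index %.4g%% (%d regions)", fe$fusionIndex,
       nrow(fe$classification))

  # AFM
  tip <- TipModel(cfg$tipHalfAngle, cfg$poissonRatio)
  curves <- lapply(seq_len(cfg$nCurves), function(i)
    simulateForceCurve(youngModulus = cfg$youngModulus,
                       tipHalfAngle = cfg$tipHalfAngle,
                       poissonRatio = cfg$poissonRatio,
                       adhesionDepth = cfg$adhesionDepth,
                       noiseSd = cfg$forceNoiseSd,
                       seed = cfg$seed + 404L + i))
  mech <- lapply(curves, analyzeForceCurve, tip = tip)
  afmTab <- data.frame(
    curve = seq_along(mech),
    young_modulus_pa = vapply(mech, youngModulus, numeric(1)),
    rupture_force_nn = vapply(mech, ruptureForceValue, numeric(1)))
  utils::write.csv(afmTab, file.path(cfg$outputDir, "afm_mechanics.csv"),
                   row.names = FALSE)
  summaryTab <- afmBatchSummary(mech)
  note("afm: %d curves, mean E %.4g Pa, mean rupture %.4g nN",
       cfg$nCurves, summaryTab$meanE[1], summaryTab$meanRupture[1])

  bundle <- list(parameters = cfg,
                 linescan = if (is.null(linescanTab)) list() else linescanTab,
                 remodeling = list(meanRI = ri@meanRI, sdRI = ri@sdRI),
                 motility = list(meanSpeed = ms@meanSpeed,
                                 sdSpeed = ms@sdSpeed),
                 fusion = list(fusionIndex = fe$fusionIndex),
                 afm = summaryTab)
  jsonlite::write_json(bundle, file.path(cfg$outputDir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log, file.path(cfg$outputDir, "pipeline.log"))
  invisible(list(config = cfg, linescan = linescanTab, remodeling = ri,
                 motility = ms, displacement = disp, fusion = fe,
                 afm = summaryTab, log = log,
                 outputDir = cfg$outputDir))
}
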