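#' Pipeline configuration
#'
#' Bundles every threshold of the SMdM analysis chain. Defaults follow the
#' standard analysis of bacterial SMdM data: 1.5-ms lag, 600-nm pairing and
#' truncation bound, 20% pole regions, 2000-20000 displacements per cell,
#' at least 100 displacements per region fit and 10 per pixel fit, and 45
#' displacements per pixel for a quality map.
#'
#' @param dt lag time, seconds.
#' @param rMax pairing/truncation bound, nm.
#' @param pixelSizes candidate map pixel sizes, nm.
#' @param poleFraction fraction of cell length per pole.
#' @param qcMin,qcMax per-cell displacement-count bounds.
#' @param minPerRegion minimum displacements per region fit.
#' @param minPerPixel minimum displacements per pixel fit.
#' @param mapQualityMin displacements per pixel for a quality map.
#' @param clusterMaxAreaFactor Voronoi density threshold (x median area).
#' @param clusterMinPoints minimum points per retained cluster.
#' @param fixKZero fit without the linear background (for simulated input).
#' @param seed integer seed.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(dt = 1.5e-3, rMax = 600,
                           pixelSizes = c(50, 100, 150, 200),
                           poleFraction = 0.20, qcMin = 2000, qcMax = 20000,
                           minPerRegion = 100, minPerPixel = 10,
                           mapQualityMin = 45, clusterMaxAreaFactor = 2,
                           clusterMinPoints = 500, fixKZero = FALSE,
                           seed = NA_integer_) {
  obj <- new("PipelineConfig", dt = dt, rMax = rMax, pixelSizes = pixelSizes,
             poleFraction = poleFraction, qcMin = qcMin, qcMax = qcMax,
             minPerRegion = minPerRegion, minPerPixel = minPerPixel,
             mapQualityMin = mapQualityMin,
             clusterMaxAreaFactor = clusterMaxAreaFactor,
             clusterMinPoints = clusterMinPoints, fixKZero = fixKZero,
             seed = as.integer(seed))
  validObject(obj)
  obj
}

configToList <- function(config) {
  nm <- slotNames(config)
  out <- lapply(nm, function(s) slot(config, s))
  names(out) <- nm
  out
}

#' Hash of the semantic content of a configuration
#'
#' MD5 of the canonical JSON serialization; changes iff any semantic field
#' changes.
#'
#' @param config a [PipelineConfig-class].
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  json <- jsonlite::toJSON(configToList(config), auto_unbox = TRUE,
                           digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

#' Run the SMdM analysis chain on a localization stream
#'
#' Orchestrates the standard order: pair frames and peaks into
#' displacements, cluster displacement origins into cells, rotate each cell
#' onto its major axis, apply count-based QC, partition into pole/center
#' regions, and fit each region by maximum likelihood. Deterministic for a
#' fixed config and input; emits a manifest (config hash, seed, package
#' version) and a per-stage log.
#'
#' @param localizations localization data.frame (see [readLocalizations()]).
#' @param config a [PipelineConfig-class].
#' @param phase frame-pairing phase (0 or 1).
#' @return results bundle: list with `displacements`, `cells` (QC-passing
#'   [CellRecord-class]s), `rejected`, `regionFits`, `ratioSummary`,
#'   `cellTable` (per-cell summary data.frame), `manifest`, `log`.
#' @export
runPipeline <- function(localizations, config = pipelineConfig(),
                        phase = 0L) {
  logLines <- character(0)
  note <- function(...) {
    logLines <<- c(logLines, sprintf(...))
  }
  manifest <- list(package = "smdmr",
                   version = as.character(utils::packageVersion("smdmr")),
                   config = configToList(config),
                   config_hash = configHash(config),
                   seed = config@seed, status = "ok", failed_stage = NA)
  empty <- function(status) {
    manifest$status <- status
    list(displacements = NULL, cells = list(), rejected = list(),
         regionFits = list(), ratioSummary = NULL, cellTable = NULL,
         manifest = manifest, log = logLines)
  }
  if (is.null(localizations) || nrow(localizations) == 0L) {
    note("input: empty localization table")
    return(empty("empty-input"))
  }
  note("input: %d localizations in %d frames", nrow(localizations),
       length(unique(localizations$frame)))

  disp <- extractDisplacements(localizations, rMax = config@rMax,
                               phase = phase)
  note("pairing: %d displacements (rMax %g nm, phase %d)", nrow(disp),
       config@rMax, phase)
  if (nrow(disp) == 0L) return(empty("no-displacements"))

  origins <- data.frame(x_nm = disp$origin_x_nm, y_nm = disp$origin_y_nm)
  clusters <- clusterCells(origins,
                           maxAreaFactor = config@clusterMaxAreaFactor,
                           minPoints = config@clusterMinPoints)
  note("clustering: %d candidate cells", length(clusters))
  if (length(clusters) == 0L) return(empty("no-cells"))

  cells <- lapply(seq_along(clusters), function(i)
    rotateToMajorAxis(disp[clusters[[i]], , drop = FALSE], id = i))
  for (cell in cells)
    note("cell %d: %d displacements, angle %.1f deg, %.2f x %.2f um",
         cell@id, nrow(displacements(cell)),
         rotationAngle(cell) * 180 / pi, cellLength(cell), cellWidth(cell))

  kept <- qcFilter(cells, minDisp = config@qcMin, maxDisp = config@qcMax)
  rejected <- attr(kept, "rejected")
  for (cell in rejected) note("cell %d rejected: %s", cell@id, cell@qcReason)
  note("qc: %d of %d cells kept", length(kept), length(cells))
  if (length(kept) == 0L) {
    manifest$failed_stage <- "qc"
    return(empty("no-qc-pass"))
  }

  regionFits <- lapply(kept, function(cell) {
    part <- partitionRegions(cell, config@poleFraction)
    tryCatch(fitRegions(part, dt = config@dt, rMax = config@rMax,
                        minPerRegion = config@minPerRegion,
                        fixKZero = config@fixKZero),
             error = function(e) {
               note("cell %d region fits skipped: %s", cell@id,
                    conditionMessage(e))
               list(center = NULL, left = NULL, right = NULL)
             })
  })
  ratio <- poleCenterRatio(regionFits)
  note("regions: %d cells with valid pole/center ratio",
       length(ratio$ratios))

  getD <- function(fr) if (is.null(fr)) NA_real_ else dHat(fr)
  cellTable <- data.frame(
    id = vapply(kept, function(cell) cell@id, integer(1)),
    n_displacements = vapply(kept, function(cell)
      nrow(displacements(cell)), integer(1)),
    length_um = vapply(kept, cellLength, numeric(1)),
    width_um = vapply(kept, cellWidth, numeric(1)),
    qc = vapply(kept, function(cell) cell@qc, character(1)),
    d_center = vapply(regionFits, function(rf) getD(rf$center), numeric(1)),
    d_pole_left = vapply(regionFits, function(rf) getD(rf$left), numeric(1)),
    d_pole_right = vapply(regionFits, function(rf) getD(rf$right),
                          numeric(1)))

  list(displacements = disp, cells = kept, rejected = rejected,
       regionFits = regionFits, ratioSummary = ratio, cellTable = cellTable,
       manifest = manifest, log = logLines)
}
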