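# Central S4 containers. Coordinates follow two unit conventions used
# throughout the package: simulated trajectories are in micrometres, while
# localizations, displacements and map geometry are in nanometres. Diffusion
# coefficients are always reported in um^2/s.

#' Spherocylinder geometry
#'
#' An idealized rod-shaped cell: a cylinder of radius `radius` capped by two
#' hemispheres, with `totalLength` measured end to end (caps included), so the
#' cylindrical section has length `totalLength - 2 * radius`.
#'
#' @slot radius radius in micrometres (> 0).
#' @slot totalLength end-to-end length in micrometres (>= 2 * radius).
#' @export
setClass("Spherocylinder",
  representation(radius = "numeric", totalLength = "numeric"))

setValidity("Spherocylinder", function(object) {
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    return("radius must be a single positive number (um)")
  if (length(object@totalLength) != 1L || !is.finite(object@totalLength))
    return("totalLength must be a single finite number (um)")
  if (object@totalLength < 2 * object@radius)
    return("totalLength must be >= 2 * radius (caps included)")
  TRUE
})

#' Configuration of a confined Brownian-dynamics run
#'
#' @slot dSim input diffusion coefficient in um^2/s (>= 0).
#' @slot dtSim simulation step time in seconds (> 0), default 1e-4.
#' @slot totalTime total simulated time in seconds; `totalTime / dtSim` must
#'   be an integer number of steps (default 2 s, i.e. 20,000 steps).
#' @slot nParticles number of independent particles (>= 1).
#' @slot seed integer seed (NA for the current RNG state).
#' @export
setClass("SimulationConfig",
  representation(dSim = "numeric", dtSim = "numeric", totalTime = "numeric",
                 nParticles = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@dSim < 0) return("dSim must be >= 0")
  if (object@dtSim <= 0) return("dtSim must be > 0")
  if (object@totalTime <= 0) return("totalTime must be > 0")
  nsteps <- object@totalTime / object@dtSim
  if (abs(nsteps - round(nsteps)) > 1e-9 * max(1, nsteps))
    return("totalTime / dtSim must be an integer number of steps")
  if (object@nParticles < 1L) return("nParticles must be >= 1")
  TRUE
})

#' Configuration of a synthetic localization stream
#'
#' @slot locNoiseSd isotropic localization error SD in nm (>= 0).
#' @slot falsePairRate expected number of spurious detections per frame of a
#'   couple per cell, uniform over the cell footprint (>= 0).
#' @slot framesPerCell number of stroboscopic frame couples per cell.
#' @slot phase frame-pairing phase (0 or 1): couples start at even or odd
#'   frame indices.
#' @slot seed integer seed (NA for the current RNG state).
#' @export
setClass("StreamConfig",
  representation(locNoiseSd = "numeric", falsePairRate = "numeric",
                 framesPerCell = "integer", phase = "integer",
                 seed = "integer"))

setValidity("StreamConfig", function(object) {
  if (!is.finite(object@locNoiseSd) || object@locNoiseSd < 0)
    return("locNoiseSd must be finite and >= 0")
  if (!is.finite(object@falsePairRate) || object@falsePairRate < 0)
    return("falsePairRate must be finite and >= 0")
  if (object@framesPerCell < 1L) return("framesPerCell must be >= 1")
  if (!object@phase %in% c(0L, 1L)) return("phase must be 0 or 1")
  TRUE
})

#' Maximum-likelihood fit of the displacement model
#'
#' @slot dHat fitted diffusion coefficient in um^2/s.
#' @slot kHat fitted linear background slope in nm^-2 (0 when fixed).
#' @slot logLik maximized log-likelihood.
#' @slot n number of displacements used.
#' @slot converged logical convergence flag.
#' @slot kFixed logical; TRUE when the background slope was held at zero.
#' @export
setClass("FitResult",
  representation(dHat = "numeric", kHat = "numeric", logLik = "numeric",
                 n = "integer", converged = "logical", kFixed = "logical"))

setValidity("FitResult", function(object) {
  if (isTRUE(object@converged) && object@dHat <= 0)
    return("dHat must be > 0 for a converged fit")
  TRUE
})

#' Per-pixel diffusion map
#'
#' @slot d matrix of fitted diffusion coefficients (um^2/s); NA where the
#'   pixel had fewer displacements than `minPerPixel`.
#' @slot k matrix of fitted background slopes (nm^-2); NA as above.
#' @slot counts integer matrix of displacement counts per pixel.
#' @slot pixelSize pixel edge in nm (one of 50, 100, 150, 200).
#' @slot origin nm coordinates (x, y) of the lower-left corner of the first pixel.
#' @slot dt lag time in seconds.
#' @slot rMax truncation bound in nm.
#' @slot complete TRUE if every occupied pixel reached the fitting threshold.
#' @slot recommendedPixelSize suggested pixel size in nm (the next larger one
#'   when the map is incomplete, otherwise `pixelSize`).
#' @export
setClass("DiffusionMap",
  representation(d = "matrix", k = "matrix", counts = "matrix",
                 pixelSize = "numeric", origin = "numeric", dt = "numeric",
                 rMax = "numeric", complete = "logical",
                 recommendedPixelSize = "numeric"))

#' A segmented, rotated cell with its displacements
#'
#' Displacement coordinates are in the cell's own frame: rotated so that the
#' major axis is parallel to x, with the centroid of displacement origins at
#' the origin. Lengths/widths are x/y extents of the displacement origins.
#'
#' @slot id integer cell identifier.
#' @slot displacements data.frame with columns origin_x_nm, origin_y_nm,
#'   end_x_nm, end_y_nm, r_nm, couple.
#' @slot rotationAngle rotation applied, radians in (-pi/2, pi/2].
#' @slot length x extent of displacement origins, micrometres.
#' @slot width y extent of displacement origins, micrometres.
#' @slot qc "pass" or "fail".
#' @slot qcReason reason string ("" when passing).
#' @slot flags named list of caller-supplied annotations (edge truncation,
#'   adjacency, division, aggregation) used by manual-style QC.
#' @export
setClass("CellRecord",
  representation(id = "integer", displacements = "data.frame",
                 rotationAngle = "numeric", length = "numeric",
                 width = "numeric", qc = "character", qcReason = "character",
                 flags = "list"))

#' Pole/center partition of a cell's displacements
#'
#' @slot left,center,right disjoint displacement data.frames whose union is
#'   the cell's displacement set; assignment is by origin x with boundaries at
#'   x_min + poleFraction * length and x_max - poleFraction * length,
#'   boundary ties going to the poles.
#' @slot poleFraction fraction of the total length per pole (default 0.20).
#' @slot bounds nm x-coordinates (left boundary, right boundary).
#' @export
setClass("RegionPartition",
  representation(left = "data.frame", center = "data.frame",
                 right = "data.frame", poleFraction = "numeric",
                 bounds = "numeric"))

#' Power-law fit D = alpha * M^beta
#'
#' @slot alpha,beta fitted scale and exponent.
#' @slot seAlpha,seBeta standard errors from the fit covariance.
#' @slot residuals observed - fitted, per point.
#' @slot weighted TRUE when per-point SDs were used as weights.
#' @export
setClass("PowerLawFit",
  representation(alpha = "numeric", beta = "numeric", seAlpha = "numeric",
                 seBeta = "numeric", residuals = "numeric",
                 weighted = "logical"))

#' Pipeline configuration
#'
#' Aggregates every threshold of the SMdM analysis chain; see the
#' constructor [pipelineConfig()] for defaults and units.
#' @slot dt lag time (s).
#' @slot rMax pairing/truncation bound (nm).
#' @slot pixelSizes candidate map pixel sizes (nm).
#' @slot poleFraction fraction of cell length per pole region.
#' @slot qcMin,qcMax per-cell displacement-count bounds.
#' @slot minPerRegion minimum displacements per region fit.
#' @slot minPerPixel minimum displacements per pixel fit.
#' @slot mapQualityMin displacements per pixel for a quality map.
#' @slot clusterMaxAreaFactor Voronoi density threshold (x median area).
#' @slot clusterMinPoints minimum points per retained cluster.
#' @slot fixKZero TRUE to fit without the linear background term.
#' @slot seed integer seed.
#' @export
setClass("PipelineConfig",
  representation(dt = "numeric", rMax = "numeric", pixelSizes = "numeric",
                 poleFraction = "numeric", qcMin = "numeric", qcMax = "numeric",
                 minPerRegion = "numeric", minPerPixel = "numeric",
                 mapQualityMin = "numeric", clusterMaxAreaFactor = "numeric",
                 clusterMinPoints = "numeric", fixKZero = "logical",
                 seed = "integer"))

setValidity("PipelineConfig", function(object) {
  pos <- c(dt = object@dt, rMax = object@rMax,
           poleFraction = object@poleFraction, qcMin = object@qcMin,
           qcMax = object@qcMax, minPerRegion = object@minPerRegion,
           minPerPixel = object@minPerPixel,
           mapQualityMin = object@mapQualityMin,
           clusterMaxAreaFactor = object@clusterMaxAreaFactor,
           clusterMinPoints = object@clusterMinPoints)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return("all thresholds must be positive and finite")
  if (object@poleFraction >= 0.5)
    return("poleFraction must be < 0.5 (poles would overlap)")
  if (object@qcMax < object@qcMin) return("qcMax must be >= qcMin")
  TRUE
})
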