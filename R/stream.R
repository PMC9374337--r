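#' Configuration for a synthetic localization stream
#'
#' @param locNoiseSd isotropic localization error SD, nm (default 20 nm, a
#'   typical single-molecule localization precision).
#' @param falsePairRate expected spurious detections per frame of a couple
#'   per cell, uniform over the cell footprint; these produce the linear
#'   background in the displacement histogram.
#' @param framesPerCell number of stroboscopic frame couples per cell.
#' @param phase 0 or 1: couples occupy frames (0,1),(2,3),... or (1,2),(3,4),...
#' @param seed integer seed; `NA` uses the current RNG state.
#' @return a [StreamConfig-class].
#' @export
streamConfig <- function(locNoiseSd = 20, falsePairRate = 0,
                         framesPerCell = 5000L, phase = 0L,
                         seed = NA_integer_) {
  obj <- new("StreamConfig", locNoiseSd = as.numeric(locNoiseSd),
             falsePairRate = as.numeric(falsePairRate),
             framesPerCell = as.integer(framesPerCell),
             phase = as.integer(phase), seed = as.integer(seed))
  tryCatch(validObject(obj),
           error = function(e) stop("configuration error: ",
                                    conditionMessage(e), call. = FALSE))
  obj
}

#' Emulate an SMdM acquisition as a frame-indexed localization table
#'
#' For each frame couple of each cell, one emitter is placed uniformly at
#' random in the 3-D compartment, propagated for 1.5 ms of confined Brownian
#' motion (15 internal 0.1-ms steps, so boundary reflections within the lag
#' are honoured), and observed in the two frames of the couple with isotropic
#' Gaussian localization noise. Spurious detections (Poisson with mean
#' `falsePairRate` per frame per cell) are uniform over the cell's 2-D
#' footprint. Ground-truth pairing labels (`truth_id`, NA for spurious
#' detections) are retained so tests can score pairing decisions.
#'
#' @param cells list of per-cell descriptors: `list(geom = Spherocylinder,
#'   d = um^2/s)`, optionally with `center = c(x_nm, y_nm)` field-of-view
#'   offset and `poleSlowdown` (see [simulateConfinedWalk()]).
#' @param stream a [StreamConfig-class].
#' @param dt lag between the two observations, seconds.
#' @param dtSim internal simulation step, seconds.
#' @return data.frame with columns `frame`, `x_nm`, `y_nm`, `truth_id`,
#'   `cell`.
#' @export
synthesizeLocalizationStream <- function(cells, stream, dt = 1.5e-3,
                                         dtSim = 1e-4) {
  stopifnot(is(stream, "StreamConfig"))
  validObject(stream)
  subSteps <- as.integer(round(dt / dtSim))
  if (abs(dt / dtSim - subSteps) > 1e-9)
    stop("configuration error: dt must be an integer multiple of dtSim")
  withSeed(stream@seed, {
    pieces <- vector("list", length(cells))
    nextTruth <- 0L
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      geom <- cell$geom
      center <- if (!is.null(cell$center)) cell$center else c(0, 0)
      poleSlowdown <- if (!is.null(cell$poleSlowdown)) cell$poleSlowdown else 1
      m <- stream@framesPerCell
      p0 <- sampleUniformInCell(geom, m)
      stepSd <- sqrt(2 * cell$d * dtSim)
      pos <- confined_walk_cpp(p0, subSteps, stepSd, radius(geom),
                               cylinderHalfLength(geom), poleSlowdown)
      last <- pos[subSteps, ]
      p1 <- cbind(last[3 * seq_len(m) - 2], last[3 * seq_len(m) - 1])
      truth <- nextTruth + seq_len(m)
      nextTruth <- nextTruth + m
      frame0 <- stream@phase + 2L * (seq_len(m) - 1L)
      mk <- function(p, frame, truth) {
        data.frame(frame = frame,
                   x_nm = p[, 1] * 1000 + center[1] +
                     rnorm(nrow(p), 0, stream@locNoiseSd),
                   y_nm = p[, 2] * 1000 + center[2] +
                     rnorm(nrow(p), 0, stream@locNoiseSd),
                   truth_id = truth, cell = ci)
      }
      locs <- list(mk(p0[, 1:2, drop = FALSE], frame0, truth),
                   mk(p1, frame0 + 1L, truth))
      if (stream@falsePairRate > 0) {
        nf <- rpois(2L * m, stream@falsePairRate)
        tot <- sum(nf)
        if (tot > 0) {
          fp <- sampleUniformFootprint(geom, tot)
          fframes <- rep(c(rbind(frame0, frame0 + 1L)), nf)
          locs[[3]] <- data.frame(frame = fframes,
                                  x_nm = fp[, 1] * 1000 + center[1],
                                  y_nm = fp[, 2] * 1000 + center[2],
                                  truth_id = NA_integer_, cell = ci)
        }
      }
      pieces[[ci]] <- do.call(rbind, locs)
    }
    out <- do.call(rbind, pieces)
    out <- out[order(out$frame, out$cell), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
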