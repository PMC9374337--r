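# Simulation benchmarks quantifying how compartment confinement biases the
# apparent diffusion coefficient recovered by displacement fitting.

# Simulate one cell, subsample lag displacements, filter to rMax; returns
# the displacement data.frame (nm).
simulateCellDisplacements <- function(geom, dSim, nParticles = 25L,
                                      totalTime = 2, dtSim = 1e-4,
                                      lagSteps = 15L, rMax = 600,
                                      poleSlowdown = 1, seed = NA_integer_) {
  cfg <- simulationConfig(dSim, dtSim = dtSim, totalTime = totalTime,
                          nParticles = nParticles, seed = seed)
  traj <- simulateConfinedWalk(cfg, geom, poleSlowdown = poleSlowdown)
  filterDisplacements(extractLagDisplacements(traj, lagSteps), rMax)
}

#' Confinement bias of the apparent diffusion coefficient
#'
#' For each input diffusion coefficient, particles are simulated in a
#' reflective spherocylinder, lag displacements are collected, and the
#' apparent coefficient is fitted (background fixed to zero, as appropriate
#' for simulated data) over two analysis areas: the whole cylindrical
#' section of the compartment, and the centermost area of `centerX` by
#' `centerY` nm. The ratio `dApp / dSim` quantifies the underestimation
#' caused by boundary reflections within the observation lag.
#'
#' @param dSimValues input diffusion coefficients, um^2/s.
#' @param geom compartment geometry (default: the median cell, 0.45-um
#'   radius, 2.25-um length).
#' @param nParticles particles per condition (default 25).
#' @param totalTime,dtSim,lagSteps simulation timing (defaults 2 s, 0.1 ms,
#'   lag 15 = 1.5 ms).
#' @param rMax truncation bound, nm.
#' @param centerX,centerY extents of the centermost analysis area, nm
#'   (defaults 150 along the long axis by 100 across).
#' @param seed integer seed.
#' @return data.frame with one row per input coefficient and, for each of
#'   the three analysis areas (whole compartment, cylindrical section,
#'   centermost area), the fitted coefficient, its ratio to `d_sim`, and the
#'   displacement count used.
#' @export
confinementBias <- function(dSimValues,
                            geom = spherocylinder(0.45, 2.25),
                            nParticles = 25L, totalTime = 2, dtSim = 1e-4,
                            lagSteps = 15L, rMax = 600,
                            centerX = 150, centerY = 100,
                            seed = NA_integer_) {
  dt <- lagSteps * dtSim
  hcyl_nm <- cylinderHalfLength(geom) * 1000
  out <- vector("list", length(dSimValues))
  withSeed(seed, {
    for (i in seq_along(dSimValues)) {
      disp <- simulateCellDisplacements(geom, dSimValues[i],
                                        nParticles = nParticles,
                                        totalTime = totalTime, dtSim = dtSim,
                                        lagSteps = lagSteps, rMax = rMax)
      cyl <- disp[abs(disp$origin_x_nm) <= hcyl_nm, , drop = FALSE]
      ctr <- disp[abs(disp$origin_x_nm) <= centerX / 2 &
                  abs(disp$origin_y_nm) <= centerY / 2, , drop = FALSE]
      fall <- fitMLE(disp$r_nm, dt = dt, rMax = rMax, fixKZero = TRUE)
      fcyl <- fitMLE(cyl$r_nm, dt = dt, rMax = rMax, fixKZero = TRUE)
      fctr <- fitMLE(ctr$r_nm, dt = dt, rMax = rMax, fixKZero = TRUE)
      out[[i]] <- data.frame(d_sim = dSimValues[i],
                             d_app_compartment = dHat(fall),
                             ratio_compartment = dHat(fall) / dSimValues[i],
                             n_compartment = nObs(fall),
                             d_app_cylinder = dHat(fcyl),
                             ratio_cylinder = dHat(fcyl) / dSimValues[i],
                             n_cylinder = nObs(fcyl),
                             d_app_center = dHat(fctr),
                             ratio_center = dHat(fctr) / dSimValues[i],
                             n_center = nObs(fctr))
    }
  })
  do.call(rbind, out)
}

#' Pole/center ratio ensemble over a simulated cell population
#'
#' Samples a heterogeneous population of spherocylinders and input diffusion
#' coefficients, simulates confined diffusion in each, partitions the lag
#' displacements into 20%-length pole regions and a center, fits each region
#' (background fixed to zero), and summarizes the per-cell ratio
#' `mean(D_pole_left, D_pole_right) / D_center` across the population. With
#' `poleSlowdown = 1` the ensemble isolates the confinement-only bias.
#'
#' @param nCells population size.
#' @param diameterRange,lengthRange,dRange uniform sampling ranges; defaults
#'   are the experimental extremes of cell width (0.41-2.34 um), length
#'   (1.1-3.64 um) and protein mobility (0.5-20 um^2/s).
#' @param nParticles,totalTime,dtSim,lagSteps,rMax as in [confinementBias()].
#' @param poleFraction fraction of cell length per pole region.
#' @param minPerRegion minimum displacements per fitted region.
#' @param poleSlowdown true multiplicative slowdown applied inside the caps
#'   during simulation (1 = confinement only).
#' @param seed integer seed.
#' @return list as from [poleCenterRatio()], plus `population` (the sampled
#'   cells) and `fits` (per-cell region fits).
#' @export
poleCenterEnsemble <- function(nCells = 40L,
                               diameterRange = c(0.41, 2.34),
                               lengthRange = c(1.1, 3.64),
                               dRange = c(0.5, 20),
                               nParticles = 25L, totalTime = 2, dtSim = 1e-4,
                               lagSteps = 15L, rMax = 600,
                               poleFraction = 0.20, minPerRegion = 100,
                               poleSlowdown = 1, seed = NA_integer_) {
  dt <- lagSteps * dtSim
  withSeed(seed, {
    pop <- generateCellPopulation(nCells, diameterRange, lengthRange, dRange)
    fits <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      disp <- simulateCellDisplacements(pop[[i]]$geom, pop[[i]]$d,
                                        nParticles = nParticles,
                                        totalTime = totalTime, dtSim = dtSim,
                                        lagSteps = lagSteps, rMax = rMax,
                                        poleSlowdown = poleSlowdown)
      cell <- new("CellRecord", id = i, displacements = disp,
                  rotationAngle = 0, length = diff(range(disp$origin_x_nm)) / 1000,
                  width = diff(range(disp$origin_y_nm)) / 1000,
                  qc = "pass", qcReason = "", flags = list())
      part <- partitionRegions(cell, poleFraction)
      fits[[i]] <- tryCatch(
        fitRegions(part, dt = dt, rMax = rMax, minPerRegion = minPerRegion,
                   fixKZero = TRUE),
        error = function(e) list(center = NULL, left = NULL, right = NULL))
    }
    res <- poleCenterRatio(fits)
    res$population <- pop
    res$fits <- fits
    res
  })
}

#' Sampling variability of the MLE at a fixed displacement count
#'
#' Repeatedly draws sets of `nDisp` displacements from the background-free
#' model and fits each by maximum likelihood; the relative SD of the
#' estimates measures the precision attainable at that per-pixel count (45
#' displacements correspond to the quality threshold used for 100-nm maps).
#'
#' @param nRep number of repetitions.
#' @param nDisp displacements per fit.
#' @param d true diffusion coefficient, um^2/s.
#' @param dt,rMax model parameters.
#' @param seed integer seed.
#' @return list with `relSdPercent`, `meanD`, and the vector `estimates`.
#' @export
mleCalibration <- function(nRep = 2000L, nDisp = 45L, d = 1,
                           dt = 1.5e-3, rMax = 600, seed = NA_integer_) {
  withSeed(seed, {
    est <- vapply(seq_len(nRep), function(i) {
      r <- sampleDisplacementModel(nDisp, d, k = 0, dt = dt, rMax = rMax)
      dHat(fitMLE(r, dt = dt, rMax = rMax, fixKZero = TRUE))
    }, numeric(1))
    list(relSdPercent = 100 * sd(est) / d, meanD = mean(est),
         estimates = est)
  })
}
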