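#' Configuration for a confined-diffusion simulation
#'
#' @param dSim input diffusion coefficient, um^2/s.
#' @param dtSim simulation time step, seconds (default 0.1 ms).
#' @param totalTime total simulated time, seconds (default 2 s); must be an
#'   integer multiple of `dtSim`.
#' @param nParticles number of particles.
#' @param seed integer seed; `NA` uses the current RNG state.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(dSim, dtSim = 1e-4, totalTime = 2,
                             nParticles = 25L, seed = NA_integer_) {
  obj <- new("SimulationConfig", dSim = as.numeric(dSim),
             dtSim = as.numeric(dtSim), totalTime = as.numeric(totalTime),
             nParticles = as.integer(nParticles), seed = as.integer(seed))
  tryCatch(validObject(obj),
           error = function(e) stop("configuration error: ",
                                    conditionMessage(e), call. = FALSE))
  obj
}

#' Simulate Brownian motion inside a reflective spherocylinder
#'
#' Particles start uniformly distributed in the compartment. At each step,
#' each coordinate is displaced by an independent normal draw with SD
#' `sqrt(2 * dSim * dtSim)`; proposals ending outside the compartment are
#' specularly reflected across the nearest boundary surface, iterating until
#' interior. The returned table records positions after steps `1..N`
#' (`N = totalTime / dtSim`); there is no t = 0 row, so lag-`L` pairing of an
#' `N`-row trajectory yields `N - L` displacements per particle.
#'
#' @param config a [SimulationConfig-class].
#' @param geom a [Spherocylinder-class].
#' @param poleSlowdown multiplicative factor applied to the diffusion
#'   coefficient while a particle is inside a hemispherical cap; 1 (default)
#'   gives spatially uniform diffusion. Used to build streams with a genuine
#'   pole slowdown on top of confinement.
#' @return data.frame with columns `step`, `particle`, `x`, `y`, `z` (um),
#'   ordered by particle then step.
#' @examples
#' geom <- spherocylinder(0.45, 2.25)
#' cfg <- simulationConfig(5, totalTime = 0.01, nParticles = 2L, seed = 1L)
#' traj <- simulateConfinedWalk(cfg, geom)
#' @export
simulateConfinedWalk <- function(config, geom, poleSlowdown = 1) {
  stopifnot(is(config, "SimulationConfig"), is(geom, "Spherocylinder"))
  validObject(config)
  validObject(geom)
  nSteps <- as.integer(round(config@totalTime / config@dtSim))
  stepSd <- sqrt(2 * config@dSim * config@dtSim)
  withSeed(config@seed, {
    init <- sampleUniformInCell(geom, config@nParticles)
    pos <- confined_walk_cpp(init, nSteps, stepSd, radius(geom),
                             cylinderHalfLength(geom), poleSlowdown)
  })
  np <- config@nParticles
  idx <- seq_len(np)
  data.frame(step = rep(seq_len(nSteps), np),
             particle = rep(idx, each = nSteps),
             x = as.vector(pos[, 3 * idx - 2, drop = FALSE]),
             y = as.vector(pos[, 3 * idx - 1, drop = FALSE]),
             z = as.vector(pos[, 3 * idx, drop = FALSE]))
}

#' Subsample a trajectory into fixed-lag planar displacements
#'
#' Every trajectory row `i` with `i + lagSteps` in range contributes one
#' displacement anchored at the planar (x, y) position of row `i`; because a
#' random walk is a Markov process, these overlapping lag-`lagSteps` pairs are
#' statistically equivalent to single steps observed at `lagSteps * dtSim`.
#' A 20,000-row trajectory at lag 15 yields 19,985 displacements per particle.
#'
#' @param traj trajectory data.frame from [simulateConfinedWalk()].
#' @param lagSteps lag in simulation steps (default 15, i.e. 1.5 ms at the
#'   default 0.1-ms step).
#' @return displacement data.frame with columns `origin_x_nm`, `origin_y_nm`,
#'   `end_x_nm`, `end_y_nm`, `r_nm`, `couple` (origin step index), `particle`.
#' @export
extractLagDisplacements <- function(traj, lagSteps = 15L) {
  lagSteps <- as.integer(lagSteps)
  if (lagSteps < 1L) stop("lagSteps must be >= 1")
  traj <- traj[order(traj$particle, traj$step), , drop = FALSE]
  parts <- unique(traj$particle)
  nSteps <- nrow(traj) / length(parts)
  if (lagSteps >= nSteps)
    stop("empty result: lagSteps (", lagSteps,
         ") must be smaller than the number of trajectory rows per particle (",
         nSteps, ")")
  xm <- matrix(traj$x, nrow = nSteps)
  ym <- matrix(traj$y, nrow = nSteps)
  i0 <- seq_len(nSteps - lagSteps)
  i1 <- i0 + lagSteps
  ox <- xm[i0, , drop = FALSE] * 1000
  oy <- ym[i0, , drop = FALSE] * 1000
  ex <- xm[i1, , drop = FALSE] * 1000
  ey <- ym[i1, , drop = FALSE] * 1000
  data.frame(origin_x_nm = as.vector(ox), origin_y_nm = as.vector(oy),
             end_x_nm = as.vector(ex), end_y_nm = as.vector(ey),
             r_nm = sqrt(as.vector(ex - ox)^2 + as.vector(ey - oy)^2),
             couple = rep(i0, length(parts)),
             particle = rep(parts, each = length(i0)))
}

#' Sample a heterogeneous population of simulated cells
#'
#' Geometries and input diffusion coefficients are drawn uniformly in the
#' given ranges; geometries with total length smaller than the diameter are
#' rejected and resampled, so every cell satisfies the spherocylinder
#' invariant. Defaults span the geometry and mobility ranges typical of
#' exponentially growing E. coli observed by SMdM.
#'
#' @param nCells number of cells.
#' @param diameterRange,lengthRange uniform ranges in micrometres.
#' @param dRange uniform range of input diffusion coefficients, um^2/s.
#' @param seed integer seed; `NA` uses the current RNG state.
#' @return list of `list(geom = Spherocylinder, d = numeric)`.
#' @export
generateCellPopulation <- function(nCells,
                                   diameterRange = c(0.2, 2.34),
                                   lengthRange = c(1.1, 3.64),
                                   dRange = c(0.5, 20),
                                   seed = NA_integer_) {
  if (nCells < 1L) stop("nCells must be >= 1")
  rngs <- list(diameterRange, lengthRange, dRange)
  if (any(vapply(rngs, function(r) length(r) != 2L || r[2] < r[1], logical(1))))
    stop("ranges must be ordered pairs (min, max)")
  if (lengthRange[2] < diameterRange[1])
    stop("infeasible ranges: maximum length smaller than minimum diameter")
  withSeed(seed, {
    out <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      repeat {
        dia <- runif(1, diameterRange[1], diameterRange[2])
        len <- runif(1, lengthRange[1], lengthRange[2])
        if (len >= dia) break
      }
      out[[i]] <- list(geom = spherocylinder(dia / 2, len),
                       d = runif(1, dRange[1], dRange[2]))
    }
    out
  })
}

#' Synthetic protein panel with a known diffusion-mass power law
#'
#' Complex masses are log-uniform in 25-320 kDa and true diffusion
#' coefficients follow `D = alpha * M^beta`, perturbed by multiplicative
#' lognormal noise with the given relative SD (mean-one noise). Ground truth
#' is retained for recovery tests.
#'
#' @param alpha,beta power-law scale and exponent of the ground truth.
#' @param n number of proteins (>= 3).
#' @param relNoise relative SD of the multiplicative noise (>= 0).
#' @param massRange complex-mass range in kDa.
#' @param seed integer seed; `NA` uses the current RNG state.
#' @return data.frame with columns `name`, `complex_mass_kda`, `d_true`,
#'   `d_mean`; attributes `alpha`, `beta`.
#' @export
generateProteinPanel <- function(alpha, beta, n, relNoise = 0,
                                 massRange = c(25, 320), seed = NA_integer_) {
  if (n < 3L) stop("n must be >= 3")
  if (relNoise < 0) stop("relNoise must be >= 0")
  if (beta >= 0)
    warning("beta >= 0 is unusual for diffusion-mass scaling; proceeding")
  withSeed(seed, {
    m <- exp(runif(n, log(massRange[1]), log(massRange[2])))
    dTrue <- alpha * m^beta
    if (relNoise > 0) {
      sdlog <- sqrt(log(1 + relNoise^2))
      noise <- rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else noise <- rep(1, n)
    out <- data.frame(name = sprintf("syn%02d", seq_len(n)),
                      complex_mass_kda = m, d_true = dTrue,
                      d_mean = dTrue * noise)
    attr(out, "alpha") <- alpha
    attr(out, "beta") <- beta
    out
  })
}
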