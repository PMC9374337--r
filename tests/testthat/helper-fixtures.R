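# Shared fixtures, built in code and cached so expensive simulations run once
# per test session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

medianCellGeom <- function() spherocylinder(0.45, 2.25)

# Full-scale trajectory in the median cell (25 particles x 20,000 steps).
medianCellTraj <- function(d, seed) {
  cached(sprintf("traj_%g_%d", d, seed), {
    cfg <- simulationConfig(d, nParticles = 25L, seed = as.integer(seed))
    simulateConfinedWalk(cfg, medianCellGeom())
  })
}

medianCellDisplacements <- function(d, seed) {
  cached(sprintf("disp_%g_%d", d, seed), {
    filterDisplacements(extractLagDisplacements(medianCellTraj(d, seed), 15L),
                        600)
  })
}

# A displacement-shaped data.frame from raw origin coordinates (for geometry
# and partition tests that do not care about the displacement lengths).
dispFrame <- function(ox, oy, r = 0) {
  data.frame(origin_x_nm = ox, origin_y_nm = oy, end_x_nm = ox + r,
             end_y_nm = oy, r_nm = r, couple = seq_along(ox))
}

makeCellRecord <- function(displacements, id = 1L, flags = list()) {
  new("CellRecord", id = as.integer(id), displacements = displacements,
      rotationAngle = 0, length = diff(range(displacements$origin_x_nm)) / 1000,
      width = diff(range(displacements$origin_y_nm)) / 1000,
      qc = "pass", qcReason = "", flags = flags)
}

# Two labelled cells plus sparse uniform background, for clustering tests.
twoCellField <- function(seed, framesPerCell = 800L) {
  cells <- list(list(geom = spherocylinder(0.45, 2.25), d = 3,
                     center = c(0, 0)),
                list(geom = spherocylinder(0.40, 2.0), d = 3,
                     center = c(500, 2000)))
  sc <- streamConfig(locNoiseSd = 20, falsePairRate = 0,
                     framesPerCell = framesPerCell, seed = as.integer(seed))
  loc <- synthesizeLocalizationStream(cells, sc)
  set.seed(seed + 10000L)
  bg <- data.frame(frame = sample(0:(2L * framesPerCell - 1L), 80, TRUE),
                   x_nm = runif(80, -2500, 3000),
                   y_nm = runif(80, -1500, 3500),
                   truth_id = NA_integer_, cell = NA_integer_)
  rbind(loc, bg)
}

# Analytic x-marginal probabilities of the uniform distribution over a
# spherocylinder, for stationarity goodness-of-fit.
spherocylinderXBinProbs <- function(geom, breaks) {
  R <- radius(geom)
  h <- cylinderHalfLength(geom)
  xsec <- function(x) ifelse(abs(x) <= h, pi * R^2,
                             pi * pmax(R^2 - (abs(x) - h)^2, 0))
  p <- vapply(seq_len(length(breaks) - 1L), function(i)
    integrate(xsec, breaks[i], breaks[i + 1])$value, numeric(1))
  p / sum(p)
}
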