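test_that("zero diffusion keeps every particle stationary", {
  geom <- spherocylinder(0.45, 2.25)
  cfg <- simulationConfig(0, totalTime = 0.01, nParticles = 5L, seed = 1L)
  traj <- simulateConfinedWalk(cfg, geom)
  for (p in unique(traj$particle)) {
    tp <- traj[traj$particle == p, ]
    expect_equal(var(tp$x), 0)
    expect_equal(var(tp$y), 0)
    expect_equal(var(tp$z), 0)
  }
  expect_true(all(insideSpherocylinder(geom, traj$x, traj$y, traj$z)))
})

test_that("trajectory row and lag-displacement bookkeeping", {
  geom <- spherocylinder(0.45, 2.25)
  cfg <- simulationConfig(2, nParticles = 1L, seed = 2L)
  traj <- simulateConfinedWalk(cfg, geom)
  expect_equal(nrow(traj), 20000L)
  disp <- extractLagDisplacements(traj, 15L)
  expect_equal(nrow(disp), 19985L)

  short <- traj[traj$step <= 16L, ]
  expect_equal(nrow(extractLagDisplacements(short, 15L)), 1L)
  expect_error(extractLagDisplacements(short, 16L), "empty result")

  # each lag-15 vector equals the sum of its 15 per-step vectors
  steps <- diff(traj$x)
  i <- 100L
  expect_equal(disp$end_x_nm[i] - disp$origin_x_nm[i],
               sum(steps[i:(i + 14L)]) * 1000, tolerance = 1e-10)
})

test_that("configuration and geometry validation reject bad inputs", {
  expect_error(simulationConfig(5, dtSim = 3e-4, totalTime = 1e-3),
               "integer number of steps")
  expect_error(spherocylinder(-0.1, 1), "geometry error")
  expect_error(spherocylinder(0.6, 1), "totalLength")
})

test_that("free-diffusion limit reproduces Rayleigh displacements", {
  # compartment >> sqrt(4 D dt): effectively unconfined
  geom <- spherocylinder(100, 400)
  cfg <- simulationConfig(5, dtSim = 1.5e-3, totalTime = 0.15,
                          nParticles = 400L, seed = 3L)
  disp <- extractLagDisplacements(simulateConfinedWalk(cfg, geom), 1L)
  r_um <- disp$r_nm / 1000
  msd <- mean(r_um^2)
  expected <- 4 * 5 * 1.5e-3
  se <- sd(r_um^2) / sqrt(length(r_um))
  expect_lt(abs(msd - expected), 3 * se)

  cdf <- function(q) 1 - exp(-q^2 / (4 * 5e6 * 1.5e-3))
  ks <- suppressWarnings(ks.test(sample(disp$r_nm, 5000), cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("confined trajectories stay inside and reach the uniform
           stationary distribution", {
  geom <- medianCellGeom()
  traj <- medianCellTraj(5, 21)
  expect_true(all(insideSpherocylinder(geom, traj$x, traj$y, traj$z)))

  # discard burn-in, thin to decorrelate, compare x-marginal to the analytic
  # uniform-compartment marginal over 8 bins
  keep <- traj[traj$step > 2000 & traj$step %% 250 == 0, ]
  breaks <- seq(-totalLength(geom) / 2, totalLength(geom) / 2,
                length.out = 9)
  counts <- hist(pmin(pmax(keep$x, breaks[1]), breaks[9]), breaks = breaks,
                 plot = FALSE)$counts
  p <- spherocylinderXBinProbs(geom, breaks)
  gof <- chisq.test(counts, p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("lag-15 pairing is consistent with direct 1.5-ms steps", {
  # Markov property: overlapping lag-15 pairs at a 0.1-ms step match single
  # steps simulated at 1.5 ms, at a mobility where boundary reflections
  # within one lag are rare
  geom <- medianCellGeom()
  traj <- medianCellTraj(1, 21)
  sub <- traj[traj$step %% 15 == 0, ]
  sub$step <- sub$step / 15
  d15 <- extractLagDisplacements(sub, 1L)
  cfg <- simulationConfig(1, dtSim = 1.5e-3, totalTime = 1.5,
                          nParticles = 25L, seed = 22L)
  d1 <- extractLagDisplacements(simulateConfinedWalk(cfg, geom), 1L)
  ks <- suppressWarnings(ks.test(d15$r_nm, d1$r_nm))
  expect_gt(ks$p.value, 0.01)
})

test_that("cell population sampling respects ranges and the geometry
           invariant", {
  one <- generateCellPopulation(1L, c(0.9, 0.9), c(2.25, 2.25), c(5, 5),
                                seed = 4L)
  expect_equal(radius(one[[1]]$geom), 0.45)
  expect_equal(totalLength(one[[1]]$geom), 2.25)
  expect_equal(one[[1]]$d, 5)

  pop <- generateCellPopulation(200L, seed = 5L)
  dia <- vapply(pop, function(cl) 2 * radius(cl$geom), numeric(1))
  len <- vapply(pop, function(cl) totalLength(cl$geom), numeric(1))
  dv <- vapply(pop, function(cl) cl$d, numeric(1))
  expect_true(all(dia >= 0.2 & dia <= 2.34))
  expect_true(all(len >= 1.1 & len <= 3.64))
  expect_true(all(dv >= 0.5 & dv <= 20))
  expect_true(all(len >= dia))

  expect_error(generateCellPopulation(1L, diameterRange = c(2, 3),
                                      lengthRange = c(0.5, 1)),
               "infeasible")
  # reproducibility
  pop2 <- generateCellPopulation(200L, seed = 5L)
  expect_identical(dv, vapply(pop2, function(cl) cl$d, numeric(1)))
})

test_that("synthetic protein panels embed the requested power law", {
  pan <- generateProteinPanel(10, -0.5, 8, relNoise = 0, seed = 6L)
  expect_true(all(pan$complex_mass_kda >= 25 & pan$complex_mass_kda <= 320))
  fit <- fitPowerLaw(pan$complex_mass_kda, pan$d_mean)
  expect_equal(fit@alpha, 10, tolerance = 1e-6)
  expect_equal(fit@beta, -0.5, tolerance = 1e-6)

  expect_warning(generateProteinPanel(10, 0.2, 5, seed = 7L), "unusual")
  expect_error(generateProteinPanel(10, -0.5, 2), ">= 3")
})

test_that("noise-free streams reproduce ground-truth displacements exactly", {
  geom <- spherocylinder(0.45, 2.25)
  sc <- streamConfig(locNoiseSd = 0, falsePairRate = 0,
                     framesPerCell = 400L, seed = 8L)
  loc <- synthesizeLocalizationStream(list(list(geom = geom, d = 4)), sc)
  disp <- extractDisplacements(loc, rMax = Inf)
  expect_equal(nrow(disp), 400L)
  expect_true(all(disp$truth_ok))
  # recompute displacement lengths straight from the labelled table
  truth <- split(loc, loc$truth_id)
  rTruth <- sort(vapply(truth, function(tt) {
    tt <- tt[order(tt$frame), ]
    sqrt(diff(tt$x_nm)^2 + diff(tt$y_nm)^2)
  }, numeric(1)))
  expect_equal(sort(disp$r_nm), unname(rTruth), tolerance = 1e-12)
})

test_that("false pairings add a background growing linearly in r", {
  geom <- spherocylinder(0.45, 2.25)
  sc <- streamConfig(locNoiseSd = 5, falsePairRate = 2,
                     framesPerCell = 4000L, seed = 31L)
  loc <- synthesizeLocalizationStream(list(list(geom = geom, d = 3)), sc)
  disp <- extractDisplacements(loc, rMax = 600)
  spurious <- disp[!disp$truth_ok, ]
  expect_gt(nrow(spurious), 1e4)
  h <- hist(spurious$r_nm, breaks = seq(0, 600, by = 25), plot = FALSE)
  fit <- lm(h$counts ~ h$mids)
  expect_gt(coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("per-cell displacement counts land in the configured range", {
  geom <- spherocylinder(0.45, 2.25)
  sc <- streamConfig(locNoiseSd = 20, falsePairRate = 0.4,
                     framesPerCell = 3000L, seed = 9L)
  loc <- synthesizeLocalizationStream(list(list(geom = geom, d = 5)), sc)
  disp <- filterDisplacements(extractDisplacements(loc, rMax = 600), 600)
  expect_gte(nrow(disp), 2000)
  expect_lte(nrow(disp), 20000)
})

test_that("simulation output is bit-reproducible for a fixed seed", {
  geom <- spherocylinder(0.45, 2.25)
  cfg <- simulationConfig(3, totalTime = 0.05, nParticles = 3L, seed = 10L)
  expect_identical(simulateConfinedWalk(cfg, geom),
                   simulateConfinedWalk(cfg, geom))
})
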