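test_that("the displacement density is a proper PDF on [0, rMax]", {
  for (d in c(0.5, 5, 50)) for (k in c(0, 1e-7, 1e-6)) {
    expect_equal(displacementPDF(0, d, k), 0)
    q <- integrate(displacementPDF, 0, 600, d = d, k = k,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
    expect_equal(q, 1, tolerance = 1e-6)
    expect_true(all(displacementPDF(seq(0, 600, 50), d, k) >= 0))
  }
  expect_error(displacementPDF(601, 5), "domain error")
  expect_error(displacementPDF(-1, 5), "domain error")
})

test_that("with no background and a wide bound the density is Rayleigh", {
  r <- seq(1, 2000, by = 7)
  got <- displacementPDF(r, 5, k = 0, dt = 1.5e-3, rMax = 1e6)
  s2 <- 4 * 5e6 * 1.5e-3
  rayleigh <- (2 * r / s2) * exp(-r^2 / s2)
  expect_equal(got, rayleigh, tolerance = 1e-9)
})

test_that("the MLE recovers the diffusion coefficient from model draws", {
  set.seed(19)
  r <- sampleDisplacementModel(1e4, 5, k = 0)
  fit <- fitMLE(r, fixKZero = TRUE)
  expect_true(converged(fit))
  expect_lt(abs(dHat(fit) - 5) / 5, 0.05)
  # truncation is negligible here, so the moment estimator is an
  # independent closed-form check
  expect_equal(dHat(fit), mean(r^2) / (4 * 1.5e-3) / 1e6, tolerance = 0.01)

  expect_error(fitMLE(numeric(0)), "no displacements")
  expect_error(fitMLE(c(100, 700)), "exceed rMax")
})

test_that("the free-background fit separates signal from mispairing", {
  set.seed(20)
  kTrue <- 2e-6
  r <- sampleDisplacementModel(12000, 5, k = kTrue)
  free <- fitMLE(r)
  expect_lt(abs(dHat(free) - 5) / 5, 0.10)
  expect_gt(kHat(free), 0)
  fixed <- fitMLE(r, fixKZero = TRUE)
  expect_gt(dHat(fixed), dHat(free) * 1.2)  # ignoring background inflates D
})

test_that("pixel maps bin each displacement once and respect the fit
           threshold", {
  set.seed(22)
  # 9 displacements in one pixel, 30 in another
  d <- dispFrame(c(rep(50, 9), rep(350, 30)), runif(39, 0, 50))
  d$r_nm <- runif(39, 10, 500)
  m <- fitPixelMap(d, 100, minPerPixel = 10, fixKZero = TRUE)
  expect_equal(sum(m@counts), 39L)
  expect_equal(sum(!is.na(m@d)), 1L)
  expect_false(m@complete)
  expect_equal(m@recommendedPixelSize, 150)
  expect_error(fitPixelMap(d, 120), "must be one of")
})

test_that("maps of a uniform simulated cell show the confinement pattern", {
  disp <- medianCellDisplacements(5, 21)
  m <- fitPixelMap(disp, 100, minPerPixel = 45, fixKZero = TRUE)
  xc <- m@origin[1] + (seq_len(nrow(m@d)) - 0.5) * m@pixelSize
  yc <- m@origin[2] + (seq_len(ncol(m@d)) - 0.5) * m@pixelSize
  centerBand <- abs(xc) <= 300
  centerRows <- abs(yc) <= 150
  dCenter <- m@d[centerBand, centerRows]
  expect_lt(abs(mean(dCenter, na.rm = TRUE) - 5) / 5, 0.10)
  # pixels at the radial edge underestimate relative to the center band
  edgeRows <- abs(yc) >= 350
  dEdge <- m@d[, edgeRows]
  expect_lt(mean(dEdge, na.rm = TRUE), mean(dCenter, na.rm = TRUE))
})

test_that("region fits enforce the minimum displacement count", {
  set.seed(23)
  mkPart <- function(nL, nC, nR) {
    mk <- function(n, x0) {
      d <- dispFrame(rep(x0, n), numeric(n))
      d$r_nm <- sampleDisplacementModel(n, 2)
      d
    }
    new("RegionPartition", left = mk(nL, -1000), center = mk(nC, 0),
        right = mk(nR, 1000), poleFraction = 0.2, bounds = c(-500, 500))
  }
  fits <- fitRegions(mkPart(99, 5000, 100), fixKZero = TRUE)
  expect_null(fits$left)
  expect_s4_class(fits$right, "FitResult")
  expect_s4_class(fits$center, "FitResult")
  expect_equal(attr(fits, "excluded"), "left")
  expect_error(fitRegions(mkPart(10, 10, 10)), "cell excluded")
})

test_that("pole and center agree when confinement bias is negligible", {
  # at 0.1 um^2/s a 1.5-ms step is ~25 nm: reflections are rare everywhere
  disp <- medianCellDisplacements(0.1, 24)
  part <- partitionRegions(makeCellRecord(disp), 0.20)
  fits <- fitRegions(part, fixKZero = TRUE)
  se <- function(f) dHat(f) / sqrt(nObs(f))
  dPole <- mean(c(dHat(fits$left), dHat(fits$right)))
  sePole <- sqrt(se(fits$left)^2 + se(fits$right)^2) / 2
  seTot <- sqrt(sePole^2 + se(fits$center)^2)
  expect_lt(abs(dPole - dHat(fits$center)), 3 * seTot)
})

test_that("RMSD-diffusion conversion follows the closed form", {
  expect_equal(dFromRMSD(0.6, 2, 1.5e-3), 60)
  expect_equal(dFromRMSD(0, 2, 1.5e-3), 0)
  D <- 7.3
  expect_equal(dFromRMSD(sqrt(2 * 2 * D * 1.5e-3), 2, 1.5e-3), D)
  expect_error(dFromRMSD(0.6, 2, 0), "t must be")
  expect_error(dFromRMSD(0.6, 4), "nDims")
})
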