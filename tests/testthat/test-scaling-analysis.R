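test_that("complex mass combines monomer, tag, and oligomeric state", {
  expect_equal(complexMass(45.7, 2), 142.8)        # Icd homodimer
  expect_equal(complexMass(25.7, 1, tagMw = 0), 25.7)  # free mEos3.2
  expect_equal(complexMass(10, 1, tagMw = 0), 10)
  expect_error(complexMass(45.7, 0), "oligomericState")
})

test_that("loneliness is the abundance ratio with a defined reciprocal", {
  lon <- loneliness(18242, 18242 / 0.025)
  expect_equal(as.numeric(lon), 0.025)
  expect_equal(as.numeric(attr(lon, "interactorsPerMolecule")), 40)
  expect_equal(as.numeric(loneliness(1000, 1000)), 1)
  expect_equal(as.numeric(loneliness(1000, 100)), 10)
  expect_warning(out <- loneliness(10, 0), "undefined")
  expect_true(is.na(out))
})

test_that("Spearman correlation handles monotone data and ties", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearmanCorrelation(x, x)$r, 1)
  expect_equal(spearmanCorrelation(x, -x)$r, -1)
  # invariance under strictly monotone transforms
  y <- c(2, 7, 1, 8, 2.8, 5.7)
  expect_equal(spearmanCorrelation(x, y)$r,
               spearmanCorrelation(log(x), y^3)$r)
  # tie handling against the explicit mean-rank formula
  xt <- c(1, 2, 2, 3, 4, 5)
  yt <- c(2, 1, 4, 3, 6, 5)
  meanRank <- function(v) {
    r <- rank(v, ties.method = "average")
    r
  }
  brute <- cor(meanRank(xt), meanRank(yt))
  expect_equal(spearmanCorrelation(xt, yt)$r, brute)
  expect_error(spearmanCorrelation(rep(1, 5), 1:5), "constant")
})

test_that("power-law fitting is exact on exact data and matches log-log
           regression", {
  M <- c(30, 60, 90, 150, 250, 320)
  D <- 10 * M^-0.5
  fit <- fitPowerLaw(M, D)
  expect_equal(fit@alpha, 10, tolerance = 1e-8)
  expect_equal(fit@beta, -0.5, tolerance = 1e-8)
  expect_equal(unname(fit@residuals), rep(0, 6), tolerance = 1e-8)
  ll <- lm(log(D) ~ log(M))
  expect_equal(fit@beta, unname(coef(ll)[2]), tolerance = 1e-8)
  expect_equal(fit@alpha, exp(unname(coef(ll)[1])), tolerance = 1e-8)
  expect_error(fitPowerLaw(c(1, 2), c(1, 2)), ">= 3")
})

test_that("power-law recovery holds across noisy synthetic panels", {
  ok <- 0L
  for (s in 1:200) {
    pan <- generateProteinPanel(55, -0.54, 10, relNoise = 0.1,
                                seed = 1000L + s)
    fit <- fitPowerLaw(pan$complex_mass_kda, pan$d_mean)
    if (abs(fit@beta - (-0.54)) <= 2 * fit@seBeta) ok <- ok + 1L
  }
  expect_gte(ok / 200, 0.90)
})

test_that("pole/center ratios summarize per-cell region fits", {
  mkFit <- function(d) new("FitResult", dHat = d, kHat = 0, logLik = -1,
                           n = 1000L, converged = TRUE, kFixed = TRUE)
  same <- list(center = mkFit(4), left = mkFit(4), right = mkFit(4))
  res <- poleCenterRatio(list(same))
  expect_equal(res$ratios, 1)

  mixed <- list(
    list(center = mkFit(4), left = mkFit(3), right = mkFit(2)),
    list(center = NULL, left = mkFit(3), right = mkFit(2)),
    list(center = mkFit(5), left = NULL, right = mkFit(4)))
  res2 <- poleCenterRatio(mixed)
  expect_equal(res2$ratios, c(2.5 / 4, 4 / 5))
  expect_match(res2$skipped[["2"]], "center")
})

test_that("a built-in pole slowdown is detected on top of confinement", {
  base <- poleCenterEnsemble(nCells = 12L, seed = 41L)
  slow <- poleCenterEnsemble(nCells = 12L, seed = 41L, poleSlowdown = 0.7)
  expect_lt(base$mean, 1)
  # slowdown pushes the ensemble well below the confinement-only baseline,
  # but diffusive exchange across region boundaries within the 1.5-ms lag
  # keeps it above the naive 0.7 x baseline
  expect_lt(slow$mean, base$mean - 0.05)
  expect_gt(slow$mean, 0.6 * base$mean)
})

test_that("perceived viscosity inverts Einstein-Stokes exactly", {
  vis <- perceivedViscosity(5, 100)
  dBack <- einsteinStokesD(vis$eta, vis$radiusNm)
  expect_equal(dBack, 5, tolerance = 1e-12)
  # exact D = a * M^-0.54 with r ~ M^(1/3) gives a viscosity exponent of
  # 0.54 - 1/3
  M <- exp(seq(log(25), log(320), length.out = 12))
  D <- 50 * M^-0.54
  vfit <- perceivedViscosity(D, M)$fit
  expect_equal(vfit@beta, 0.54 - 1 / 3, tolerance = 1e-6)
})

test_that("the rank-sum test matches its exact small-sample distribution", {
  same <- twoSampleRankTest(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8)          # n^2 / 2
  expect_gt(same$p, 0.97)

  sep <- twoSampleRankTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1)         # 2 / choose(6, 3)

  a <- c(1.2, 3.4, 0.5, 7.7)
  b <- c(2.2, 5.1, 0.1)
  ab <- twoSampleRankTest(a, b)
  ba <- twoSampleRankTest(b, a)
  expect_equal(ab$U, length(a) * length(b) - ba$U)
  expect_equal(ab$p, ba$p)
  expect_error(twoSampleRankTest(numeric(0), 1), "non-empty")
})

test_that("the normality test is affine-invariant and calibrated", {
  set.seed(25)
  x <- rnorm(50)
  expect_equal(normalityTest(x)$W, normalityTest(3 * x - 7)$W,
               tolerance = 1e-10)
  expect_error(normalityTest(c(1, 2)), "at least 3")
  expect_error(normalityTest(rep(2, 10)), "constant")

  # rejection rates at the 1% level: near-nominal for normal samples,
  # far above nominal for uniform samples
  rejN <- rejU <- 0L
  for (i in 1:400) {
    set.seed(3000 + i)
    if (normalityTest(rnorm(100))$p < 0.01) rejN <- rejN + 1L
    if (normalityTest(runif(100))$p < 0.01) rejU <- rejU + 1L
  }
  expect_lte(rejN / 400, 0.04)
  expect_gt(rejU / 400, 0.10)
})

test_that("the nested F test penalizes constrained fits sensibly", {
  ft <- nestedFTest(rssConstrained = 20, rssFull = 10, pConstrained = 1,
                    pFull = 2, n = 12)
  expect_gt(ft$F, 0)
  expect_lt(ft$p, 0.05)
  same <- nestedFTest(10, 10, 1, 2, 12)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
})
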