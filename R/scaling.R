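# Downstream scaling statistics: complex mass, loneliness, rank correlation,
# the diffusion-mass power law, pole/center ratio ensembles, perceived
# viscosity, and the rank tests used for group comparisons.

#' Mass of the diffusing complex
#'
#' `(monomer MW + tag MW) * oligomeric state`, assuming every subunit of a
#' homo-oligomer carries the fluorescent tag. The mEos3.2 tag weighs
#' 25.7 kDa.
#'
#' @param monomerMw monomer molecular weight, kDa.
#' @param oligomericState integer >= 1.
#' @param tagMw tag molecular weight, kDa (default mEos3.2; use 0 for an
#'   untagged protein or for the free tag itself).
#' @return complex mass, kDa.
#' @examples
#' complexMass(45.7, 2)        # Icd homodimer: 142.8 kDa
#' complexMass(25.7, 1, 0)     # free mEos3.2:  25.7 kDa
#' @export
complexMass <- function(monomerMw, oligomericState, tagMw = 25.7) {
  if (any(oligomericState < 1)) stop("oligomericState must be >= 1")
  if (any(monomerMw < 0) || any(tagMw < 0)) stop("masses must be >= 0")
  (monomerMw + tagMw) * oligomericState
}

#' Loneliness of a protein
#'
#' Copy number of the protein divided by the summed copy numbers of its known
#' binary interaction partners; an abstraction of how many potential
#' interactors each molecule faces (the reciprocal, interactors per
#' molecule, is returned as attribute `"interactorsPerMolecule"`).
#'
#' @param abundance copies per cell (> 0).
#' @param interactorSum summed interactor copies per cell.
#' @return loneliness ratio; `NA` (flagged by a warning) when the interactor
#'   sum is zero.
#' @examples
#' loneliness(18242, 18242 / 0.025)  # ~0.025, ~40 interactors per molecule
#' @export
loneliness <- function(abundance, interactorSum) {
  if (any(abundance <= 0)) stop("abundance must be > 0")
  out <- ifelse(interactorSum > 0, abundance / interactorSum, NA_real_)
  if (anyNA(out))
    warning("loneliness undefined for zero interactor abundance")
  attr(out, "interactorsPerMolecule") <- ifelse(is.na(out), NA_real_, 1 / out)
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mean-ranked values (ties get average ranks), with a
#' permutation or asymptotic p-value from [stats::cor.test()].
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return list with elements `r` and `p`.
#' @export
spearmanCorrelation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Fit the power law D = alpha * M^beta
#'
#' Nonlinear least squares on the linear scale, initialized from the log-log
#' regression solution. When per-point SDs are supplied the fit is weighted
#' by `1 / sd^2` (the usual chi-square weighting when each point is a mean
#' with known spread); standard errors come from the fit covariance.
#'
#' @param masses complex masses, kDa (> 0).
#' @param dValues diffusion coefficients, um^2/s (> 0).
#' @param sd optional per-point SDs for weighting.
#' @return a [PowerLawFit-class].
#' @export
fitPowerLaw <- function(masses, dValues, sd = NULL) {
  if (length(masses) != length(dValues) || length(masses) < 3L)
    stop("need >= 3 paired points")
  if (any(masses <= 0) || any(dValues <= 0))
    stop("masses and dValues must be positive")
  ll <- lm(log(dValues) ~ log(masses))
  start <- list(alpha = exp(unname(coef(ll)[1])), beta = unname(coef(ll)[2]))
  df <- data.frame(M = masses, D = dValues)
  args <- list(D ~ alpha * M^beta, data = df, start = start,
               lower = c(alpha = 1e-12, beta = -10),
               upper = c(alpha = 1e12, beta = 10),
               control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(sd)) args$weights <- 1 / sd^2
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
    error = function(e) stop("power-law fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  new("PowerLawFit", alpha = unname(est["alpha"]), beta = unname(est["beta"]),
      seAlpha = unname(se["alpha"]), seBeta = unname(se["beta"]),
      residuals = dValues - unname(est["alpha"]) * masses^unname(est["beta"]),
      weighted = !is.null(sd))
}

#' Pole/center diffusion-ratio ensemble
#'
#' For each cell the available pole estimates are averaged and divided by the
#' center estimate; the ensemble mean and SD summarize the population. Cells
#' without a converged center fit, or without any pole fit, are skipped with
#' a reason.
#'
#' @param regionFits list (one element per cell) of region-fit lists as
#'   returned by [fitRegions()].
#' @return list with `ratios` (per-cell), `mean`, `sd`, and `skipped`
#'   (named reasons).
#' @export
poleCenterRatio <- function(regionFits) {
  ratios <- numeric(0)
  skipped <- character(0)
  for (i in seq_along(regionFits)) {
    rf <- regionFits[[i]]
    ctr <- rf$center
    if (is.null(ctr) || !converged(ctr)) {
      skipped[as.character(i)] <- "no valid center fit"
      next
    }
    poles <- c(if (!is.null(rf$left) && converged(rf$left)) dHat(rf$left),
               if (!is.null(rf$right) && converged(rf$right)) dHat(rf$right))
    if (length(poles) == 0L) {
      skipped[as.character(i)] <- "no valid pole fit"
      next
    }
    ratios <- c(ratios, mean(poles) / dHat(ctr))
  }
  list(ratios = ratios, mean = mean(ratios), sd = sd(ratios),
       skipped = skipped)
}

#' Perceived viscosity of the cytoplasm for a complex of given mass
#'
#' Inverts the Einstein-Stokes relation `D = kB T / (6 pi eta r)` using a
#' hydrodynamic radius from mass, `(3 M vbar / (4 pi NA))^(1/3)`, for a
#' compact globular particle with partial specific volume `vbar`. When a
#' panel of (mass, D) pairs is supplied the mass dependence of the resulting
#' viscosities is summarized by a power-law fit `eta = a * M^gamma`.
#'
#' @param d diffusion coefficients, um^2/s.
#' @param mass complex masses, kDa.
#' @param temperature absolute temperature, K (default 294.15 K, a 21 C
#'   microscope stage).
#' @param specificVolume partial specific volume, cm^3/g (default 0.73).
#' @param sd optional per-point SDs of `d` for the power-law weighting.
#' @return list with `eta` (cP per point), `radiusNm` (hydrodynamic radii),
#'   and `fit` (a [PowerLawFit-class] of eta on mass; NULL for < 3 points).
#' @export
perceivedViscosity <- function(d, mass, temperature = 294.15,
                               specificVolume = 0.73, sd = NULL) {
  if (any(d <= 0) || any(mass <= 0)) stop("d and mass must be positive")
  kB <- 1.380649e-23                       # J/K
  NAvo <- 6.02214076e23                    # 1/mol
  vol_cm3 <- mass * 1000 * specificVolume / NAvo   # per molecule
  r_m <- (3 * vol_cm3 / (4 * pi))^(1 / 3) / 100    # cm -> m
  eta_pa_s <- kB * temperature / (6 * pi * (d * 1e-12) * r_m)
  eta_cp <- eta_pa_s * 1000
  fit <- if (length(d) >= 3L) fitPowerLaw(mass, eta_cp, sd = sd) else NULL
  list(eta = eta_cp, radiusNm = r_m * 1e9, fit = fit)
}

#' Einstein-Stokes diffusion coefficient
#'
#' `D = kB T / (6 pi eta r)`; the algebraic inverse of
#' [perceivedViscosity()]'s viscosity-from-D step.
#'
#' @param eta viscosity, cP.
#' @param radiusNm hydrodynamic radius, nm.
#' @param temperature absolute temperature, K.
#' @return diffusion coefficient, um^2/s.
#' @export
einsteinStokesD <- function(eta, radiusNm, temperature = 294.15) {
  kB <- 1.380649e-23
  d_m2s <- kB * temperature / (6 * pi * (eta / 1000) * (radiusNm * 1e-9))
  d_m2s * 1e12
}

#' Mann-Whitney U rank test
#'
#' Two-sided rank-sum comparison of two samples; exact null distribution for
#' small tie-free samples, normal approximation with tie correction
#' otherwise (via [stats::wilcox.test()]).
#'
#' @param a,b numeric samples.
#' @return list with `U` (statistic for the first sample) and `p`.
#' @export
twoSampleRankTest <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b, exact = NULL, correct = TRUE))
  list(U = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list with `W` and `p`; typically used at the 1% level before
#'   choosing rank-based comparisons.
#' @export
normalityTest <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0) stop("undefined for a constant sample")
  st <- shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}

#' F test comparing nested power-law fits
#'
#' Standard extra-sum-of-squares comparison of a constrained fit (fewer free
#' parameters) against an unconstrained one.
#'
#' @param rssConstrained,rssFull residual sums of squares.
#' @param pConstrained,pFull numbers of free parameters (pFull >
#'   pConstrained).
#' @param n number of data points.
#' @return list with `F` and `p`.
#' @export
nestedFTest <- function(rssConstrained, rssFull, pConstrained, pFull, n) {
  if (pFull <= pConstrained) stop("pFull must exceed pConstrained")
  df1 <- pFull - pConstrained
  df2 <- n - pFull
  if (df2 <= 0) stop("not enough data points")
  Fstat <- ((rssConstrained - rssFull) / df1) / (rssFull / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}
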