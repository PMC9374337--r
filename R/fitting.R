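# Truncated Rayleigh displacement model with linear mispairing background,
# and its maximum-likelihood machinery.
#
# Unnormalized density on [0, rMax]:
#   g(r) = (2 r / (4 D t)) exp(-r^2 / (4 D t)) + k r
# with integral A + B, A = 1 - exp(-rMax^2 / (4 D t)) (Rayleigh mass) and
# B = k rMax^2 / 2 (background mass). The normalized density is the
# two-component mixture
#   p(r) = (1 - w) f_ray(r) + w f_lin(r),   w = B / (A + B),
# where f_ray is the truncated Rayleigh density and f_lin(r) = 2 r / rMax^2.
# Internally D is in nm^2/s; the API reports um^2/s (1 um^2 = 1e6 nm^2).

#' Displacement probability density
#'
#' Density of planar displacement lengths observed over a lag `dt` for
#' diffusion coefficient `d`, truncated and renormalized on `[0, rMax]`, with
#' a linear term of slope `k` absorbing misassigned pairs. With `k = 0` and
#' `rMax` large it reduces to the Rayleigh density
#' `(2 r / (4 D t)) exp(-r^2 / (4 D t))`.
#'
#' @param r displacement lengths in nm (must lie in `[0, rMax]`).
#' @param d diffusion coefficient, um^2/s (> 0).
#' @param k background slope, nm^-2 (>= 0).
#' @param dt lag time in seconds (default 1.5 ms).
#' @param rMax truncation bound in nm (default 600).
#' @return densities in nm^-1.
#' @export
displacementPDF <- function(r, d, k = 0, dt = 1.5e-3, rMax = 600) {
  if (any(r < 0 | r > rMax))
    stop("domain error: r must lie within [0, rMax]")
  if (d <= 0) stop("d must be > 0")
  if (k < 0) stop("k must be >= 0")
  s2 <- 4 * d * 1e6 * dt            # 4 D dt in nm^2
  A <- 1 - exp(-rMax^2 / s2)
  B <- k * rMax^2 / 2
  ((2 * r / s2) * exp(-r^2 / s2) + k * r) / (A + B)
}

#' Sample displacement lengths from the displacement model
#'
#' Inverse-CDF sampling of the mixture: background draws are linear on
#' `[0, rMax]`, signal draws follow the truncated Rayleigh component.
#'
#' @inheritParams displacementPDF
#' @param n number of draws.
#' @return numeric vector of displacement lengths in nm.
#' @export
sampleDisplacementModel <- function(n, d, k = 0, dt = 1.5e-3, rMax = 600) {
  s2 <- 4 * d * 1e6 * dt
  A <- 1 - exp(-rMax^2 / s2)
  B <- k * rMax^2 / 2
  w <- B / (A + B)
  bg <- runif(n) < w
  r <- numeric(n)
  nbg <- sum(bg)
  if (nbg > 0) r[bg] <- rMax * sqrt(runif(nbg))
  ns <- n - nbg
  if (ns > 0) {
    u <- runif(ns)
    r[!bg] <- sqrt(-s2 * log(1 - u * A))
  }
  r
}

negLogLik <- function(r, logDnm, w, dt, rMax) {
  s2 <- 4 * exp(logDnm) * dt
  A <- 1 - exp(-rMax^2 / s2)
  fray <- (2 * r / s2) * exp(-r^2 / s2) / A
  flin <- 2 * r / rMax^2
  dens <- (1 - w) * fray + w * flin
  -sum(log(pmax(dens, 1e-300)))
}

#' Maximum-likelihood fit of the displacement model
#'
#' Maximizes the truncated-model likelihood over `d > 0` (and the background
#' slope `k >= 0` unless `fixKZero`). Initialization uses the method of
#' moments, `d0 = mean(r^2) / (4 dt)`, and a small starting background
#' weight; the free-`k` problem is optimized over (log d, logit w) where `w`
#' is the background mixture weight, which is well-conditioned for any
#' magnitude of `k`.
#'
#' @param r displacement lengths in nm, or a displacement data.frame with a
#'   column `r_nm`; all values must be `<= rMax`.
#' @param dt lag time, seconds.
#' @param rMax truncation bound, nm.
#' @param fixKZero if TRUE the background slope is held at zero (appropriate
#'   for simulation-derived displacements, which have no mispairing).
#' @return a [FitResult-class].
#' @export
fitMLE <- function(r, dt = 1.5e-3, rMax = 600, fixKZero = FALSE) {
  if (is.data.frame(r)) r <- r$r_nm
  if (length(r) == 0L) stop("no displacements to fit")
  if (any(!is.finite(r)) || any(r < 0)) stop("displacements must be finite and >= 0")
  if (any(r > rMax)) stop("displacements exceed rMax; filter first")
  d0nm <- max(mean(r^2) / (4 * dt), 1e-6)
  lo <- log(d0nm) - 12
  hi <- log(d0nm) + 6
  if (fixKZero) {
    opt <- optimize(function(ld) negLogLik(r, ld, 0, dt, rMax),
                    interval = c(lo, hi), tol = 1e-10)
    dHat <- exp(opt$minimum) / 1e6
    res <- new("FitResult", dHat = dHat, kHat = 0, logLik = -opt$objective,
               n = length(r), converged = is.finite(opt$objective),
               kFixed = TRUE)
    return(res)
  }
  fn <- function(p) negLogLik(r, p[1], plogis(p[2]), dt, rMax)
  opt <- optim(c(log(d0nm), qlogis(0.01)), fn, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  dnm <- exp(opt$par[1])
  w <- plogis(opt$par[2])
  A <- 1 - exp(-rMax^2 / (4 * dnm * dt))
  kHat <- (w / (1 - w)) * A * 2 / rMax^2
  new("FitResult", dHat = dnm / 1e6, kHat = kHat, logLik = -opt$value,
      n = length(r), converged = opt$convergence == 0L, kFixed = FALSE)
}

#' Per-pixel diffusion map of one cell
#'
#' Displacements are binned into a square pixel grid by their origin (each
#' displacement falls in exactly one pixel); every pixel holding at least
#' `minPerPixel` displacements is fitted independently with [fitMLE()]. When
#' occupied pixels fall below the fitting threshold the map is flagged
#' incomplete and the next larger pixel size from `sizes` is recommended.
#'
#' @param cell a [CellRecord-class], or a displacement data.frame.
#' @param pixelSize pixel edge in nm; one of `sizes`.
#' @param minPerPixel minimum displacements to fit a pixel (default 10).
#' @param dt,rMax,fixKZero passed to [fitMLE()].
#' @param sizes the permitted pixel-size ladder, nm.
#' @return a [DiffusionMap-class].
#' @export
fitPixelMap <- function(cell, pixelSize = 100, minPerPixel = 10,
                        dt = 1.5e-3, rMax = 600, fixKZero = FALSE,
                        sizes = c(50, 100, 150, 200)) {
  if (!pixelSize %in% sizes)
    stop("pixelSize must be one of ", paste(sizes, collapse = ", "), " nm")
  d <- if (is(cell, "CellRecord")) displacements(cell) else cell
  if (nrow(d) == 0L) stop("no displacements to map")
  x <- d$origin_x_nm
  y <- d$origin_y_nm
  x0 <- min(x); y0 <- min(y)
  nx <- max(1L, ceiling((max(x) - x0) / pixelSize + 1e-12))
  ny <- max(1L, ceiling((max(y) - y0) / pixelSize + 1e-12))
  ix <- pmin(pmax(floor((x - x0) / pixelSize) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((y - y0) / pixelSize) + 1L, 1L), ny)
  pix <- (iy - 1L) * nx + ix
  counts <- matrix(0L, nx, ny)
  tab <- tabulate(pix, nbins = nx * ny)
  counts[] <- tab
  dmat <- matrix(NA_real_, nx, ny)
  kmat <- matrix(NA_real_, nx, ny)
  fit_pix <- which(tab >= minPerPixel)
  groups <- split(d$r_nm, pix)
  for (p in fit_pix) {
    fr <- fitMLE(groups[[as.character(p)]], dt = dt, rMax = rMax,
                 fixKZero = fixKZero)
    if (converged(fr)) {
      dmat[p] <- dHat(fr)
      kmat[p] <- kHat(fr)
    }
  }
  complete <- !any(tab > 0L & tab < minPerPixel)
  larger <- sizes[sizes > pixelSize]
  rec <- if (complete || length(larger) == 0L) pixelSize else larger[1]
  new("DiffusionMap", d = dmat, k = kmat, counts = counts,
      pixelSize = pixelSize, origin = c(x0, y0), dt = dt, rMax = rMax,
      complete = complete, recommendedPixelSize = rec)
}

#' Fit the pole and center regions of a cell
#'
#' Fits each region of a [RegionPartition-class] with [fitMLE()] provided it
#' holds at least `minPerRegion` displacements (default 100, which bounds the
#' relative error of the estimate near 10%); under-threshold regions are
#' excluded with a reason. If all three regions are under threshold the cell
#' is rejected with an error.
#'
#' @param partition a [RegionPartition-class].
#' @param dt,rMax,fixKZero passed to [fitMLE()].
#' @param minPerRegion minimum displacements per fitted region.
#' @return named list with elements `center`, `left`, `right`: each a
#'   [FitResult-class] or `NULL`; attribute `"excluded"` names the skipped
#'   regions.
#' @export
fitRegions <- function(partition, dt = 1.5e-3, rMax = 600,
                       minPerRegion = 100, fixKZero = FALSE) {
  stopifnot(is(partition, "RegionPartition"))
  regions <- list(center = partition@center, left = partition@left,
                  right = partition@right)
  counts <- vapply(regions, nrow, integer(1))
  if (all(counts < minPerRegion))
    stop("cell excluded: all regions below ", minPerRegion, " displacements")
  out <- lapply(regions, function(reg) {
    if (nrow(reg) < minPerRegion) return(NULL)
    fitMLE(reg$r_nm, dt = dt, rMax = rMax, fixKZero = fixKZero)
  })
  attr(out, "excluded") <- names(regions)[counts < minPerRegion]
  out
}

#' Diffusion coefficient from a root-mean-square displacement
#'
#' Closed form `D = RMSD^2 / (2 n t)` for `n`-dimensional Brownian motion
#' (`RMSD = sqrt(2 n D t)` inverted). With the default pairing bound of
#' 0.6 um taken as a 2-D RMSD over 1.5 ms this gives 60 um^2/s, the mobility
#' ceiling the bound can accommodate.
#'
#' @param rmsd root-mean-square displacement, um (>= 0).
#' @param nDims number of spatial dimensions (1, 2 or 3).
#' @param t lag time, seconds (> 0).
#' @return diffusion coefficient, um^2/s.
#' @export
dFromRMSD <- function(rmsd, nDims = 2, t = 1.5e-3) {
  if (t <= 0) stop("t must be > 0")
  if (!nDims %in% 1:3) stop("nDims must be 1, 2 or 3")
  if (any(rmsd < 0)) stop("rmsd must be >= 0")
  rmsd^2 / (2 * nDims * t)
}
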