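#' Construct a spherocylinder
#'
#' @param radius radius in micrometres (> 0).
#' @param totalLength end-to-end length in micrometres, hemispherical caps
#'   included; must be >= `2 * radius`.
#' @return a [Spherocylinder-class] object.
#' @examples
#' spherocylinder(0.45, 2.25)
#' @export
spherocylinder <- function(radius, totalLength) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("geometry error: radius must be a single positive number")
  obj <- new("Spherocylinder", radius = as.numeric(radius),
             totalLength = as.numeric(totalLength))
  validObject(obj)
  obj
}

#' Test whether points lie inside a spherocylinder
#'
#' A point is inside when its distance to the axis segment is at most the
#' radius (boundary inclusive, with a small tolerance for round-off).
#'
#' @param geom a [Spherocylinder-class].
#' @param x,y,z point coordinates in micrometres (axis along x, centred at 0).
#' @param tol absolute tolerance in micrometres.
#' @return logical vector.
#' @export
insideSpherocylinder <- function(geom, x, y, z, tol = 1e-9) {
  h <- cylinderHalfLength(geom)
  cx <- pmin(pmax(x, -h), h)
  (x - cx)^2 + y^2 + z^2 <= (radius(geom) + tol)^2
}

# Uniform sample inside the 3-D compartment (rejection from the bounding box).
sampleUniformInCell <- function(geom, n) {
  R <- radius(geom)
  hl <- totalLength(geom) / 2
  out <- matrix(NA_real_, 0L, 3L)
  while (nrow(out) < n) {
    m <- max(16L, ceiling((n - nrow(out)) / 0.4))
    cand <- cbind(runif(m, -hl, hl), runif(m, -R, R), runif(m, -R, R))
    keep <- insideSpherocylinder(geom, cand[, 1], cand[, 2], cand[, 3])
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Uniform sample over the 2-D footprint (projection: rectangle + two half
# discs), used for spurious detections; returns an n x 2 matrix in um.
sampleUniformFootprint <- function(geom, n) {
  R <- radius(geom)
  hl <- totalLength(geom) / 2
  out <- matrix(NA_real_, 0L, 2L)
  while (nrow(out) < n) {
    m <- max(16L, ceiling((n - nrow(out)) / 0.5))
    cand <- cbind(runif(m, -hl, hl), runif(m, -R, R))
    h <- cylinderHalfLength(geom)
    cx <- pmin(pmax(cand[, 1], -h), h)
    keep <- (cand[, 1] - cx)^2 + cand[, 2]^2 <= R^2
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG
# stream; seed = NA/NULL runs expr with the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
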