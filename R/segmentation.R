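# Cell segmentation: Voronoi-density clustering, major-axis rotation,
# displacement-count QC, and pole/center partitioning.

# Voronoi polygon areas for planar points (Inf for convex-hull points whose
# polygons are unbounded). Interior polygons are assembled from the
# circumcentres of the incident Delaunay triangles, ordered angularly.
# Returns list(areas, triangles).
voronoiAreas <- function(x, y) {
  tri <- tryCatch(delaunay_cpp(x, y), error = function(e)
    stop("tessellation error: ", conditionMessage(e), call. = FALSE))
  ax <- x[tri[, 1]]; ay <- y[tri[, 1]]
  bx <- x[tri[, 2]]; by <- y[tri[, 2]]
  cx <- x[tri[, 3]]; cy <- y[tri[, 3]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ccx <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  ccy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  n <- length(x)
  hull <- chull(x, y)
  incid <- split(rep(seq_len(nrow(tri)), 3L), as.vector(tri))
  areas <- rep(Inf, n)
  interior <- setdiff(seq_len(n), hull)
  for (p in interior) {
    ts <- incid[[as.character(p)]]
    if (is.null(ts) || length(ts) < 3L) next
    vx <- ccx[ts]; vy <- ccy[ts]
    o <- order(atan2(vy - y[p], vx - x[p]))
    vx <- vx[o]; vy <- vy[o]
    j <- c(seq_along(vx)[-1], 1L)
    areas[p] <- abs(sum(vx * vy[j] - vx[j] * vy)) / 2
  }
  list(areas = areas, triangles = tri)
}

#' Detect cells by Voronoi-density clustering
#'
#' Localization positions are tessellated; points whose Voronoi polygon area
#' is below `maxAreaFactor` times the median (finite) polygon area are kept
#' as "dense", and connected components of dense points (adjacency = shared
#' Voronoi edge, i.e. a Delaunay edge) become candidate cells. Components
#' smaller than `minPoints` are discarded.
#'
#' @param localizations data.frame with `x_nm`, `y_nm` columns.
#' @param maxAreaFactor density threshold as a multiple of the median
#'   Voronoi polygon area (default 2).
#' @param minPoints minimum number of points per retained cluster
#'   (default 500).
#' @return list of integer vectors of row indices into `localizations`, one
#'   per detected cluster, ordered by decreasing size. Empty input gives an
#'   empty list; collinear input raises a tessellation error.
#' @export
clusterCells <- function(localizations, maxAreaFactor = 2, minPoints = 500) {
  if (is.null(localizations) || nrow(localizations) < 3L) return(list())
  x <- localizations$x_nm
  y <- localizations$y_nm
  # exact duplicates break the tessellation; dedupe and map back
  key <- paste(x, y, sep = "\r")
  first <- !duplicated(key)
  ux <- x[first]; uy <- y[first]
  umap <- match(key, key[first])
  if (length(ux) < 3L) return(list())
  va <- voronoiAreas(ux, uy)
  med <- median(va$areas[is.finite(va$areas)])
  dense <- is.finite(va$areas) & va$areas < maxAreaFactor * med
  tri <- va$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- e[dense[e[, 1]] & dense[e[, 2]], , drop = FALSE]
  g <- igraph::graph_from_edgelist(apply(e, 2, as.character), directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  vnames <- as.integer(igraph::V(g)$name)
  clusters <- split(vnames, comp$membership)
  clusters <- clusters[order(-vapply(clusters, length, integer(1)))]
  out <- list()
  for (cl in clusters) {
    rows <- which(umap %in% cl)
    if (length(rows) >= minPoints) out[[length(out) + 1L]] <- rows
  }
  out
}

#' Rotate a displacement cloud onto its major axis
#'
#' The leading eigenvector of the covariance matrix of displacement origins
#' defines the cell's long axis; all positions (origins and endpoints) are
#' rotated about the origin centroid so that this axis is parallel to x, and
#' re-centred so the centroid sits at (0, 0). Rotation is an isometry, so
#' displacement lengths are unchanged.
#'
#' @param displacements displacement data.frame for one cell.
#' @param id integer cell id.
#' @param isotropyTol eigenvalue ratio below which the axis is flagged
#'   ambiguous (near-isotropic cloud); the default 1.2 leaves headroom for
#'   the sampling spread of eigenvalue ratios in finite isotropic clouds.
#' @return a [CellRecord-class]; the recorded angle is in (-pi/2, pi/2]
#'   radians and `flags$axisAmbiguous` marks isotropic clouds.
#' @export
rotateToMajorAxis <- function(displacements, id = 1L, isotropyTol = 1.2) {
  ox <- displacements$origin_x_nm
  oy <- displacements$origin_y_nm
  if (length(ox) < 3L) stop("need >= 3 displacement origins to orient a cell")
  cv <- cov(cbind(ox, oy))
  if (!all(is.finite(cv)) || det(cv) <= 0 && sum(diag(cv)) == 0)
    stop("degenerate cluster: zero-variance origins")
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1]
  theta <- atan2(v[2], v[1])
  # orientation is defined mod pi; report in (-pi/2, pi/2]
  if (theta > pi / 2) theta <- theta - pi
  if (theta <= -pi / 2) theta <- theta + pi
  ambiguous <- eg$values[2] > 0 && eg$values[1] / eg$values[2] < isotropyTol
  ct <- cos(-theta); st <- sin(-theta)
  cx <- mean(ox); cy <- mean(oy)
  rot <- function(px, py)
    list(x = ct * (px - cx) - st * (py - cy),
         y = st * (px - cx) + ct * (py - cy))
  o <- rot(ox, oy)
  d <- displacements
  d$origin_x_nm <- o$x
  d$origin_y_nm <- o$y
  if (!is.null(d$end_x_nm)) {
    e <- rot(displacements$end_x_nm, displacements$end_y_nm)
    d$end_x_nm <- e$x
    d$end_y_nm <- e$y
  }
  rownames(d) <- NULL
  geomv <- c(length = diff(range(o$x)), width = diff(range(o$y))) / 1000
  new("CellRecord", id = as.integer(id), displacements = d,
      rotationAngle = theta, length = unname(geomv["length"]),
      width = unname(geomv["width"]), qc = "pass", qcReason = "",
      flags = list(axisAmbiguous = ambiguous))
}

#' Measure cell length and width from displacement origins
#'
#' Length is the x extent and width the y extent of the displacement origins
#' of a rotated cell.
#'
#' @param cell a [CellRecord-class] (rotated).
#' @return named numeric `c(length, width)` in micrometres.
#' @export
measureGeometry <- function(cell) {
  d <- displacements(cell)
  if (nrow(d) < 2L)
    stop("undefined geometry: need at least 2 displacement origins")
  c(length = diff(range(d$origin_x_nm)),
    width = diff(range(d$origin_y_nm))) / 1000
}

#' Filter cells by displacement count and manual annotations
#'
#' Keeps cells whose (already distance-filtered) displacement count lies in
#' `[minDisp, maxDisp]` (bounds inclusive) and which carry no truthy manual
#' QC flag (`edgeTruncated`, `adjacent`, `dividing`, `aggregating` — these
#' mirror visual-inspection criteria and are supplied by the caller, never
#' inferred). Rejected cells, with reasons recorded, are attached as
#' attribute `"rejected"`.
#'
#' @param cells list of [CellRecord-class] objects.
#' @param minDisp,maxDisp inclusive count bounds (defaults 2000 and 20000).
#' @return list of passing cells (attribute `"rejected"` holds the rest).
#' @export
qcFilter <- function(cells, minDisp = 2000, maxDisp = 20000) {
  manual <- c("edgeTruncated", "adjacent", "dividing", "aggregating")
  kept <- list()
  rejected <- list()
  for (cell in cells) {
    n <- nrow(displacements(cell))
    reason <- ""
    if (n < minDisp) reason <- sprintf("too few displacements (%d < %g)", n,
                                       minDisp)
    else if (n > maxDisp) reason <- sprintf("too many displacements (%d > %g)",
                                            n, maxDisp)
    else {
      bad <- manual[vapply(manual, function(f) isTRUE(cell@flags[[f]]),
                           logical(1))]
      if (length(bad)) reason <- paste("manual flag:", bad[1])
    }
    if (nzchar(reason)) {
      cell@qc <- "fail"
      cell@qcReason <- reason
      rejected[[length(rejected) + 1L]] <- cell
    } else {
      cell@qc <- "pass"
      cell@qcReason <- ""
      kept[[length(kept) + 1L]] <- cell
    }
  }
  attr(kept, "rejected") <- rejected
  kept
}

#' Partition a cell's displacements into left pole, center, right pole
#'
#' Each pole spans `poleFraction` of the measured cell length from the
#' outermost origin x coordinates; assignment is by displacement origin, with
#' boundary ties going to the poles. For the median cell geometry
#' (0.45-um radius, 2.25-um length) the default fraction 0.20 equals
#' radius / length, i.e. each pole region covers one hemispherical cap.
#'
#' @param cell a rotated [CellRecord-class].
#' @param poleFraction fraction of the total length per pole (< 0.5).
#' @return a [RegionPartition-class].
#' @export
partitionRegions <- function(cell, poleFraction = 0.20) {
  if (poleFraction >= 0.5)
    stop("invalid poleFraction: poles would overlap (must be < 0.5)")
  if (poleFraction <= 0) stop("poleFraction must be > 0")
  d <- displacements(cell)
  if (nrow(d) == 0L) stop("empty cell: no displacements to partition")
  x <- d$origin_x_nm
  xmin <- min(x); xmax <- max(x)
  len <- xmax - xmin
  lb <- xmin + poleFraction * len
  rb <- xmax - poleFraction * len
  left <- x <= lb
  right <- !left & x >= rb
  center <- !left & !right
  new("RegionPartition",
      left = d[left, , drop = FALSE],
      center = d[center, , drop = FALSE],
      right = d[right, , drop = FALSE],
      poleFraction = poleFraction, bounds = c(lb, rb))
}
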