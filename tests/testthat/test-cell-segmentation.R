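test_that("a single dense cloud forms one cluster containing its points", {
  set.seed(14)
  n <- 800
  loc <- data.frame(x_nm = runif(n, 0, 2000), y_nm = runif(n, 0, 700))
  cl <- clusterCells(loc, minPoints = 300)
  expect_length(cl, 1L)
  # the density threshold trims sparse hull/edge points; the bulk of the
  # cloud must end up in the single cluster
  expect_gt(length(cl[[1]]), 0.75 * n)

  expect_identical(clusterCells(loc[0, ]), list())
  collinear <- data.frame(x_nm = as.numeric(1:50), y_nm = rep(1, 50))
  expect_error(clusterCells(collinear, minPoints = 5), "tessellation error")
})

test_that("two-cell fields are segmented with high membership agreement", {
  purity <- numeric(0)
  for (s in 1:20) {
    field <- twoCellField(100L + s)
    cl <- clusterCells(field, minPoints = 300)
    expect_length(cl, 2L)
    lab <- rep(NA_integer_, nrow(field))
    for (i in seq_along(cl)) lab[cl[[i]]] <- i
    assigned <- !is.na(lab) & !is.na(field$cell)
    tab <- table(field$cell[assigned], lab[assigned])
    purity <- c(purity, sum(apply(tab, 1, max)) / sum(tab))
  }
  expect_gte(mean(purity), 0.99)
})

test_that("major-axis rotation recovers known orientations within 1 degree", {
  set.seed(15)
  n <- 2000
  ox <- rnorm(n, 0, 700)
  oy <- rnorm(n, 0, 150)
  aligned <- dispFrame(ox, oy)
  cell0 <- rotateToMajorAxis(aligned)
  expect_lt(abs(rotationAngle(cell0)) * 180 / pi, 1)

  th <- 37 * pi / 180
  rotated <- dispFrame(cos(th) * ox - sin(th) * oy,
                       sin(th) * ox + cos(th) * oy)
  cell37 <- rotateToMajorAxis(rotated)
  expect_lt(abs(rotationAngle(cell37) * 180 / pi - 37), 1)
})

test_that("rotation is an isometry and is idempotent", {
  set.seed(16)
  n <- 300
  d <- dispFrame(rnorm(n, 0, 600), rnorm(n, 0, 200))
  d$end_x_nm <- d$origin_x_nm + rnorm(n, 0, 50)
  d$end_y_nm <- d$origin_y_nm + rnorm(n, 0, 50)
  d$r_nm <- sqrt((d$end_x_nm - d$origin_x_nm)^2 +
                 (d$end_y_nm - d$origin_y_nm)^2)
  cell <- rotateToMajorAxis(d)
  rd <- displacements(cell)
  # displacement vectors keep their length under rotation
  expect_equal(sqrt((rd$end_x_nm - rd$origin_x_nm)^2 +
                    (rd$end_y_nm - rd$origin_y_nm)^2), d$r_nm,
               tolerance = 1e-10)
  # pairwise origin distances preserved (spot check)
  i <- 1:50; j <- 51:100
  before <- sqrt((d$origin_x_nm[i] - d$origin_x_nm[j])^2 +
                 (d$origin_y_nm[i] - d$origin_y_nm[j])^2)
  after <- sqrt((rd$origin_x_nm[i] - rd$origin_x_nm[j])^2 +
                (rd$origin_y_nm[i] - rd$origin_y_nm[j])^2)
  expect_equal(after, before, tolerance = 1e-10)

  again <- rotateToMajorAxis(displacements(cell))
  expect_lt(abs(rotationAngle(again)) * 180 / pi, 1)
})

test_that("near-isotropic clouds are flagged as ambiguous", {
  set.seed(17)
  iso <- dispFrame(rnorm(5000, 0, 300), rnorm(5000, 0, 300))
  cell <- rotateToMajorAxis(iso)
  expect_true(cell@flags$axisAmbiguous)
  expect_error(rotateToMajorAxis(iso[1:2, ]), ">= 3")
})

test_that("QC keeps cells inside the displacement-count window", {
  mk <- function(n, id) makeCellRecord(dispFrame(seq_len(n), rep(0, n)),
                                       id = id)
  cells <- list(mk(1999, 1L), mk(2000, 2L), mk(20000, 3L), mk(20001, 4L))
  kept <- qcFilter(cells)
  expect_equal(vapply(kept, function(cl) cl@id, integer(1)), c(2L, 3L))
  rej <- attr(kept, "rejected")
  expect_equal(vapply(rej, function(cl) cl@id, integer(1)), c(1L, 4L))
  expect_match(rej[[1]]@qcReason, "too few")
  expect_match(rej[[2]]@qcReason, "too many")

  counts <- c(1999, 2000, 20000, 20001)
  expect_equal(sum(counts >= 2000 & counts <= 20000), length(kept))

  expect_identical(qcFilter(list()), structure(list(), rejected = list()))

  flagged <- makeCellRecord(dispFrame(seq_len(5000), rep(0, 5000)), id = 5L,
                            flags = list(aggregating = TRUE))
  kept2 <- qcFilter(list(flagged))
  expect_length(kept2, 0L)
  expect_match(attr(kept2, "rejected")[[1]]@qcReason, "aggregating")
})

test_that("region partitioning is complete, disjoint, and pole-inclusive", {
  set.seed(18)
  ox <- c(-1125, 1125, 0, runif(500, -1125, 1125))
  cell <- makeCellRecord(dispFrame(ox, rnorm(length(ox), 0, 100)))
  part <- partitionRegions(cell, 0.20)
  n <- regionCounts(part)
  expect_equal(sum(n), length(ox))
  # 2.25-um cell: each pole spans 450 nm of x
  expect_equal(unname(part@bounds), c(-1125 + 450, 1125 - 450))
  # extreme origins are poles, the centroid is center
  expect_true(-1125 %in% part@left$origin_x_nm)
  expect_true(1125 %in% part@right$origin_x_nm)
  expect_true(0 %in% part@center$origin_x_nm)
  # boundary tie goes to the pole
  cellB <- makeCellRecord(dispFrame(c(0, 1000, 200), c(0, 0, 0)))
  partB <- partitionRegions(cellB, 0.20)
  expect_true(200 %in% partB@left$origin_x_nm)

  expect_error(partitionRegions(cell, 0.5), "overlap")
})

test_that("geometry is measured from displacement origins", {
  cell <- makeCellRecord(dispFrame(c(-1125, 1125), c(0, 10)))
  g <- measureGeometry(cell)
  expect_equal(unname(g["length"]), 2.25)
  one <- new("CellRecord", id = 1L, displacements = dispFrame(0, 0),
             rotationAngle = 0, length = 0, width = 0, qc = "pass",
             qcReason = "", flags = list())
  expect_error(measureGeometry(one), "undefined geometry")
})

test_that("a densely sampled median cell measures near its true size", {
  disp <- medianCellDisplacements(5, 21)
  cell <- makeCellRecord(disp)
  g <- measureGeometry(cell)
  expect_lt(abs(g["length"] - 2.25) / 2.25, 0.05)
  expect_lt(abs(g["width"] - 0.90) / 0.90, 0.05)
})
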