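test_that("log-spaced bands are geometric between the printed limits", {
  edges <- logSpacedBands()
  expect_length(edges, 11)
  expect_equal(edges[1], 1)
  expect_equal(edges[11], 8)
  ratios <- edges[-1] / edges[-11]
  expect_equal(ratios, rep(8^(1 / 10), 10))
  expect_equal(logSpacedBands(nBands = 1), c(1, 8))
  expect_error(logSpacedBands(nBands = 0), "nBands")
})

test_that("distance maps are multi-source geodesics with zero at seeds", {
  grid <- flatGridMesh(15, 10)
  seeds <- which(meshVertices(grid)[, 1] == 0)  # left column as a line
  dm <- corticalDistanceMap(grid, seeds)
  expect_true(all(dm@distance[seeds] == 0))
  # on a regular grid the graph distance to a straight seed line equals the
  # perpendicular Euclidean distance (grid edges realize it exactly)
  expect_equal(dm@distance, meshVertices(grid)[, 1], tolerance = 1e-12)
  # shortest-path property: |d(u) - d(v)| <= edge length on every edge
  f <- meshFaces(grid)
  edges <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)]))
  len <- sqrt(rowSums((meshVertices(grid)[edges[, 1], ] -
                       meshVertices(grid)[edges[, 2], ])^2))
  expect_true(all(abs(dm@distance[edges[, 1]] - dm@distance[edges[, 2]]) <=
                    len + 1e-9))
})

test_that("meridian line vertices lie on the meridian and span the range", {
  ret <- groundTruthRetinotopy(isoLeft)
  line <- meridianLineVertices(ret, isoLeft, "HM", angleTol = 2)
  expect_true(all(cortmag:::angularOffset(polarAngles(isoLeft)[line], 0)
                  <= 2))
  ecc <- eccentricities(isoLeft)[line]
  expect_lt(min(ecc), 1)
  expect_gt(max(ecc), 8)
  # a mesh without a spoke exactly on the meridian has a measure-zero line
  offMesh <- makeSyntheticHemisphere(isoModel, 31, 24, hemisphere = "left")
  retOff <- groundTruthRetinotopy(offMesh)
  expect_error(meridianLineVertices(retOff, offMesh, "HM", angleTol = 1e-9),
               "angleTol")
})

test_that("iso-angle boundary distance averages the pooled vertices", {
  # pool with constant distance d returns d
  ret <- fakeRetinotopy(angle = rep(15, 20), ecc = runif(20, 1, 2))
  dm <- new("DistanceMap", distance = rep(3.5, 20), meridian = "HM")
  expect_equal(isoangleBoundaryDistance(c(1, 2), dm, ret, 0), 3.5)
  # offsets uniform over [7, 23] with distance = offset / c gives 15 / c
  off <- seq(7, 23, length.out = 33)
  ret2 <- fakeRetinotopy(angle = off, ecc = rep(1.5, 33))
  cc <- 4
  dm2 <- new("DistanceMap", distance = off / cc, meridian = "HM")
  expect_equal(isoangleBoundaryDistance(c(1, 2), dm2, ret2, 0), 15 / cc)
  # empty pool (band holds no vertices) is invalid even after widening
  expect_true(is.na(isoangleBoundaryDistance(c(5, 6), dm2, ret2, 0)))
})

test_that("wedge masks honour boundaries and grow with the boundary angle", {
  ret <- groundTruthRetinotopy(isoLeft)
  seeds <- meridianLineVertices(ret, isoLeft, "HM", angleTol = 2.5)
  dm <- corticalDistanceMap(isoLeft, seeds, "HM")
  mask15 <- buildWedgeMask(dm, ret, isoLeft, "HM")
  # ground-truth angular offsets of masked vertices stay near +/-15 deg
  offs <- cortmag:::angularOffset(polarAngles(isoLeft)[mask15@vertices], 0)
  expect_gte(mean(offs <= 15 + 1e-9), 0.95)
  # widening the wedge gives a superset
  mask20 <- buildWedgeMask(dm, ret, isoLeft, "HM",
                           wedgeConfig(halfWidth = 20))
  expect_true(all(mask15@vertices %in% mask20@vertices))
  # zero boundaries collapse the mask onto the meridian line
  dm0 <- dm
  zeroMask <- new("WedgeROIMask", meridian = "HM", hemisphere = "left",
                  vertices = mask15@vertices[
                    dm@distance[mask15@vertices] <= 0],
                  boundaryDistance = rep(0, 10))
  expect_true(all(cortmag:::angularOffset(
    polarAngles(isoLeft)[zeroMask@vertices], 0) <= 2.5))
})

test_that("wedge surface area sums vertex areas and is additive", {
  mask <- new("WedgeROIMask", meridian = "HM", hemisphere = "left",
              vertices = 1:5, boundaryDistance = rep(1, 10))
  expect_equal(wedgeSurfaceArea(mask, isoLeft),
               sum(vertexAreas(isoLeft)[1:5]))
  # left + right hemisphere areas add exactly
  wa <- wedgeAreasByMeridian(isoLeft, isoRight)
  expect_equal(wa$combined[["HM"]],
               sum(wa$perHemisphere$area[wa$perHemisphere$meridian == "HM"]))
  expect_equal(wa$combined[["VM"]],
               wa$combined[["UVM"]] + wa$combined[["LVM"]])
})

test_that("meridian combination sums hemifield halves and flags gaps", {
  df <- expand.grid(hemisphere = c("left", "right"),
                    meridian = c("HM", "UVM", "LVM"),
                    stringsAsFactors = FALSE)
  df$area <- 10
  out <- combineMeridianAreas(df)
  expect_equal(unname(out["HM"]), 20)
  expect_equal(unname(out["VM"]), 40)
  expect_error(combineMeridianAreas(df[-1, ]), "missing")
  dfz <- df; dfz$area[dfz$meridian == "UVM"] <- 0
  outz <- combineMeridianAreas(dfz)
  expect_equal(unname(outz["VM"]), unname(outz["LVM"]))
})

test_that("the four wedges are pairwise disjoint on the synthetic mesh", {
  for (mesh in list(isoLeft, isoRight)) {
    ret <- groundTruthRetinotopy(mesh)
    masks <- lapply(c("HM", "UVM", "LVM"), function(m) {
      seeds <- meridianLineVertices(ret, mesh, m, angleTol = 3)
      buildWedgeMask(corticalDistanceMap(mesh, seeds, m), ret, mesh, m)
    })
    for (i in 1:2) for (j in (i + 1):3)
      expect_length(intersect(masks[[i]]@vertices, masks[[j]]@vertices), 0)
  }
})

test_that("wedge area matches the analytic integral, improving with resolution", {
  an <- analyticSectorArea(isoModel, c(-15, 15), c(1, 8))
  # grid spacing halves at each rung of the ladder
  err <- vapply(list(c(31, 21), c(61, 45), c(121, 91)), function(res) {
    m <- makeSyntheticHemisphere(isoModel, res[1], res[2],
                                 hemisphere = "left")
    ret <- groundTruthRetinotopy(m)
    seeds <- meridianLineVertices(ret, m, "HM", angleTol = 3)
    mask <- buildWedgeMask(corticalDistanceMap(m, seeds, "HM"), ret, m, "HM")
    abs(wedgeSurfaceArea(mask, m) / an - 1)
  }, numeric(1))
  expect_lt(err[3], 0.03)
  expect_true(all(diff(err) < 0))
})

test_that("V1 size uses the 0-8 deg limit and degenerates sensibly", {
  expect_equal(v1TotalArea(isoLeft, eccMax = 13), sum(vertexAreas(isoLeft)))
  expect_equal(v1TotalArea(isoLeft, eccMax = 0.1), 0)
  an <- analyticSectorArea(isoModel, c(-90, 90), c(0.2, 8))
  expect_equal(v1TotalArea(isoLeft), an, tolerance = 0.03)
})
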