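test_that("ascii grid round-trips through disk", {
  g <- DepthGrid(matrix(round(runif(20, 500, 600), 3), 4, 5),
                 cellSize = 2, xll = 10, yll = 20)
  path <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(g, path)
  g2 <- readAsciiGrid(path)
  expect_equal(gridValues(g2), gridValues(g), ignore_attr = TRUE)
  expect_equal(cellSize(g2), 2)
  expect_equal(g2@xll, 10)
  expect_equal(g2@yll, 20)
})

test_that("interpolation honours nearest and idw semantics", {
  g <- DepthGrid(matrix(0, 5, 5), cellSize = 1)
  one <- data.frame(x = 2.1, y = 3.3, value = 7)
  expect_true(all(gridValues(interpolateToGrid(one, g, "nearest")) == 7))
  expect_equal(gridValues(interpolateToGrid(one, g, "idw")),
               matrix(7, 5, 5), tolerance = 1e-12)

  ## a point on a cell centre pins that cell under nearest
  pts <- data.frame(x = c(0.5, 4.5), y = c(4.5, 0.5), value = c(1, 9))
  nv <- gridValues(interpolateToGrid(pts, g, "nearest"))
  expect_equal(nv[1, 1], 1)    # top-left centre is (0.5, 4.5)
  expect_equal(nv[5, 5], 9)

  ## two equidistant idw points average at the midpoint cell centre
  pts2 <- data.frame(x = c(0.5, 4.5), y = c(2.5, 2.5), value = c(1, 3))
  iv <- gridValues(interpolateToGrid(pts2, g, "idw"))
  expect_equal(iv[3, 3], 2)
  expect_error(interpolateToGrid(pts2[0, ], g), "at least one")
})

test_that("annual NPP sums twelve months under both conventions", {
  expect_equal(annualNpp(rep(0, 12)), 0)
  expect_equal(annualNpp(rep(10, 12)), 120)
  expect_equal(annualNpp(rep(10, 12), convention = "mean_times_days"),
               3650)
  expect_error(annualNpp(rep(10, 11)), "12")
  expect_error(annualNpp(c(rep(10, 11), -1)), "negative")
})

test_that("export flux attenuates exponentially to a refractory floor", {
  pars <- list(prd = 0.1, rld = 800, prr = 0.015)
  npp <- 1000
  expect_equal(exportFlux(npp, 0, pars), npp * (0.1 + 0.015))
  expect_equal(exportFlux(npp, 800, pars), npp * (0.1 / exp(1) + 0.015))
  expect_lt(exportFlux(npp, 2000, pars), exportFlux(npp, 500, pars))
  ## linear in npp
  expect_equal(exportFlux(2 * npp, 123, pars),
               2 * exportFlux(npp, 123, pars))
  expect_error(exportFlux(npp, 100, list(prd = 0.1, rld = 0,
                                         prr = 0.01)), "rld")
})

test_that("terrain indices match closed forms", {
  flat <- DepthGrid(matrix(1000, 6, 6), cellSize = 1)
  expect_true(all(gridValues(terrainSlope(flat)) == 0))
  expect_true(all(gridValues(terrainTri(flat)) == 0))
  expect_true(all(gridValues(terrainTpi(flat)) == 0))

  spike <- matrix(1, 3, 3)
  spike[2, 2] <- 9
  g <- DepthGrid(spike, cellSize = 1)
  expect_equal(gridValues(terrainTpi(g))[2, 2], 8)
  expect_equal(gridValues(terrainTri(g))[2, 2], 8)

  ## inclined plane depth = g x: slope = atan(g), interior TPI = 0
  grad <- 0.25
  plane <- DepthGrid(outer(rep(1, 8), grad * (1:8)), cellSize = 1)
  sl <- gridValues(terrainSlope(plane))[3:6, 3:6]
  expect_equal(sl, matrix(atan(grad) * 180 / pi, 4, 4),
               tolerance = 1e-10)
  expect_equal(gridValues(terrainTpi(plane))[3:6, 3:6],
               matrix(0, 4, 4), tolerance = 1e-12)
})

test_that("terrain indices agree with direct-definition oracles on random grids", {
  set.seed(77)
  for (r in 1:5) {
    m <- matrix(rnorm(100, 1000, 5), 10, 10)
    cs <- runif(1, 0.5, 3)
    g <- DepthGrid(m, cellSize = cs)
    sl <- gridValues(terrainSlope(g))
    tri <- gridValues(terrainTri(g))
    tpi <- gridValues(terrainTpi(g))
    for (i in 2:9) for (j in 2:9) {
      expect_equal(sl[i, j], oracle_slope_deg(m, cs, i, j),
                   tolerance = 1e-10)
      expect_equal(tri[i, j], oracle_tri(m, i, j), tolerance = 1e-10)
      expect_equal(tpi[i, j], oracle_tpi(m, i, j), tolerance = 1e-10)
    }
  }
})

test_that("interior TPI sums to zero over whole periods of a sinusoid", {
  P <- 16L
  x <- seq_len(P + 2L)
  z <- outer(rep(1, 12), sin(2 * pi * x / P))
  g <- DepthGrid(z, cellSize = 1)
  tpi <- gridValues(terrainTpi(g))[2:11, 2:(P + 1L)]
  expect_lt(abs(sum(tpi)) / sum(abs(tpi)), 1e-9)
})

test_that("extraction looks up the containing cell and flags out-of-bounds", {
  m <- matrix(seq_len(12), 3, 4)
  g <- DepthGrid(m, cellSize = 10, xll = 100, yll = 200)
  co <- data.frame(sample = c("a", "b"),
                   x = c(105, 135), y = c(225, 205))
  out <- extractAtSamples(list(v = g), co)
  expect_equal(out$v, c(m[1, 1], m[3, 4]))

  const <- DepthGrid(matrix(5, 3, 4), cellSize = 10, xll = 100,
                     yll = 200)
  expect_true(all(extractAtSamples(list(v = const), co)$v == 5))
  bad <- data.frame(sample = "oops", x = 99, y = 225)
  expect_error(extractAtSamples(list(v = g), bad), "oops")
})
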