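waterGrid <- function(n = 40, sp = 2) voxelGrid(array(1, dim = rep(n, 3)), sp)

test_that("radiological depth equals geometric depth in uniform water", {
  g <- waterGrid()
  geo <- fieldGeometry(0)
  ## entry face at x = -40 mm; voxel (26, 20, 20) centre at x = 11 mm
  expect_equal(radiologicalDepth(g, geo, c(26, 20, 20)), 51, tolerance = 1e-9)
})

test_that("radiological depth scales with slab density", {
  d <- array(1, dim = c(40, 40, 40))
  d[1:10, , ] <- 0.3                      # 20 mm slab at the entry face
  g <- voxelGrid(d, 2)
  geo <- fieldGeometry(0)
  ## voxel (15,20,20): centre x = -11, i.e. 9 mm past the slab
  expect_equal(radiologicalDepth(g, geo, c(15, 20, 20)), 0.3 * 20 + 9,
               tolerance = 0.05)
})

test_that("depth on heterogeneous grids matches fine-step ray marching", {
  set.seed(21)
  ## smooth random density field (low-frequency modulation of water)
  n <- 30
  ax <- seq_len(n)
  base <- outer(sin(ax / 4), cos(ax / 5))
  vals <- array(0.8, dim = rep(n, 3))
  for (k in ax) vals[, , k] <- 0.8 + 0.35 * base * sin(k / 6)
  g <- voxelGrid(vals, 3)
  for (ang in c(0, 37, 90, 205)) {
    geo <- fieldGeometry(ang)
    fr <- flashPBS:::beamFrame(geo)
    for (vox in list(c(15, 15, 15), c(20, 10, 18), c(8, 22, 5))) {
      target <- gridOrigin(g) + (vox - 1) * gridSpacing(g)
      expected <- oracleRayDepth(g, fr$b, target, step = 0.1)
      got <- radiologicalDepth(g, geo, vox)
      expect_lt(abs(got - expected), 0.02 * max(expected, 1),
                label = sprintf("angle %g voxel %s", ang,
                                paste(vox, collapse = ",")))
    }
  }
})

test_that("batch field context agrees with per-voxel ray marching", {
  set.seed(22)
  n <- 24
  vals <- array(0.7 + 0.3 * runif(1), dim = rep(n, 3))
  vals[, 1:8, ] <- 0.4
  g <- voxelGrid(vals, 3)
  for (ang in c(0, 90, 180, 270, 30)) {
    geo <- fieldGeometry(ang)
    rows <- c(5000L, 7000L, 9000L)
    ctx <- flashPBS:::fieldContext(g, geo, rows)
    for (j in seq_along(rows)) {
      vox <- arrayInd(rows[j], rep(n, 3))[1, ]
      expect_equal(ctx$rdepth[j], radiologicalDepth(g, geo, vox),
                   tolerance = 0.03,
                   label = sprintf("angle %g row %d", ang, rows[j]))
    }
  }
})

test_that("a degenerate double Gaussian reduces to the single Gaussian", {
  g <- waterGrid(30)
  geo <- fieldGeometry(0)
  single <- beamModel("electron", 200, "single_gaussian", sigma1Mm = 5,
                      sigmaGrowthMmPerMm = 0.07)
  degen <- beamModel("electron", 200, "double_gaussian", sigma1Mm = 5,
                     sigma2Mm = 15, weight1 = 1, sigmaGrowthMmPerMm = 0.07)
  c1 <- spotDoseColumn(g, geo, single, c(3, -2))
  c2 <- spotDoseColumn(g, geo, degen, c(3, -2))
  expect_equal(as.numeric(c1), as.numeric(c2), tolerance = 1e-12)
})

test_that("the on-axis column value matches the closed form", {
  g <- waterGrid()
  geo <- fieldGeometry(0)
  m <- defaultVheeModel(200)
  col <- spotDoseColumn(g, geo, m, c(1, 1))
  ctx <- flashPBS:::fieldContext(g, geo)
  i <- which(ctx$u == 1 & ctx$v == 1 & ctx$w == 11)   # on the spot axis
  rd <- ctx$rdepth[i]
  lat <- m@lateral
  s1 <- lat$sigma1Mm + lat$sigmaGrowthMmPerMm * rd
  s2 <- lat$sigma2Mm + lat$sigmaGrowthMmPerMm * rd
  pred <- m@calibrationGyPerMU * flashPBS:::pddFun(m)(rd) *
    (lat$weight1 / (2 * pi * s1^2) + (1 - lat$weight1) / (2 * pi * s2^2))
  expect_equal(as.numeric(col[i]), pred, tolerance = 1e-9)
})

test_that("the lateral mixture is normalized and fluence is conserved", {
  ## numeric quadrature of the 2-D mixture on a wide plane
  h <- 0.5
  xs <- seq(-120, 120, by = h)
  r2 <- outer(xs^2, xs^2, "+")
  mix <- flashPBS:::lateralMixture(r2, sigma1 = 5, sigma2 = 15, weight1 = 0.9)
  expect_equal(sum(mix) * h^2, 1, tolerance = 0.01)
  ## transverse-plane sum of a real column at fixed depth
  g <- waterGrid(50)
  geo <- fieldGeometry(0)
  m <- defaultProtonModel()
  col <- spotDoseColumn(g, geo, m, c(0, 0))
  ctx <- flashPBS:::fieldContext(g, geo)
  sl <- which(ctx$w == 1)                 # one transverse plane
  planeSum <- sum(as.numeric(col[sl])) * prod(gridSpacing(g)[2:3])
  expect_equal(planeSum,
               m@calibrationGyPerMU * flashPBS:::pddFun(m)(ctx$rdepth[sl][1]),
               tolerance = 0.02)
})

test_that("proton lateral width grows with depth and VHEE PDDs order correctly", {
  g <- waterGrid(50)
  geo <- fieldGeometry(0)
  m <- defaultProtonModel()
  col <- spotDoseColumn(g, geo, m, c(0, 0))
  ctx <- flashPBS:::fieldContext(g, geo)
  widthAt <- function(w0) {
    sl <- which(ctx$w == w0)
    v <- as.numeric(col[sl])
    sqrt(sum(v * (ctx$u[sl]^2 + ctx$v[sl]^2)) / (2 * sum(v)))
  }
  expect_gt(widthAt(47), widthAt(-47))
  pdd150 <- flashPBS:::pddFun(defaultVheeModel(150))
  pdd200 <- flashPBS:::pddFun(defaultVheeModel(200))
  depths <- seq(30, 200, by = 10)
  drop150 <- pdd150(30) - pdd150(depths)
  drop200 <- pdd200(30) - pdd200(depths)
  expect_true(all(drop150 >= drop200))
  expect_gt(drop150[length(depths)], drop200[length(depths)])
})

test_that("a spot missing the body yields an empty column", {
  d <- array(0, dim = c(20, 20, 20))
  d[8:12, 8:12, 8:12] <- 1
  g <- voxelGrid(d, 2)
  col <- spotDoseColumn(g, fieldGeometry(0), defaultProtonModel(), c(500, 500))
  expect_equal(sum(as.numeric(col) != 0), 0)
})

test_that("beam models round-trip through JSON", {
  m <- defaultVheeModel(150)
  f <- withr::local_tempfile(fileext = ".json")
  writeBeamModel(m, f)
  r <- readBeamModel(f)
  expect_equal(r@lateral, m@lateral)
  expect_equal(r@pdd, m@pdd)
  expect_identical(r@particle, m@particle)
})
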