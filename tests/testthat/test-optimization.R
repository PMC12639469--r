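test_that("the objective matches its closed forms and a naive oracle", {
  ph <- tinyWaterPhantom()
  st <- ph$structures
  n <- gridDims(ph$density)
  ## every objective satisfied -> 0
  dose <- voxelGrid(array(20, dim = n), gridSpacing(ph$density))
  sc0 <- scorecard(c("PTV", "OAR1"), c("min_dose", "max_dose"), c(19, 21),
                   c(10, 10))
  expect_equal(objectiveValue(dose, sc0, st), 0)
  ## single max_dose objective violated by exactly 1 Gy everywhere
  sc1 <- scorecard("OAR1", "max_dose", 19, priority = 7)
  expect_equal(objectiveValue(dose, sc1, st), 7 * 1)
  ## random dose vs per-voxel loop oracle
  set.seed(41)
  rdose <- voxelGrid(array(runif(prod(n), 0, 40), dim = n),
                     gridSpacing(ph$density))
  sc <- scorecard(c("PTV", "PTV", "OAR1", "BODY"),
                  c("uniform", "min_dose", "max_dose", "mean_dose_max"),
                  c(30, 28, 15, 8), c(50, 100, 5, 1))
  expect_equal(objectiveValue(rdose, sc, st),
               oracleObjective(gridValues(rdose), sc, st))
  expect_error(objectiveValue(rdose, scorecard("NOPE", "max_dose", 1), st),
               "unknown structure")
})

## small but real fitting problem shared by the recovery tests
fitFixture <- function() {
  ph <- tinyWaterPhantom(n = 20, spacingMm = 5)
  geo <- fieldGeometry(0)
  model <- defaultProtonModel()
  spots <- expand.grid(u = seq(-10, 10, 5), v = seq(-10, 10, 5))
  spots$weight <- 0; spots$fieldId <- 1L
  rows <- which(structureMask(ph$structures, "PTV") |
                  structureMask(ph$structures, "OAR1"))
  A <- flashPBS:::directSpotMatrix(ph$density, geo, model, spots,
                                   rows = rows)
  list(ph = ph, A = A, rows = rows, spots = spots)
}

test_that("weights are recovered when the target dose is representable", {
  fx <- fitFixture()
  set.seed(42)
  wStar <- runif(nrow(fx$spots), 5, 15)
  dStar <- as.numeric(fx$A@matrix %*% wStar)
  ## one single-voxel "structure" per scored voxel, each with a uniform
  ## objective at its achievable dose -> least-squares dose matching
  dims <- gridDims(fx$ph$density)
  masks <- list(BODY = array(TRUE, dims),
                PTV = structureMask(fx$ph$structures, "PTV"))
  pick <- seq(1, length(fx$rows), by = 4)
  scRows <- NULL
  for (j in pick) {
    m <- array(FALSE, dims); m[fx$rows[j]] <- TRUE
    masks[[paste0("vox", j)]] <- m
    scRows <- rbind(scRows,
                    scorecard(paste0("vox", j), "uniform", dStar[j]))
  }
  st <- structureSet(masks, fx$ph$density)
  res <- optimizeWeights(fx$A, scRows, st, tol = 1e-10, maxIter = 2000L)
  dFit <- as.numeric(fx$A@matrix %*% res@weights)
  rms <- sqrt(mean((dFit[pick] - dStar[pick])^2)) /
    sqrt(mean(dStar[pick]^2))
  expect_lt(rms, 1e-3)
  expect_true(all(diff(res@trace) <= 1e-9))        # monotone trace
})

test_that("an empty scorecard returns the initial weights untouched", {
  fx <- fitFixture()
  sc <- scorecard(character(), character(), numeric(), numeric())
  init <- runif(nrow(fx$spots))
  res <- optimizeWeights(fx$A, sc, fx$ph$structures, init = init)
  expect_identical(res@weights, init)
  expect_equal(res@trace, 0)
})

test_that("rescaling all priorities leaves the optimized dose unchanged", {
  fx <- fitFixture()
  sc <- scorecard(c("PTV", "PTV", "OAR1"),
                  c("uniform", "min_dose", "max_dose"),
                  c(30, 28.5, 15), c(50, 100, 5))
  sc10 <- sc; sc10$priority <- sc10$priority * 10
  r1 <- optimizeWeights(fx$A, sc, fx$ph$structures, tol = 1e-9,
                        maxIter = 800L)
  r2 <- optimizeWeights(fx$A, sc10, fx$ph$structures, tol = 1e-9,
                        maxIter = 800L)
  d1 <- as.numeric(fx$A@matrix %*% r1@weights)
  d2 <- as.numeric(fx$A@matrix %*% r2@weights)
  expect_equal(d1, d2, tolerance = 1e-5)
})

test_that("an all-zero influence matrix is rejected", {
  fx <- fitFixture()
  A0 <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                             dims = dim(fx$A@matrix))
  expect_error(optimizeWeights(A0,
                               scorecard("PTV", "uniform", 30),
                               fx$ph$structures, rows = fx$rows),
               "all-zero")
})

test_that("position refinement only ever improves the objective", {
  ph <- tinyWaterPhantom(n = 20, spacingMm = 5)
  geo <- fieldGeometry(0)
  model <- defaultProtonModel()
  spots <- data.frame(u = c(-4.4, 3.6), v = c(0.8, -1.2), weight = 0,
                      fieldId = 1L)
  rows <- which(structureMask(ph$structures, "PTV"))
  M <- buildInfluence(ph$density, ph$structures, geo, model,
                      rows = rows, nodes = nodesForSpots(spots, 2, 6))
  sc <- scorecard(c("PTV", "PTV"), c("uniform", "min_dose"), c(30, 28.5),
                  c(50, 100))
  ref <- optimizePositions(spots, M, sc, ph$structures, rounds = 3L)
  expect_true(all(diff(ref$objectiveByRound) <= 1e-9))
  expect_true(all(ref$spots$weight >= 0))
})

test_that("an off-axis spot migrates toward a symmetric target's axis", {
  ph <- tinyWaterPhantom(n = 20, spacingMm = 5)
  geo <- fieldGeometry(0)
  model <- defaultProtonModel()
  dims <- gridDims(ph$density)
  ## two-voxel target symmetric about u = 5: one spot cannot dose both
  ## equally unless it sits on the symmetry axis
  tgt <- array(FALSE, dims); tgt[10, 11, 11] <- TRUE; tgt[10, 12, 11] <- TRUE
  ctr <- flashPBS:::voxelCentersMm(ph$density, which(tgt))
  uMid <- mean(ctr[, 2]); vTgt <- ctr[1, 3]
  st <- structureSet(list(BODY = array(TRUE, dims), PTV = tgt), ph$density)
  sc <- scorecard("PTV", "uniform", 20)
  spots <- data.frame(u = uMid + 1, v = vTgt, weight = 0, fieldId = 1L)
  M <- buildInfluence(ph$density, st, geo, model, rows = which(tgt),
                      nodes = nodesForSpots(spots, 2, 6))
  ref <- optimizePositions(spots, M, sc, st, rounds = 2L)
  expect_lt(abs(ref$spots$u - uMid), 1)            # moved toward the axis
  ## an already-centred spot stays put (zero gradient by symmetry)
  spots0 <- data.frame(u = uMid, v = vTgt, weight = 0, fieldId = 1L)
  M0 <- buildInfluence(ph$density, st, geo, model, rows = which(tgt),
                       nodes = nodesForSpots(spots0, 2, 6))
  ref0 <- optimizePositions(spots0, M0, sc, st, rounds = 2L)
  expect_equal(ref0$spots$u, uMid, tolerance = 1e-6)
  expect_equal(ref0$spots$v, vTgt, tolerance = 1e-6)
})
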