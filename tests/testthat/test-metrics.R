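boxMask <- function(dims, idx) { m <- array(FALSE, dims); m[idx] <- TRUE; m }

test_that("the DVH matches its closed forms and the counting oracle", {
  dims <- c(10, 10, 10)
  u <- voxelGrid(array(30, dims), 2)
  mask <- array(TRUE, dims)
  cv <- dvhCurve(u, mask, levels = c(0, 10, 29.9, 30, 35))
  expect_equal(cv@volumeFraction, c(1, 1, 1, 0, 0))   # strict >
  half <- array(c(rep(20, 500), rep(0, 500)), dims)
  cvh <- dvhCurve(voxelGrid(half, 2), mask, levels = 10)
  expect_equal(cvh@volumeFraction, 0.5)
  set.seed(61)
  r <- array(runif(1000, 0, 40), dims)
  lv <- seq(0, 45, by = 1.5)
  cvr <- dvhCurve(voxelGrid(r, 2), mask, levels = lv)
  expect_equal(cvr@volumeFraction, oracleDvh(r, mask, lv))
  expect_error(dvhCurve(u, array(FALSE, dims)), "empty mask")
})

test_that("the DRDVH never exceeds the DVH and hits its edge cases", {
  dims <- c(10, 10, 10)
  mask <- array(TRUE, dims)
  set.seed(62)
  dose <- voxelGrid(array(runif(1000, 0, 30), dims), 2)
  keep <- array(runif(1000) < 0.6, dims)
  fdose <- voxelGrid(gridValues(dose) * keep, 2)
  lv <- seq(0, 35, by = 2.5)
  dvh <- dvhCurve(dose, mask, lv)
  drdvh <- drdvhCurve(fdose, mask, lv)
  expect_true(all(drdvh@volumeFraction <= dvh@volumeFraction + 1e-12))
  same <- drdvhCurve(dose, mask, lv)
  expect_equal(same@volumeFraction, dvh@volumeFraction)
  zero <- drdvhCurve(voxelGrid(array(0, dims), 2), mask, lv)
  expect_true(all(zero@volumeFraction == 0))
})

test_that("dose quantiles follow the descending-sort convention", {
  dims <- c(2, 2, 1)
  g <- voxelGrid(array(c(10, 20, 30, 40), dims), 2)
  mask <- array(TRUE, dims)
  expect_equal(doseQuantile(g, mask, 50), 25)          # hand-interpolated
  u <- voxelGrid(array(30, c(4, 4, 4)), 2)
  for (x in c(2, 50, 95, 98))
    expect_equal(doseQuantile(u, array(TRUE, c(4, 4, 4)), x), 30)
  set.seed(63)
  rg <- voxelGrid(array(runif(64, 0, 50), c(4, 4, 4)), 2)
  m <- array(TRUE, c(4, 4, 4))
  expect_lte(doseQuantile(rg, m, 98), doseQuantile(rg, m, 95))
  expect_lte(doseQuantile(rg, m, 95), doseQuantile(rg, m, 2))
})

test_that("plan metrics reproduce closed-form conformity cases", {
  dims <- c(12, 12, 12)
  body <- array(TRUE, dims)
  ptv <- boxMask(dims, as.matrix(expand.grid(5:8, 5:8, 5:8)))
  st <- structureSet(list(BODY = body, PTV = ptv),
                     voxelGrid(array(1, dims), 2))
  ## prescription exactly on the PTV only
  dose <- voxelGrid(array(ifelse(ptv, 30, 0), dims), 2)
  pm <- planMetrics(dose, st, 30)
  ptvRow <- pm[pm$structure == "PTV", ]
  expect_equal(ptvRow$HI98, 1)
  expect_equal(ptvRow$CI95, 1)
  expect_equal(ptvRow$D2, ptvRow$D98)
  expect_equal(ptvRow$D2, ptvRow$Dmean)
  ## spill to twice the PTV volume at >= 95 % of prescription
  spill <- ptv
  spill[9:12, 5:8, 5:8] <- TRUE                        # same volume again
  dose2 <- voxelGrid(array(ifelse(spill, 30, 0), dims), 2)
  pm2 <- planMetrics(dose2, st, 30)
  expect_equal(pm2[pm2$structure == "PTV", "CI95"], 0.5)
  ## no voxel at the isodose -> NA
  pm3 <- planMetrics(voxelGrid(array(1, dims), 2), st, 30)
  expect_true(is.na(pm3[pm3$structure == "PTV", "CI95"]))
  ## random dose vs naive loop
  set.seed(64)
  rd <- array(runif(prod(dims), 0, 35), dims)
  pm4 <- planMetrics(voxelGrid(rd, 2), st, 30)
  d <- rd[ptv]
  expect_equal(pm4[pm4$structure == "PTV", "Dmean"], mean(d))
  expect_equal(pm4[pm4$structure == "PTV", "V10Gy_pct"],
               100 * sum(d > 10) / length(d))
  expect_equal(pm4[pm4$structure == "PTV", "D95"],
               unname(quantile(d, 0.05, type = 7)))
})

test_that("the FLASH index follows its definition and stays in [0, 1]", {
  dims <- c(10, 10, 10)
  mask <- array(TRUE, dims)
  hot <- array(2, dims); hot[3:7, 3:7, 3:7] <- 30
  dose <- voxelGrid(hot, 2)
  ## every voxel above 10 Gy delivered at UHDR
  full <- voxelGrid(hot * (hot > 10), 2)
  expect_equal(fiValue(flashIndex(dose, full, mask)), 1)
  ## no voxel above 10 Gy
  cold <- voxelGrid(array(9, dims), 2)
  expect_equal(fiValue(flashIndex(cold, voxelGrid(array(0, dims), 2), mask)), 0)
  ## counting oracle on random maps
  set.seed(65)
  d <- array(runif(1000, 0, 25), dims)
  f <- d * (array(runif(1000), dims) < 0.5)
  r <- flashIndex(voxelGrid(d, 2), voxelGrid(f, 2), mask)
  expect_equal(r@volDVH, sum(d > 10) / 1000)
  expect_equal(r@volDRDVH, sum(f > 10) / 1000)
  expect_equal(fiValue(r), sum(f > 10) / sum(d > 10))
  expect_gte(fiValue(r), 0); expect_lte(fiValue(r), 1)
  expect_error(flashIndex(voxelGrid(d, 2), voxelGrid(array(0, c(5, 5, 5)), 2),
                          mask), "mismatched")
})

test_that("the robustness scan is monotone in the dose-rate threshold", {
  dims <- c(10, 10, 10)
  mask <- array(TRUE, dims)
  set.seed(66)
  fieldDose <- list(voxelGrid(array(runif(1000, 0, 18), dims), 2),
                    voxelGrid(array(runif(1000, 0, 18), dims), 2))
  fieldRate <- list(voxelGrid(array(runif(1000, 0, 120), dims), 2),
                    voxelGrid(array(runif(1000, 0, 120), dims), 2))
  tab <- fiRobustnessScan(fieldDose, fieldRate, mask,
                          doseThresholdsGy = c(0, 5, 10, 20),
                          drThresholdsGyPerS = c(0, 30, 40, 70, 100))
  for (X in unique(tab$doseThresholdGy)) {
    sub <- tab[tab$doseThresholdGy == X, ]
    sub <- sub[order(sub$drThresholdGyPerS), ]
    expect_true(all(diff(sub$fi) <= 1e-12), label = paste("dose thr", X))
  }
  ## dr threshold 0 -> every voxel qualifies wherever VolDVH > 0
  at0 <- tab[tab$drThresholdGyPerS == 0 & tab$volDVH > 0, ]
  expect_true(all(abs(at0$fi - 1) < 1e-12))
  ## brute-force recount of one cell
  total <- voxelGrid(gridValues(fieldDose[[1]]) + gridValues(fieldDose[[2]]), 2)
  fmap <- gridValues(fieldDose[[1]]) * (gridValues(fieldRate[[1]]) >= 40) +
    gridValues(fieldDose[[2]]) * (gridValues(fieldRate[[2]]) >= 40)
  cell <- tab[tab$doseThresholdGy == 10 & tab$drThresholdGyPerS == 40, ]
  expect_equal(cell$volDVH, mean(gridValues(total) > 10))
  expect_equal(cell$volDRDVH, mean(fmap > 10))
})
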