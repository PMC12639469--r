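test_that("proton scheduling follows dwell + travel arithmetic", {
  m <- protonMachine(nozzleDoseRateMUPerS = 1000,
                     scanSpeedMmPerS = 1e4, spotSwitchOverheadS = 0)
  one <- data.frame(u = 0, v = 0, weight = 100)
  tl <- scheduleProton(one, m)
  expect_equal(tl@events$startS, 0)
  expect_equal(tl@events$durationS, 0.1)
  two <- data.frame(u = c(0, 10), v = c(0, 0), weight = c(100, 50))
  tl2 <- scheduleProton(two, m)
  expect_equal(tl2@events$startS[2], 0.1 + 0.001)
  ## serpentine grid: total time equals an independent accumulation
  set.seed(51)
  grid <- expand.grid(u = seq(0, 20, 5), v = seq(0, 20, 5))
  grid$weight <- runif(nrow(grid), 10, 50)
  grid <- grid[serpentineOrder(as.matrix(grid[, 1:2]), 5), ]
  mo <- protonMachine(2000, c(8000, 5000), 1e-3)
  tl3 <- scheduleProton(grid, mo)
  expected <- sum(grid$weight / 2000) +
    sum(pmax(abs(diff(grid$u)) / 8000, abs(diff(grid$v)) / 5000) + 1e-3)
  expect_equal(fieldTimeS(tl3), expected, tolerance = 1e-12)
  ## zero-weight spots dwell 0 but still cost travel
  zw <- data.frame(u = c(0, 5, 10), v = 0, weight = c(10, 0, 10))
  tlz <- scheduleProton(zw, protonMachine(1000, 1e4, 0))
  expect_equal(tlz@events$durationS[2], 0)
  expect_equal(tlz@events$startS[3] - tlz@events$startS[2], 5 / 1e4)
})

test_that("VHEE pulses fire consecutively on the PRF lattice", {
  m <- vheeMachine(prfHz = 100, pulseWidthS = 4e-6, maxDosePerPulseMU = 10)
  spots <- data.frame(u = 1:10, v = 0, weight = rep(5, 10))
  tl <- scheduleVhee(spots, m)
  expect_equal(nrow(tl@events), 10)
  expect_equal(tl@events$startS[10], 0.09)
  expect_equal(fieldTimeS(tl), 9 / 100 + 4e-6)
  ## a spot over the per-pulse limit splits into ceiling(w/max) pulses
  big <- data.frame(u = 0, v = 0, weight = 25)
  tlb <- scheduleVhee(big, m)
  expect_equal(nrow(tlb@events), 3)
  expect_equal(sum(tlb@events$weightMU), 25)
  expect_error(vheeMachine(prfHz = 1000, pulseWidthS = 2e-3), "pulse width")
})

## one-voxel sparse matrix helper for direct dose-rate checks
oneVoxelMatrix <- function(dosePerMU) {
  A <- Matrix::sparseMatrix(i = rep(1L, length(dosePerMU)),
                            j = seq_along(dosePerMU), x = dosePerMU,
                            dims = c(1L, length(dosePerMU)))
  new("DoseInfluenceMatrix", matrix = A,
      nodeIU = rep(NA_integer_, length(dosePerMU)),
      nodeIV = rep(NA_integer_, length(dosePerMU)), pitchMm = 1,
      rows = 1L, refDims = c(1L, 1L, 1L), refSpacing = c(1, 1, 1),
      refOrigin = c(0, 0, 0), fieldId = 1L)
}

timelineOf <- function(start, dur, w) {
  new("DeliveryTimeline",
      events = data.frame(spot = seq_along(start), startS = start,
                          durationS = dur, weightMU = w),
      fieldId = 1L, fraction = 1L)
}

test_that("a single ramp gives dose rate D / duration", {
  M <- oneVoxelMatrix(1)                       # 1 Gy per MU
  tl <- timelineOf(0.2, 0.05, 3)               # 3 Gy over 50 ms
  dr <- pbsDoseRateMap(M, 3, tl, doseRateConfig(thresholdDoseGy = 0.1))
  expect_equal(gridValues(dr)[1], 3 / 0.05)
})

test_that("two pulses invert to the hand-derived closed form", {
  for (prf in c(100, 500, 1000)) {
    tau <- 4e-6
    M <- oneVoxelMatrix(c(1, 1))               # 1 Gy from each pulse
    tl <- timelineOf(c(0, 1 / prf), c(tau, tau), c(1, 1))
    dr <- pbsDoseRateMap(M, c(1, 1), tl, doseRateConfig(0.1))
    expect_equal(gridValues(dr)[1], 1.8 / (1 / prf + 0.8 * tau),
                 tolerance = 1e-9)
    ## and matches the time-stepping oracle when the pulses are wide
    ## enough for a 10 us step to resolve
    tlw <- timelineOf(c(0, 1 / prf), c(2e-4, 2e-4), c(1, 1))
    drw <- pbsDoseRateMap(M, c(1, 1), tlw, doseRateConfig(0.1))
    events <- data.frame(startS = c(0, 1 / prf), durationS = c(2e-4, 2e-4),
                         doseGy = c(1, 1))
    expect_equal(gridValues(drw)[1], oracleDoseRate(events), tolerance = 0.01)
  }
})

test_that("voxels below the 2 d-hat floor get dose rate zero", {
  M <- oneVoxelMatrix(0.15)
  tl <- timelineOf(0, 0.01, 1)
  dr <- pbsDoseRateMap(M, 1, tl, doseRateConfig(thresholdDoseGy = 0.1))
  expect_equal(gridValues(dr)[1], 0)
})

test_that("the event-based engine matches 10 us time stepping", {
  set.seed(52)
  for (rep in 1:25) {
    nEv <- sample(2:6, 1)
    dur <- runif(nEv, 1e-3, 5e-2)
    gap <- runif(nEv, 0, 2e-2)
    start <- cumsum(gap + c(0, dur[-nEv]))
    dose <- runif(nEv, 0.05, 5)
    M <- oneVoxelMatrix(dose)
    tl <- timelineOf(start, dur, rep(1, nEv))
    dr <- gridValues(pbsDoseRateMap(M, rep(1, nEv), tl,
                                    doseRateConfig(0.1)))[1]
    ref <- oracleDoseRate(data.frame(startS = start, durationS = dur,
                                     doseGy = dose))
    if (ref == 0) expect_equal(dr, 0)
    else expect_lt(abs(dr - ref) / ref, 0.01)
  }
})

test_that("VHEE dose rate never decreases with PRF", {
  set.seed(53)
  nSpot <- 12
  dosePerMU <- runif(nSpot, 0, 0.4)
  M <- oneVoxelMatrix(dosePerMU)
  w <- runif(nSpot, 10, 30)
  spots <- data.frame(u = seq_len(nSpot), v = 0, weight = w)
  drAt <- function(prf) {
    tl <- scheduleVhee(spots, vheeMachine(prfHz = prf,
                                          maxDosePerPulseMU = 50))
    gridValues(pbsDoseRateMap(M, w, tl, doseRateConfig(0.1)))[1]
  }
  drs <- vapply(c(100, 200, 500, 1000), drAt, 0)
  expect_true(all(diff(drs) >= -1e-9))
})

test_that("permuting non-contributing spots leaves a voxel's rate alone", {
  set.seed(54)
  dosePerMU <- c(0.5, 0, 0.8, 0, 0, 0.3)       # spots 2, 4, 5 miss the voxel
  w <- rep(10, 6)
  spots <- data.frame(u = 1:6, v = 0, weight = w)
  m <- vheeMachine(prfHz = 250, maxDosePerPulseMU = 50)
  base <- gridValues(pbsDoseRateMap(oneVoxelMatrix(dosePerMU), w,
                                    scheduleVhee(spots, m),
                                    doseRateConfig(0.1)))[1]
  perm <- c(1, 5, 3, 2, 4, 6)                   # swaps only misses
  drP <- gridValues(pbsDoseRateMap(oneVoxelMatrix(dosePerMU[perm]), w[perm],
                                   scheduleVhee(spots[perm, ], m),
                                   doseRateConfig(0.1)))[1]
  expect_equal(drP, base)
})

test_that("the UHDR dose map obeys its bounds and the counting oracle", {
  dims <- c(10, 10, 10)
  set.seed(55)
  d1 <- voxelGrid(array(runif(1000, 0, 20), dims), 2)
  d2 <- voxelGrid(array(runif(1000, 0, 20), dims), 2)
  r1 <- voxelGrid(array(runif(1000, 0, 80), dims), 2)
  r2 <- voxelGrid(array(runif(1000, 0, 80), dims), 2)
  cfg <- doseRateConfig(uhdrThresholdGyPerS = 40, fractions = 2L)
  fd <- flashDoseMap(list(d1, d2), list(r1, r2), cfg)
  manual <- 2 * (gridValues(d1) * (gridValues(r1) >= 40) +
                   gridValues(d2) * (gridValues(r2) >= 40))
  expect_equal(gridValues(fd), manual)
  total <- 2 * (gridValues(d1) + gridValues(d2))
  expect_true(all(gridValues(fd) <= total + 1e-12))
  expect_true(all(gridValues(fd) >= 0))
  ## degenerate cases
  rLow <- voxelGrid(array(1, dims), 2)
  expect_true(all(gridValues(flashDoseMap(list(d1), list(rLow), cfg)) == 0))
  rHigh <- voxelGrid(array(100, dims), 2)
  cfg1 <- doseRateConfig(fractions = 1L)
  expect_equal(gridValues(flashDoseMap(list(d1), list(rHigh), cfg1)),
               gridValues(d1))
  bad <- voxelGrid(array(1, c(5, 5, 5)), 2)
  expect_error(flashDoseMap(list(d1), list(bad), cfg), "mismatched")
})

test_that("timelines must cover every weighted spot", {
  M <- oneVoxelMatrix(c(1, 1))
  tl <- timelineOf(0, 0.01, 1)                  # only spot 1
  expect_error(pbsDoseRateMap(M, c(1, 1), tl, doseRateConfig(0.1)),
               "cover")
})
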