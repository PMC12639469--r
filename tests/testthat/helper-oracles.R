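# Independent brute-force oracles used to verify the package's
# event-based / vectorized implementations on small instances.

# trilinear sampling written independently of the package internals:
# clamp to the nearest voxel centre inside the grid, zero outside the
# grid box (half a voxel beyond the outer centres)
oracleSample <- function(vals, spacing, origin, p) {
  d <- dim(vals)
  f <- (p - origin) / spacing + 1
  if (any(f < 0.5) || any(f > d + 0.5)) return(0)
  f <- pmin(pmax(f, 1), d)
  i0 <- pmin(floor(f), d - 1); i0[d == 1] <- 1
  w <- f - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[1] else 1 - w[1]) * (if (dy) w[2] else 1 - w[2]) *
      (if (dz) w[3] else 1 - w[3])
    if (wt > 0)
      acc <- acc + wt * vals[min(i0[1] + dx, d[1]), min(i0[2] + dy, d[2]),
                             min(i0[3] + dz, d[3])]
  }
  acc
}

# fine-step ray marching from the grid box entry to the target point
oracleRayDepth <- function(grid, dirUnit, target, step = 0.1) {
  vals <- gridValues(grid); sp <- gridSpacing(grid); or <- gridOrigin(grid)
  d <- dim(vals)
  lo <- or - sp / 2; hi <- lo + d * sp
  tmax <- Inf
  for (ax in 1:3) if (abs(dirUnit[ax]) > 1e-12)
    tmax <- min(tmax, max((target[ax] - lo[ax]) / dirUnit[ax],
                          (target[ax] - hi[ax]) / dirUnit[ax]))
  if (!is.finite(tmax) || tmax <= 0) return(0)
  n <- ceiling(tmax / step)
  dt <- tmax / n
  acc <- 0
  for (k in seq_len(n)) {
    t <- tmax - (k - 0.5) * dt
    acc <- acc + oracleSample(vals, sp, or, target - t * dirUnit)
  }
  acc * dt
}

# 10-microsecond time-stepping PBS dose-rate oracle for one voxel.
# events: data.frame(startS, durationS, doseGy); crossing times are
# linearly interpolated inside each time step.
oracleDoseRate <- function(events, dhat = 0.1, dt = 1e-5) {
  Dtot <- sum(events$doseGy)
  if (Dtot <= 2 * dhat) return(0)
  tmax <- max(events$startS + events$durationS)
  ts <- seq(0, tmax + dt, by = dt)
  D <- numeric(length(ts))
  for (e in seq_len(nrow(events))) {
    frac <- pmin(pmax((ts - events$startS[e]) / events$durationS[e], 0), 1)
    D <- D + frac * events$doseGy[e]
  }
  crossing <- function(thr) {
    k <- which(D >= thr)[1]
    if (k == 1) return(ts[1])
    ts[k - 1] + dt * (thr - D[k - 1]) / (D[k] - D[k - 1])
  }
  (Dtot - 2 * dhat) / (crossing(Dtot - dhat) - crossing(dhat))
}

# per-voxel counting oracles
oracleDvh <- function(doseVals, maskArr, levels) {
  d <- doseVals[maskArr]
  vapply(levels, function(L) sum(d > L) / length(d), 0)
}

oracleObjective <- function(doseArr, sc, structures) {
  f <- 0
  for (o in seq_len(nrow(sc))) {
    m <- structureMask(structures, sc$structure[o])
    d <- doseArr[m]; L <- sc$levelGy[o]; p <- sc$priority[o]
    term <- switch(sc$type[o],
      min_dose = mean(pmax(L - d, 0)^2),
      max_dose = mean(pmax(d - L, 0)^2),
      mean_dose_max = max(mean(d) - L, 0)^2,
      uniform = mean((d - L)^2))
    f <- f + p * term
  }
  f
}

# small uniform water phantom with simple box structures
tinyWaterPhantom <- function(n = 24, spacingMm = 4) {
  vals <- array(1, dim = rep(n, 3))
  grid <- voxelGrid(vals, spacingMm = spacingMm)
  body <- array(TRUE, dim = rep(n, 3))
  mid <- seq(n / 2 - n / 6, n / 2 + n / 6)
  ptv <- array(FALSE, dim = rep(n, 3)); ptv[mid, mid, mid] <- TRUE
  oar <- array(FALSE, dim = rep(n, 3))
  oar[mid, max(mid) + seq_len(2), mid] <- TRUE
  list(density = grid,
       structures = structureSet(list(BODY = body, PTV = ptv, OAR1 = oar),
                                 grid))
}

# dose grid with given values on a fresh water-box geometry
doseGridOf <- function(vals, spacingMm = 2) voxelGrid(vals, spacingMm)
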