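#' FieldGeometry: beam axis and isocenter of one field
#'
#' The gantry rotates in the axial (x-y) plane about the isocenter. For a
#' gantry angle g (degrees) the beam travels along
#' \code{b = (cos g, sin g, 0)}; the beam's-eye-view (BEV) axes are
#' \code{u = (-sin g, cos g, 0)} and \code{v = (0, 0, 1)}, so a spot at
#' BEV position (u, v) runs parallel to the beam axis through
#' \code{isocenter + u*u_hat + v*v_hat}.
#'
#' @slot gantryAngleDeg angle in [0, 360).
#' @slot isocenterMm world coordinates of the isocenter (mm).
#' @export
setClass("FieldGeometry",
  representation(gantryAngleDeg = "numeric", isocenterMm = "numeric"),
  validity = function(object) {
    if (object@gantryAngleDeg < 0 || object@gantryAngleDeg >= 360)
      return("gantry angle must be in [0, 360)")
    if (length(object@isocenterMm) != 3L) return("isocenter must be length 3")
    TRUE
  })

#' @rdname FieldGeometry-class
#' @param gantryAngleDeg gantry angle in degrees, [0, 360).
#' @param isocenterMm isocenter in mm (default: world origin).
#' @export
fieldGeometry <- function(gantryAngleDeg = 0, isocenterMm = c(0, 0, 0)) {
  new("FieldGeometry", gantryAngleDeg = as.numeric(gantryAngleDeg),
      isocenterMm = as.numeric(isocenterMm))
}

## orthonormal beam frame: rows b (beam axis), u, v
beamFrame <- function(geometry) {
  g <- geometry@gantryAngleDeg * pi / 180
  list(b = c(cos(g), sin(g), 0),
       u = c(-sin(g), cos(g), 0),
       v = c(0, 0, 1))
}

#' BeamModel: analytic transmission pencil-beam kernel
#'
#' A transmission spot deposits
#' \code{dose = calibration * PDD(z_rad) * L(r; z_rad)} where
#' \code{z_rad} is the radiological depth along the beam axis, \code{PDD}
#' a tabulated normalized depth-dose (linearly interpolated, constant
#' beyond the table), and \code{L} a normalized single or double Gaussian
#' in the transverse plane with depth-broadened widths
#' \code{sigma_i(z) = sigma_i0 + growth * z}. No dose is scored in air
#' (relative density below 0.05).
#'
#' @slot particle \code{"proton"} or \code{"electron"}.
#' @slot energyMeV nominal beam energy.
#' @slot lateral list with \code{kind} (\code{"single_gaussian"} or
#'   \code{"double_gaussian"}), \code{sigma1Mm}, \code{sigma2Mm},
#'   \code{weight1}, \code{sigmaGrowthMmPerMm}.
#' @slot pdd data.frame with columns \code{depthMm}, \code{value} (> 0).
#' @slot calibrationGyPerMU Gy mm^2 per MU scaling of the kernel.
#' @export
setClass("BeamModel",
  representation(particle = "character", energyMeV = "numeric",
                 lateral = "list", pdd = "data.frame",
                 calibrationGyPerMU = "numeric"),
  validity = function(object) {
    msg <- character()
    lat <- object@lateral
    if (!lat$kind %in% c("single_gaussian", "double_gaussian"))
      msg <- c(msg, "unknown lateral kind")
    if (lat$sigma1Mm <= 0) msg <- c(msg, "sigma1 must be > 0")
    if (lat$kind == "double_gaussian") {
      if (lat$sigma2Mm <= lat$sigma1Mm)
        msg <- c(msg, "sigma2 must exceed sigma1")
      if (lat$weight1 <= 0 || lat$weight1 > 1)
        msg <- c(msg, "weight1 must be in (0, 1]")
    }
    if (lat$sigmaGrowthMmPerMm < 0) msg <- c(msg, "sigma growth must be >= 0")
    if (any(object@pdd$value <= 0)) msg <- c(msg, "pdd values must be > 0")
    if (is.unsorted(object@pdd$depthMm, strictly = TRUE))
      msg <- c(msg, "pdd depths must be strictly increasing")
    if (object@calibrationGyPerMU <= 0) msg <- c(msg, "calibration must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a beam model
#'
#' @param particle \code{"proton"} or \code{"electron"}.
#' @param energyMeV beam energy in MeV.
#' @param kind lateral profile kind.
#' @param sigma1Mm,sigma2Mm,weight1 Gaussian mixture parameters
#'   (\code{weight2 = 1 - weight1}).
#' @param sigmaGrowthMmPerMm linear depth-broadening rate of both sigmas.
#' @param pdd data.frame \code{depthMm}, \code{value}.
#' @param calibrationGyPerMU kernel calibration (Gy mm^2 / MU).
#' @return A [BeamModel-class].
#' @export
beamModel <- function(particle, energyMeV, kind = "single_gaussian",
                      sigma1Mm, sigma2Mm = 3 * sigma1Mm, weight1 = 1,
                      sigmaGrowthMmPerMm = 0,
                      pdd = data.frame(depthMm = c(0, 300), value = c(1, 1)),
                      calibrationGyPerMU = 25) {
  new("BeamModel", particle = particle, energyMeV = as.numeric(energyMeV),
      lateral = list(kind = kind, sigma1Mm = sigma1Mm, sigma2Mm = sigma2Mm,
                     weight1 = weight1,
                     sigmaGrowthMmPerMm = sigmaGrowthMmPerMm),
      pdd = pdd, calibrationGyPerMU = calibrationGyPerMU)
}

#' Default transmission beam models
#'
#' \code{defaultProtonModel()} is a 250 MeV shoot-through proton kernel:
#' single Gaussian of 10 mm FWHM (sigma 10/2.355 = 4.25 mm), mild
#' multiple-Coulomb-scattering broadening (0.05 mm/mm) and a gently
#' rising transmission depth-dose (0.95 to 1.10 over 0-300 mm).
#' \code{defaultVheeModel()} is a 150 or 200 MeV VHEE kernel: double
#' Gaussian with core sigma 5 mm, halo sigma 15 mm carrying 10\% of the
#' fluence, broadening 0.10 (150 MeV) or 0.07 (200 MeV) mm/mm, and a
#' depth-dose with 30 mm build-up then a linear decline of 0.7\%/cm
#' (150 MeV) or 0.4\%/cm (200 MeV). The halo parameters and broadening
#' rates are configuration with documented defaults, not measured data.
#'
#' @param energyMeV VHEE energy, 150 or 200.
#' @return A [BeamModel-class].
#' @export
defaultProtonModel <- function() {
  beamModel("proton", 250, kind = "single_gaussian",
            sigma1Mm = 10 / 2.355, sigmaGrowthMmPerMm = 0.05,
            pdd = data.frame(depthMm = c(0, 300), value = c(0.95, 1.10)),
            calibrationGyPerMU = 25)
}

#' @rdname defaultProtonModel
#' @export
defaultVheeModel <- function(energyMeV = 200) {
  stopifnot(energyMeV %in% c(150, 200))
  slope <- if (energyMeV == 150) 7e-4 else 4e-4   # per mm past build-up
  beamModel("electron", energyMeV, kind = "double_gaussian",
            sigma1Mm = 5, sigma2Mm = 15, weight1 = 0.9,
            sigmaGrowthMmPerMm = if (energyMeV == 150) 0.10 else 0.07,
            pdd = data.frame(depthMm = c(0, 30, 300),
                             value = c(0.90, 1.0, 1.0 - slope * 270)),
            calibrationGyPerMU = 25)
}

#' Read or write a beam model as JSON
#'
#' @param model a [BeamModel-class].
#' @param path JSON file path.
#' @export
writeBeamModel <- function(model, path) {
  jsonlite::write_json(list(
    particle = model@particle, energy_MeV = model@energyMeV,
    lateral = model@lateral,
    pdd = list(depth_mm = model@pdd$depthMm, value = model@pdd$value),
    calibration_Gy_per_MU = model@calibrationGyPerMU),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBeamModel
#' @export
readBeamModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  beamModel(j$particle, j$energy_MeV, kind = j$lateral$kind,
            sigma1Mm = j$lateral$sigma1Mm, sigma2Mm = j$lateral$sigma2Mm,
            weight1 = j$lateral$weight1,
            sigmaGrowthMmPerMm = j$lateral$sigmaGrowthMmPerMm,
            pdd = data.frame(depthMm = j$pdd$depth_mm, value = j$pdd$value),
            calibrationGyPerMU = j$calibration_Gy_per_MU)
}

pddFun <- function(model) {
  approxfun(model@pdd$depthMm, model@pdd$value, rule = 2)
}

## normalized 2-D Gaussian mixture at squared radius r2 (1/mm^2)
lateralMixture <- function(r2, sigma1, sigma2, weight1) {
  out <- weight1 * exp(-r2 / (2 * sigma1^2)) / (2 * pi * sigma1^2)
  if (weight1 < 1)
    out <- out + (1 - weight1) * exp(-r2 / (2 * sigma2^2)) / (2 * pi * sigma2^2)
  out
}

## trilinear sampling of a grid at world points (n x 3), clamped to the
## nearest voxel centre inside the grid box; 0 outside the box (half a
## voxel beyond the outermost centres)
trilinearSample <- function(grid, pts) {
  d <- dim(grid@values); sp <- grid@spacingMm; or <- grid@originMm
  f1 <- (pts[, 1] - or[1]) / sp[1] + 1
  f2 <- (pts[, 2] - or[2]) / sp[2] + 1
  f3 <- (pts[, 3] - or[3]) / sp[3] + 1
  inside <- f1 >= 0.5 & f1 <= d[1] + 0.5 &
            f2 >= 0.5 & f2 <= d[2] + 0.5 &
            f3 >= 0.5 & f3 <= d[3] + 0.5
  f1 <- pmin(pmax(f1, 1), d[1]); f2 <- pmin(pmax(f2, 1), d[2])
  f3 <- pmin(pmax(f3, 1), d[3])
  i0 <- pmin(floor(f1), d[1] - 1L); j0 <- pmin(floor(f2), d[2] - 1L)
  k0 <- pmin(floor(f3), d[3] - 1L)
  if (d[1] == 1L) i0 <- rep(1, length(f1))
  if (d[2] == 1L) j0 <- rep(1, length(f2))
  if (d[3] == 1L) k0 <- rep(1, length(f3))
  wx <- f1 - i0; wy <- f2 - j0; wz <- f3 - k0
  v <- grid@values
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
         (if (dz) wz else 1 - wz)
    keep <- w > 0
    if (any(keep)) {
      idx <- cbind(pmin(i0 + dx, d[1]), pmin(j0 + dy, d[2]),
                   pmin(k0 + dz, d[3]))
      contrib <- numeric(length(f1))
      contrib[keep] <- w[keep] * v[idx[keep, , drop = FALSE]]
      val <- val + contrib
    }
  }
  val * inside
}

#' Radiological depth of one voxel along the beam axis
#'
#' Line integral of relative density from the grid boundary to the voxel
#' centre along the beam direction, sampled with a step no larger than
#' half the smallest voxel spacing (midpoint rule). In uniform water it
#' equals the geometric depth; rays that miss the body accumulate nothing
#' (air has density 0).
#'
#' @param density density [VoxelGrid-class] (water = 1, air = 0).
#' @param geometry a [FieldGeometry-class].
#' @param voxelIndex integer(3) voxel index (1-based).
#' @param stepMm integration step; default half the smallest spacing.
#' @return Radiological depth in mm (>= 0).
#' @export
radiologicalDepth <- function(density, geometry, voxelIndex,
                              stepMm = min(gridSpacing(density)) / 2) {
  d <- gridDims(density)
  if (any(voxelIndex < 1) || any(voxelIndex > d))
    stop("voxel index outside grid")
  fr <- beamFrame(geometry)
  p <- gridOrigin(density) + (voxelIndex - 1) * gridSpacing(density)
  ## distance back to the grid bounding box along -b
  lo <- gridOrigin(density) - gridSpacing(density) / 2
  hi <- lo + d * gridSpacing(density)
  tmax <- Inf
  for (ax in 1:3) {
    if (abs(fr$b[ax]) > 1e-12) {
      t1 <- (p[ax] - lo[ax]) / fr$b[ax]
      t2 <- (p[ax] - hi[ax]) / fr$b[ax]
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (!is.finite(tmax) || tmax <= 0) return(0)
  n <- ceiling(tmax / stepMm)
  dt <- tmax / n
  ts <- tmax - (seq_len(n) - 0.5) * dt     # midpoints from entry to voxel
  pts <- cbind(p[1] - ts * fr$b[1], p[2] - ts * fr$b[2], p[3] - ts * fr$b[3])
  sum(trilinearSample(density, pts)) * dt
}

## Per-field precomputation shared by all spot columns of that field:
## BEV coordinates (u, v, w) and radiological depth of every candidate
## voxel. Axis-aligned gantry angles use an exact cumulative sum along
## the grid axis; other angles resample the density on a BEV-aligned
## lattice (step = half the smallest spacing) and integrate there.
fieldContext <- function(density, geometry, rows = NULL) {
  d <- gridDims(density); sp <- gridSpacing(density)
  if (is.null(rows)) rows <- seq_len(prod(d))
  fr <- beamFrame(geometry)
  ctr <- voxelCentersMm(density, rows)
  rel <- sweep(ctr, 2, geometry@isocenterMm, "-")
  u <- rel %*% fr$u; v <- rel %*% fr$v; w <- rel %*% fr$b
  g <- geometry@gantryAngleDeg %% 360
  if (g %in% c(0, 90, 180, 270)) {
    ax <- if (g %in% c(0, 180)) 1L else 2L
    dens <- density@values
    csum <- apply(dens, setdiff(1:3, ax), function(line) {
      if (g %in% c(180, 270)) line <- rev(line)
      out <- cumsum(line) - line / 2
      if (g %in% c(180, 270)) out <- rev(out)
      out
    })
    ## apply() puts the iterated axis first; restore (i, j, k) order
    rd <- if (ax == 1L) csum else aperm(csum, c(2, 1, 3))
    rd <- rd * sp[ax]
    rdepth <- rd[rows]
  } else {
    ## general in-plane rotation: per-slice 2-D resampling
    du <- min(sp[1:2]); dw <- min(sp) / 2
    us <- seq(min(u) - du, max(u) + du, by = du)
    extent <- sqrt(sum((d[1:2] * sp[1:2])^2))
    ws <- seq(-extent, max(w) + dw, by = dw)
    pu <- rep(us, times = length(ws)); pw <- rep(ws, each = length(us))
    px <- geometry@isocenterMm[1] + pu * fr$u[1] + pw * fr$b[1]
    py <- geometry@isocenterMm[2] + pu * fr$u[2] + pw * fr$b[2]
    nuw <- length(pu)
    rdArr <- array(0, dim = c(length(us), length(ws), d[3]))
    for (k in seq_len(d[3])) {
      pz <- rep(gridOrigin(density)[3] + (k - 1) * sp[3], nuw)
      dens <- trilinearSample(density, cbind(px, py, pz))
      dm <- matrix(dens, nrow = length(us))
      rdArr[, , k] <- (t(apply(dm, 1, cumsum)) - dm / 2) * dw
    }
    rdGrid <- new("VoxelGrid", values = rdArr,
                  spacingMm = c(du, dw, sp[3]),
                  originMm = c(us[1], ws[1], gridOrigin(density)[3]))
    rdepth <- trilinearSample(rdGrid, cbind(u, w, ctr[, 3]))
  }
  list(rows = rows, u = as.numeric(u), v = as.numeric(v),
       w = as.numeric(w), rdepth = pmax(as.numeric(rdepth), 0),
       densityAtVoxel = density@values[rows])
}

#' Dose column of one spot (dose per unit weight)
#'
#' Evaluates the transmission kernel of \code{model} for a spot at BEV
#' position \code{spotBevMm} on every voxel of the grid (or of the
#' \code{rows} subset): \code{calibration * PDD(z_rad) * L(r_perp; z_rad)}
#' with the lateral mixture widths broadened linearly in radiological
#' depth. Values below \code{truncRel} of the column maximum are dropped
#' and the column is returned sparse; no dose is scored in air. A spot
#' that misses the body yields an empty column.
#'
#' @param density density [VoxelGrid-class].
#' @param geometry a [FieldGeometry-class].
#' @param model a [BeamModel-class].
#' @param spotBevMm numeric(2): (u, v) spot position in the BEV plane.
#' @param rows optional integer vector of linear voxel indices to score
#'   (default: whole grid).
#' @param ctx optional precomputed field context (internal; lets callers
#'   amortize ray tracing across many spots of one field).
#' @param truncRel relative sparsity threshold (default 1e-4).
#' @return A \code{Matrix::sparseVector} of length \code{length(rows)}
#'   with the dose per unit weight (Gy/MU).
#' @export
spotDoseColumn <- function(density, geometry, model, spotBevMm,
                           rows = NULL, ctx = NULL, truncRel = 1e-4) {
  if (is.null(ctx)) ctx <- fieldContext(density, geometry, rows)
  colv <- spotColumnValues(ctx, model, spotBevMm, truncRel)
  Matrix::sparseVector(colv$x, colv$i, length(ctx$rows))
}

## dense work: returns list(i = index into ctx$rows, x = values)
spotColumnValues <- function(ctx, model, spotBevMm, truncRel = 1e-4) {
  lat <- model@lateral
  maxDepth <- max(ctx$rdepth)
  sMax <- (if (lat$kind == "double_gaussian") lat$sigma2Mm else lat$sigma1Mm) +
    lat$sigmaGrowthMmPerMm * maxDepth
  rmax2 <- (2 * sMax * sqrt(log(1 / max(truncRel, 1e-12)) / 2) + 3 * sMax)^2
  r2 <- (ctx$u - spotBevMm[1])^2 + (ctx$v - spotBevMm[2])^2
  cand <- which(r2 <= rmax2 & ctx$densityAtVoxel > 0.05)
  if (!length(cand)) return(list(i = integer(), x = numeric()))
  rd <- ctx$rdepth[cand]
  s1 <- lat$sigma1Mm + lat$sigmaGrowthMmPerMm * rd
  w1 <- if (lat$kind == "double_gaussian") lat$weight1 else 1
  lv <- w1 * exp(-r2[cand] / (2 * s1^2)) / (2 * pi * s1^2)
  if (w1 < 1) {
    s2 <- lat$sigma2Mm + lat$sigmaGrowthMmPerMm * rd
    lv <- lv + (1 - w1) * exp(-r2[cand] / (2 * s2^2)) / (2 * pi * s2^2)
  }
  val <- model@calibrationGyPerMU * pddFun(model)(rd) * lv
  keep <- val > truncRel * max(val)
  list(i = cand[keep], x = val[keep])
}
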