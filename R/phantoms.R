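#' PhantomSpec: recipe for a synthetic planning phantom
#'
#' Describes a density grid plus structure set emulating one of four
#' clinical geometry classes. The presets reproduce the qualitative
#' contrast that drives pulse-repetition-frequency (PRF) findings in
#' transmission-beam FLASH planning - small shallow target, small target
#' in low-density surroundings, mid-size target, large deep target with
#' abutting organs at risk - not any particular patient anatomy.
#'
#' Preset geometry (all targets spherical, radii chosen so that the PTV
#' volumes are strictly ordered brain < lung < liver <= prostate):
#' \describe{
#'   \item{\code{brain_like}}{15 mm radius target, centre 40 mm below the
#'     body surface; one small box OAR 10 mm deeper.}
#'   \item{\code{lung_like}}{20 mm radius water-density target embedded in
#'     a 0.3-density lung-like ellipsoid; a cord-like box OAR posteriorly.}
#'   \item{\code{liver_like}}{22.5 mm radius target, offset laterally; one
#'     adjacent box OAR.}
#'   \item{\code{prostate_like}}{40 mm radius target at the grid centre
#'     with two abutting box OARs (anterior and posterior).}
#' }
#'
#' @slot preset character; one of \code{brain_like}, \code{lung_like},
#'   \code{liver_like}, \code{prostate_like}, \code{custom}.
#' @slot dims,spacingMm grid dimensions and isotropic-by-default spacing.
#' @slot targetRadiusMm,targetCenterMm sphere radius and centre (mm, world
#'   coordinates; the grid is centred on the world origin).
#' @slot oars named list; each element a list with \code{shape="box"},
#'   \code{lo}, \code{hi} (mm corners) or \code{shape="sphere"},
#'   \code{center}, \code{radius}.
#' @slot inserts named list of density inserts (ellipsoids:
#'   \code{center}, \code{semiAxes}, \code{density}).
#' @slot bodySemiAxesMm semi-axes of the elliptical BODY contour.
#' @slot seed integer RNG seed recorded with the phantom.
#' @export
setClass("PhantomSpec",
  representation(preset = "character", dims = "integer", spacingMm = "numeric",
                 targetRadiusMm = "numeric", targetCenterMm = "numeric",
                 oars = "list", inserts = "list", bodySemiAxesMm = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@dims <= 0)) msg <- c(msg, "dims must be positive")
    if (any(object@spacingMm <= 0)) msg <- c(msg, "spacing must be positive")
    if (!is.finite(object@targetRadiusMm) || object@targetRadiusMm <= 0)
      msg <- c(msg, "invalid spec: target radius must be > 0")
    for (ins in object@inserts)
      if (ins$density <= 0) msg <- c(msg, "insert densities must be > 0")
    ## target must fit inside the body ellipse
    rel <- (abs(object@targetCenterMm) + object@targetRadiusMm) /
      object@bodySemiAxesMm
    if (any(rel > 1))
      msg <- c(msg, "invalid spec: target does not fit inside the body")
    if (length(msg)) msg else TRUE
  })

presetNames <- c("brain_like", "lung_like", "liver_like", "prostate_like")

#' Build a PhantomSpec
#'
#' @param preset preset name (see [PhantomSpec-class]) or \code{"custom"}.
#' @param dims grid dimensions (default 100^3).
#' @param spacingMm voxel spacing in mm (default 2, isotropic).
#' @param seed integer seed recorded with the phantom (the analytic
#'   presets are deterministic; the seed keeps provenance for any
#'   downstream randomness driven from the phantom).
#' @param targetRadiusMm,targetCenterMm,oars,inserts,bodySemiAxesMm
#'   overrides for \code{preset = "custom"} (or to tweak a preset).
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec("brain_like")
#' ph <- generatePhantom(spec)
#' ph$structures
#' @export
phantomSpec <- function(preset = "custom", dims = c(100L, 100L, 100L),
                        spacingMm = 2, seed = 1L,
                        targetRadiusMm = NULL, targetCenterMm = NULL,
                        oars = NULL, inserts = NULL, bodySemiAxesMm = NULL) {
  preset <- match.arg(preset, c(presetNames, "custom"))
  dims <- rep(as.integer(dims), length.out = 3)
  spacingMm <- rep(as.numeric(spacingMm), length.out = 3)
  extent <- dims * spacingMm
  body <- 0.45 * extent                       # ellipse semi-axes, mm
  p <- switch(preset,
    brain_like = list(
      r = 15, center = c(0, body[2] - 40 - 15, 0),
      oars = list(OAR1 = list(shape = "box",
                              lo = c(-10, body[2] - 80, -10),
                              hi = c(10, body[2] - 65, 10))),
      inserts = list()),
    lung_like = list(
      r = 20, center = c(-0.35 * extent[1], 0, 0),
      oars = list(OAR1 = list(shape = "box",
                              lo = c(-10, -0.40 * extent[2], -25),
                              hi = c(10, -0.40 * extent[2] + 15, 25))),
      inserts = list(lung = list(center = c(-0.35 * extent[1], 0, 0),
                                 semiAxes = c(0.28, 0.30, 0.35) * extent,
                                 density = 0.3)),
      targetDensity = 1.0),
    liver_like = list(
      r = 22.5, center = c(0.25 * extent[1], 0.1 * extent[2], 0),
      oars = list(OAR1 = list(shape = "box",
                              lo = c(0.25 * extent[1] - 15, 0.1 * extent[2] + 25, -20),
                              hi = c(0.25 * extent[1] + 15, 0.1 * extent[2] + 45, 20))),
      inserts = list()),
    prostate_like = list(
      r = 40, center = c(0, 0, 0),
      oars = list(
        OAR_ANT = list(shape = "box", lo = c(-25, 40, -25), hi = c(25, 70, 25)),
        OAR_POST = list(shape = "box", lo = c(-25, -70, -25), hi = c(25, -40, 25))),
      inserts = list()),
    custom = list(r = 20, center = c(0, 0, 0), oars = list(), inserts = list()))
  new("PhantomSpec",
      preset = preset, dims = dims, spacingMm = spacingMm,
      targetRadiusMm = as.numeric(targetRadiusMm %||% p$r),
      targetCenterMm = as.numeric(targetCenterMm %||% p$center),
      oars = oars %||% p$oars,
      inserts = inserts %||% p$inserts,
      bodySemiAxesMm = as.numeric(bodySemiAxesMm %||% body),
      seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## logical mask helpers on precomputed world coordinate vectors
maskSphere <- function(X, Y, Z, center, radius)
  (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2 <= radius^2

maskEllipsoid <- function(X, Y, Z, center, semi)
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1

maskBox <- function(X, Y, Z, lo, hi)
  X >= lo[1] & X <= hi[1] & Y >= lo[2] & Y <= hi[2] & Z >= lo[3] & Z <= hi[3]

#' Generate a synthetic phantom
#'
#' Rasterizes the analytic shapes of a [PhantomSpec-class] on its voxel
#' grid: relative density is 1 inside BODY (water), 0 outside (air),
#' overridden by density inserts; the target keeps water density. All
#' masks are clipped to BODY. Deterministic for a fixed spec and seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements \code{density} ([VoxelGrid-class]),
#'   \code{structures} ([StructureSet-class]) and \code{spec}.
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  d <- spec@dims; sp <- spec@spacingMm
  origin <- -(d - 1) / 2 * sp
  xs <- origin[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(xs, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zs, each = d[1] * d[2]), dim = d)

  body <- maskEllipsoid(X, Y, Z, c(0, 0, 0), spec@bodySemiAxesMm)
  dens <- array(0, dim = d)
  dens[body] <- 1
  for (ins in spec@inserts) {
    m <- maskEllipsoid(X, Y, Z, ins$center, ins$semiAxes) & body
    dens[m] <- ins$density
  }
  ptv <- maskSphere(X, Y, Z, spec@targetCenterMm, spec@targetRadiusMm) & body
  dens[ptv] <- 1                               # tumours are water-density
  if (!any(ptv)) stop("invalid spec: PTV rasterizes to zero voxels")

  masks <- list(BODY = body, PTV = ptv)
  for (nm in names(spec@oars)) {
    o <- spec@oars[[nm]]
    m <- switch(o$shape,
                box = maskBox(X, Y, Z, o$lo, o$hi),
                sphere = maskSphere(X, Y, Z, o$center, o$radius),
                stop("unknown OAR shape '", o$shape, "'"))
    masks[[nm]] <- m & body
  }
  grid <- voxelGrid(dens, spacingMm = sp, originMm = origin)
  list(density = grid,
       structures = structureSet(masks, grid),
       spec = spec)
}

#' Write a phantom to disk
#'
#' Density and each mask go to separate NIfTI volumes; a JSON sidecar
#' records the spec and seed so the phantom can be regenerated exactly.
#'
#' @param phantom result of [generatePhantom()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, "density.nii")
  writeGrid(phantom$density, files)
  st <- phantom$structures
  for (nm in structureNames(st)) {
    f <- file.path(dir, paste0("mask_", nm, ".nii"))
    writeGrid(sameGrid(phantom$density, structureMask(st, nm) * 1), f)
    files <- c(files, f)
  }
  spec <- phantom$spec
  side <- list(preset = spec@preset, dims = spec@dims,
               spacing_mm = spec@spacingMm,
               target_radius_mm = spec@targetRadiusMm,
               target_center_mm = spec@targetCenterMm,
               body_semi_axes_mm = spec@bodySemiAxesMm,
               seed = spec@seed)
  sidecar <- file.path(dir, "phantom.json")
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sidecar))
}
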