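#' BevRegion: binary beam's-eye-view projection of the target
#'
#' A 2-D pixel raster of the PTV projected along the beam axis onto the
#' plane through the isocenter, plus its closed contour polyline(s).
#'
#' @slot mask logical matrix (u along rows, v along columns).
#' @slot pixU,pixV pixel centre coordinates (mm, BEV frame).
#' @slot spacingMm pixel size (mm, isotropic).
#' @slot contours list of closed polylines, each a list with numeric
#'   vectors \code{x} (u) and \code{y} (v).
#' @export
setClass("BevRegion",
  representation(mask = "matrix", pixU = "numeric", pixV = "numeric",
                 spacingMm = "numeric", contours = "list"),
  validity = function(object) {
    if (!any(object@mask)) return("region is empty")
    if (object@spacingMm <= 0) return("pixel spacing must be > 0")
    TRUE
  })

#' @rdname BevRegion-class
#' @param mask logical matrix.
#' @param pixU,pixV pixel centre coordinates.
#' @param spacingMm pixel size in mm.
#' @param contours optional contour polylines; traced from the mask at
#'   level 0.5 when omitted.
#' @export
bevRegion <- function(mask, pixU, pixV, spacingMm, contours = NULL) {
  if (is.null(contours)) {
    ## pad so every contour closes inside the raster
    pm <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
    pm[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
    pu <- c(pixU[1] - spacingMm, pixU, pixU[length(pixU)] + spacingMm)
    pv <- c(pixV[1] - spacingMm, pixV, pixV[length(pixV)] + spacingMm)
    cl <- grDevices::contourLines(pu, pv, pm, levels = 0.5)
    contours <- lapply(cl, function(co) list(x = co$x, y = co$y))
  }
  new("BevRegion", mask = mask, pixU = pixU, pixV = pixV,
      spacingMm = spacingMm, contours = contours)
}

#' @describeIn bevRegion Region area in mm^2.
#' @param region a \code{BevRegion}.
#' @export
regionAreaMm2 <- function(region) sum(region@mask) * region@spacingMm^2

## n x 2 matrix of in-region pixel centres
regionPixels <- function(region) {
  idx <- which(region@mask, arr.ind = TRUE)
  cbind(region@pixU[idx[, 1]], region@pixV[idx[, 2]])
}

setMethod("show", "BevRegion", function(object) {
  cat(sprintf("BevRegion %dx%d px @ %.2f mm, area %.0f mm^2, %d contour(s)\n",
              nrow(object@mask), ncol(object@mask), object@spacingMm,
              regionAreaMm2(object), length(object@contours)))
})

#' Project the PTV into the beam's-eye-view
#'
#' Orthographic projection of the PTV mask along the beam axis onto the
#' plane through the isocenter. A BEV pixel is in-region iff at least one
#' PTV voxel centre projects into it.
#'
#' @param structures a [StructureSet-class] (or any object accepted by
#'   [structureMask()]).
#' @param geometry a [FieldGeometry-class].
#' @param name structure to project (default \code{"PTV"}).
#' @param pixelMm BEV pixel size; defaults to the smallest voxel spacing.
#' @return A [BevRegion-class].
#' @export
projectPTV <- function(structures, geometry, name = "PTV",
                       pixelMm = min(structures@spacingMm)) {
  mask3 <- structureMask(structures, name)
  if (!any(mask3)) stop("empty projection: structure has no voxels")
  fr <- beamFrame(geometry)
  idx <- which(mask3)
  dgrid <- new("VoxelGrid", values = array(0, dim(mask3)),
               spacingMm = structures@spacingMm,
               originMm = structures@originMm)
  ctr <- voxelCentersMm(dgrid, idx)
  rel <- sweep(ctr, 2, geometry@isocenterMm, "-")
  u <- as.numeric(rel %*% fr$u); v <- as.numeric(rel %*% fr$v)
  ## bins anchored on the projected data so voxel centres fall at pixel
  ## centres for axis-aligned beams
  iu <- floor((u - (min(u) - pixelMm / 2)) / pixelMm) + 1
  iv <- floor((v - (min(v) - pixelMm / 2)) / pixelMm) + 1
  pu <- min(u) + (seq_len(max(iu)) - 1) * pixelMm
  pv <- min(v) + (seq_len(max(iv)) - 1) * pixelMm
  mask <- matrix(FALSE, length(pu), length(pv))
  mask[cbind(iu, iv)] <- TRUE
  bevRegion(mask, pu, pv, pixelMm)
}

#' Interior spot positions by centroidal Voronoi tessellation
#'
#' Places \code{k = round(area / spacing^2)} generators inside the region
#' and relaxes them with Lloyd iterations (assign region pixels to their
#' nearest generator, move each generator to the centroid of its cell)
#' until the largest generator movement falls below \code{tolMm} or
#' \code{maxIter} is reached. Initial generators are drawn uniformly from
#' the region pixels under the given seed; generators that end up outside
#' the (possibly non-convex) region are snapped to the nearest in-region
#' pixel. A region smaller than one cell yields a single central spot.
#'
#' @param region a [BevRegion-class].
#' @param spacingMm target spot spacing (default 5 mm).
#' @param seed RNG seed for the initialization.
#' @param maxIter,tolMm Lloyd iteration controls.
#' @return A two-column matrix of (u, v) positions in mm.
#' @export
cvtInteriorSpots <- function(region, spacingMm = 5, seed = 1L,
                             maxIter = 50L, tolMm = 0.1) {
  P <- regionPixels(region)
  k <- round(regionAreaMm2(region) / spacingMm^2)
  if (k <= 1) {
    cen <- colMeans(P)
    return(matrix(snapToRegion(cen, P), ncol = 2,
                  dimnames = list(NULL, c("u", "v"))))
  }
  gen <- P[drawSample(nrow(P), k, seed), , drop = FALSE]
  for (it in seq_len(maxIter)) {
    d2 <- outer(P[, 1], gen[, 1], "-")^2 + outer(P[, 2], gen[, 2], "-")^2
    assign <- max.col(-d2, ties.method = "first")
    newGen <- gen
    for (g in seq_len(k)) {
      m <- assign == g
      if (any(m)) newGen[g, ] <- colMeans(P[m, , drop = FALSE])
    }
    move <- sqrt(max(rowSums((newGen - gen)^2)))
    gen <- newGen
    if (move < tolMm) break
  }
  ## keep every generator inside the region
  for (g in seq_len(k)) {
    pix <- round((gen[g, ] - c(region@pixU[1], region@pixV[1])) /
                   region@spacingMm) + 1
    inside <- pix[1] >= 1 && pix[1] <= nrow(region@mask) &&
      pix[2] >= 1 && pix[2] <= ncol(region@mask) &&
      region@mask[pix[1], pix[2]]
    if (!inside) gen[g, ] <- snapToRegion(gen[g, ], P)
  }
  colnames(gen) <- c("u", "v")
  gen
}

snapToRegion <- function(p, P) {
  P[which.min((P[, 1] - p[1])^2 + (P[, 2] - p[2])^2), ]
}

## deterministic sample of k out of n that leaves the caller's RNG alone
drawSample <- function(n, k, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(n, min(k, n))
}

#' Border spot positions along the region contour
#'
#' Walks each closed contour of the region and drops points at equal
#' arc-length steps: \code{n = round(L / spacing)} points per contour of
#' length L, so consecutive gaps stay within 20\% of the target spacing
#' (the closure remainder is spread evenly).
#'
#' @param region a [BevRegion-class].
#' @param spacingMm target arc-length step (default 5 mm).
#' @return A two-column matrix of (u, v) positions in mm.
#' @export
borderSpots <- function(region, spacingMm = 5) {
  out <- NULL
  for (co in region@contours) {
    x <- co$x; y <- co$y
    if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
      x <- c(x, x[1]); y <- c(y, y[1])
    }
    seg <- sqrt(diff(x)^2 + diff(y)^2)
    L <- sum(seg)
    if (L < spacingMm) next
    n <- max(1L, round(L / spacingMm))
    s <- cumsum(c(0, seg))
    targets <- (seq_len(n) - 1) * L / n
    px <- approx(s, x, xout = targets, rule = 2)$y
    py <- approx(s, y, xout = targets, rule = 2)$y
    out <- rbind(out, cbind(px, py))
  }
  if (is.null(out)) out <- matrix(numeric(), ncol = 2)
  colnames(out) <- c("u", "v")
  out
}

#' Place and order all spots of one field
#'
#' Combines [cvtInteriorSpots()] and [borderSpots()] on the projected PTV
#' and orders the result in a serpentine (boustrophedon) scan over BEV
#' rows of height \code{spacingMm}, the order later used by the delivery
#' models.
#'
#' @inheritParams projectPTV
#' @inheritParams cvtInteriorSpots
#' @param fieldId identifier stored with the spots.
#' @return A data.frame with columns \code{u}, \code{v}, \code{weight}
#'   (initialized to 0), \code{fieldId}, in delivery order.
#' @export
placeSpots <- function(structures, geometry, spacingMm = 5, seed = 1L,
                       fieldId = 1L, pixelMm = min(structures@spacingMm)) {
  region <- projectPTV(structures, geometry, pixelMm = pixelMm)
  pos <- rbind(cvtInteriorSpots(region, spacingMm, seed = seed),
               borderSpots(region, spacingMm))
  pos <- pos[serpentineOrder(pos, spacingMm), , drop = FALSE]
  data.frame(u = pos[, 1], v = pos[, 2], weight = 0,
             fieldId = fieldId)
}

#' Serpentine scan order
#'
#' Orders 2-D points row by row (rows of the given height along v),
#' alternating the u direction between consecutive rows.
#'
#' @param pos two-column matrix of (u, v) positions.
#' @param rowHeightMm scan row height.
#' @return Integer permutation of \code{seq_len(nrow(pos))}.
#' @export
serpentineOrder <- function(pos, rowHeightMm = 5) {
  row <- floor((pos[, 2] - min(pos[, 2])) / rowHeightMm)
  uKey <- ifelse(row %% 2 == 0, pos[, 1], -pos[, 1])
  order(row, uKey)
}
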