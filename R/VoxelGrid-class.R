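#' VoxelGrid: a 3-D scalar field with spacing and origin
#'
#' Container for any per-voxel scalar quantity used in the pipeline:
#' relative density (unitless, water = 1), dose (Gy) or dose rate (Gy/s).
#' The world position of voxel \code{(i, j, k)} (1-based) is
#' \code{origin + (c(i, j, k) - 1) * spacing}; \code{origin} is therefore
#' the centre of the first voxel, in mm.
#'
#' @slot values numeric 3-D array of voxel values.
#' @slot spacingMm numeric(3), voxel spacing in mm, all > 0.
#' @slot originMm numeric(3), world coordinates (mm) of the first voxel
#'   centre.
#'
#' @seealso [voxelGrid()], [readGrid()], [writeGrid()]
#' @export
setClass("VoxelGrid",
  representation(values = "array", spacingMm = "numeric", originMm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "'values' must be a 3-D array")
    if (length(object@spacingMm) != 3L || any(!is.finite(object@spacingMm)) ||
        any(object@spacingMm <= 0))
      msg <- c(msg, "'spacingMm' must be 3 positive finite numbers")
    if (length(object@originMm) != 3L || any(!is.finite(object@originMm)))
      msg <- c(msg, "'originMm' must be 3 finite numbers")
    if (anyNA(object@values) || any(!is.finite(object@values)))
      msg <- c(msg, "'values' must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct a VoxelGrid
#'
#' @param values 3-D numeric array.
#' @param spacingMm voxel spacing in mm (length 1 or 3).
#' @param originMm world position (mm) of the first voxel centre (length 3).
#'   The default centres the grid on the world origin, which is also the
#'   default isocenter used by [fieldGeometry()].
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- voxelGrid(array(1, dim = c(10, 10, 10)), spacingMm = 2)
#' gridDims(g)
#' @export
voxelGrid <- function(values, spacingMm = 2,
                      originMm = -(dim(values) - 1) / 2 * rep(spacingMm, length.out = 3)) {
  if (length(dim(values)) != 3L) stop("'values' must be a 3-D array")
  if (is.logical(values)) storage.mode(values) <- "double"
  new("VoxelGrid", values = values,
      spacingMm = rep(as.numeric(spacingMm), length.out = 3),
      originMm = as.numeric(originMm))
}

#' @describeIn voxelGrid Voxel values as a 3-D array.
#' @param x,object a \code{VoxelGrid}.
#' @export
gridValues <- function(x) x@values

#' @describeIn voxelGrid Grid dimensions (3 integers).
#' @export
gridDims <- function(x) dim(x@values)

#' @describeIn voxelGrid Voxel spacing in mm.
#' @export
gridSpacing <- function(x) x@spacingMm

#' @describeIn voxelGrid World position (mm) of the first voxel centre.
#' @export
gridOrigin <- function(x) x@originMm

#' @describeIn voxelGrid Volume of one voxel in mm^3.
#' @export
voxelVolumeMm3 <- function(x) prod(x@spacingMm)

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelGrid %dx%dx%d, spacing [%s] mm, origin [%s] mm\n",
              d[1], d[2], d[3],
              paste(signif(object@spacingMm, 4), collapse = ", "),
              paste(signif(object@originMm, 4), collapse = ", ")))
  cat(sprintf("  values in [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

## new grid with same geometry, different values
sameGrid <- function(template, values) {
  new("VoxelGrid", values = values, spacingMm = template@spacingMm,
      originMm = template@originMm)
}

## congruence check used by every map-combining operation
stopIfNotCongruent <- function(a, b, what = "grids") {
  if (!identical(dim(a@values), dim(b@values)) ||
      max(abs(a@spacingMm - b@spacingMm)) > 1e-9 ||
      max(abs(a@originMm - b@originMm)) > 1e-6)
    stop("mismatched ", what, ": dimensions, spacing and origin must agree")
  invisible(TRUE)
}

## world coordinates (n x 3 matrix) of a set of linear voxel indices
voxelCentersMm <- function(grid, linearIdx = NULL) {
  d <- dim(grid@values)
  if (is.null(linearIdx)) linearIdx <- seq_len(prod(d))
  idx <- arrayInd(linearIdx, d)
  sweep(sweep(idx - 1, 2, grid@spacingMm, "*"), 2, grid@originMm, "+")
}
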