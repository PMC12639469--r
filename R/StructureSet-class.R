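#' StructureSet: named binary masks on a common voxel grid
#'
#' Holds the segmentation used for planning and evaluation: one planning
#' target volume (\code{"PTV"}), one outer contour (\code{"BODY"}) and any
#' number of organs at risk. All masks live on the same grid as the
#' phantom density and every non-BODY mask is contained in BODY.
#'
#' @slot masks named list of logical 3-D arrays.
#' @slot spacingMm,originMm grid geometry shared with the density grid.
#' @export
setClass("StructureSet",
  representation(masks = "list", spacingMm = "numeric", originMm = "numeric"),
  validity = function(object) {
    msg <- character()
    nm <- names(object@masks)
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
      msg <- c(msg, "masks must have unique non-empty names")
    if (!("PTV" %in% nm)) msg <- c(msg, "a 'PTV' mask is required")
    if (!("BODY" %in% nm)) msg <- c(msg, "a 'BODY' mask is required")
    dims <- unique(lapply(object@masks, dim))
    if (length(dims) > 1L) msg <- c(msg, "all masks must share the same dims")
    if (!length(msg)) {
      if (!any(object@masks[["PTV"]])) msg <- c(msg, "PTV mask is empty")
      body <- object@masks[["BODY"]]
      for (n in setdiff(nm, "BODY"))
        if (any(object@masks[[n]] & !body))
          msg <- c(msg, sprintf("mask '%s' extends outside BODY", n))
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a StructureSet
#'
#' @param masks named list of logical arrays; must include \code{"PTV"} and
#'   \code{"BODY"}.
#' @param grid a [VoxelGrid-class] providing spacing and origin.
#' @return A [StructureSet-class].
#' @export
structureSet <- function(masks, grid) {
  new("StructureSet", masks = masks, spacingMm = grid@spacingMm,
      originMm = grid@originMm)
}

#' @describeIn structureSet Names of the masks.
#' @param x a \code{StructureSet}.
#' @export
structureNames <- function(x) names(x@masks)

#' @describeIn structureSet One mask as a logical array.
#' @param name structure name.
#' @export
structureMask <- function(x, name) {
  if (!name %in% names(x@masks))
    stop("unknown structure '", name, "'")
  x@masks[[name]]
}

#' @describeIn structureSet Structure volume in cm^3.
#' @export
structureVolumeCm3 <- function(x, name) {
  sum(structureMask(x, name)) * prod(x@spacingMm) / 1000
}

setMethod("show", "StructureSet", function(object) {
  cat("StructureSet with", length(object@masks), "structures:\n")
  for (n in names(object@masks))
    cat(sprintf("  %-12s %8d voxels (%.1f cm^3)\n", n,
                sum(object@masks[[n]]),
                sum(object@masks[[n]]) * prod(object@spacingMm) / 1000))
})
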