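#' DoseInfluenceMatrix: sparse voxel-by-node dose per unit weight
#'
#' Columns are transmission-kernel dose columns (Gy/MU) precomputed at
#' the nodes of a regular BEV lattice (the "spot grid", default 2 mm
#' pitch, anchored at the isocenter). Columns for spots at arbitrary BEV
#' positions are obtained by bilinear interpolation of the four
#' surrounding node columns ([interpolateColumn()]). Rows are a subset of
#' the voxel grid (linear indices in \code{rows}); the full grid is the
#' default.
#'
#' @slot matrix a \code{dgCMatrix}, \code{length(rows)} x \code{n_nodes}.
#' @slot nodeIU,nodeIV integer lattice indices of each column's node
#'   (node position = index * pitch, BEV mm).
#' @slot pitchMm lattice pitch in mm.
#' @slot rows integer linear voxel indices of the rows.
#' @slot refDims,refSpacing,refOrigin geometry of the underlying grid.
#' @slot fieldId integer field identifier.
#' @export
setClass("DoseInfluenceMatrix",
  representation(matrix = "dgCMatrix", nodeIU = "integer", nodeIV = "integer",
                 pitchMm = "numeric", rows = "integer", refDims = "integer",
                 refSpacing = "numeric", refOrigin = "numeric",
                 fieldId = "integer"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@matrix) != length(object@nodeIU) ||
        ncol(object@matrix) != length(object@nodeIV))
      msg <- c(msg, "one node coordinate pair per column required")
    if (nrow(object@matrix) != length(object@rows))
      msg <- c(msg, "row count must match 'rows'")
    if (length(object@matrix@x) && min(object@matrix@x) < 0)
      msg <- c(msg, "influence entries must be >= 0")
    if (object@pitchMm <= 0) msg <- c(msg, "pitch must be > 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "DoseInfluenceMatrix", function(object) {
  cat(sprintf(
    "DoseInfluenceMatrix: %d voxels x %d nodes (%.0f mm pitch), %.2f%% filled\n",
    nrow(object@matrix), ncol(object@matrix), object@pitchMm,
    100 * length(object@matrix@x) / prod(dim(object@matrix))))
})

#' @describeIn buildInfluence Node BEV positions (mm) of the columns.
#' @export
nodePositions <- function(M) {
  cbind(u = M@nodeIU * M@pitchMm, v = M@nodeIV * M@pitchMm)
}

#' Build a dose-influence matrix on a regular spot grid
#'
#' Precomputes one sparse dose column per lattice node. By default the
#' node set covers the projected PTV plus an apron of two core sigmas,
#' and the rows cover all BODY voxels; both can be restricted (e.g. to
#' the nodes actually needed for a given spot list, and to the scoring
#' voxels of the optimization) to keep desk-scale problems small.
#'
#' @param density,structures,geometry,model phantom and beam inputs
#'   ([VoxelGrid-class], [StructureSet-class], [FieldGeometry-class],
#'   [BeamModel-class]).
#' @param spotGridPitchMm lattice pitch (default 2 mm).
#' @param rows integer linear voxel indices to score; default all BODY
#'   voxels.
#' @param nodes optional two-column matrix of node BEV positions (mm;
#'   must lie on the lattice), e.g. from [nodesForSpots()]. Default: all
#'   nodes covering the projected PTV plus the apron.
#' @param apronSigmaMult apron width in units of the model's core sigma.
#' @param fieldId integer field identifier.
#' @param truncRel per-column relative sparsity threshold.
#' @return A [DoseInfluenceMatrix-class].
#' @export
buildInfluence <- function(density, structures, geometry, model,
                           spotGridPitchMm = 2, rows = NULL, nodes = NULL,
                           apronSigmaMult = 2, fieldId = 1L,
                           truncRel = 1e-4) {
  if (is.null(rows)) rows <- which(structureMask(structures, "BODY"))
  rows <- as.integer(rows)
  if (is.null(nodes)) {
    region <- projectPTV(structures, geometry)
    apron <- apronSigmaMult * model@lateral$sigma1Mm
    P <- regionPixels(region)
    iu <- seq(floor((min(P[, 1]) - apron) / spotGridPitchMm),
              ceiling((max(P[, 1]) + apron) / spotGridPitchMm))
    iv <- seq(floor((min(P[, 2]) - apron) / spotGridPitchMm),
              ceiling((max(P[, 2]) + apron) / spotGridPitchMm))
    cand <- cbind(rep(iu, times = length(iv)) * spotGridPitchMm,
                  rep(iv, each = length(iu)) * spotGridPitchMm)
    ## keep nodes within the apron distance of the region
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      d2 <- (P[, 1] - cand[i, 1])^2 + (P[, 2] - cand[i, 2])^2
      keep[i] <- min(d2) <= apron^2
    }
    nodes <- cand[keep, , drop = FALSE]
  }
  iu <- as.integer(round(nodes[, 1] / spotGridPitchMm))
  iv <- as.integer(round(nodes[, 2] / spotGridPitchMm))
  if (max(abs(nodes[, 1] - iu * spotGridPitchMm),
          abs(nodes[, 2] - iv * spotGridPitchMm)) > 1e-6)
    stop("'nodes' must lie on the spot-grid lattice")
  ctx <- fieldContext(density, geometry, rows)
  ti <- vector("list", length(iu)); tx <- vector("list", length(iu))
  for (k in seq_along(iu)) {
    col <- spotColumnValues(ctx, model,
                            c(iu[k], iv[k]) * spotGridPitchMm, truncRel)
    ti[[k]] <- col$i; tx[[k]] <- col$x
  }
  nn <- lengths(ti)
  M <- Matrix::sparseMatrix(i = unlist(ti), j = rep(seq_along(iu), nn),
                            x = unlist(tx),
                            dims = c(length(rows), length(iu)))
  new("DoseInfluenceMatrix", matrix = M, nodeIU = iu, nodeIV = iv,
      pitchMm = as.numeric(spotGridPitchMm), rows = rows,
      refDims = as.integer(gridDims(density)),
      refSpacing = gridSpacing(density), refOrigin = gridOrigin(density),
      fieldId = as.integer(fieldId))
}

#' Lattice nodes needed to interpolate a set of spots
#'
#' The four lattice neighbours of every spot, optionally padded by
#' \code{marginMm} on each side (useful when spot positions will be
#' refined within the node pitch).
#'
#' @param spots data.frame with columns \code{u}, \code{v} (mm).
#' @param pitchMm lattice pitch.
#' @param marginMm extra lattice margin around each spot.
#' @return Two-column matrix of unique node positions (mm).
#' @export
nodesForSpots <- function(spots, pitchMm = 2, marginMm = 0) {
  pad <- ceiling(marginMm / pitchMm)
  keys <- unique(unlist(lapply(seq_len(nrow(spots)), function(s) {
    iu <- seq(floor(spots$u[s] / pitchMm) - pad,
              ceiling(spots$u[s] / pitchMm) + pad)
    iv <- seq(floor(spots$v[s] / pitchMm) - pad,
              ceiling(spots$v[s] / pitchMm) + pad)
    outer(iu, iv, function(a, b) paste(a, b))
  })))
  ij <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  cbind(ij[, 1], ij[, 2]) * pitchMm
}

#' Interpolate a dose column at an arbitrary BEV position
#'
#' Bilinear combination of the four node columns surrounding the
#' position; at a node it returns that node's column exactly. An error is
#' raised if a needed node (nonzero interpolation weight) is absent from
#' the matrix.
#'
#' @param M a [DoseInfluenceMatrix-class].
#' @param positionBevMm numeric(2), (u, v) in mm.
#' @return A sparse numeric column (\code{Matrix::sparseVector}).
#' @export
interpolateColumn <- function(M, positionBevMm) {
  w <- interpWeights(M, positionBevMm)
  out <- methods::as(
    M@matrix[, w$cols, drop = FALSE] %*%
      Matrix::Matrix(w$w, ncol = 1, sparse = TRUE),
    "CsparseMatrix")
  Matrix::sparseVector(out@x, out@i + 1L, nrow(M@matrix))
}

## shared node lookup: columns + bilinear weights for one position
interpWeights <- function(M, pos) {
  p <- M@pitchMm
  fu <- pos[1] / p; fv <- pos[2] / p
  iu0 <- floor(fu); iv0 <- floor(fv)
  wu <- fu - iu0; wv <- fv - iv0
  cand <- cbind(iu = c(iu0, iu0 + 1, iu0, iu0 + 1),
                iv = c(iv0, iv0, iv0 + 1, iv0 + 1))
  wt <- c((1 - wu) * (1 - wv), wu * (1 - wv), (1 - wu) * wv, wu * wv)
  keep <- wt > 1e-12
  cand <- cand[keep, , drop = FALSE]; wt <- wt[keep]
  cols <- match(paste(cand[, 1], cand[, 2]), paste(M@nodeIU, M@nodeIV))
  if (anyNA(cols))
    stop("position outside the precomputed node hull")
  list(cols = cols, w = wt)
}

#' Interpolated columns for a whole spot list
#'
#' @param M a [DoseInfluenceMatrix-class].
#' @param spots data.frame with \code{u}, \code{v} columns.
#' @return Sparse matrix (\code{dgCMatrix}), one interpolated column per
#'   spot, rows as in \code{M}.
#' @export
spotColumns <- function(M, spots) {
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (s in seq_len(nrow(spots))) {
    w <- interpWeights(M, c(spots$u[s], spots$v[s]))
    ii <- c(ii, w$cols); jj <- c(jj, rep(s, length(w$cols)))
    xx <- c(xx, w$w)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(ncol(M@matrix), nrow(spots)))
  methods::as(M@matrix %*% W, "CsparseMatrix")
}

#' Dense dose grid from influence columns and weights
#'
#' @param M a [DoseInfluenceMatrix-class] (or any sparse matrix plus the
#'   matching row index set).
#' @param weights nonnegative spot/node weights, one per column.
#' @return A [VoxelGrid-class] dose map (zero outside \code{rows}).
#' @export
doseFromInfluence <- function(M, weights) {
  vals <- array(0, dim = M@refDims)
  vals[M@rows] <- as.numeric(M@matrix %*% weights)
  new("VoxelGrid", values = vals, spacingMm = M@refSpacing,
      originMm = M@refOrigin)
}

## same columns evaluated directly (no node interpolation); used for the
## final full-grid dose and dose-rate maps
directSpotMatrix <- function(density, geometry, model, spots, rows = NULL,
                             ctx = NULL, truncRel = 1e-4, fieldId = 1L) {
  if (is.null(rows)) rows <- seq_len(prod(gridDims(density)))
  rows <- as.integer(rows)
  if (is.null(ctx)) ctx <- fieldContext(density, geometry, rows)
  ti <- vector("list", nrow(spots)); tx <- vector("list", nrow(spots))
  for (s in seq_len(nrow(spots))) {
    col <- spotColumnValues(ctx, model, c(spots$u[s], spots$v[s]), truncRel)
    ti[[s]] <- col$i; tx[[s]] <- col$x
  }
  nn <- lengths(ti)
  M <- Matrix::sparseMatrix(i = unlist(ti), j = rep(seq_len(nrow(spots)), nn),
                            x = unlist(tx),
                            dims = c(length(rows), nrow(spots)))
  new("DoseInfluenceMatrix", matrix = M,
      nodeIU = rep(NA_integer_, nrow(spots)),
      nodeIV = rep(NA_integer_, nrow(spots)),
      pitchMm = 1, rows = rows, refDims = as.integer(gridDims(density)),
      refSpacing = gridSpacing(density), refOrigin = gridOrigin(density),
      fieldId = as.integer(fieldId))
}
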