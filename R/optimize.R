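#' Scorecard objectives
#'
#' A scorecard is a data.frame of planning objectives, one row each:
#' \code{structure} (name in the structure set), \code{type} (one of
#' \code{min_dose}, \code{max_dose}, \code{mean_dose_max},
#' \code{uniform}), \code{levelGy} (>= 0) and \code{priority} (> 0). The
#' objective functional is the priority-weighted sum of mean squared
#' one-sided violations:
#' \itemize{
#'   \item \code{min_dose}: mean over structure voxels of
#'     \code{pmax(L - d, 0)^2}
#'   \item \code{max_dose}: mean of \code{pmax(d - L, 0)^2}
#'   \item \code{mean_dose_max}: \code{pmax(mean(d) - L, 0)^2}
#'   \item \code{uniform}: mean of \code{(d - L)^2}
#' }
#'
#' @param structure,type,levelGy,priority vectors of equal length (or
#'   length 1, recycled).
#' @return A scorecard data.frame.
#' @examples
#' scorecard(c("PTV", "PTV", "OAR1"),
#'           c("uniform", "min_dose", "max_dose"),
#'           c(30, 28.5, 15), c(50, 100, 5))
#' @export
scorecard <- function(structure, type, levelGy, priority = 1) {
  sc <- data.frame(structure = structure, type = type,
                   levelGy = levelGy, priority = priority)
  bad <- !sc$type %in% c("min_dose", "max_dose", "mean_dose_max", "uniform")
  if (any(bad)) stop("unknown objective type: ", sc$type[bad][1])
  if (any(sc$levelGy < 0)) stop("objective levels must be >= 0")
  if (any(sc$priority <= 0)) stop("priorities must be > 0")
  sc
}

## read/write scorecards as JSON (external interface)
#' @rdname scorecard
#' @param path JSON file path.
#' @param sc a scorecard data.frame.
#' @export
writeScorecard <- function(sc, path) {
  jsonlite::write_json(sc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname scorecard
#' @export
readScorecard <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scorecard(j$structure, j$type, j$levelGy, j$priority)
}

## objective value (+ gradient wrt the dose vector) on a row subset;
## idxList maps each scorecard structure to indices into doseVec
objectiveCore <- function(doseVec, sc, idxList, gradient = FALSE) {
  f <- 0
  g <- if (gradient) numeric(length(doseVec)) else NULL
  for (o in seq_len(nrow(sc))) {
    idx <- idxList[[sc$structure[o]]]
    d <- doseVec[idx]; L <- sc$levelGy[o]; p <- sc$priority[o]
    n <- length(d)
    if (sc$type[o] == "min_dose") {
      viol <- pmax(L - d, 0)
      f <- f + p * mean(viol^2)
      if (gradient) g[idx] <- g[idx] - 2 * p * viol / n
    } else if (sc$type[o] == "max_dose") {
      viol <- pmax(d - L, 0)
      f <- f + p * mean(viol^2)
      if (gradient) g[idx] <- g[idx] + 2 * p * viol / n
    } else if (sc$type[o] == "mean_dose_max") {
      viol <- max(mean(d) - L, 0)
      f <- f + p * viol^2
      if (gradient) g[idx] <- g[idx] + 2 * p * viol / n
    } else {                                   # uniform
      f <- f + p * mean((d - L)^2)
      if (gradient) g[idx] <- g[idx] + 2 * p * (d - L) / n
    }
  }
  list(f = f, g = g)
}

#' Scorecard objective value of a dose distribution
#'
#' @param dose a [VoxelGrid-class] dose map on the same grid as the
#'   masks.
#' @param sc a [scorecard()] data.frame.
#' @param structures a [StructureSet-class].
#' @return Nonnegative scalar; 0 iff every objective is met.
#' @export
objectiveValue <- function(dose, sc, structures) {
  doseVec <- as.numeric(dose@values)
  idxList <- lapply(setNames(nm = unique(sc$structure)), function(nm)
    which(structureMask(structures, nm)))
  objectiveCore(doseVec, sc, idxList, gradient = FALSE)$f
}

#' OptimizationResult: fitted spot weights and convergence trace
#'
#' @slot weights nonnegative spot weights (MU).
#' @slot trace objective value per accepted iterate (non-increasing).
#' @slot converged logical.
#' @slot iterations number of iterations run.
#' @export
setClass("OptimizationResult",
  representation(weights = "numeric", trace = "numeric",
                 converged = "logical", iterations = "integer"),
  validity = function(object) {
    if (any(object@weights < 0)) return("weights must be >= 0")
    if (is.unsorted(rev(object@trace)) && any(diff(object@trace) > 1e-9))
      return("objective trace must be non-increasing")
    TRUE
  })

setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf(
    "OptimizationResult: %d spots, objective %.4g after %d iterations (%s)\n",
    length(object@weights), tail(object@trace, 1), object@iterations,
    if (object@converged) "converged" else "not converged"))
})

## accept a DoseInfluenceMatrix, a list of them, or a plain dgCMatrix
normalizeColumns <- function(M) {
  if (is(M, "DoseInfluenceMatrix")) return(list(A = M@matrix, rows = M@rows))
  if (is(M, "sparseMatrix") || is.matrix(M))
    return(list(A = methods::as(M, "CsparseMatrix"), rows = NULL))
  if (is.list(M)) {
    parts <- lapply(M, normalizeColumns)
    rows <- parts[[1]]$rows
    for (p in parts) if (!identical(p$rows, rows))
      stop("all per-field matrices must share the same row set")
    return(list(A = do.call(cbind, lapply(parts, `[[`, "A")), rows = rows))
  }
  stop("unsupported influence input")
}

#' Optimize nonnegative spot weights against a scorecard
#'
#' Minimizes the scorecard objective of the summed dose
#' \code{sum_f M_f w_f} subject to \code{w >= 0} with a projected
#' gradient method (Barzilai-Borwein step seeded, monotone backtracking
#' line search, so the objective trace is non-increasing by
#' construction). Stops when the relative objective change drops below
#' \code{tol} or after \code{maxIter} iterations.
#'
#' @param M a [DoseInfluenceMatrix-class], a list of them (one per
#'   field, identical row sets), or a plain sparse matrix of spot
#'   columns; combined with \code{rows} when not self-describing.
#' @param sc a [scorecard()] data.frame (no objectives: \code{init} is
#'   returned unchanged with objective 0).
#' @param structures a [StructureSet-class]; every scorecard structure
#'   must intersect the matrix rows.
#' @param init initial weights; default uniform, scaled so the mean PTV
#'   dose equals the first \code{uniform} (else \code{min_dose})
#'   objective level on the PTV, or 1 MU if there is none.
#' @param tol relative objective-change tolerance.
#' @param maxIter iteration cap.
#' @param rows linear voxel indices of the matrix rows (only needed for
#'   plain-matrix input).
#' @return An [OptimizationResult-class].
#' @export
optimizeWeights <- function(M, sc, structures, init = NULL, tol = 1e-6,
                            maxIter = 500L, rows = NULL) {
  nc <- normalizeColumns(M)
  A <- nc$A
  rows <- nc$rows %||% rows %||% seq_len(nrow(A))
  if (ncol(A) < 1L) stop("at least one spot is required")
  if (length(A@x) == 0L || max(A@x) == 0)
    stop("all-zero influence: no spot reaches the scored voxels")
  idxList <- lapply(setNames(nm = unique(sc$structure)), function(nm) {
    idx <- match(which(structureMask(structures, nm)), rows)
    idx <- idx[!is.na(idx)]
    if (!length(idx))
      stop("structure '", nm, "' has no voxels among the matrix rows")
    idx
  })
  if (is.null(init)) {
    w0 <- rep(1, ncol(A))
    ref <- sc$levelGy[sc$structure == "PTV" & sc$type == "uniform"][1]
    if (is.na(ref))
      ref <- sc$levelGy[sc$structure == "PTV" & sc$type == "min_dose"][1]
    if (!is.na(ref) && "PTV" %in% names(idxList)) {
      mPTV <- mean((A %*% w0)[idxList[["PTV"]]])
      if (mPTV > 0) w0 <- w0 * ref / mPTV
    }
  } else w0 <- pmax(init, 0)
  if (nrow(sc) == 0L)
    return(new("OptimizationResult", weights = w0, trace = 0,
               converged = TRUE, iterations = 0L))

  w <- w0
  d <- as.numeric(A %*% w)
  ob <- objectiveCore(d, sc, idxList, gradient = TRUE)
  f <- ob$f
  grad <- as.numeric(Matrix::crossprod(A, ob$g))
  trace <- f
  ## scale-free first step: rescaling all priorities rescales the
  ## gradient and this step alike, leaving the iterate path unchanged
  alpha <- (sum(abs(w)) + 1) / (sum(abs(grad)) + 1e-300)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    accepted <- FALSE
    a <- alpha
    for (bt in 1:60) {
      wNew <- pmax(w - a * grad, 0)
      dNew <- as.numeric(A %*% wNew)
      fNew <- objectiveCore(dNew, sc, idxList)$f
      dec <- sum(grad * (w - wNew))
      if (fNew <= f - 1e-4 * dec && fNew <= f) { accepted <- TRUE; break }
      a <- a / 2
    }
    if (!accepted) { converged <- TRUE; break }
    sVec <- wNew - w
    obNew <- objectiveCore(dNew, sc, idxList, gradient = TRUE)
    gradNew <- as.numeric(Matrix::crossprod(A, obNew$g))
    yVec <- gradNew - grad
    sy <- sum(sVec * yVec)
    alpha <- if (sy > 0) sum(sVec^2) / sy else a * 2
    relChange <- (f - fNew) / max(f, .Machine$double.eps)
    w <- wNew; f <- fNew; grad <- gradNew
    trace <- c(trace, f)
    if (relChange < tol || f == 0) { converged <- TRUE; break }
  }
  new("OptimizationResult", weights = w, trace = trace,
      converged = converged, iterations = it)
}

#' Refine spot positions by local search on interpolated columns
#'
#' Alternates (a) a per-spot position move along the negative
#' finite-difference gradient of the objective (evaluated through
#' [interpolateColumn()] with all other spots fixed), with the move
#' length capped at half the node pitch, and (b) a re-fit of all weights
#' with [optimizeWeights()]. A round's moves are kept only if the re-fit
#' objective improves, so the objective never increases.
#'
#' @param spots data.frame from [placeSpots()] (columns \code{u},
#'   \code{v}).
#' @param M a [DoseInfluenceMatrix-class] whose node set covers the
#'   spots plus the intended movement range (see [nodesForSpots()]).
#' @param sc,structures scorecard and structures, as in
#'   [optimizeWeights()].
#' @param rounds number of alternating rounds.
#' @param deltaMm finite-difference probe distance.
#' @param tol,maxIter weight-fit controls.
#' @return A list with \code{spots} (updated positions and weights),
#'   \code{result} (final [OptimizationResult-class]) and
#'   \code{objectiveByRound} (initial value followed by one value per
#'   accepted round; non-increasing).
#' @export
optimizePositions <- function(spots, M, sc, structures, rounds = 3L,
                              deltaMm = 0.5, tol = 1e-6, maxIter = 200L) {
  maxStep <- M@pitchMm / 2
  fit <- function(sp) {
    S <- spotColumns(M, sp)
    optimizeWeights(S, sc, structures, rows = M@rows, tol = tol,
                    maxIter = maxIter)
  }
  res <- fit(spots)
  fBest <- tail(res@trace, 1)
  objByRound <- fBest
  idxList <- lapply(setNames(nm = unique(sc$structure)), function(nm) {
    idx <- match(which(structureMask(structures, nm)), M@rows)
    idx[!is.na(idx)]
  })
  for (r in seq_len(rounds)) {
    S <- spotColumns(M, spots)
    dTot <- as.numeric(S %*% res@weights)
    cand <- spots
    for (s in seq_len(nrow(spots))) {
      ws <- res@weights[s]
      if (ws == 0) next
      pos <- c(spots$u[s], spots$v[s])
      base <- dTot - ws * as.numeric(S[, s])
      probe <- function(p) {
        col <- tryCatch(as.numeric(interpolateColumn(M, p)),
                        error = function(e) NULL)
        if (is.null(col)) return(NA_real_)
        objectiveCore(base + ws * col, sc, idxList)$f
      }
      fdu <- (probe(pos + c(deltaMm, 0)) - probe(pos - c(deltaMm, 0))) /
        (2 * deltaMm)
      fdv <- (probe(pos + c(0, deltaMm)) - probe(pos - c(0, deltaMm))) /
        (2 * deltaMm)
      if (anyNA(c(fdu, fdv))) next
      gn <- sqrt(fdu^2 + fdv^2)
      if (gn < 1e-12) next
      newPos <- pos - c(fdu, fdv) / gn * maxStep
      fOld <- probe(pos); fMoved <- probe(newPos)
      if (!is.na(fMoved) && fMoved < fOld) {
        cand$u[s] <- newPos[1]; cand$v[s] <- newPos[2]
      }
    }
    resCand <- tryCatch(fit(cand), error = function(e) NULL)
    if (!is.null(resCand) && tail(resCand@trace, 1) < fBest) {
      spots <- cand; res <- resCand; fBest <- tail(resCand@trace, 1)
      objByRound <- c(objByRound, fBest)
    } else {
      objByRound <- c(objByRound, fBest)
    }
  }
  spots$weight <- res@weights
  list(spots = spots, result = res, objectiveByRound = objByRound)
}
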