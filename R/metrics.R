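#' CumulativeVolumeCurve: DVH or DRDVH
#'
#' Fraction of a structure's volume receiving strictly more than each
#' dose level. A DRDVH is the same curve evaluated on the UHDR dose map
#' ([flashDoseMap()]), i.e. the dose delivered at PBS dose rate at or
#' above the UHDR threshold; it is pointwise below the DVH.
#'
#' @slot levelsGy strictly increasing dose levels (Gy).
#' @slot volumeFraction fraction of structure volume above each level.
#' @slot structure structure name.
#' @slot kind \code{"DVH"} or \code{"DRDVH"}.
#' @export
setClass("CumulativeVolumeCurve",
  representation(levelsGy = "numeric", volumeFraction = "numeric",
                 structure = "character", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@levelsGy, strictly = TRUE))
      msg <- c(msg, "levels must be strictly increasing")
    if (any(object@volumeFraction < 0 | object@volumeFraction > 1))
      msg <- c(msg, "volume fractions must be in [0, 1]")
    if (any(diff(object@volumeFraction) > 1e-12))
      msg <- c(msg, "curve must be non-increasing")
    if (!object@kind %in% c("DVH", "DRDVH")) msg <- c(msg, "bad kind")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "CumulativeVolumeCurve", function(object) {
  cat(sprintf("%s of %s: %d levels in [%.3g, %.3g] Gy, V(first) = %.3f\n",
              object@kind, object@structure, length(object@levelsGy),
              min(object@levelsGy), max(object@levelsGy),
              object@volumeFraction[1]))
})

#' @describeIn dvhCurve Curve as a data.frame (for CSV export).
#' @param curve a \code{CumulativeVolumeCurve}.
#' @export
curveAsDataFrame <- function(curve) {
  data.frame(structure = curve@structure, kind = curve@kind,
             levelGy = curve@levelsGy, volumeFraction = curve@volumeFraction)
}

#' Cumulative dose-volume histogram
#'
#' \code{value(L) = #\{mask voxels with dose > L\} / #\{mask voxels\}}
#' (strict inequality, matching the FLASH-index convention of counting
#' dose strictly above the threshold).
#'
#' @param dose a [VoxelGrid-class].
#' @param mask logical array congruent with the dose grid, or a
#'   structure name resolved in \code{structures}.
#' @param levels dose levels (Gy).
#' @param structures optional [StructureSet-class] when \code{mask} is a
#'   name.
#' @param name label stored on the curve.
#' @return A [CumulativeVolumeCurve-class].
#' @export
dvhCurve <- function(dose, mask, levels = seq(0, 1.2 * max(gridValues(dose)),
                                              length.out = 121),
                     structures = NULL, name = "structure") {
  m <- resolveMask(mask, structures, dose)
  if (!any(m)) stop("empty mask")
  d <- dose@values[m]
  frac <- vapply(levels, function(L) mean(d > L), 0)
  new("CumulativeVolumeCurve", levelsGy = as.numeric(levels),
      volumeFraction = frac, structure = name, kind = "DVH")
}

#' @rdname dvhCurve
#' @param flashDose the UHDR dose map from [flashDoseMap()].
#' @export
drdvhCurve <- function(flashDose, mask, levels = seq(0, 1.2 * max(gridValues(flashDose)) + 1e-9,
                                                     length.out = 121),
                       structures = NULL, name = "structure") {
  cv <- dvhCurve(flashDose, mask, levels, structures, name)
  cv@kind <- "DRDVH"
  cv
}

resolveMask <- function(mask, structures, grid) {
  if (is.character(mask)) {
    if (is.null(structures)) stop("'structures' needed to resolve '", mask, "'")
    mask <- structureMask(structures, mask)
  }
  if (!identical(dim(mask), dim(grid@values)))
    stop("mismatched grids: mask and dose dimensions differ")
  mask
}

#' Dose quantile D_x\%
#'
#' Minimum dose received by the hottest x\% of the structure volume:
#' voxel doses are sorted descending and linearly interpolated at rank
#' \code{1 + (x/100) * (N - 1)} (the standard sample-quantile
#' convention; equals \code{quantile(d, 1 - x/100, type = 7)}).
#'
#' @param dose a [VoxelGrid-class].
#' @param mask logical array or structure name.
#' @param xPercent quantile in (0, 100): 2 gives D2\% (near-max), 98
#'   gives D98\% (near-min).
#' @param structures optional [StructureSet-class].
#' @return Dose in Gy.
#' @export
doseQuantile <- function(dose, mask, xPercent, structures = NULL) {
  stopifnot(xPercent > 0, xPercent < 100)
  m <- resolveMask(mask, structures, dose)
  if (!any(m)) stop("empty mask")
  unname(quantile(dose@values[m], 1 - xPercent / 100, type = 7))
}

#' Standard plan metrics
#'
#' Per structure: D2\%, D95\%, D98\%, mean dose, and the percentage of
#' the volume receiving strictly more than 10 Gy. For the PTV
#' additionally the homogeneity index \code{HI98 = D98\% / D2\%} and the
#' conformity indices \code{CI_X = V(PTV, >= X\% of prescription) /
#' V(total, >= X\%)} at X = 95 and 50, with the BODY mask as the total
#' volume. A conformity index with an empty denominator is reported as
#' \code{NA}.
#'
#' @param dose a [VoxelGrid-class].
#' @param structures a [StructureSet-class].
#' @param prescriptionGy prescription dose (Gy).
#' @return A data.frame, one row per structure.
#' @export
planMetrics <- function(dose, structures, prescriptionGy) {
  out <- NULL
  body <- structureMask(structures, "BODY")
  for (nm in structureNames(structures)) {
    m <- structureMask(structures, nm)
    d <- dose@values[m]
    row <- data.frame(
      structure = nm,
      D2 = unname(quantile(d, 0.98, type = 7)),
      D95 = unname(quantile(d, 0.05, type = 7)),
      D98 = unname(quantile(d, 0.02, type = 7)),
      Dmean = mean(d),
      V10Gy_pct = 100 * mean(d > 10),
      HI98 = NA_real_, CI95 = NA_real_, CI50 = NA_real_)
    if (nm == "PTV") {
      row$HI98 <- row$D98 / row$D2
      for (X in c(95, 50)) {
        thr <- X / 100 * prescriptionGy
        denom <- sum(dose@values[body] >= thr)
        val <- if (denom > 0) sum(d >= thr) / denom else NA_real_
        if (X == 95) row$CI95 <- val else row$CI50 <- val
      }
    }
    out <- rbind(out, row)
  }
  out
}

#' FlashIndexResult: the FLASH index and its ingredients
#'
#' @slot doseThresholdGy,drThresholdGyPerS the two thresholds X and Y of
#'   FI(X Gy, Y Gy/s).
#' @slot volDVH fraction of mask voxels with dose > X.
#' @slot volDRDVH fraction with UHDR dose > X (the UHDR map already
#'   encodes the dose-rate condition).
#' @slot fi the index: \code{volDRDVH / volDVH}, defined as 0 when
#'   \code{volDVH = 0}; always in [0, 1].
#' @export
setClass("FlashIndexResult",
  representation(doseThresholdGy = "numeric", drThresholdGyPerS = "numeric",
                 volDVH = "numeric", volDRDVH = "numeric", fi = "numeric"),
  validity = function(object) {
    if (object@fi < -1e-12 || object@fi > 1 + 1e-12)
      return("FI must be in [0, 1]")
    if (object@volDRDVH > object@volDVH + 1e-12)
      return("VolDRDVH must not exceed VolDVH")
    TRUE
  })

setMethod("show", "FlashIndexResult", function(object) {
  cat(sprintf(
    "FI(%g Gy, %g Gy/s) = %.4f  [VolDVH = %.4f, VolDRDVH = %.4f]\n",
    object@doseThresholdGy, object@drThresholdGyPerS, object@fi,
    object@volDVH, object@volDRDVH))
})

#' @describeIn flashIndex Numeric FI value of a result object.
#' @param x a \code{FlashIndexResult}.
#' @export
fiValue <- function(x) x@fi

#' FLASH index FI(X Gy, Y Gy/s)
#'
#' Fraction of the structure's voxels receiving dose strictly above X Gy
#' at a PBS dose rate at or above Y Gy/s, divided by the fraction of
#' voxels receiving dose strictly above X Gy. An FI of 1 means every
#' voxel above the dose threshold met the UHDR condition; when no voxel
#' exceeds the dose threshold the index is defined as 0.
#'
#' @param dose total dose [VoxelGrid-class].
#' @param flashDose UHDR dose map from [flashDoseMap()] (already encodes
#'   the dose-rate threshold Y).
#' @param mask logical array or structure name.
#' @param doseThresholdGy X (default 10 Gy).
#' @param drThresholdGyPerS Y, recorded with the result (default 40
#'   Gy/s).
#' @param structures optional [StructureSet-class].
#' @return A [FlashIndexResult-class].
#' @export
flashIndex <- function(dose, flashDose, mask, doseThresholdGy = 10,
                       drThresholdGyPerS = 40, structures = NULL) {
  stopIfNotCongruent(dose, flashDose)
  m <- resolveMask(mask, structures, dose)
  if (!any(m)) stop("empty mask")
  volDVH <- mean(dose@values[m] > doseThresholdGy)
  volDRDVH <- mean(flashDose@values[m] > doseThresholdGy)
  fi <- if (volDVH > 0) volDRDVH / volDVH else 0
  new("FlashIndexResult", doseThresholdGy = doseThresholdGy,
      drThresholdGyPerS = drThresholdGyPerS, volDVH = volDVH,
      volDRDVH = volDRDVH, fi = fi)
}

#' Threshold-robustness scan of the FLASH index
#'
#' Recomputes the UHDR dose map for every dose-rate threshold of the
#' grid and evaluates FI at every dose threshold: a full factorial table
#' over the ranges explored in FLASH-planning robustness analyses
#' (default 0-20 Gy and 30-100 Gy/s). For a fixed dose threshold, FI is
#' non-increasing in the dose-rate threshold.
#'
#' @param fieldDose,fieldRate per-field dose and dose-rate maps (lists
#'   of [VoxelGrid-class]).
#' @param mask logical array or structure name.
#' @param doseThresholdsGy,drThresholdsGyPerS scan grids.
#' @param cfg a [doseRateConfig()] (fraction count).
#' @param structures optional [StructureSet-class].
#' @return A data.frame with columns \code{doseThresholdGy},
#'   \code{drThresholdGyPerS}, \code{volDVH}, \code{volDRDVH},
#'   \code{fi}.
#' @export
fiRobustnessScan <- function(fieldDose, fieldRate, mask,
                             doseThresholdsGy = seq(0, 20, by = 5),
                             drThresholdsGyPerS = seq(30, 100, by = 10),
                             cfg = doseRateConfig(), structures = NULL) {
  total <- Reduce(function(a, b) sameGrid(a, a@values + b@values), fieldDose)
  total <- sameGrid(total, total@values * cfg$fractions)
  out <- NULL
  for (dr in drThresholdsGyPerS) {
    cfgDr <- cfg; cfgDr$uhdrThresholdGyPerS <- dr
    fd <- flashDoseMap(fieldDose, fieldRate, cfgDr)
    for (X in doseThresholdsGy) {
      r <- flashIndex(total, fd, mask, X, dr, structures)
      out <- rbind(out, data.frame(doseThresholdGy = X,
                                   drThresholdGyPerS = dr,
                                   volDVH = r@volDVH, volDRDVH = r@volDRDVH,
                                   fi = r@fi))
    }
  }
  out
}
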