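#' Machine models for delivery-time computation
#'
#' \code{protonMachine()} describes a cyclotron-driven scanned beam that
#' dwells on each spot (dwell = weight / nozzle dose rate) and travels
#' between spots at finite scan speed (per-axis; the travel time is the
#' slower axis) plus a fixed switch overhead. No dose is delivered during
#' travel. \code{vheeMachine()} describes a pulsed linac: pulses of width
#' \code{pulseWidthS} fire on the global \code{1/prfHz} time lattice, one
#' spot per pulse, consecutively; a spot needing more than
#' \code{maxDosePerPulseMU} takes \code{ceiling(weight / max)} pulses.
#' Beam deflection between spots is assumed faster than the pulse gap.
#'
#' The defaults are configuration surrogates representative of a
#' ProBeam-class FLASH proton delivery (a 30 MU spot dwells 3 ms) and of
#' published preliminary FLASH linac designs; they are not measured
#' machine data.
#'
#' @param nozzleDoseRateMUPerS beam-on nozzle output (MU/s).
#' @param scanSpeedMmPerS per-axis scan speed (length 1 or 2, mm/s).
#' @param spotSwitchOverheadS fixed per-move overhead (s).
#' @return A list with class tag carried in \code{$kind}.
#' @export
protonMachine <- function(nozzleDoseRateMUPerS = 1e4,
                          scanSpeedMmPerS = c(1e4, 1e4),
                          spotSwitchOverheadS = 0) {
  stopifnot(nozzleDoseRateMUPerS > 0, all(scanSpeedMmPerS > 0),
            spotSwitchOverheadS >= 0)
  list(kind = "proton", nozzleDoseRateMUPerS = nozzleDoseRateMUPerS,
       scanSpeedMmPerS = rep(scanSpeedMmPerS, length.out = 2),
       spotSwitchOverheadS = spotSwitchOverheadS)
}

#' @rdname protonMachine
#' @param prfHz pulse repetition frequency (Hz); 100-1000 is the range of
#'   interest for FLASH-compatible linacs.
#' @param pulseWidthS pulse width tau (s); must satisfy
#'   \code{tau < 1/prf}.
#' @param maxDosePerPulseMU largest spot weight deliverable in one pulse.
#' @export
vheeMachine <- function(prfHz = 500, pulseWidthS = 4e-6,
                        maxDosePerPulseMU = 100) {
  stopifnot(prfHz > 0, pulseWidthS > 0, maxDosePerPulseMU > 0)
  if (pulseWidthS >= 1 / prfHz)
    stop("pulse width must be shorter than the pulse period 1/prf")
  list(kind = "vhee", prfHz = prfHz, pulseWidthS = pulseWidthS,
       maxDosePerPulseMU = maxDosePerPulseMU)
}

#' DeliveryTimeline: beam-on intervals for one field of one fraction
#'
#' Each row is one beam-on interval: the spot it belongs to, its start
#' time, duration and the weight (MU) delivered in it. Intervals are
#' ordered and non-overlapping. A multi-pulse VHEE spot occupies several
#' rows; a zero-weight proton spot occupies a zero-duration row (it still
#' costs travel time).
#'
#' @slot events data.frame with columns \code{spot}, \code{startS},
#'   \code{durationS}, \code{weightMU}.
#' @slot fieldId,fraction identifiers.
#' @export
setClass("DeliveryTimeline",
  representation(events = "data.frame", fieldId = "integer",
                 fraction = "integer"),
  validity = function(object) {
    ev <- object@events
    need <- c("spot", "startS", "durationS", "weightMU")
    if (!all(need %in% names(ev))) return("missing event columns")
    if (any(ev$durationS < 0)) return("durations must be >= 0")
    if (is.unsorted(ev$startS)) return("events must be ordered in time")
    if (nrow(ev) > 1) {
      ends <- ev$startS + ev$durationS
      if (any(ev$startS[-1] < ends[-nrow(ev)] - 1e-12))
        return("events must not overlap")
    }
    TRUE
  })

setMethod("show", "DeliveryTimeline", function(object) {
  ev <- object@events
  cat(sprintf(
    "DeliveryTimeline field %d: %d events over %.4f s (beam-on %.4f s)\n",
    object@fieldId, nrow(ev),
    if (nrow(ev)) max(ev$startS + ev$durationS) else 0, sum(ev$durationS)))
})

#' @describeIn scheduleProton Total field delivery time in seconds.
#' @param timeline a \code{DeliveryTimeline}.
#' @export
fieldTimeS <- function(timeline) {
  ev <- timeline@events
  if (!nrow(ev)) return(0)
  max(ev$startS + ev$durationS)
}

#' Delivery timeline of a scanned continuous proton beam
#'
#' Spots are delivered in the order given (use [serpentineOrder()]
#' upstream): dwell \code{weight / nozzleDoseRate} on each spot, then
#' travel \code{max(|du|/v_u, |dv|/v_v) + overhead} to the next.
#'
#' @param spots data.frame with columns \code{u}, \code{v},
#'   \code{weight} in delivery order.
#' @param machine a [protonMachine()].
#' @param fieldId,fraction identifiers stored on the timeline.
#' @return A [DeliveryTimeline-class].
#' @export
scheduleProton <- function(spots, machine, fieldId = 1L, fraction = 1L) {
  stopifnot(machine$kind == "proton")
  n <- nrow(spots)
  dwell <- spots$weight / machine$nozzleDoseRateMUPerS
  travel <- c(0, abs(diff(spots$u)) / machine$scanSpeedMmPerS[1])
  travel <- pmax(travel,
                 c(0, abs(diff(spots$v)) / machine$scanSpeedMmPerS[2]))
  travel[-1] <- travel[-1] + machine$spotSwitchOverheadS
  start <- numeric(n)
  t <- 0
  for (k in seq_len(n)) {
    t <- t + travel[k]
    start[k] <- t
    t <- t + dwell[k]
  }
  new("DeliveryTimeline",
      events = data.frame(spot = seq_len(n), startS = start,
                          durationS = dwell, weightMU = spots$weight),
      fieldId = as.integer(fieldId), fraction = as.integer(fraction))
}

#' Delivery timeline of a pulsed VHEE linac
#'
#' Spot k needs \code{ceiling(weight_k / maxDosePerPulse)} pulses; the
#' pulses of all spots fire consecutively on the global \code{1/prf}
#' lattice, each an interval of width tau carrying an equal share of the
#' spot weight.
#'
#' @inheritParams scheduleProton
#' @param machine a [vheeMachine()].
#' @return A [DeliveryTimeline-class].
#' @export
scheduleVhee <- function(spots, machine, fieldId = 1L, fraction = 1L) {
  stopifnot(machine$kind == "vhee")
  nPulse <- pmax(1L, ceiling(spots$weight / machine$maxDosePerPulseMU))
  spot <- rep(seq_len(nrow(spots)), nPulse)
  wPerPulse <- rep(spots$weight / nPulse, nPulse)
  start <- (seq_along(spot) - 1) / machine$prfHz
  new("DeliveryTimeline",
      events = data.frame(spot = spot, startS = start,
                          durationS = machine$pulseWidthS,
                          weightMU = wPerPulse),
      fieldId = as.integer(fieldId), fraction = as.integer(fraction))
}

#' Dose-rate configuration
#'
#' @param thresholdDoseGy the trim dose d-hat (Gy) of the PBS dose-rate
#'   definition (default 0.1 Gy).
#' @param uhdrThresholdGyPerS UHDR ("FLASH") dose-rate threshold
#'   (default 40 Gy/s).
#' @param fractions number of identical fractions (>= 1); fractions are
#'   treated as infinitely separated in time, so dose rates are per
#'   field and the UHDR dose map scales with the fraction count.
#' @return A list of settings.
#' @export
doseRateConfig <- function(thresholdDoseGy = 0.1,
                           uhdrThresholdGyPerS = 40, fractions = 1L) {
  stopifnot(thresholdDoseGy > 0, uhdrThresholdGyPerS >= 0, fractions >= 1)
  list(thresholdDoseGy = thresholdDoseGy,
       uhdrThresholdGyPerS = uhdrThresholdGyPerS,
       fractions = as.integer(fractions))
}

#' Per-voxel PBS dose-rate map of one field
#'
#' Implements the trimmed-window PBS dose-rate definition: for voxel j
#' with cumulative dose-versus-time curve \code{D_j(t)} (a linear ramp
#' during each contributing beam-on interval, flat between) and total
#' dose \code{D_j}, the dose rate is
#' \deqn{DR_j = (D_j - 2 \hat d) / (t_j(D_j - \hat d) - t_j(\hat d))}
#' with the crossing times taken at the earliest crossing of the
#' piecewise-linear curve. Voxels with \code{D_j <= 2 d-hat} get dose
#' rate 0 (they can never satisfy a FLASH condition at meaningful dose
#' anyway). The computation is event-based and exact for the
#' piecewise-linear curve.
#'
#' @param M a [DoseInfluenceMatrix-class] whose columns are the per-spot
#'   dose columns of the field (e.g. from [spotColumns()] wrapped, or
#'   the direct spot matrix built by the pipeline).
#' @param weights spot weights (MU), one per column of \code{M}.
#' @param timeline a [DeliveryTimeline-class] covering all spots with
#'   positive weight.
#' @param cfg a [doseRateConfig()].
#' @return A [VoxelGrid-class] dose-rate map (Gy/s; zero outside the
#'   matrix rows).
#' @export
pbsDoseRateMap <- function(M, weights, timeline, cfg = doseRateConfig()) {
  ev <- timeline@events
  ev <- ev[ev$durationS > 0 & ev$weightMU > 0, , drop = FALSE]
  if (any(weights > 0 & !(seq_along(weights) %in% ev$spot)))
    stop("timeline does not cover every spot with positive weight")
  A <- M@matrix
  n <- nrow(A)
  dhat <- cfg$thresholdDoseGy
  ## pass 1: total dose; per-event dose share of each spot's weight
  evFrac <- ev$weightMU / vapply(split(ev$weightMU, ev$spot), sum,
                                 0)[as.character(ev$spot)]
  Dtot <- numeric(n)
  cols <- vector("list", nrow(ev))
  for (e in seq_len(nrow(ev))) {
    s <- ev$spot[e]
    if (A@p[s + 1L] == A@p[s]) { cols[[e]] <- list(i = integer(0)); next }
    ptr <- (A@p[s] + 1L):A@p[s + 1L]
    idx <- A@i[ptr] + 1L
    dose <- A@x[ptr] * weights[s] * evFrac[e]
    cols[[e]] <- list(i = idx, d = dose)
    Dtot[idx] <- Dtot[idx] + dose
  }
  ## pass 2: earliest crossings of d-hat and Dtot - d-hat
  t1 <- rep(NA_real_, n); t2 <- rep(NA_real_, n)
  Drun <- numeric(n)
  for (e in seq_len(nrow(ev))) {
    ce <- cols[[e]]
    if (!length(ce$i)) next
    i <- ce$i; d <- ce$d
    r <- Drun[i]
    hit1 <- r < dhat & r + d >= dhat
    if (any(hit1)) {
      ii <- i[hit1]
      t1[ii] <- ev$startS[e] +
        ev$durationS[e] * (dhat - r[hit1]) / d[hit1]
    }
    b <- Dtot[i] - dhat
    hit2 <- r < b & r + d >= b & is.na(t2[i])
    if (any(hit2)) {
      ii <- i[hit2]
      t2[ii] <- ev$startS[e] +
        ev$durationS[e] * (b[hit2] - r[hit2]) / d[hit2]
    }
    Drun[i] <- r + d
  }
  if (any(Drun > Dtot + 1e-9))
    stop("internal error: non-monotone cumulative dose")
  dr <- numeric(n)
  ok <- Dtot > 2 * dhat & !is.na(t1) & !is.na(t2) & t2 > t1
  dr[ok] <- (Dtot[ok] - 2 * dhat) / (t2[ok] - t1[ok])
  vals <- array(0, dim = M@refDims)
  vals[M@rows] <- dr
  new("VoxelGrid", values = vals, spacingMm = M@refSpacing,
      originMm = M@refOrigin)
}

#' UHDR ("FLASH") dose map
#'
#' Sum over fields (times the fraction count) of the dose delivered at a
#' PBS dose rate at or above the UHDR threshold:
#' \code{F(x) = fractions * sum_f dose_f(x) * [DR_f(x) >= threshold]}.
#' Satisfies \code{0 <= F(x) <= total dose(x)} per fraction-scaled total.
#'
#' @param fieldDose list of per-field [VoxelGrid-class] dose maps (one
#'   fraction's worth).
#' @param fieldRate list of matching per-field dose-rate maps.
#' @param cfg a [doseRateConfig()] (UHDR threshold and fraction count).
#' @return A [VoxelGrid-class].
#' @export
flashDoseMap <- function(fieldDose, fieldRate, cfg = doseRateConfig()) {
  if (length(fieldDose) != length(fieldRate))
    stop("one dose-rate map per dose map is required")
  out <- NULL
  for (f in seq_along(fieldDose)) {
    stopIfNotCongruent(fieldDose[[f]], fieldRate[[f]])
    if (!is.null(out)) stopIfNotCongruent(fieldDose[[f]], out)
    part <- fieldDose[[f]]@values *
      (fieldRate[[f]]@values >= cfg$uhdrThresholdGyPerS)
    out <- if (is.null(out)) sameGrid(fieldDose[[f]], part)
           else sameGrid(out, out@values + part)
  }
  sameGrid(out, out@values * cfg$fractions)
}

#' Write a delivery timeline as CSV
#'
#' @param timeline a [DeliveryTimeline-class].
#' @param path CSV file path.
#' @export
writeTimeline <- function(timeline, path) {
  write.csv(timeline@events, path, row.names = FALSE)
  invisible(path)
}
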