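#' Default scorecard for a phantom
#'
#' Surrogate objectives standing in for protocol-based clinical
#' scorecards: a uniform PTV objective at the prescription, a PTV
#' minimum-dose objective at 95\% of it, and for every OAR a maximum-dose
#' and a mean-dose objective at half the prescription. Identical
#' objectives are used for every modality compared on a phantom.
#'
#' @param structures a [StructureSet-class].
#' @param prescriptionGy prescription dose (default 30 Gy in one
#'   fraction, large enough that the 10 Gy FLASH dose threshold is
#'   exercised).
#' @return A [scorecard()] data.frame.
#' @export
defaultScorecard <- function(structures, prescriptionGy = 30) {
  oars <- setdiff(structureNames(structures), c("PTV", "BODY"))
  sc <- scorecard(c("PTV", "PTV"), c("uniform", "min_dose"),
                  c(prescriptionGy, 0.95 * prescriptionGy), c(50, 100))
  for (o in oars)
    sc <- rbind(sc,
                scorecard(c(o, o), c("max_dose", "mean_dose_max"),
                          c(0.5, 0.4) * prescriptionGy, c(2, 1)))
  sc
}

## gantry angles per preset (transmission fields; arrangements are a
## desk-scale design choice, two fields per plan)
presetFieldAngles <- function(preset) {
  switch(preset,
         brain_like = c(0, 90),
         lung_like = c(0, 90),
         liver_like = c(90, 180),
         prostate_like = c(90, 270),
         c(0, 90))
}

## binary dilation by ~mm using the 6-neighbourhood, used to build the
## conformity ring of scored voxels around the PTV
dilateMask <- function(mask, mm, spacingMm) {
  n <- ceiling(mm / min(spacingMm))
  d <- dim(mask)
  for (i in seq_len(n)) {
    m <- mask
    m[-1, , ] <- m[-1, , ] | mask[-d[1], , ]
    m[-d[1], , ] <- m[-d[1], , ] | mask[-1, , ]
    m[, -1, ] <- m[, -1, ] | mask[, -d[2], ]
    m[, -d[2], ] <- m[, -d[2], ] | mask[, -1, ]
    m[, , -1] <- m[, , -1] | mask[, , -d[3]]
    m[, , -d[3]] <- m[, , -d[3]] | mask[, , -1]
    mask <- m
  }
  mask
}

## voxels scored during optimization: all structures except BODY, plus a
## ring around the PTV (keeps the sparse problem desk-sized; the final
## dose maps are evaluated on the full grid)
scoringRows <- function(structures, ringMm = 15) {
  body <- structureMask(structures, "BODY")
  acc <- dilateMask(structureMask(structures, "PTV"), ringMm,
                    structures@spacingMm)
  for (nm in setdiff(structureNames(structures), c("BODY", "PTV")))
    acc <- acc | structureMask(structures, nm)
  which(acc & body)
}

#' Plan one transmission field arrangement on a phantom
#'
#' End-to-end planning of one modality: spot placement per field
#' (centroidal Voronoi tessellation plus border spots at the target
#' spacing, serpentine-ordered), dose-influence matrices on the
#' precomputed spot grid restricted to the scored voxels, bilinear spot
#' columns, and nonnegative weight optimization against the scorecard.
#' Final full-grid per-field dose maps are then recomputed with exact
#' kernels at the optimized spot positions.
#'
#' @param phantom result of [generatePhantom()].
#' @param model a [BeamModel-class].
#' @param gantryAnglesDeg one angle per field; default per preset.
#' @param prescriptionGy prescription dose (Gy).
#' @param sc scorecard; default [defaultScorecard()].
#' @param spotSpacingMm spot spacing (default 5 mm).
#' @param pitchMm spot-grid pitch for the influence matrices (default
#'   2 mm).
#' @param seed seed driving the CVT initialization.
#' @param tol,maxIter weight-optimization controls.
#' @param refinePositions if TRUE, run [optimizePositions()] after the
#'   weight fit.
#' @return A list: \code{fields} (per field: \code{geometry},
#'   \code{spots} with optimized weights, \code{delivery} - the exact
#'   full-grid spot-dose matrix - and \code{dose}), \code{totalDose},
#'   \code{result} ([OptimizationResult-class]), \code{sc},
#'   \code{model}, \code{prescriptionGy}.
#' @export
planPhantom <- function(phantom, model,
                        gantryAnglesDeg = presetFieldAngles(phantom$spec@preset),
                        prescriptionGy = 30,
                        sc = defaultScorecard(phantom$structures, prescriptionGy),
                        spotSpacingMm = 5, pitchMm = 2, seed = 1L,
                        tol = 1e-5, maxIter = 300L,
                        refinePositions = FALSE) {
  density <- phantom$density; structures <- phantom$structures
  rows <- scoringRows(structures)
  fields <- list()
  Slist <- list()
  for (f in seq_along(gantryAnglesDeg)) {
    geom <- fieldGeometry(gantryAnglesDeg[f])
    spots <- placeSpots(structures, geom, spacingMm = spotSpacingMm,
                        seed = seed + f, fieldId = f)
    margin <- if (refinePositions) 2 * pitchMm else 0
    M <- buildInfluence(density, structures, geom, model,
                        spotGridPitchMm = pitchMm, rows = rows,
                        nodes = nodesForSpots(spots, pitchMm, margin),
                        fieldId = f)
    fields[[f]] <- list(geometry = geom, spots = spots, M = M)
    Slist[[f]] <- spotColumns(M, spots)
  }
  A <- do.call(cbind, Slist)
  res <- optimizeWeights(A, sc, structures, rows = rows,
                         tol = tol, maxIter = maxIter)
  nPer <- vapply(fields, function(fl) nrow(fl$spots), 0L)
  splitIdx <- rep(seq_along(fields), nPer)
  for (f in seq_along(fields)) {
    fields[[f]]$spots$weight <- res@weights[splitIdx == f]
    if (refinePositions) {
      ref <- optimizePositions(fields[[f]]$spots, fields[[f]]$M, sc,
                               structures, tol = tol, maxIter = maxIter)
      fields[[f]]$spots <- ref$spots
    }
  }
  ## exact full-grid dose recomputation at the final spot positions
  bodyRows <- which(structureMask(structures, "BODY"))
  total <- NULL
  for (f in seq_along(fields)) {
    fields[[f]]$M <- NULL
    deliv <- directSpotMatrix(density, fields[[f]]$geometry, model,
                              fields[[f]]$spots, rows = bodyRows,
                              fieldId = f)
    fields[[f]]$delivery <- deliv
    fields[[f]]$dose <- doseFromInfluence(deliv, fields[[f]]$spots$weight)
    total <- if (is.null(total)) fields[[f]]$dose
             else sameGrid(total, total@values + fields[[f]]$dose@values)
  }
  list(fields = fields, totalDose = total, result = res, sc = sc,
       model = model, prescriptionGy = prescriptionGy)
}

#' Delivery timelines and dose-rate maps for a plan
#'
#' Schedules every field of a plan on the given machine (scanned
#' continuous beam for \code{protonMachine()}, pulsed lattice for
#' \code{vheeMachine()}; spots with negligible weight are skipped) and
#' maps the per-voxel PBS dose rate of each field.
#'
#' @param plan result of [planPhantom()].
#' @param machine a [protonMachine()] or [vheeMachine()].
#' @param cfg a [doseRateConfig()].
#' @param minWeightMU spots below this weight are not delivered.
#' @return A list per field with \code{timeline}
#'   ([DeliveryTimeline-class]), \code{rate} ([VoxelGrid-class]) and
#'   \code{dose}.
#' @export
planDoseRate <- function(plan, machine, cfg = doseRateConfig(),
                         minWeightMU = 1e-3) {
  out <- list()
  for (f in seq_along(plan$fields)) {
    fl <- plan$fields[[f]]
    keep <- fl$spots$weight > minWeightMU
    spots <- fl$spots[keep, , drop = FALSE]
    M <- fl$delivery
    Mk <- new("DoseInfluenceMatrix",
              matrix = M@matrix[, keep, drop = FALSE],
              nodeIU = M@nodeIU[keep], nodeIV = M@nodeIV[keep],
              pitchMm = M@pitchMm, rows = M@rows, refDims = M@refDims,
              refSpacing = M@refSpacing, refOrigin = M@refOrigin,
              fieldId = M@fieldId)
    tl <- if (machine$kind == "proton")
      scheduleProton(spots, machine, fieldId = f)
    else scheduleVhee(spots, machine, fieldId = f)
    rate <- pbsDoseRateMap(Mk, spots$weight, tl, cfg)
    out[[f]] <- list(timeline = tl, rate = rate, dose = fl$dose)
  }
  out
}

#' FLASH summary of one delivered plan
#'
#' @param plan result of [planPhantom()].
#' @param delivery result of [planDoseRate()].
#' @param structures a [StructureSet-class].
#' @param cfg a [doseRateConfig()].
#' @param doseThresholdGy FI dose threshold (default 10 Gy).
#' @return A list with \code{flashDose} ([VoxelGrid-class]) and
#'   \code{fi}, a data.frame of FI results per structure.
#' @export
planFlashSummary <- function(plan, delivery, structures,
                             cfg = doseRateConfig(), doseThresholdGy = 10) {
  fieldDose <- lapply(delivery, `[[`, "dose")
  fieldRate <- lapply(delivery, `[[`, "rate")
  fd <- flashDoseMap(fieldDose, fieldRate, cfg)
  total <- sameGrid(plan$totalDose,
                    plan$totalDose@values * cfg$fractions)
  fi <- NULL
  for (nm in structureNames(structures)) {
    r <- flashIndex(total, fd, nm, doseThresholdGy,
                    cfg$uhdrThresholdGyPerS, structures)
    fi <- rbind(fi, data.frame(structure = nm, volDVH = r@volDVH,
                               volDRDVH = r@volDRDVH, fi = r@fi))
  }
  list(flashDose = fd, fi = fi)
}

#' Proton-vs-VHEE comparison with a PRF sweep
#'
#' Runs the full chain on one phantom: a proton transmission plan
#' (scanned continuous delivery) and a VHEE transmission plan (pulsed
#' delivery) with identical scorecard objectives, then sweeps the VHEE
#' pulse repetition frequency and tabulates the FLASH index of every
#' structure for every delivery. This is the desk-scale analogue of a
#' modality comparison on a clinical case.
#'
#' @param preset phantom preset name.
#' @param prfHz vector of pulse repetition frequencies to sweep.
#' @param spacingMm voxel spacing of the phantom used for planning
#'   (default 3 mm; the phantom keeps its full 200 mm extent).
#' @param seed top-level seed for all randomness.
#' @param vheeEnergyMeV 150 or 200.
#' @param prescriptionGy,fractions prescription (default 30 Gy x 1).
#' @param proton,vheeBase machine models ([protonMachine()],
#'   [vheeMachine()]; the PRF of \code{vheeBase} is overridden by the
#'   sweep).
#' @param cfg base [doseRateConfig()].
#' @param doseThresholdGy FI dose threshold.
#' @param tol,maxIter optimization controls.
#' @return A list: \code{fiTable} (structure x delivery FI table),
#'   \code{metrics} (plan metrics per modality), \code{plans},
#'   \code{deliveries} (per modality label, each a [planDoseRate()]
#'   result), \code{phantom}, \code{cfg}.
#' @export
comparePlans <- function(preset = "prostate_like",
                         prfHz = c(100, 250, 500, 1000),
                         spacingMm = 3, seed = 1L, vheeEnergyMeV = 200,
                         prescriptionGy = 30, fractions = 1L,
                         proton = protonMachine(),
                         vheeBase = vheeMachine(),
                         cfg = doseRateConfig(fractions = fractions),
                         doseThresholdGy = 10, tol = 1e-5,
                         maxIter = 300L) {
  dims <- rep(round(200 / spacingMm), 3)
  phantom <- generatePhantom(phantomSpec(preset, dims = dims,
                                         spacingMm = spacingMm, seed = seed))
  structures <- phantom$structures
  plans <- list(
    proton = planPhantom(phantom, defaultProtonModel(),
                         prescriptionGy = prescriptionGy, seed = seed,
                         tol = tol, maxIter = maxIter),
    vhee = planPhantom(phantom, defaultVheeModel(vheeEnergyMeV),
                       prescriptionGy = prescriptionGy, seed = seed,
                       tol = tol, maxIter = maxIter))
  metrics <- lapply(plans, function(p)
    planMetrics(sameGrid(p$totalDose, p$totalDose@values * cfg$fractions),
                structures, prescriptionGy))
  deliveries <- list()
  fiTable <- NULL
  addFI <- function(label, modality, prf, plan, delivery) {
    s <- planFlashSummary(plan, delivery, structures, cfg, doseThresholdGy)
    rbind(fiTable, cbind(data.frame(delivery = label, modality = modality,
                                    prfHz = prf), s$fi))
  }
  dl <- planDoseRate(plans$proton, proton, cfg)
  deliveries[["proton"]] <- dl
  fiTable <- addFI("proton", "proton", NA_real_, plans$proton, dl)
  for (p in prfHz) {
    m <- vheeBase; m$prfHz <- p
    dl <- planDoseRate(plans$vhee, m, cfg)
    lab <- sprintf("vhee_%dHz", p)
    deliveries[[lab]] <- dl
    fiTable <- addFI(lab, "vhee", p, plans$vhee, dl)
  }
  list(fiTable = fiTable, metrics = metrics, plans = plans,
       deliveries = deliveries, phantom = phantom, cfg = cfg,
       config = list(preset = preset, prfHz = prfHz, spacingMm = spacingMm,
                     seed = seed, vheeEnergyMeV = vheeEnergyMeV,
                     prescriptionGy = prescriptionGy,
                     fractions = fractions,
                     doseThresholdGy = doseThresholdGy))
}

## tiny FNV-1a hash for the run manifest (config fingerprint); 32-bit
## arithmetic done on 16-bit half-words to stay within double precision
fnv1a <- function(txt) {
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    lo <- h %% 65536; hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), as.integer(b))
    h <- hi * 65536 + lo
    hi <- h %/% 65536; lo <- h %% 65536
    ## h * 16777619 mod 2^32, split to avoid exceeding 2^53
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  ## format in half-words: %x only accepts values within integer range
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run a comparison and write its report to disk
#'
#' Writes the FI table, per-modality metrics and DVH/DRDVH curves as
#' CSV, total and UHDR dose maps as NIfTI, and a \code{manifest.json}
#' with the configuration, its hash, the seed and the package version -
#' enough to reproduce the outputs exactly. Output files contain no
#' timestamps, so identical configurations produce byte-identical CSVs.
#'
#' @param outDir output directory (created if needed).
#' @param ... passed to [comparePlans()].
#' @return Invisibly, the [comparePlans()] result.
#' @export
runCompare <- function(outDir, ...) {
  cmp <- comparePlans(...)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cmp$fiTable, file.path(outDir, "fi_table.csv"),
            row.names = FALSE)
  for (m in names(cmp$metrics))
    write.csv(cmp$metrics[[m]],
              file.path(outDir, sprintf("metrics_%s.csv", m)),
              row.names = FALSE)
  structures <- cmp$phantom$structures
  curves <- NULL
  for (m in names(cmp$plans)) {
    tot <- cmp$plans[[m]]$totalDose
    tot <- sameGrid(tot, tot@values * cmp$cfg$fractions)
    writeGrid(tot, file.path(outDir, sprintf("dose_%s.nii", m)))
    for (nm in structureNames(structures)) {
      cv <- dvhCurve(tot, nm, structures = structures, name = nm)
      curves <- rbind(curves, cbind(modality = m, curveAsDataFrame(cv)))
    }
  }
  write.csv(curves, file.path(outDir, "dvh_curves.csv"), row.names = FALSE)
  manifest <- list(config = cmp$config,
                   configHash = fnv1a(jsonlite::toJSON(cmp$config)),
                   seed = cmp$config$seed,
                   package = "flashPBS",
                   version = as.character(utils::packageVersion("flashPBS")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cmp)
}
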