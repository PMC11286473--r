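# Synthetic multi-modal subject phantoms: co-registered perfusion maps, a DWI
# pair consistent with a ground-truth ADC field, a susceptibility volume with
# mirrored vein trees, and ground-truth region masks.

#' Default per-region, per-class regional mean targets
#'
#' Mean and SD of the subject-level regional means of each perfusion map, per
#' region and class, used as the generator's class-effect defaults. CBF in
#' mL/100g/min, CBV in mL/100g, MTT and Tmax in s.
#'
#' @param regions subset of regions to keep.
#' @return data.frame with columns region, map, good_mean, good_sd,
#'   poor_mean, poor_sd.
#' @export
defaultRegionTargets <- function(regions = c("ischemic", "infarct", "hypoxic")) {
  tb <- rbind(
    data.frame(region = "ischemic",
               map = c("CBF", "CBV", "MTT", "Tmax"),
               good_mean = c(28.05, 3.83, 9.42, 6.24),
               good_sd   = c(11.90, 1.44, 3.27, 4.49),
               poor_mean = c(20.34, 3.49, 13.67, 12.18),
               poor_sd   = c(9.47, 1.11, 5.31, 6.28)),
    data.frame(region = "infarct",
               map = c("CBF", "CBV", "MTT", "Tmax"),
               good_mean = c(28.22, 3.54, 9.53, 5.80),
               good_sd   = c(16.56, 1.59, 4.49, 5.33),
               poor_mean = c(17.81, 2.88, 14.73, 13.99),
               poor_sd   = c(10.81, 1.31, 5.83, 8.39)),
    data.frame(region = "hypoxic",
               map = c("CBF", "CBV", "MTT", "Tmax"),
               good_mean = c(58.54, 7.91, 8.13, 3.65),
               good_sd   = c(18.50, 2.09, 1.19, 0.97),
               poor_mean = c(47.36, 6.94, 9.51, 5.32),
               poor_sd   = c(18.83, 2.11, 2.22, 2.43)))
  tb[tb$region %in% regions, , drop = FALSE]
}

# healthy-tissue background levels of the four maps
mapBackgrounds <- function() c(CBF = 50, CBV = 4, MTT = 5, Tmax = 1.5)

#' Configure a synthetic cohort
#'
#' Defaults mirror the two-class study design: 45 subjects per class,
#' unilateral ellipsoidal lesions with Gaussian-tapered boundaries, regional
#' mean targets from [defaultRegionTargets()], mirrored random-walk vein
#' trees with baseline susceptibility in `veinChiRange`, and a handful of
#' affected-hemisphere grid units whose vein susceptibility is elevated by
#' `hypoxiaFactor` (rendering them hypoxic at the 0.7 reference).
#'
#' @param nGood,nPoor subjects per class.
#' @param volumeShape voxels (x, y, z).
#' @param voxelSpacing mm.
#' @param lesionRadiusRange in-plane lesion semi-axis range, voxels.
#' @param classEffects regional mean targets (see [defaultRegionTargets()]).
#' @param veinChiRange baseline vein susceptibility range, ppb; kept inside
#'   the (90, 300) vein window even after hypoxic elevation.
#' @param noiseSd named per-map additive voxel noise SD.
#' @param chiNoiseSd,dwiNoiseSd susceptibility / DWI noise SD (0 keeps the
#'   vein pairing and the ADC field exactly recoverable).
#' @param hypoxicUnits number of grid units rendered hypoxic per subject.
#' @param hypoxiaFactor vein susceptibility elevation factor (> 1).
#' @param seed master seed.
#' @return a validated [CohortConfig-class].
#' @export
cohortConfig <- function(nGood = 45, nPoor = 45,
                         volumeShape = c(48, 48, 12),
                         voxelSpacing = c(4, 4, 5),
                         lesionRadiusRange = c(5, 9),
                         classEffects = defaultRegionTargets(),
                         veinChiRange = c(120, 180),
                         noiseSd = c(CBF = 3, CBV = 0.4, MTT = 0.8, Tmax = 0.8),
                         chiNoiseSd = 0, dwiNoiseSd = 0,
                         hypoxicUnits = 6, hypoxiaFactor = 1.5,
                         seed = 1) {
  new("CohortConfig",
      nGood = as.integer(nGood), nPoor = as.integer(nPoor),
      volumeShape = as.integer(volumeShape),
      voxelSpacing = as.numeric(voxelSpacing),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      classEffects = classEffects,
      veinChiRange = as.numeric(veinChiRange),
      noiseSd = noiseSd, chiNoiseSd = chiNoiseSd, dwiNoiseSd = dwiNoiseSd,
      hypoxicUnits = as.integer(hypoxicUnits),
      hypoxiaFactor = hypoxiaFactor, seed = as.integer(seed))
}

# one target draw per (region, map): subject-level regional mean
drawRegionTargets <- function(ce, label) {
  if (!nrow(ce)) return(ce)
  m <- if (label == "good") ce$good_mean else ce$poor_mean
  s <- if (label == "good") ce$good_sd else ce$poor_sd
  ce$target <- vapply(seq_len(nrow(ce)),
                      function(k) rtruncnormMeanMatched(1, m[k], s[k]), numeric(1))
  ce
}

randomWalkTube <- function(brain, midline, d, dilate) {
  # start well inside the right hemisphere
  for (try in 1:50) {
    start <- c(runif(1, midline + 2, d[1] - 2), runif(1, 3, d[2] - 2),
               runif(1, 2, d[3] - 1))
    if (brain[round(start[1]), round(start[2]), round(start[3])]) break
  }
  pos <- start
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  vox <- matrix(0L, 0, 3)
  for (s in 1:25) {
    p <- round(pos)
    if (p[1] > midline + 0.5 && p[1] <= d[1] && p[2] >= 1 && p[2] <= d[2] &&
        p[3] >= 1 && p[3] <= d[3] && brain[p[1], p[2], p[3]])
      vox <- rbind(vox, p)
    dir <- dir + rnorm(3, 0, 0.35)
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + dir
  }
  if (!nrow(vox)) return(NULL)
  tube <- array(FALSE, d)
  tube[vox] <- TRUE
  if (dilate) tube <- dilateInBox(tube, 1, "6") & brain &
      (slice.index(tube, 1) > midline)
  tube
}

#' Generate one synthetic subject
#'
#' Deterministic given `seed`. Inside the ground-truth ischemic lesion the
#' perfusion values are set so the subject-level regional means follow the
#' configured class targets (the infarct core gets its own target and the
#' surrounding ring the complementary value, so both regional means converge
#' to their targets across subjects). The DWI pair is synthesized by
#' inverting the ADC relation from a ground-truth ADC field whose infarct
#' core lies strictly below 620e-6 mm^2/s. The susceptibility volume holds
#' mirrored vein trees; in the designated hypoxic units of the affected
#' hemisphere the vein susceptibility is elevated so the unit SvO2 falls
#' below the reference.
#'
#' @param config a [CohortConfig-class].
#' @param label `"good"` or `"poor"`.
#' @param seed subject seed.
#' @param id subject identifier.
#' @return a [SubjectPhantom-class].
#' @export
generateSubject <- function(config, label, seed, id = sprintf("S%06d", seed)) {
  if (!label %in% c("good", "poor"))
    stop("label must be 'good' or 'poor'")
  validObject(config)
  withSeed(seed, {
    d <- config@volumeShape
    center <- (d + 1) / 2
    midline <- center[1]
    brain <- ellipsoidMask(d, center, c(0.45 * d[1], 0.45 * d[2], 0.48 * d[3]))
    side <- sample(c(-1, 1), 1)

    # --- lesion geometry (ellipsoid, confined to one hemisphere) ---
    lesion <- NULL
    for (try in 1:25) {
      rx <- runif(1, config@lesionRadiusRange[1], config@lesionRadiusRange[2])
      ry <- runif(1, config@lesionRadiusRange[1], config@lesionRadiusRange[2])
      rz <- max(1.2, (rx + ry) / 5)
      lcen <- c(midline + side * (d[1] / 4 + runif(1, -1, 1)),
                center[2] + runif(1, -2, 2),
                center[3] + sample(-1:1, 1))
      cand <- ellipsoidMask(d, lcen, c(rx, ry, rz)) & brain
      hemi <- if (side < 0) slice.index(cand, 1) < midline else
        slice.index(cand, 1) > midline
      cand <- cand & hemi
      if (sum(cand) >= 30) { lesion <- cand; break }
    }
    if (is.null(lesion)) stop("lesion cannot fit the volume")
    infarct <- ellipsoidMask(d, lcen, 0.55 * c(rx, ry, max(1.2, rz))) & lesion
    ring <- lesion & !infarct

    # --- susceptibility: mirrored vein trees + hypoxic units ---
    chi <- array(0, d)
    for (t in 1:3) {
      tube <- randomWalkTube(brain, midline, d, dilate = (t == 1))
      if (is.null(tube)) next
      chi[tube] <- runif(1, config@veinChiRange[1], config@veinChiRange[2])
    }
    chi <- chi + mirrorX(chi)   # left hemisphere is the exact mirror
    part <- partitionHemisphereGrid(brain, midline = midline)
    u <- part@units
    sideName <- if (side < 0) "left" else "right"
    hypoxic <- array(FALSE, d)
    if (config@hypoxicUnits > 0) {
      lesionWide <- dilateInBox(lesion, 2, "26")
      onSide <- which(u$hemisphere == sideName)
      idxList <- unitIndexList(u[onSide, , drop = FALSE], d)
      ok <- vapply(idxList, function(vox) {
        any(chi[vox] > 0) && !any(lesionWide[vox])
      }, logical(1))
      cand <- which(ok)
      if (length(cand)) {
        pick <- if (length(cand) <= config@hypoxicUnits) cand else
          sample(cand, config@hypoxicUnits)
        for (r in pick) {
          vox <- idxList[[r]]
          vein <- vox[chi[vox] > 0]
          chi[vein] <- chi[vein] * config@hypoxiaFactor
          hypoxic[vox] <- TRUE
        }
        hypoxic <- hypoxic & brain
      }
    }
    if (config@chiNoiseSd > 0)
      chi[brain] <- chi[brain] + rnorm(sum(brain), 0, config@chiNoiseSd)

    # --- perfusion maps ---
    ce <- drawRegionTargets(config@classEffects, label)
    bg <- mapBackgrounds()
    maps <- list()
    for (mapName in names(bg)) {
      vol <- array(0, d)
      sdv <- config@noiseSd[[mapName]]
      vol[brain] <- bg[[mapName]]
      tI <- ce$target[ce$region == "ischemic" & ce$map == mapName]
      tF <- ce$target[ce$region == "infarct" & ce$map == mapName]
      tH <- ce$target[ce$region == "hypoxic" & ce$map == mapName]
      if (length(tI) && length(tF)) {
        vr <- max(0, (tI * sum(lesion) - tF * sum(infarct)) / max(1, sum(ring)))
        vol[infarct] <- tF
        vol[ring] <- vr
        edge <- vr
      } else if (length(tI)) {
        vol[lesion] <- tI
        edge <- tI
      } else if (length(tF)) {
        vol[infarct] <- tF
        edge <- NULL
      } else edge <- NULL
      if (!is.null(edge)) {
        # Gaussian-tapered boundary outside the lesion; the taper decays fast
        # enough that shell Tmax stays below the ischemic threshold, keeping
        # the thresholded map consistent with the ground-truth lesion
        dil1 <- dilateInBox(lesion, 1, "6")
        sh1 <- dil1 & !lesion & brain
        sh2 <- dilateInBox(dil1, 1, "6") & !dil1 & brain
        vol[sh1] <- bg[[mapName]] + exp(-2) * (edge - bg[[mapName]])
        vol[sh2] <- bg[[mapName]] + exp(-8) * (edge - bg[[mapName]])
      }
      if (length(tH) && any(hypoxic)) vol[hypoxic] <- tH
      if (sdv > 0) vol[brain] <- vol[brain] + rnorm(sum(brain), 0, sdv)
      vol[brain] <- pmax(vol[brain], 0)   # physical floor
      maps[[mapName]] <- vol
    }

    # --- DWI pair from a ground-truth ADC field ---
    adc <- array(0, d)
    adc[brain] <- 800e-6
    adc[infarct] <- runif(sum(infarct), 430e-6, 560e-6)
    b0 <- array(0, d)
    b0[brain] <- 1200
    b1000 <- b0 * exp(-1000 * adc)
    if (config@dwiNoiseSd > 0) {
      b0[brain] <- pmax(b0[brain] + rnorm(sum(brain), 0, config@dwiNoiseSd), 1e-3)
      b1000[brain] <- pmax(b1000[brain] + rnorm(sum(brain), 0, config@dwiNoiseSd), 1e-4)
      b1000 <- pmin(b1000, b0)
    }

    new("SubjectPhantom",
        maps = maps, dwiB0 = b0, dwiB1000 = b1000, chi = chi,
        brainMask = brain,
        truthMasks = list(ischemic = lesion, infarct = infarct,
                          hypoxic = hypoxic),
        label = label, subjectId = id, spacing = config@voxelSpacing,
        seed = as.integer(seed))
  })
}

#' Generate a two-class cohort
#'
#' Subject seeds are derived as `seed + index - 1`, so a cohort is
#' reproducible yet its subjects are distinct.
#'
#' @param config a [CohortConfig-class].
#' @return list with `subjects` (list of [SubjectPhantom-class]) and
#'   `labels` (character vector).
#' @export
generateCohort <- function(config) {
  validObject(config)
  n <- config@nGood + config@nPoor
  if (n < 1) stop("zero subjects requested")
  labels <- c(rep("good", config@nGood), rep("poor", config@nPoor))
  subjects <- vector("list", n)
  for (k in seq_len(n)) {
    subjects[[k]] <- generateSubject(config, labels[k],
                                     seed = config@seed + k - 1L,
                                     id = sprintf("S%03d", k))
  }
  list(subjects = subjects, labels = labels)
}

#' Summarize regional perfusion statistics of a cohort
#'
#' One row per (region, map, class) with the mean and sample SD of the
#' subject-level regional means over the ground-truth masks. Subjects with an
#' empty region are flagged missing (counted in `nMissing`), never silently
#' zero.
#'
#' @param cohort output of [generateCohort()] or a list of subjects.
#' @param regions regions to summarize.
#' @return data.frame with columns region, map, class, mean, sd, n, nMissing.
#' @export
summarizeCohort <- function(cohort, regions = c("ischemic", "infarct", "hypoxic")) {
  subjects <- if (!is.null(cohort$subjects)) cohort$subjects else cohort
  if (!length(subjects)) stop("empty cohort")
  rows <- list()
  for (reg in regions) {
    per <- lapply(subjects, function(s) {
      regionMeanParameters(perfusionMaps(s), truthMask(s, reg))
    })
    miss <- vapply(per, function(p) isTRUE(attr(p, "missing")), logical(1))
    labs <- vapply(subjects, subjectLabel, character(1))
    for (mapName in c("CBF", "CBV", "MTT", "Tmax")) {
      vals <- vapply(per, `[[`, numeric(1), mapName)
      for (cl in unique(labs)) {
        v <- vals[labs == cl & !miss]
        rows[[length(rows) + 1L]] <- data.frame(
          region = reg, map = mapName, class = cl,
          mean = if (length(v)) mean(v) else NA_real_,
          sd = if (length(v) > 1) sd(v) else NA_real_,
          n = length(v), nMissing = sum(miss[labs == cl]))
      }
    }
  }
  do.call(rbind, rows)
}
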