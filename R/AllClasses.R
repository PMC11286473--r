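# S4 classes for the central data objects.

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' CohortConfig: parameters of the synthetic two-class cohort
#'
#' Holds everything the phantom generator needs: cohort sizes, grid geometry,
#' lesion geometry, the per-(region, map, class) regional mean/SD targets, the
#' vein susceptibility range and per-map noise levels. Defaults are supplied
#' by [cohortConfig()].
#'
#' @slot nGood,nPoor number of subjects per class (NIHSS 0-4 vs 5-42).
#' @slot volumeShape integer(3), voxels (x, y, z).
#' @slot voxelSpacing numeric(3), mm.
#' @slot lesionRadiusRange numeric(2), in-plane lesion semi-axis range, voxels.
#' @slot classEffects data.frame with columns region, map, good_mean, good_sd,
#'   poor_mean, poor_sd giving the targets of the subject-level regional means.
#' @slot veinChiRange numeric(2), baseline vein susceptibility range, ppb.
#' @slot noiseSd named numeric(4), per-map additive voxel noise SD (map units).
#' @slot chiNoiseSd,dwiNoiseSd susceptibility / DWI signal noise SD.
#' @slot hypoxicUnits number of hemisphere-grid units rendered hypoxic.
#' @slot hypoxiaFactor multiplicative vein-susceptibility elevation in those
#'   units (> 1 lowers SvO2 below the 0.7 reference).
#' @slot seed master seed; subject seeds are derived as seed + index - 1.
#' @export
setClass("CohortConfig", representation(
  nGood = "integer", nPoor = "integer",
  volumeShape = "integer", voxelSpacing = "numeric",
  lesionRadiusRange = "numeric", classEffects = "data.frame",
  veinChiRange = "numeric", noiseSd = "numeric",
  chiNoiseSd = "numeric", dwiNoiseSd = "numeric",
  hypoxicUnits = "integer", hypoxiaFactor = "numeric",
  seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  if (object@nGood < 0 || object@nPoor < 0) msg <- c(msg, "cohort sizes must be >= 0")
  if (length(object@volumeShape) != 3 || any(object@volumeShape < 8))
    msg <- c(msg, "volumeShape must be 3 dimensions of at least 8 voxels")
  if (any(object@voxelSpacing <= 0)) msg <- c(msg, "voxelSpacing must be positive")
  ce <- object@classEffects
  need <- c("region", "map", "good_mean", "good_sd", "poor_mean", "poor_sd")
  if (!all(need %in% names(ce))) {
    msg <- c(msg, paste("classEffects needs columns", paste(need, collapse = ", ")))
  } else if (nrow(ce) && any(c(ce$good_sd, ce$poor_sd) < 0)) {
    msg <- c(msg, "classEffects SDs must be >= 0")
  }
  rmax <- max(object@lesionRadiusRange)
  if (any(object@lesionRadiusRange <= 0) || diff(object@lesionRadiusRange) < 0)
    msg <- c(msg, "lesionRadiusRange must be positive and non-decreasing")
  # lesion (plus a 1-voxel margin) must fit inside one hemisphere
  if (2 * rmax + 2 > floor(object@volumeShape[1] / 2) || 2 * rmax + 2 > object@volumeShape[2])
    msg <- c(msg, "lesion radii do not fit inside one hemisphere of volumeShape")
  if (diff(object@veinChiRange) < 0 || any(object@veinChiRange <= 0))
    msg <- c(msg, "veinChiRange must be positive and non-decreasing")
  if (any(object@noiseSd < 0) || object@chiNoiseSd < 0 || object@dwiNoiseSd < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (object@hypoxiaFactor <= 0) msg <- c(msg, "hypoxiaFactor must be positive")
  if (length(msg)) msg else TRUE
})

#' SubjectPhantom: one subject's co-registered volume set
#'
#' All volumes share the same grid. `maps` holds the four perfusion parameter
#' maps (CBF mL/100g/min, CBV mL/100g, MTT s, Tmax s); `dwiB0`/`dwiB1000` are
#' the DWI signal pair; `chi` is the susceptibility volume in ppb;
#' `truthMasks` holds the generator's ground-truth ischemic/infarct/hypoxic
#' masks.
#'
#' @slot maps named list of four 3D arrays (CBF, CBV, MTT, Tmax).
#' @slot dwiB0,dwiB1000 DWI signal volumes (arbitrary units, >= 0).
#' @slot chi susceptibility volume (ppb).
#' @slot brainMask logical 3D array.
#' @slot truthMasks named list of logical arrays (ischemic, infarct, hypoxic).
#' @slot label "good" or "poor".
#' @slot subjectId character scalar.
#' @slot spacing numeric(3) voxel spacing, mm.
#' @slot seed the seed this subject was generated from.
#' @export
setClass("SubjectPhantom", representation(
  maps = "list", dwiB0 = "array", dwiB1000 = "array", chi = "array",
  brainMask = "array", truthMasks = "list", label = "character",
  subjectId = "character", spacing = "numeric", seed = "integer"))

setValidity("SubjectPhantom", function(object) {
  msg <- character(0)
  if (!setequal(names(object@maps), c("CBF", "CBV", "MTT", "Tmax")))
    msg <- c(msg, "maps must be named CBF, CBV, MTT, Tmax")
  d <- dim(object@brainMask)
  vols <- c(object@maps, list(object@dwiB0, object@dwiB1000, object@chi),
            object@truthMasks)
  if (!all(vapply(vols, function(v) identical(dim(v), d), logical(1))))
    msg <- c(msg, "all volumes must share the brain-mask dimensions")
  if (!object@label %in% c("good", "poor"))
    msg <- c(msg, "label must be 'good' or 'poor'")
  bm <- as.logical(object@brainMask)
  for (nm in names(object@truthMasks)) {
    if (any(as.logical(object@truthMasks[[nm]]) & !bm))
      msg <- c(msg, paste0("truth mask '", nm, "' extends outside the brain mask"))
  }
  if (any(object@dwiB1000[bm] > object@dwiB0[bm] + 1e-9))
    msg <- c(msg, "dwiB1000 must not exceed dwiB0 inside the brain (ADC >= 0)")
  if (length(msg)) msg else TRUE
})

#' RegionMask: a delineated region on the common voxel grid
#'
#' @slot mask logical 3D array.
#' @slot regionKind "ischemic", "infarct", "hypoxic" or "control".
#' @slot threshold the threshold value that produced the mask.
#' @slot thresholdUnits units of the threshold (e.g. "s", "mm^2/s", "fraction").
#' @export
setClass("RegionMask", representation(
  mask = "array", regionKind = "character",
  threshold = "numeric", thresholdUnits = "character"))

setValidity("RegionMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical array")
  if (!object@regionKind %in% c("ischemic", "infarct", "hypoxic", "control"))
    return("regionKind must be ischemic, infarct, hypoxic or control")
  TRUE
})

#' ADCMap: apparent diffusion coefficient volume with validity flags
#'
#' @slot adc ADC volume in mm^2/s; NA outside `validMask`.
#' @slot validMask logical array: voxels where both DWI signals are positive.
#' @export
setClass("ADCMap", representation(adc = "array", validMask = "array"))

#' SvO2Grid: hemisphere grid units with vein susceptibility and SvO2
#'
#' One row per grid unit and hemisphere: unit indices (`i` counts away from
#' the midline, `j` along the anterior-posterior axis, `slice` along z), the
#' voxel extent, the mean vein susceptibility of the unit (NA when the unit
#' contains no vein voxels), and -- once [computeUnitSvO2()] has run -- the
#' SvO2 change relative to the mirrored contralateral unit and the resulting
#' SvO2 with its hypoxia flag.
#'
#' @slot units data.frame of per-unit rows.
#' @slot grid integer(3) unit counts (in-plane i, in-plane j, slices per unit).
#' @slot midline x coordinate (voxel units) of the interhemispheric plane.
#' @slot volumeDim integer(3) dimensions of the source grid.
#' @slot svo2Ref the reference SvO2 assumed for the healthy hemisphere.
#' @export
setClass("SvO2Grid", representation(
  units = "data.frame", grid = "integer", midline = "numeric",
  volumeDim = "integer", svo2Ref = "numeric"))

#' FeatureTable: subjects-by-features container
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass: the single
#' assay `"features"` stores features in rows and subjects in columns;
#' `colData` carries the binary class label (`good`/`poor`) and, when a split
#' has been made, a `split` tag (`train`/`test`).
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  cd <- colData(object)
  if (!"label" %in% names(cd)) return("colData must contain a 'label' column")
  if (!all(cd$label %in% c("good", "poor")))
    return("labels must be 'good' or 'poor'")
  if ("split" %in% names(cd) && !all(cd$split %in% c("train", "test")))
    return("split tags must be 'train' or 'test'")
  if (anyDuplicated(rownames(object))) return("feature names must be unique")
  TRUE
})
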