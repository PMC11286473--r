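# Region delineation: ADC from the DWI pair, threshold rules, regional means.

#' Compute the apparent diffusion coefficient from a DWI pair
#'
#' ADC = -(1/b) * ln(S_b / S_0) per voxel, in mm^2/s when `b` is in s/mm^2.
#' Voxels where either signal is non-positive are flagged invalid and set NA.
#'
#' @param dwiB0 signal volume with diffusion gradients off.
#' @param dwiB1000 signal volume at the diffusion weighting `b`.
#' @param b diffusion weighting factor in s/mm^2 (default 1000).
#' @return an [ADCMap-class] with slots `adc` and `validMask`.
#' @examples
#' m <- computeADC(array(1000, c(2, 2, 1)), array(1000 * exp(-0.62), c(2, 2, 1)))
#' m@adc[1, 1, 1] * 1e6  # 620, the infarct boundary value
#' @export
computeADC <- function(dwiB0, dwiB1000, b = 1000) {
  if (b <= 0) stop("b must be positive")
  ensure3d(dwiB0, "dwiB0"); ensure3d(dwiB1000, "dwiB1000")
  sameDim(dwiB0, dwiB1000, "DWI volumes")
  valid <- dwiB0 > 0 & dwiB1000 > 0
  adc <- array(NA_real_, dim(dwiB0))
  adc[valid] <- -(1 / b) * log(dwiB1000[valid] / dwiB0[valid])
  new("ADCMap", adc = adc, validMask = valid)
}

#' Threshold a parameter map into a region mask
#'
#' Applies a strict inequality (`greater_than` or `less_than`) to `map`,
#' restricted to `brainMask` (and to `validMask` when given); boundary voxels
#' equal to the threshold are excluded.
#'
#' @param map 3D parameter volume.
#' @param brainMask logical 3D array.
#' @param rule `"greater_than"` or `"less_than"` (strict).
#' @param threshold threshold value in map units.
#' @param regionKind label stored in the returned mask.
#' @param thresholdUnits unit string stored for provenance.
#' @param validMask optional logical array of voxels where `map` is defined.
#' @return a [RegionMask-class]; an empty mask is a valid result.
#' @export
segmentThreshold <- function(map, brainMask, rule = c("greater_than", "less_than"),
                             threshold, regionKind = "ischemic",
                             thresholdUnits = "", validMask = NULL) {
  rule <- match.arg(rule)
  ensure3d(map, "map"); sameDim(map, brainMask, "map and brainMask")
  sel <- if (rule == "greater_than") map > threshold else map < threshold
  sel[is.na(sel)] <- FALSE
  sel <- sel & (brainMask > 0)
  if (!is.null(validMask)) sel <- sel & (validMask > 0)
  new("RegionMask", mask = array(as.logical(sel), dim(map)),
      regionKind = regionKind, threshold = threshold,
      thresholdUnits = thresholdUnits)
}

#' Ischemic region: Tmax > 6 s
#'
#' @param tmax Tmax volume in seconds.
#' @param brainMask logical 3D array.
#' @param threshold hypoperfusion threshold, seconds (default 6).
#' @return a [RegionMask-class] of kind `"ischemic"`.
#' @export
segmentIschemic <- function(tmax, brainMask, threshold = 6) {
  segmentThreshold(tmax, brainMask, "greater_than", threshold,
                   regionKind = "ischemic", thresholdUnits = "s")
}

#' Infarct region: ADC < 620e-6 mm^2/s
#'
#' Applied on valid ADC voxels only (both DWI signals positive).
#'
#' @param adcMap an [ADCMap-class] from [computeADC()].
#' @param brainMask logical 3D array.
#' @param threshold absolute ADC threshold, mm^2/s (default 620e-6).
#' @return a [RegionMask-class] of kind `"infarct"`.
#' @export
segmentInfarct <- function(adcMap, brainMask, threshold = 620e-6) {
  stopifnot(is(adcMap, "ADCMap"))
  segmentThreshold(adcMap@adc, brainMask, "less_than", threshold,
                   regionKind = "infarct", thresholdUnits = "mm^2/s",
                   validMask = adcMap@validMask)
}

#' Mean perfusion parameters over a region
#'
#' Arithmetic mean of each of the four perfusion maps over the region voxels.
#' An empty region yields NA values flagged via the `"missing"` attribute.
#'
#' @param maps named list of the four perfusion volumes (CBF, CBV, MTT, Tmax).
#' @param region a [RegionMask-class] or logical array.
#' @return named numeric(4) of regional means; attribute `missing` is TRUE
#'   when the region was empty.
#' @export
regionMeanParameters <- function(maps, region) {
  m <- if (is(region, "RegionMask")) maskArray(region) else region
  nm <- names(maps)
  if (sum(m) == 0) {
    out <- setNames(rep(NA_real_, length(maps)), nm)
    attr(out, "missing") <- TRUE
    return(out)
  }
  out <- vapply(maps, function(v) mean(v[m]), numeric(1))
  attr(out, "missing") <- FALSE
  out
}
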