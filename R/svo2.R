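# QSM-based venous oxygen saturation: upright alignment, hemisphere grid,
# unit-wise SvO2 relative to the mirrored contralateral unit, hypoxic mask.

#' Parameters of the SvO2 grid procedure
#'
#' `deltaChiDo` (susceptibility difference between fully oxygenated and fully
#' deoxygenated blood, 0.18 ppm) and `hct` (hematocrit) are carried for
#' documentation: both cancel in the contralateral-ratio form actually
#' computed, which needs only the reference saturation and the vein
#' susceptibility means.
#'
#' @param svo2Ref assumed SvO2 of the healthy (reference) hemisphere, 0.7.
#' @param veinLow,veinHigh vein susceptibility window in ppb (90, 300); both
#'   bounds strict.
#' @param grid unit counts: in-plane i x j and slices per unit (10, 10, 1).
#' @param deltaChiDo,hct documented constants (ppm; fraction); not used in the
#'   simplified computation.
#' @return a named list of validated parameters.
#' @export
svo2Params <- function(svo2Ref = 0.7, veinLow = 90, veinHigh = 300,
                       grid = c(10L, 10L, 1L), deltaChiDo = 0.18, hct = 0.42) {
  stopifnot(svo2Ref > 0, svo2Ref < 1, veinLow < veinHigh,
            length(grid) == 3, all(grid >= 1))
  list(svo2Ref = svo2Ref, veinLow = veinLow, veinHigh = veinHigh,
       grid = as.integer(grid), deltaChiDo = deltaChiDo, hct = hct)
}

#' In-plane rotation of a volume about the slice centre
#'
#' Nearest-neighbour resampling (values are preserved exactly, which matters
#' for binary masks and for vein susceptibilities); voxels mapped from outside
#' the grid become `fill`.
#'
#' @param vol 3D array.
#' @param angleDeg rotation angle in degrees (counter-clockwise in the x-y
#'   index plane).
#' @param center in-plane rotation centre (default volume centre).
#' @param fill value for unmapped voxels.
#' @return the rotated array.
#' @export
rotateInPlane <- function(vol, angleDeg, center = NULL, fill = 0) {
  d <- dim(vol)
  if (angleDeg == 0) return(vol)
  center <- center %||% c((d[1] + 1) / 2, (d[2] + 1) / 2)
  th <- angleDeg * pi / 180
  gx <- rep(seq_len(d[1]), d[2]) - center[1]
  gy <- rep(seq_len(d[2]), each = d[1]) - center[2]
  # inverse mapping: source = R(-theta) (p - c) + c
  sx <- round(cos(th) * gx + sin(th) * gy + center[1])
  sy <- round(-sin(th) * gx + cos(th) * gy + center[2])
  ok <- sx >= 1 & sx <= d[1] & sy >= 1 & sy <= d[2]
  src <- sx + (sy - 1L) * d[1]
  out <- array(fill, d)
  plane <- d[1] * d[2]
  for (z in seq_len(d[3])) {
    slab <- vol[, , z]
    o <- rep(fill, plane)
    o[ok] <- slab[src[ok]]
    out[, , z] <- o
  }
  out
}

mirrorX <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]

#' Upright alignment of a susceptibility volume
#'
#' Translates the brain-mask centroid to the in-plane volume centre (integer
#' shift) and rotates in-plane so the estimated midsagittal axis is vertical.
#' The deviation angle is estimated by minimizing the left-right reflection
#' mismatch of the brain mask over a +/- `angleRange` degree search at
#' `angleStep` degree steps; ties prefer the smallest magnitude.
#'
#' @param chi susceptibility volume (ppb).
#' @param brainMask logical 3D array; must be non-empty.
#' @param angleRange,angleStep search half-range and step, degrees.
#' @return list with `chi` and `brainMask` (aligned), and `rotation` -- a
#'   record with `angle` (estimated deviation, degrees), `shift` (applied
#'   integer in-plane translation) and `center`, sufficient to invert the
#'   alignment with [alignmentInvert()].
#' @export
uprightAlign <- function(chi, brainMask, angleRange = 20, angleStep = 0.25) {
  ensure3d(chi, "chi"); sameDim(chi, brainMask, "chi and brainMask")
  brainMask <- brainMask > 0
  nvox <- sum(brainMask)
  if (nvox == 0) stop("brainMask is empty")
  d <- dim(chi)
  center <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
  if (nvox == 1) {
    warning("degenerate brain mask (single voxel): zero rotation applied")
    rot <- list(angle = 0, shift = c(0L, 0L), center = center)
    return(list(chi = chi, brainMask = brainMask, rotation = rot))
  }
  cen <- maskCentroid(brainMask)
  shift <- as.integer(round(center - cen[1:2]))
  off <- c(shift, 0L)
  maskS <- arrayShift(brainMask, off, FALSE)
  mismatch <- function(a) {
    r <- rotateInPlane(maskS, a, center, FALSE)
    sum(r != mirrorX(r))
  }
  searchMin <- function(angles) {
    angles <- angles[order(abs(angles), angles)]  # prefer small |angle| on ties
    angles[which.min(vapply(angles, mismatch, numeric(1)))]
  }
  # coarse-to-fine search at the requested final resolution
  coarse <- searchMin(seq(-angleRange, angleRange, by = 8 * angleStep))
  corr <- searchMin(seq(max(-angleRange, coarse - 8 * angleStep),
                        min(angleRange, coarse + 8 * angleStep),
                        by = angleStep))
  rot <- list(angle = -corr, shift = shift, center = center)
  list(chi = rotateInPlane(arrayShift(chi, off, 0), corr, center, 0),
       brainMask = rotateInPlane(maskS, corr, center, FALSE),
       rotation = rot)
}

#' Map a volume from the aligned frame back to the original grid
#'
#' @param vol volume in the upright-aligned frame.
#' @param rotation the rotation record returned by [uprightAlign()].
#' @param fill fill value for unmapped voxels.
#' @return the volume resampled back onto the original grid.
#' @export
alignmentInvert <- function(vol, rotation, fill = 0) {
  un <- rotateInPlane(vol, rotation$angle, rotation$center, fill)
  arrayShift(un, c(-rotation$shift, 0L), fill)
}

axisChunks <- function(lo, hi, g, fromHigh = FALSE) {
  n <- hi - lo + 1L
  if (n <= 0) return(NULL)
  k <- min(g, n)
  sizes <- rep(n %/% k, k)
  sizes[k] <- sizes[k] + n - sum(sizes)      # remainder to the last unit
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  pos <- if (fromHigh) hi:lo else lo:hi      # unit 1 nearest the midline
  data.frame(idx = seq_len(k),
             min = pmin(pos[starts], pos[ends]),
             max = pmax(pos[starts], pos[ends]))
}

#' Partition the brain into mirrored hemisphere grid units
#'
#' Works on an upright-aligned brain mask. The midline is the vertical plane
#' through the mask centroid; for every slab of `grid[3]` slices, each
#' hemisphere's in-plane bounding box is divided into `grid[1] x grid[2]`
#' units (remainder voxels joining the last unit per axis). Unit index `i`
#' counts away from the midline so unit (i, j) of one hemisphere mirrors unit
#' (i, j) of the other.
#'
#' @param brainMask logical 3D array (upright-aligned).
#' @param midline x coordinate of the interhemispheric plane; default the
#'   brain-mask centroid.
#' @param grid integer(3): in-plane unit counts and slices per unit.
#' @return a [SvO2Grid-class] holding the unit extents (no SvO2 yet).
#' @export
partitionHemisphereGrid <- function(brainMask, midline = NULL, grid = c(10L, 10L, 1L)) {
  brainMask <- brainMask > 0
  d <- dim(brainMask)
  grid <- as.integer(grid)
  midline <- midline %||% maskCentroid(brainMask)[1]
  zStarts <- seq(1L, d[3], by = grid[3])
  rows <- list()
  for (bi in seq_along(zStarts)) {
    zs <- zStarts[bi]:min(zStarts[bi] + grid[3] - 1L, d[3])
    slab <- brainMask[, , zs, drop = FALSE]
    idx <- which(slab, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    for (hemi in c("left", "right")) {
      sel <- if (hemi == "left") idx[, 1] < midline else idx[, 1] > midline
      if (!any(sel)) next
      hx <- range(idx[sel, 1]); hy <- range(idx[sel, 2])
      cx <- axisChunks(hx[1], hx[2], grid[1], fromHigh = (hemi == "left"))
      cy <- axisChunks(hy[1], hy[2], grid[2])
      g <- expand.grid(i = cx$idx, j = cy$idx)
      g$xmin <- cx$min[g$i]; g$xmax <- cx$max[g$i]
      g$ymin <- cy$min[g$j]; g$ymax <- cy$max[g$j]
      g$hemisphere <- hemi
      g$slice <- bi
      g$zmin <- zs[1]; g$zmax <- zs[length(zs)]
      rows[[length(rows) + 1L]] <- g
    }
  }
  units <- do.call(rbind, rows)
  units <- units[, c("hemisphere", "slice", "i", "j",
                     "xmin", "xmax", "ymin", "ymax", "zmin", "zmax")]
  rownames(units) <- NULL
  new("SvO2Grid", units = units, grid = grid, midline = midline,
      volumeDim = as.integer(d), svo2Ref = NA_real_)
}

unitVoxelIndices <- function(u, d) {
  blockIndices(u[["xmin"]]:u[["xmax"]], u[["ymin"]]:u[["ymax"]],
               u[["zmin"]]:u[["zmax"]], d)
}

# voxel indices of every unit, without data.frame row overhead
unitIndexList <- function(units, d) {
  xmin <- units$xmin; xmax <- units$xmax
  ymin <- units$ymin; ymax <- units$ymax
  zmin <- units$zmin; zmax <- units$zmax
  lapply(seq_len(nrow(units)), function(r) {
    blockIndices(xmin[r]:xmax[r], ymin[r]:ymax[r], zmin[r]:zmax[r], d)
  })
}

#' Unit-wise venous oxygen saturation from susceptibility
#'
#' Vein voxels are those with `veinLow < chi < veinHigh` (both strict) inside
#' the brain. For each grid unit, the mean vein susceptibility Xbar is taken
#' over the unit's vein voxels (missing when there are none). With the
#' mirrored contralateral unit as reference, the SvO2 change is
#' `dSvO2 = -(1 - svo2Ref) * (XbarRef - XbarROI) / XbarRef` and
#' `SvO2 = svo2Ref - dSvO2`. Units with a missing or zero reference mean are
#' flagged invalid (NA), never infinite. SvO2 is reported unclipped and
#' compared strictly to `svo2Ref` for the hypoxia flag.
#'
#' @param chi upright-aligned susceptibility volume (ppb).
#' @param brainMask upright-aligned logical brain mask.
#' @param partition a [SvO2Grid-class] from [partitionHemisphereGrid()].
#' @param params parameter list from [svo2Params()].
#' @return the [SvO2Grid-class] with columns `nVein`, `xbarVein`, `xbarRef`,
#'   `deltaSvO2`, `svo2`, `isHypoxic` filled in.
#' @export
computeUnitSvO2 <- function(chi, brainMask, partition, params = svo2Params()) {
  stopifnot(is(partition, "SvO2Grid"))
  d <- dim(chi)
  vein <- (chi > params$veinLow) & (chi < params$veinHigh) & (brainMask > 0)
  u <- partition@units
  n <- nrow(u)
  idxList <- unitIndexList(u, d)
  nVein <- integer(n); xbar <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    vox <- idxList[[r]]
    v <- vox[vein[vox]]
    nVein[r] <- length(v)
    if (length(v)) xbar[r] <- mean(chi[v])
  }
  u$nVein <- nVein; u$xbarVein <- xbar
  key <- paste(u$slice, u$i, u$j)
  mirrorHemi <- ifelse(u$hemisphere == "left", "right", "left")
  ref <- u$xbarVein[match(paste(mirrorHemi, key), paste(u$hemisphere, key))]
  u$xbarRef <- ref
  ok <- !is.na(u$xbarVein) & !is.na(ref) & ref != 0
  u$deltaSvO2 <- NA_real_
  u$deltaSvO2[ok] <- -(1 - params$svo2Ref) * (ref[ok] - u$xbarVein[ok]) / ref[ok]
  u$svo2 <- params$svo2Ref - u$deltaSvO2
  u$isHypoxic <- ifelse(is.na(u$svo2), NA, u$svo2 < params$svo2Ref)
  new("SvO2Grid", units = u, grid = partition@grid,
      midline = partition@midline, volumeDim = partition@volumeDim,
      svo2Ref = params$svo2Ref)
}

#' Which hemisphere contains a region
#'
#' @param region a [RegionMask-class] or logical array (aligned frame).
#' @param midline x coordinate of the interhemispheric plane.
#' @return `"left"` or `"right"` -- the side holding the region centroid.
#' @export
affectedHemisphere <- function(region, midline) {
  m <- if (is(region, "RegionMask")) maskArray(region) else region
  if (maskCentroid(m)[1] < midline) "left" else "right"
}

#' Hypoxic region from a computed SvO2 grid
#'
#' Union of the voxel extents of affected-hemisphere units with SvO2 strictly
#' below the reference (0.7 by default), intersected with the brain mask;
#' units with undefined SvO2 are excluded. An empty mask is a valid result.
#'
#' @param svo2Grid a [SvO2Grid-class] from [computeUnitSvO2()].
#' @param brainMask logical 3D array in the same (aligned) frame.
#' @param affected `"left"` or `"right"`, from [affectedHemisphere()].
#' @return a [RegionMask-class] of kind `"hypoxic"`.
#' @export
segmentHypoxic <- function(svo2Grid, brainMask, affected) {
  stopifnot(is(svo2Grid, "SvO2Grid"), affected %in% c("left", "right"))
  u <- svo2Grid@units
  if (!"svo2" %in% names(u)) stop("run computeUnitSvO2() first")
  d <- dim(brainMask)
  mask <- array(FALSE, d)
  sel <- which(u$hemisphere == affected & !is.na(u$isHypoxic) & u$isHypoxic)
  idxList <- unitIndexList(u[sel, , drop = FALSE], d)
  for (vox in idxList) mask[vox] <- TRUE
  mask <- mask & (brainMask > 0)
  new("RegionMask", mask = mask, regionKind = "hypoxic",
      threshold = svo2Grid@svo2Ref, thresholdUnits = "fraction")
}
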