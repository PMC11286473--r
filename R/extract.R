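# Feature extraction driver: map x filter x feature-class cross product over
# a region mask, with schema-compliant names
# region__map__filter__class__Feature.

#' Extract the radiomics feature vector of one subject region
#'
#' For each perfusion map and each filter in the bank, the map is filtered,
#' discretized over the region, and the requested feature classes computed.
#' Names follow `region__map__filter__class__Feature`
#' (e.g. `ischemic__Tmax__log-sigma-3__glszm__ZoneEntropy`).
#'
#' @param maps named list of perfusion volumes (CBF, CBV, MTT, Tmax), or a
#'   [SubjectPhantom-class].
#' @param region a [RegionMask-class] or logical array.
#' @param filters list of [filterSpec()]s (default [defaultFilterBank()]).
#' @param classes feature classes to compute.
#' @param scheme,width,bins discretization settings (see [discretize()]).
#' @param aggregation GLCM/GLRLM direction handling.
#' @param minVoxels regions smaller than this yield an all-NA vector flagged
#'   with attribute `flagged = TRUE` (features are never fabricated).
#' @param spacing voxel spacing in mm (taken from a `SubjectPhantom` input).
#' @return named numeric vector; attribute `flagged` marks an unusable region.
#' @export
extractFeatureVector <- function(maps, region,
                                 filters = defaultFilterBank(),
                                 classes = c("firstorder", "glcm", "glrlm",
                                             "glszm", "gldm", "ngtdm"),
                                 scheme = "fixed_bin_width", width = 25,
                                 bins = 16, aggregation = "average",
                                 minVoxels = 10, spacing = c(1, 1, 1)) {
  if (is(maps, "SubjectPhantom")) {
    spacing <- maps@spacing
    maps <- perfusionMaps(maps)
  }
  classes <- match.arg(classes, several.ok = TRUE)
  regionName <- if (is(region, "RegionMask")) regionKind(region) else "region"
  mask <- if (is(region, "RegionMask")) maskArray(region) else region > 0
  nvox <- sum(mask)
  voxVol <- prod(spacing)
  names(filters) <- vapply(filters, `[[`, character(1), "label")
  featNames <- NULL
  out <- numeric(0)
  if (nvox >= minVoxels) {
    cr <- cropToMask(mask, mask)  # shared bounding box for all maps
    idxCrop <- which(cr$mask)
    for (mapName in names(maps)) {
      cropped <- cropToMask(maps[[mapName]], mask)$arr
      for (fl in filters) {
        # filters are applied on the full volume so neighbourhood context
        # outside the region still contributes, then restricted to the crop
        filt <- applyFilter(maps[[mapName]], fl, spacing)
        filtCrop <- cropToMask(filt, mask)$arr
        disc <- discretize(filtCrop, cr$mask, scheme, width = width, bins = bins)
        vals <- filtCrop[idxCrop]
        levs <- disc$levels[idxCrop]
        for (cl in classes) {
          f <- switch(cl,
            firstorder = firstOrderFeatures(vals, levs, voxVol),
            glcm = textureFeatures(glcmMatrices(disc), "glcm",
                                   aggregation = aggregation),
            glrlm = textureFeatures(glrlmMatrices(disc), "glrlm",
                                    nVoxels = nvox, aggregation = aggregation),
            glszm = textureFeatures(glszmMatrix(disc), "glszm", nVoxels = nvox),
            gldm = textureFeatures(gldmMatrix(disc), "gldm", nVoxels = nvox),
            ngtdm = textureFeatures(ngtdmTable(disc), "ngtdm"))
          names(f) <- paste(regionName, mapName, fl$label, cl, names(f),
                            sep = "__")
          out <- c(out, f)
        }
      }
    }
    attr(out, "flagged") <- FALSE
    return(out)
  }
  # region too small: emit NA with the full name schema so tables stay aligned
  template <- featureNameSchema(names(maps), filters, classes, regionName)
  out <- setNames(rep(NA_real_, length(template)), template)
  attr(out, "flagged") <- TRUE
  out
}

featureNameSchema <- function(mapNames, filters, classes, regionName) {
  clNames <- list(
    firstorder = names(firstOrderFeatures(c(1, 2), c(1L, 2L))),
    glcm = names(glcmFeaturesOne(matrix(1, 1, 1))),
    glrlm = names(glrlmFeaturesOne(matrix(1, 1, 1), 1)),
    glszm = names(rlmStyleFeatures(matrix(1, 1, 1), 1, "SmallArea", "LargeArea", "Zone")),
    gldm = names(textureFeatures(matrix(1, 1, 1), "gldm", nVoxels = 1)),
    ngtdm = names(ngtdmFeatures(data.frame(level = 1, n = 1, s = 0))))
  out <- character(0)
  for (mapName in mapNames)
    for (fl in filters)
      for (cl in classes)
        out <- c(out, paste(regionName, mapName, fl$label, cl,
                            clNames[[cl]], sep = "__"))
  out
}

#' Extract features for a whole cohort into a FeatureTable
#'
#' @param cohort list of [SubjectPhantom-class] (e.g. from [generateCohort()]).
#' @param regions list of [RegionMask-class], one per subject, or a region
#'   kind string (`"ischemic"`, `"infarct"`, `"hypoxic"`) to use the truth
#'   masks.
#' @param ... passed to [extractFeatureVector()].
#' @return a [FeatureTable-class]; subjects whose region was too small carry
#'   NA rows and are listed in `metadata(x)$flaggedSubjects`.
#' @export
extractCohortFeatures <- function(cohort, regions = "ischemic", ...) {
  if (is.character(regions)) {
    kind <- regions
    regions <- lapply(cohort, function(s) {
      new("RegionMask", mask = array(as.logical(truthMask(s, kind)),
                                     dim(brainMask(s))),
          regionKind = kind, threshold = NA_real_, thresholdUnits = "")
    })
  }
  vecs <- vector("list", length(cohort))
  flagged <- character(0)
  for (k in seq_along(cohort)) {
    vecs[[k]] <- extractFeatureVector(cohort[[k]], regions[[k]], ...)
    if (isTRUE(attr(vecs[[k]], "flagged")))
      flagged <- c(flagged, subjectId(cohort[[k]]))
  }
  values <- do.call(rbind, vecs)
  rownames(values) <- vapply(cohort, subjectId, character(1))
  ft <- featureTable(values, vapply(cohort, subjectLabel, character(1)))
  metadata(ft)$flaggedSubjects <- flagged
  ft
}
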