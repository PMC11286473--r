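# Generics, accessors and show methods.

#' @rdname SubjectPhantom-class
#' @param object,x a `SubjectPhantom`
#' @export
setGeneric("perfusionMaps", function(x) standardGeneric("perfusionMaps"))
#' @rdname SubjectPhantom-class
#' @export
setMethod("perfusionMaps", "SubjectPhantom", function(x) x@maps)

#' @rdname SubjectPhantom-class
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @rdname SubjectPhantom-class
#' @export
setMethod("brainMask", "SubjectPhantom", function(x) x@brainMask)

#' @rdname SubjectPhantom-class
#' @param kind one of "ischemic", "infarct", "hypoxic"
#' @export
setGeneric("truthMask", function(x, kind) standardGeneric("truthMask"))
#' @rdname SubjectPhantom-class
#' @export
setMethod("truthMask", "SubjectPhantom", function(x, kind) {
  kind <- match.arg(kind, c("ischemic", "infarct", "hypoxic"))
  x@truthMasks[[kind]]
})

#' @rdname SubjectPhantom-class
#' @export
setGeneric("subjectLabel", function(x) standardGeneric("subjectLabel"))
#' @rdname SubjectPhantom-class
#' @export
setMethod("subjectLabel", "SubjectPhantom", function(x) x@label)

#' @rdname SubjectPhantom-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname SubjectPhantom-class
#' @export
setMethod("subjectId", "SubjectPhantom", function(x) x@subjectId)

setMethod("show", "SubjectPhantom", function(object) {
  d <- dim(object@brainMask)
  cat("SubjectPhantom", object@subjectId, "(", object@label, ")\n")
  cat("  grid:", paste(d, collapse = " x "), "voxels,",
      paste(object@spacing, collapse = " x "), "mm\n")
  cat("  truth voxels:",
      paste(vapply(object@truthMasks, sum, numeric(1)), collapse = " / "),
      paste0("(", paste(names(object@truthMasks), collapse = "/"), ")\n"))
})

#' @rdname RegionMask-class
#' @param object,x a `RegionMask`
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname RegionMask-class
#' @export
setMethod("maskArray", "RegionMask", function(x) x@mask)

#' @rdname RegionMask-class
#' @export
setGeneric("regionKind", function(x) standardGeneric("regionKind"))
#' @rdname RegionMask-class
#' @export
setMethod("regionKind", "RegionMask", function(x) x@regionKind)

setMethod("show", "RegionMask", function(object) {
  cat("RegionMask <", object@regionKind, ">: ", sum(object@mask),
      " voxels (threshold ", object@threshold, " ", object@thresholdUnits,
      ")\n", sep = "")
})

#' @rdname SvO2Grid-class
#' @param object,x a `SvO2Grid`
#' @export
setGeneric("svo2Units", function(x) standardGeneric("svo2Units"))
#' @rdname SvO2Grid-class
#' @export
setMethod("svo2Units", "SvO2Grid", function(x) x@units)

setMethod("show", "SvO2Grid", function(object) {
  u <- object@units
  cat("SvO2Grid:", nrow(u), "units,",
      sum(!is.na(u$xbarVein)), "with vein voxels")
  if ("svo2" %in% names(u))
    cat(",", sum(u$isHypoxic, na.rm = TRUE), "hypoxic")
  cat("\n  grid", paste(object@grid, collapse = " x "),
      "| midline x =", round(object@midline, 2), "\n")
})

#' @rdname FeatureTable-class
#' @param object,x a `FeatureTable`
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname FeatureTable-class
#' @details `featureValues()` returns the subjects-by-features numeric matrix
#'   (the transpose of the stored assay).
#' @export
setMethod("featureValues", "FeatureTable", function(x) t(assay(x, "features")))

#' @rdname FeatureTable-class
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))
#' @rdname FeatureTable-class
#' @export
setMethod("subjectLabels", "FeatureTable", function(x) {
  as.character(colData(x)$label)
})

#' @rdname FeatureTable-class
#' @export
setGeneric("splitTags", function(x) standardGeneric("splitTags"))
#' @rdname FeatureTable-class
#' @export
setMethod("splitTags", "FeatureTable", function(x) {
  cd <- colData(x)
  if (!"split" %in% names(cd)) return(NULL)
  as.character(cd$split)
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix, subjects in rows, features in columns.
#' @param labels character/factor of `"good"`/`"poor"`, one per subject.
#' @param split optional character of `"train"`/`"test"` tags.
#' @param subjectIds optional subject identifiers (default from rownames).
#' @return a [FeatureTable-class]
#' @export
featureTable <- function(values, labels, split = NULL, subjectIds = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("feature%03d", seq_len(ncol(values)))
  subjectIds <- subjectIds %||% rownames(values) %||%
    sprintf("S%03d", seq_len(nrow(values)))
  cd <- DataFrame(label = as.character(labels), row.names = subjectIds)
  if (!is.null(split)) cd$split <- as.character(split)
  se <- SummarizedExperiment(
    assays = list(features = t(values)), colData = cd)
  new("FeatureTable", se)
}

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", ncol(object), "subjects x", nrow(object), "features\n")
  lab <- table(subjectLabels(object))
  cat("  labels:", paste(names(lab), lab, sep = "=", collapse = ", "), "\n")
  sp <- splitTags(object)
  if (!is.null(sp)) {
    tb <- table(sp)
    cat("  split:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})
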