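# Pipeline orchestration: configuration validation, per-subject segmentation,
# the in-memory end-to-end run, and the persisting runAll() wrapper.

#' Parse filter labels into FilterSpecs
#'
#' Accepts labels like `"original"`, `"log-sigma-3"`, `"wavelet-LLH"`,
#' `"square-root"`, or the keyword `"default"` for the full bank.
#'
#' @param labels character vector of filter labels.
#' @return list of `FilterSpec`s.
#' @export
parseFilterLabels <- function(labels) {
  if (identical(labels, "default")) return(defaultFilterBank())
  lapply(labels, function(l) {
    if (grepl("^log-sigma-", l))
      return(filterSpec("log_sigma", sigma = as.numeric(sub("^log-sigma-", "", l))))
    if (grepl("^wavelet-", l))
      return(filterSpec("wavelet", subband = sub("^wavelet-", "", l)))
    filterSpec(switch(l, "square-root" = "square_root", original = "original",
                      square = "square", logarithm = "logarithm",
                      exponential = "exponential",
                      stop("unknown filter label '", l, "'")))
  })
}

#' Segment the three regions of one subject from its volumes
#'
#' Ischemic: Tmax > `tmaxThreshold` s. Infarct: ADC < `adcThreshold` mm^2/s
#' from the DWI pair. Hypoxic: upright-align the susceptibility volume,
#' partition mirrored hemisphere grid units, compute unit SvO2 against the
#' contralateral reference and flag units strictly below `svo2Ref` in the
#' hemisphere containing the ischemic lesion; the unit mask is mapped back to
#' the native grid.
#'
#' @param subject a [SubjectPhantom-class] (or any object with the same
#'   accessors).
#' @param tmaxThreshold,adcThreshold,b segmentation constants.
#' @param svo2 parameter list from [svo2Params()].
#' @return named list of [RegionMask-class] (ischemic, infarct, hypoxic) plus
#'   the `svo2Grid` and alignment record in attributes.
#' @export
segmentSubject <- function(subject, tmaxThreshold = 6, adcThreshold = 620e-6,
                           b = 1000, svo2 = svo2Params()) {
  maps <- perfusionMaps(subject)
  bm <- brainMask(subject)
  ischemic <- segmentIschemic(maps$Tmax, bm, tmaxThreshold)
  adc <- computeADC(subject@dwiB0, subject@dwiB1000, b = b)
  infarct <- segmentInfarct(adc, bm, adcThreshold)
  al <- uprightAlign(subject@chi, bm)
  part <- partitionHemisphereGrid(al$brainMask, grid = svo2$grid)
  grid <- computeUnitSvO2(al$chi, al$brainMask, part, svo2)
  ischAligned <- rotateInPlane(
    arrayShift(maskArray(ischemic), c(al$rotation$shift, 0L), FALSE),
    -al$rotation$angle, al$rotation$center, FALSE)
  affected <- if (sum(ischAligned) > 0) {
    affectedHemisphere(ischAligned, part@midline)
  } else "right"
  hypAligned <- segmentHypoxic(grid, al$brainMask, affected)
  hypoxic <- new("RegionMask",
                 mask = alignmentInvert(maskArray(hypAligned), al$rotation,
                                        FALSE) & (bm > 0),
                 regionKind = "hypoxic", threshold = svo2$svo2Ref,
                 thresholdUnits = "fraction")
  out <- list(ischemic = ischemic, infarct = infarct, hypoxic = hypoxic)
  attr(out, "svo2Grid") <- grid
  attr(out, "rotation") <- al$rotation
  attr(out, "affectedHemisphere") <- affected
  out
}

regionsNeeded <- function(groups) {
  unique(unlist(lapply(groups, function(g) parseGroupName(g)$regions)))
}

#' Run the pipeline in memory on a generated cohort
#'
#' Segments every subject (or takes the ground-truth masks), extracts the
#' radiomics tables and regional parameter means for the regions the
#' requested groups need, makes one shared stratified split, runs selection
#' per region on the training rows, assembles the groups and evaluates the
#' classifier panel.
#'
#' @param cohort output of [generateCohort()].
#' @param groups experimental groups to evaluate (subset of [groupNames()]).
#' @param useTruthMasks use the generator's ground-truth masks instead of
#'   segmenting (default FALSE).
#' @param filters,classes,scheme,width,bins,aggregation,minVoxels extraction
#'   settings (see [extractFeatureVector()]).
#' @param alpha,cvFolds,lassoSeed,perMap,standardizeOn selection settings.
#' @param ratio,classifiers,seed evaluation settings; `seed` drives the split
#'   and classifier fits.
#' @param tmaxThreshold,adcThreshold,svo2 segmentation settings.
#' @return list: `report`, `best` (from [runExperimentMatrix()]),
#'   `selection` (per-region reports), `split`, `dropped` (subjects flagged
#'   for an unusably small region).
#' @export
runPipeline <- function(cohort, groups = groupNames(), useTruthMasks = FALSE,
                        filters = defaultFilterBank(),
                        classes = c("firstorder", "glcm", "glrlm", "glszm",
                                    "gldm", "ngtdm"),
                        scheme = "fixed_bin_width", width = 25, bins = 16,
                        aggregation = "average", minVoxels = 10,
                        alpha = 0.05, cvFolds = 5, lassoSeed = 1,
                        perMap = TRUE, standardizeOn = "train",
                        ratio = 0.7, classifiers = c("SVM", "MLP", "RF",
                                                     "Ada", "LR", "NB"),
                        seed = 1, tmaxThreshold = 6, adcThreshold = 620e-6,
                        svo2 = svo2Params()) {
  subjects <- cohort$subjects
  labels <- cohort$labels
  regions <- regionsNeeded(groups)
  radRegions <- regionsNeeded(grep("_radiomics$", groups, value = TRUE))
  parRegions <- regionsNeeded(grep("_parameters$", groups, value = TRUE))

  masks <- if (useTruthMasks) {
    lapply(subjects, function(s) {
      out <- lapply(setNames(regions, regions), function(r) {
        new("RegionMask", mask = array(as.logical(truthMask(s, r)),
                                       dim(brainMask(s))),
            regionKind = r, threshold = NA_real_, thresholdUnits = "")
      })
      out
    })
  } else {
    lapply(subjects, function(s) {
      segmentSubject(s, tmaxThreshold, adcThreshold, svo2 = svo2)[regions]
    })
  }

  sp <- splitCohort(labels, ratio, seed)

  radiomicsByRegion <- list(); parametersByRegion <- list()
  selectionReports <- list()
  dropped <- character(0)
  for (r in regions) {
    regMasks <- lapply(masks, `[[`, r)
    if (r %in% radRegions) {
      ft <- extractCohortFeatures(subjects, regMasks, filters = filters,
                                  classes = classes, scheme = scheme,
                                  width = width, bins = bins,
                                  aggregation = aggregation,
                                  minVoxels = minVoxels)
      dropped <- union(dropped, metadata(ft)$flaggedSubjects)
      radiomicsByRegion[[r]] <- ft
    }
    if (r %in% parRegions) {
      pm <- t(vapply(seq_along(subjects), function(k) {
        regionMeanParameters(perfusionMaps(subjects[[k]]), regMasks[[k]])
      }, numeric(4)))
      rownames(pm) <- vapply(subjects, subjectId, character(1))
      parametersByRegion[[r]] <- pm
    }
  }

  keep <- !(vapply(subjects, subjectId, character(1)) %in% dropped)
  if (length(parRegions)) {
    paramNA <- Reduce(`|`, lapply(parametersByRegion, function(m) apply(is.na(m), 1, any)))
    if (!is.null(paramNA)) keep <- keep & !paramNA
  }
  if (any(!keep))
    warning(sum(!keep), " subject(s) dropped: region below ", minVoxels,
            " voxels or empty")
  splitTagsVec <- sp$split[keep]
  labelsKept <- labels[keep]

  selectedByRegion <- list()
  for (r in names(radiomicsByRegion)) {
    ft <- radiomicsByRegion[[r]][, keep]
    ft <- featureTable(featureValues(ft), labelsKept, splitTagsVec,
                       subjectIds = colnames(assay(ft, "features")))
    sel <- selectFeatures(ft, alpha = alpha, cvFolds = cvFolds,
                          lassoSeed = lassoSeed, perMap = perMap,
                          standardizeOn = standardizeOn)
    selectionReports[[r]] <- sel$report
    kept <- sel$retained
    if (!length(kept)) {
      warning("region '", r, "': Lasso retained no feature; ",
              "falling back to the t-test survivors")
      kept <- sel$report$feature[sel$report$passedTtest]
    }
    if (!length(kept)) kept <- sel$report$feature[seq_len(min(5, nrow(sel$report)))]
    selectedByRegion[[r]] <- sel$table[rownames(sel$table) %in% kept, ]
  }
  parametersKept <- lapply(parametersByRegion, function(m) m[keep, , drop = FALSE])

  groupTables <- lapply(setNames(groups, groups), function(g) {
    assembleGroup(selectedByRegion, parametersKept, g,
                  labels = labelsKept, split = splitTagsVec)
  })
  ev <- runExperimentMatrix(groupTables, classifiers = classifiers, seed = seed)
  list(report = ev$report, best = ev$best, selection = selectionReports,
       split = sp, dropped = dropped, groupTables = groupTables,
       masks = masks)
}

#' Mirror a region mask into the contralateral hemisphere
#'
#' Reflects the mask about the midsagittal plane of its grid -- useful as a
#' deliberately mis-localized control region carrying no lesion signal.
#'
#' @param region a [RegionMask-class] or logical array.
#' @param brainMask logical array; the mirrored mask is restricted to it.
#' @return a [RegionMask-class] of kind `"control"`.
#' @export
mirrorRegionMask <- function(region, brainMask) {
  m <- if (is(region, "RegionMask")) maskArray(region) else region > 0
  mm <- mirrorX(m) & (brainMask > 0)
  new("RegionMask", mask = mm, regionKind = "control",
      threshold = NA_real_, thresholdUnits = "")
}

#' Select and evaluate a single custom region's radiomics
#'
#' Runs extraction, selection and the classifier panel for one per-subject
#' region-mask list (e.g. a mirrored control region), reusing the shared
#' split convention of [runPipeline()].
#'
#' @param cohort output of [generateCohort()].
#' @param masks per-subject list of [RegionMask-class].
#' @param ... extraction settings passed to [extractCohortFeatures()].
#' @param alpha,cvFolds,lassoSeed selection settings.
#' @param ratio,classifiers,seed evaluation settings.
#' @return list with `report` and `best` as in [runExperimentMatrix()].
#' @export
evaluateRegionSet <- function(cohort, masks, ..., alpha = 0.05, cvFolds = 5,
                              lassoSeed = 1, ratio = 0.7,
                              classifiers = c("SVM", "MLP", "RF", "Ada",
                                              "LR", "NB"),
                              seed = 1) {
  ft <- extractCohortFeatures(cohort$subjects, masks, ...)
  keep <- !(colnames(assay(ft, "features")) %in% metadata(ft)$flaggedSubjects)
  selectAndEvaluate(featureValues(ft)[keep, , drop = FALSE],
                    cohort$labels[keep], alpha = alpha, cvFolds = cvFolds,
                    lassoSeed = lassoSeed, ratio = ratio,
                    classifiers = classifiers, seed = seed)
}

#' Select features and run the classifier panel on a feature matrix
#'
#' The selection + evaluation tail of the pipeline, reusable on any
#' precomputed subjects-by-features matrix (the labels may be permuted to
#' obtain null distributions without re-extracting features).
#'
#' @param values subjects x features numeric matrix.
#' @param labels `"good"`/`"poor"` labels.
#' @param alpha,cvFolds,lassoSeed selection settings.
#' @param ratio,classifiers,seed split and panel settings.
#' @return list with `report`, `best` and the selection report.
#' @export
selectAndEvaluate <- function(values, labels, alpha = 0.05, cvFolds = 5,
                              lassoSeed = 1, ratio = 0.7,
                              classifiers = c("SVM", "MLP", "RF", "Ada",
                                              "LR", "NB"),
                              seed = 1) {
  sp <- splitCohort(labels, ratio, seed)
  ft <- featureTable(values, labels, sp$split)
  sel <- selectFeatures(ft, alpha = alpha, cvFolds = cvFolds,
                        lassoSeed = lassoSeed)
  kept <- sel$retained
  if (!length(kept)) kept <- sel$report$feature[sel$report$passedTtest]
  if (!length(kept)) kept <- sel$report$feature[seq_len(min(5, nrow(sel$report)))]
  tab <- sel$table[rownames(sel$table) %in% kept, ]
  ev <- runExperimentMatrix(list(Ischemic_radiomics = tab),
                            classifiers = classifiers, seed = seed)
  list(report = ev$report, best = ev$best, selection = sel$report)
}

# ---------------------------------------------------------------------------
# configuration

defaultRunConfig <- function() {
  list(
    cohort = list(nGood = 45, nPoor = 45, volumeShape = c(48, 48, 12),
                  voxelSpacing = c(4, 4, 5), lesionRadiusRange = c(5, 9),
                  veinChiRange = c(120, 180),
                  noiseSd = c(CBF = 3, CBV = 0.4, MTT = 0.8, Tmax = 0.8),
                  chiNoiseSd = 0, dwiNoiseSd = 0, hypoxicUnits = 6,
                  hypoxiaFactor = 1.5),
    segmentation = list(tmaxThreshold = 6, adcThreshold = 620e-6,
                        veinLow = 90, veinHigh = 300, svo2Ref = 0.7,
                        grid = c(10, 10, 1), b = 1000),
    extraction = list(filters = "default",
                      classes = c("firstorder", "glcm", "glrlm", "glszm",
                                  "gldm", "ngtdm"),
                      scheme = "fixed_bin_width", binWidth = 25,
                      binCount = 16, aggregation = "average", minVoxels = 10),
    selection = list(alpha = 0.05, cvFolds = 5, lassoSeed = 1, perMap = TRUE,
                     standardizeOn = "train"),
    evaluation = list(ratio = 0.7,
                      classifiers = c("SVM", "MLP", "RF", "Ada", "LR", "NB"),
                      groups = groupNames()),
    useTruthMasks = FALSE,
    masterSeed = 1)
}

#' Validate a run configuration
#'
#' Accepts a YAML file path or a nested list; injects defaults (every
#' threshold default is the study constant: 6 s, 620e-6 mm^2/s, 90 ppb,
#' 300 ppb, 0.7, alpha 0.05, split ratio 0.7), checks units/signs and rejects
#' unknown keys and unknown group names before any computation.
#'
#' @param config path to a YAML file, or a nested list (possibly empty).
#' @return the completed configuration list (class `RunConfig`).
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config) %||% list()
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  def <- defaultRunConfig()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  out <- def
  for (sec in names(config)) {
    if (is.list(def[[sec]]) && !is.null(names(def[[sec]]))) {
      badk <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(badk))
        stop("unknown key(s) in '", sec, "': ", paste(badk, collapse = ", "))
      for (k in names(config[[sec]])) out[[sec]][[k]] <- config[[sec]][[k]]
    } else out[[sec]] <- config[[sec]]
  }
  seg <- out$segmentation
  for (k in c("tmaxThreshold", "adcThreshold", "veinLow", "veinHigh", "svo2Ref")) {
    if (!is.numeric(seg[[k]]) || seg[[k]] <= 0)
      stop("segmentation$", k, " must be a positive number")
  }
  if (seg$veinLow >= seg$veinHigh) stop("segmentation$veinLow must be < veinHigh")
  if (out$selection$alpha <= 0 || out$selection$alpha >= 1)
    stop("selection$alpha must be in (0, 1)")
  if (out$evaluation$ratio <= 0 || out$evaluation$ratio >= 1)
    stop("evaluation$ratio must be in (0, 1)")
  badg <- setdiff(out$evaluation$groups, groupNames())
  if (length(badg))
    stop("unknown group name(s): ", paste(badg, collapse = ", "),
         "; valid groups: ", paste(groupNames(), collapse = ", "))
  unknownCl <- setdiff(out$evaluation$classifiers,
                       c("SVM", "MLP", "RF", "Ada", "LR", "NB"))
  if (length(unknownCl))
    stop("unknown classifier(s): ", paste(unknownCl, collapse = ", "))
  class(out) <- c("RunConfig", "list")
  out
}

configToCohortConfig <- function(cfg) {
  co <- cfg$cohort
  ns <- unlist(co$noiseSd)
  cohortConfig(nGood = co$nGood, nPoor = co$nPoor,
               volumeShape = co$volumeShape, voxelSpacing = co$voxelSpacing,
               lesionRadiusRange = co$lesionRadiusRange,
               veinChiRange = co$veinChiRange,
               noiseSd = ns[c("CBF", "CBV", "MTT", "Tmax")],
               chiNoiseSd = co$chiNoiseSd, dwiNoiseSd = co$dwiNoiseSd,
               hypoxicUnits = co$hypoxicUnits,
               hypoxiaFactor = co$hypoxiaFactor, seed = cfg$masterSeed)
}

# ---------------------------------------------------------------------------
# disk I/O

#' Write a subject's volumes as NIfTI plus a JSON sidecar
#'
#' @param subject a [SubjectPhantom-class].
#' @param dir output directory (created).
#' @return the sidecar path, invisibly.
#' @export
writeSubject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wr <- function(vol, name) {
    p <- file.path(dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vol * 1, pixdim = subject@spacing), p)
    paths[[name]] <<- p
    p
  }
  for (nm in names(subject@maps)) wr(subject@maps[[nm]], nm)
  wr(subject@dwiB0, "dwi_b0"); wr(subject@dwiB1000, "dwi_b1000")
  wr(subject@chi, "chi"); wr(subject@brainMask, "brain_mask")
  for (nm in names(subject@truthMasks))
    wr(subject@truthMasks[[nm]], paste0("truth_", nm))
  sidecar <- file.path(dir, "subject.json")
  jsonlite::write_json(
    list(subject_id = subject@subjectId, label = subject@label,
         seed = subject@seed, spacing = subject@spacing,
         volumes = lapply(paths, basename)),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Read a subject written by [writeSubject()]
#'
#' @param dir subject directory containing `subject.json`.
#' @return a [SubjectPhantom-class].
#' @export
readSubject <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "subject.json"),
                              simplifyVector = TRUE)
  rd <- function(name) {
    v <- RNifti::readNifti(file.path(dir, meta$volumes[[name]]))
    array(as.numeric(v), dim(v))
  }
  maps <- lapply(setNames(c("CBF", "CBV", "MTT", "Tmax"),
                          c("CBF", "CBV", "MTT", "Tmax")), rd)
  new("SubjectPhantom", maps = maps,
      dwiB0 = rd("dwi_b0"), dwiB1000 = rd("dwi_b1000"), chi = rd("chi"),
      brainMask = array(rd("brain_mask") > 0, dim(maps$CBF)),
      truthMasks = lapply(setNames(c("ischemic", "infarct", "hypoxic"),
                                   c("ischemic", "infarct", "hypoxic")),
                          function(r) {
                            m <- rd(paste0("truth_", r))
                            array(m > 0, dim(maps$CBF))
                          }),
      label = meta$label, subjectId = meta$subject_id,
      spacing = as.numeric(meta$spacing), seed = as.integer(meta$seed))
}

#' Run the whole pipeline from a configuration, persisting artifacts
#'
#' Executes simulate, segment, extract, select and evaluate in order, writing
#' every intermediate under `outDir`: per-subject NIfTI volumes and masks, a
#' cohort manifest CSV, per-region feature and selection CSVs, the evaluation
#' report CSV/JSON and a manifest of all settings and seeds. A rerun with an
#' identical configuration reproduces the report byte-identically.
#'
#' @param config anything [validateConfig()] accepts.
#' @param outDir output directory.
#' @param writeVolumes write per-subject NIfTI volumes (default TRUE).
#' @return the [runPipeline()] result, invisibly.
#' @export
runAll <- function(config = list(), outDir, writeVolumes = TRUE) {
  cfg <- validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generateCohort(configToCohortConfig(cfg))
  manifest <- data.frame(
    subject_id = vapply(cohort$subjects, subjectId, character(1)),
    label = cohort$labels,
    seed = vapply(cohort$subjects, function(s) s@seed, integer(1)),
    path = file.path("subjects",
                     vapply(cohort$subjects, subjectId, character(1))))
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  if (writeVolumes) {
    for (s in cohort$subjects)
      writeSubject(s, file.path(outDir, "subjects", subjectId(s)))
  }
  ex <- cfg$extraction; se <- cfg$selection; ev <- cfg$evaluation
  res <- runPipeline(
    cohort, groups = ev$groups, useTruthMasks = isTRUE(cfg$useTruthMasks),
    filters = parseFilterLabels(ex$filters), classes = ex$classes,
    scheme = ex$scheme, width = ex$binWidth, bins = ex$binCount,
    aggregation = ex$aggregation, minVoxels = ex$minVoxels,
    alpha = se$alpha, cvFolds = se$cvFolds, lassoSeed = se$lassoSeed,
    perMap = se$perMap, standardizeOn = se$standardizeOn,
    ratio = ev$ratio, classifiers = ev$classifiers, seed = cfg$masterSeed,
    tmaxThreshold = cfg$segmentation$tmaxThreshold,
    adcThreshold = cfg$segmentation$adcThreshold,
    svo2 = svo2Params(cfg$segmentation$svo2Ref, cfg$segmentation$veinLow,
                      cfg$segmentation$veinHigh, cfg$segmentation$grid))
  for (r in names(res$selection))
    write.csv(res$selection[[r]],
              file.path(outDir, paste0("selection_", r, ".csv")),
              row.names = FALSE)
  for (g in names(res$groupTables))
    write.csv(data.frame(featureValues(res$groupTables[[g]]),
                         check.names = FALSE),
              file.path(outDir, paste0("features_", g, ".csv")))
  write.csv(res$report, file.path(outDir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(cfg), dropped = res$dropped,
         best = res$best),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(res)
}
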