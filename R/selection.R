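# Feature standardization, t-test filtering, Lasso selection, and assembly of
# the 14 experimental groups.

resolveFitRows <- function(ft, rows) {
  if (!is.null(rows)) return(rows)
  sp <- splitTags(ft)
  if (!is.null(sp)) which(sp == "train") else seq_len(ncol(ft))
}

#' Standardize features: (F - mean) / (max - min)
#'
#' Statistics are fitted on `fitRows` (the training subjects by default, to
#' avoid leakage) and applied to every row. Constant features (range 0) map
#' to 0, with a warning naming how many were degenerate.
#'
#' @param ft a [FeatureTable-class].
#' @param fitRows subject indices to fit the statistics on; default the
#'   `train` rows when a split is present, else all rows.
#' @return the standardized [FeatureTable-class]; the fitted per-feature
#'   `center` (mean) and `range` (max - min) are stored in `metadata()$fit`.
#' @export
standardizeFeatures <- function(ft, fitRows = NULL) {
  fitRows <- resolveFitRows(ft, fitRows)
  if (!length(fitRows)) stop("empty fit set")
  x <- featureValues(ft)
  xf <- x[fitRows, , drop = FALSE]
  ctr <- colMeans(xf)
  rng <- apply(xf, 2, function(v) max(v) - min(v))
  bad <- rng == 0
  if (any(bad))
    warning(sum(bad), " constant feature(s) mapped to 0 (range 0)")
  scl <- ifelse(bad, 1, rng)
  z <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  z[, bad] <- 0
  out <- featureTable(z, subjectLabels(ft), splitTags(ft),
                      subjectIds = rownames(x))
  metadata(out) <- metadata(ft)
  metadata(out)$fit <- list(center = ctr, range = rng, fitRows = fitRows)
  out
}

#' Two-sample t-test filter
#'
#' Two-sided independent two-sample t-test per feature (Student's
#' equal-variance form by default; Welch via `varEqual = FALSE`), on the
#' training rows. A feature passes iff p < alpha (strict); features constant
#' in both classes get p = NA and are dropped.
#'
#' @param ft a [FeatureTable-class].
#' @param alpha significance level (default 0.05).
#' @param rows subject rows to test on (default the train rows).
#' @param varEqual pool the variance (Student) or not (Welch).
#' @return data.frame with columns feature, t, p, passedTtest.
#' @export
ttestFilter <- function(ft, alpha = 0.05, rows = NULL, varEqual = TRUE) {
  rows <- resolveFitRows(ft, rows)
  x <- featureValues(ft)[rows, , drop = FALSE]
  y <- subjectLabels(ft)[rows]
  g0 <- y == "good"; g1 <- y == "poor"
  n0 <- sum(g0); n1 <- sum(g1)
  if (n0 < 2 || n1 < 2) stop("both classes need at least 2 subjects")
  m0 <- colMeans(x[g0, , drop = FALSE]); m1 <- colMeans(x[g1, , drop = FALSE])
  v0 <- apply(x[g0, , drop = FALSE], 2, var)
  v1 <- apply(x[g1, , drop = FALSE], 2, var)
  if (varEqual) {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
    df <- n0 + n1 - 2
  } else {
    se <- sqrt(v0 / n0 + v1 / n1)
    df <- (v0 / n0 + v1 / n1)^2 /
      ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  }
  t <- (m1 - m0) / se
  t[se == 0] <- NA
  p <- 2 * pt(-abs(t), df)
  data.frame(feature = colnames(x), t = t, p = p,
             passedTtest = !is.na(p) & p < alpha, row.names = NULL)
}

#' Lasso selection of t-test survivors
#'
#' L1-penalized least squares of the 0/1 label on the features, with the
#' penalty chosen by k-fold cross-validation over a logarithmic grid
#' (mirroring the CV-Lasso routine of the mainstream ML toolkit); features
#' with non-zero weight at the chosen penalty are retained.
#'
#' @param x numeric matrix (subjects x features), already standardized.
#' @param y numeric 0/1 labels (poor = 1).
#' @param cvFolds cross-validation folds (default 5).
#' @param seed seed for the fold assignment.
#' @param nlambda size of the penalty grid.
#' @return list with `weights` (named, at the chosen penalty), `retained`
#'   (feature names), `lambda`.
#' @export
lassoSelect <- function(x, y, cvFolds = 5, seed = 1, nlambda = 100) {
  if (ncol(x) == 0)
    return(list(weights = numeric(0), retained = character(0), lambda = NA_real_))
  if (length(unique(y)) < 2) stop("labels are constant")
  xin <- x
  pad <- ncol(x) == 1
  if (pad) xin <- cbind(x, `.pad.` = 0)  # glmnet needs >= 2 columns
  fit <- withSeed(seed, glmnet::cv.glmnet(
    xin, y, family = "gaussian", nfolds = cvFolds, nlambda = nlambda,
    standardize = FALSE))
  w <- as.numeric(coef(fit, s = "lambda.min"))[-1]
  names(w) <- colnames(xin)
  if (pad) w <- w[colnames(x)]
  list(weights = w, retained = names(w)[w != 0], lambda = fit$lambda.min)
}

featureMapToken <- function(nm) {
  parts <- strsplit(nm, "__", fixed = TRUE)
  vapply(parts, function(p) if (length(p) >= 2) p[2] else "all", character(1))
}

#' Full selection pipeline for one region's feature table
#'
#' Standardizes (training statistics), filters by t-test, then runs the Lasso
#' separately per perfusion map on the survivors (matching the per-map
#' selection-then-combination design) and unions the retained sets.
#'
#' @param ft a [FeatureTable-class] (one region), split tags recommended.
#' @param alpha t-test significance level.
#' @param cvFolds,lassoSeed Lasso cross-validation settings.
#' @param perMap run the Lasso per perfusion map (default) or once overall.
#' @param standardizeOn `"train"` (default, leakage-free) or `"all"`.
#' @return list: `table` (standardized [FeatureTable-class]), `report`
#'   (per-feature data.frame with t, p, passedTtest, lassoWeight, retained),
#'   `retained` (feature names).
#' @export
selectFeatures <- function(ft, alpha = 0.05, cvFolds = 5, lassoSeed = 1,
                           perMap = TRUE, standardizeOn = c("train", "all")) {
  standardizeOn <- match.arg(standardizeOn)
  fitRows <- if (standardizeOn == "train") NULL else seq_len(ncol(ft))
  st <- suppressWarnings(standardizeFeatures(ft, fitRows))
  rep <- ttestFilter(st, alpha = alpha)
  rep$lassoWeight <- 0
  trainRows <- resolveFitRows(st, NULL)
  x <- featureValues(st)[trainRows, , drop = FALSE]
  y <- as.numeric(subjectLabels(st)[trainRows] == "poor")
  surv <- rep$feature[rep$passedTtest]
  groups <- if (perMap) split(surv, featureMapToken(surv)) else list(all = surv)
  for (g in groups) {
    if (!length(g)) next
    ls <- lassoSelect(x[, g, drop = FALSE], y, cvFolds = cvFolds, seed = lassoSeed)
    rep$lassoWeight[match(g, rep$feature)] <- ls$weights
  }
  rep$retained <- rep$passedTtest & rep$lassoWeight != 0
  list(table = st, report = rep, retained = rep$feature[rep$retained])
}

#' The 14 experimental group names
#'
#' Seven region combinations (ischemic, infarct, hypoxic and their unions)
#' crossed with the two feature types (selected radiomics features vs the
#' four regional perfusion parameters).
#'
#' @return character(14).
#' @export
groupNames <- function() {
  combos <- c("Ischemic", "Infarct", "Hypoxic",
              "Ischemic_infarct", "Ischemic_hypoxic", "Infarct_hypoxic",
              "Ischemic_infarct_hypoxic")
  c(paste0(combos, "_radiomics"), paste0(combos, "_parameters"))
}

parseGroupName <- function(group) {
  if (!group %in% groupNames())
    stop("unknown group '", group, "'; valid groups: ",
         paste(groupNames(), collapse = ", "))
  parts <- strsplit(group, "_", fixed = TRUE)[[1]]
  list(regions = tolower(parts[-length(parts)]),
       type = parts[length(parts)])
}

#' Assemble an experimental group table
#'
#' Concatenates, per the group name, either the per-region selected radiomics
#' features or the per-region four regional perfusion parameter means.
#'
#' @param radiomicsByRegion named list (ischemic/infarct/hypoxic) of
#'   [FeatureTable-class]s already restricted to their retained features.
#' @param parametersByRegion named list of subjects x 4 matrices of regional
#'   means (CBF, CBV, MTT, Tmax).
#' @param group one of [groupNames()].
#' @param labels,split optional label / split-tag vectors; defaulted from the
#'   first available radiomics table.
#' @return a [FeatureTable-class] for the group.
#' @export
assembleGroup <- function(radiomicsByRegion, parametersByRegion, group,
                          labels = NULL, split = NULL) {
  gp <- parseGroupName(group)
  if (gp$type == "radiomics") {
    tabs <- radiomicsByRegion[gp$regions]
    if (any(vapply(tabs, is.null, logical(1))))
      stop("missing radiomics table(s) for group ", group)
    vals <- do.call(cbind, lapply(tabs, featureValues))
    ref <- tabs[[1]]
  } else {
    mats <- parametersByRegion[gp$regions]
    if (any(vapply(mats, is.null, logical(1))))
      stop("missing parameter table(s) for group ", group)
    vals <- do.call(cbind, lapply(names(mats), function(r) {
      m <- as.matrix(mats[[r]])
      colnames(m) <- paste(r, colnames(m), sep = "__")
      m
    }))
    avail <- Filter(Negate(is.null), radiomicsByRegion)
    ref <- if (length(avail)) avail[[1]] else NULL
  }
  if (is.null(labels)) {
    if (is.null(ref)) stop("labels must be supplied when no radiomics table is available")
    labels <- subjectLabels(ref)
  }
  if (is.null(split) && !is.null(ref)) split <- splitTags(ref)
  if (anyNA(vals))
    stop("group ", group, ": a subject is missing a required region")
  featureTable(vals, labels, split, subjectIds = rownames(vals))
}
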