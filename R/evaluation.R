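# Classifier panel: stratified split, six classifiers, confusion metrics and
# rank-based AUC, and the full group x classifier experiment matrix.

#' Stratified train/test split
#'
#' Per-class train counts follow a fixed rounding convention: floor for the
#' `good` class, ceiling for `poor` (so 45 + 45 at 0.7 gives 31 + 32 train
#' and 14 + 13 test). Deterministic given the seed.
#'
#' @param labels character vector of `"good"`/`"poor"`.
#' @param ratio train fraction (default 0.7).
#' @param seed RNG seed for the within-class shuffles.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive) and a `split` tag vector aligned with `labels`.
#' @export
splitCohort <- function(labels, ratio = 0.7, seed = 1) {
  labels <- as.character(labels)
  if (!all(labels %in% c("good", "poor")))
    stop("labels must be 'good' or 'poor'")
  idxG <- which(labels == "good"); idxP <- which(labels == "poor")
  if (!length(idxG) || !length(idxP)) stop("a class has 0 members")
  withSeed(seed, {
    idxG <- sample(idxG); idxP <- sample(idxP)
  })
  nG <- floor(length(idxG) * ratio)
  nP <- ceiling(length(idxP) * ratio)
  train <- sort(c(idxG[seq_len(nG)], idxP[seq_len(nP)]))
  test <- sort(setdiff(seq_along(labels), train))
  split <- rep("test", length(labels)); split[train] <- "train"
  list(train = train, test = test, split = split)
}

#' Specify a classifier
#'
#' @param kind one of `"SVM"`, `"MLP"`, `"RF"`, `"Ada"`, `"LR"`, `"NB"`.
#' @param hyper named list of hyperparameter overrides.
#' @param seed seed for stochastic fits.
#' @return a `ClassifierSpec` list.
#' @export
classifierSpec <- function(kind = c("SVM", "MLP", "RF", "Ada", "LR", "NB"),
                           hyper = list(), seed = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hyper = hyper, seed = seed),
            class = "ClassifierSpec")
}

# discrete AdaBoost (SAMME) over depth-1 rpart stumps; no boosting package
# is shipped for R here, so the classic algorithm is implemented directly
adaboostFit <- function(x, y01, nRounds = 50) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(.y = factor(y01), x, check.names = FALSE)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(nRounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y01))
    if (err <= 0) { stumps[[m]] <- fit; alphas[m] <- 10; break }
    if (err >= 0.5) break
    a <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- a
    w <- w * exp(a * ifelse(pred != y01, 1, -1))
    w <- w / sum(w)
  }
  if (!length(stumps)) {  # no usable stump: fall back to the majority class
    stumps <- list(NULL); alphas <- 0
  }
  list(stumps = stumps, alphas = alphas, majority = as.integer(mean(y01) >= 0.5))
}

adaboostScore <- function(model, x) {
  df <- data.frame(x, check.names = FALSE)
  s <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    fit <- model$stumps[[m]]
    if (is.null(fit)) { s <- s + (2 * model$majority - 1); next }
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    s <- s + model$alphas[m] * (2 * pred - 1)
  }
  1 / (1 + exp(-2 * s))  # logistic margin -> pseudo-probability of class 1
}

#' Fit one classifier and predict the test set
#'
#' Models are fitted on the training rows only. Scores are continuous
#' positive-class probabilities (or a monotone surrogate) for AUC;
#' predictions use the model's default 0.5 rule on that score. Positive
#' class is `poor`. A failing classifier returns NULL with a warning rather
#' than aborting the panel.
#'
#' @param spec a [classifierSpec()].
#' @param trainX,trainY training matrix and `"good"`/`"poor"` labels.
#' @param testX test matrix.
#' @return list with `score` (P(poor)) and `pred` (`"good"`/`"poor"`), or
#'   NULL on failure.
#' @export
fitPredict <- function(spec, trainX, trainY, testX) {
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  y01 <- as.integer(trainY == "poor")
  if (length(unique(y01)) < 2) stop("training set must contain both classes")
  h <- spec$hyper
  score <- tryCatch(withSeed(spec$seed, switch(spec$kind,
    SVM = {
      fit <- e1071::svm(trainX, factor(y01, levels = 0:1),
                        kernel = h$kernel %||% "radial",
                        cost = h$cost %||% 1, probability = TRUE)
      pr <- predict(fit, testX, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    MLP = {
      fit <- nnet::nnet(trainX, y01, size = h$size %||% 16,
                        decay = h$decay %||% 1e-4,
                        maxit = h$maxit %||% 200, entropy = TRUE,
                        trace = FALSE, MaxNWts = 100000)
      as.numeric(predict(fit, testX))
    },
    RF = {
      fit <- randomForest::randomForest(trainX, factor(y01, levels = 0:1),
                                        ntree = h$ntree %||% 500)
      predict(fit, testX, type = "prob")[, "1"]
    },
    Ada = {
      fit <- adaboostFit(trainX, y01, nRounds = h$nRounds %||% 50)
      adaboostScore(fit, testX)
    },
    LR = {
      df <- data.frame(.y = y01, trainX, check.names = FALSE)
      fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial(),
                                  control = list(maxit = 100)))
      suppressWarnings(as.numeric(
        predict(fit, data.frame(testX, check.names = FALSE),
                type = "response")))
    },
    NB = {
      fit <- e1071::naiveBayes(trainX, factor(y01, levels = 0:1))
      predict(fit, testX, type = "raw")[, "1"]
    })),
    error = function(e) {
      warning(spec$kind, " failed: ", conditionMessage(e))
      NULL
    })
  if (is.null(score)) return(NULL)
  score[is.na(score)] <- 0.5
  list(score = unname(score),
       pred = ifelse(score > 0.5, "poor", "good"))
}

#' Rank-statistic AUC
#'
#' Probability that a random positive outranks a random negative, ties
#' counted half (the Mann-Whitney form).
#'
#' @param scores continuous positive-class scores.
#' @param truth `"good"`/`"poor"` truth labels (positive = poor).
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(scores, truth) {
  pos <- truth == "poor"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion metrics and AUC for one prediction set
#'
#' @param truth,pred `"good"`/`"poor"` vectors; positive class is `poor`.
#' @param scores continuous scores for AUC (optional).
#' @return one-row data.frame: TP/FP/TN/FN, accuracy, sensitivity,
#'   specificity, PPV, NPV, AUC. With single-class truth the class-conditional
#'   metrics are NA (flagged, not an error).
#' @export
computeMetrics <- function(truth, pred, scores = NULL) {
  if (length(truth) != length(pred)) stop("length mismatch")
  tp <- sum(truth == "poor" & pred == "poor")
  fn <- sum(truth == "poor" & pred == "good")
  tn <- sum(truth == "good" & pred == "good")
  fp <- sum(truth == "good" & pred == "poor")
  div <- function(a, b) if (b > 0) a / b else NA_real_
  data.frame(
    TP = tp, FP = fp, TN = tn, FN = fn,
    accuracy = div(tp + tn, tp + tn + fp + fn),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    auc = if (is.null(scores)) NA_real_ else aucScore(scores, truth))
}

#' Run the full group x classifier experiment matrix
#'
#' Evaluates every requested experimental group with every classifier of the
#' panel on the shared split carried by the group tables, and reports the
#' per-group best classifier by AUC.
#'
#' @param groupTables named list of [FeatureTable-class]s with split tags
#'   (e.g. from [assembleGroup()]).
#' @param classifiers character vector from the six-member panel.
#' @param seed seed passed to each classifier fit.
#' @return list: `report` (one row per group x classifier with the metrics)
#'   and `best` (per-group best classifier by AUC).
#' @export
runExperimentMatrix <- function(groupTables,
                                classifiers = c("SVM", "MLP", "RF", "Ada",
                                                "LR", "NB"),
                                seed = 1) {
  stopifnot(length(names(groupTables)) == length(groupTables))
  unknown <- setdiff(names(groupTables), groupNames())
  if (length(unknown))
    stop("unknown group name(s): ", paste(unknown, collapse = ", "),
         "; valid groups: ", paste(groupNames(), collapse = ", "))
  rows <- list()
  for (g in names(groupTables)) {
    ft <- groupTables[[g]]
    sp <- splitTags(ft)
    if (is.null(sp)) stop("group ", g, " has no split tags")
    x <- featureValues(ft); y <- subjectLabels(ft)
    tr <- sp == "train"; te <- sp == "test"
    for (cl in classifiers) {
      res <- fitPredict(classifierSpec(cl, seed = seed),
                        x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE])
      met <- if (is.null(res)) {
        data.frame(TP = NA, FP = NA, TN = NA, FN = NA, accuracy = NA,
                   sensitivity = NA, specificity = NA, ppv = NA, npv = NA,
                   auc = NA)
      } else computeMetrics(y[te], res$pred, res$score)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(group = g, classifier = cl,
                   nTrain = sum(tr), nTest = sum(te)), met)
    }
  }
  report <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(report, report$group), function(d) {
    d[which.max(d$auc), , drop = FALSE]
  }))
  rownames(best) <- NULL
  list(report = report, best = best)
}
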