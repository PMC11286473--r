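# Stratified split, classifier panel, confusion metrics, AUC.

test_that("the 7:3 stratified split reproduces the documented counts", {
  labels <- rep(c("good", "poor"), each = 45)
  sp <- splitCohort(labels, 0.7, seed = 1)
  expect_length(sp$train, 63)
  expect_length(sp$test, 27)
  expect_equal(sum(labels[sp$train] == "good"), 31)
  expect_equal(sum(labels[sp$train] == "poor"), 32)
  expect_equal(sum(labels[sp$test] == "good"), 14)
  expect_equal(sum(labels[sp$test] == "poor"), 13)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  # 10 + 10 at 0.5
  sp2 <- splitCohort(rep(c("good", "poor"), each = 10), 0.5, seed = 2)
  expect_length(sp2$train, 10)
  expect_equal(sum(rep(c("good", "poor"), each = 10)[sp2$train] == "good"), 5)
  # determinism
  expect_identical(splitCohort(labels, 0.7, seed = 7),
                   splitCohort(labels, 0.7, seed = 7))
  expect_error(splitCohort(rep("good", 5)), "0 members")
})

test_that("confusion metrics follow their identities on every report row", {
  set.seed(4)
  for (k in 1:20) {
    n <- sample(10:40, 1)
    truth <- sample(c("good", "poor"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- runif(n)
    pred <- ifelse(scores > 0.5, "poor", "good")
    m <- computeMetrics(truth, pred, scores)
    expect_equal(m$accuracy, (m$TP + m$TN) / n)
    expect_equal(m$sensitivity, m$TP / (m$TP + m$FN))
    expect_equal(m$specificity, m$TN / (m$TN + m$FP))
    if (m$TP + m$FP > 0) expect_equal(m$ppv, m$TP / (m$TP + m$FP))
    if (m$TN + m$FN > 0) expect_equal(m$npv, m$TN / (m$TN + m$FN))
    expect_true(all(unlist(m[c("accuracy", "sensitivity", "specificity")]) >= 0 &
                    unlist(m[c("accuracy", "sensitivity", "specificity")]) <= 1))
  }
  # perfect predictions
  mall <- computeMetrics(c("poor", "good"), c("poor", "good"), c(0.9, 0.1))
  expect_equal(unlist(mall[c("accuracy", "sensitivity", "specificity",
                             "ppv", "npv", "auc")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 ppv = 1, npv = 1, auc = 1))
  expect_error(computeMetrics(c("poor", "good"), "poor"), "length")
  single <- computeMetrics(rep("poor", 3), rep("poor", 3))
  expect_true(is.na(single$specificity))  # flagged, not an error
})

test_that("rank AUC equals the brute-force all-pairs oracle, ties half", {
  set.seed(9)
  for (k in 1:25) {
    n <- sample(5:40, 1)
    truth <- c(rep("poor", max(1, n %/% 3)), rep("good", n))[1:n]
    truth <- sample(truth)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), 1)   # coarse scores force ties
    expect_equal(aucScore(scores, truth), bfAUC(scores, truth))
  }
  expect_equal(aucScore(c(0.9, 0.8, 0.1, 0.2),
                        c("poor", "poor", "good", "good")), 1)
  # independent library cross-check
  set.seed(31)
  sc <- runif(30); tr <- sample(c("good", "poor"), 30, replace = TRUE)
  expect_equal(aucScore(sc, tr),
               as.numeric(pROC::auc(pROC::roc(tr, sc, levels = c("good", "poor"),
                                              direction = "<", quiet = TRUE))))
})

test_that("every classifier separates a linearly separable toy set", {
  set.seed(6)
  n <- 40
  y <- rep(c("good", "poor"), each = n / 2)
  x <- cbind(f1 = ifelse(y == "poor", 4, -4) + rnorm(n, 0, 0.3),
             f2 = rnorm(n))
  xt <- cbind(f1 = ifelse(y == "poor", 4, -4) + rnorm(n, 0, 0.3),
              f2 = rnorm(n))
  for (cl in c("SVM", "MLP", "RF", "Ada", "LR", "NB")) {
    res <- fitPredict(classifierSpec(cl, seed = 3), x, y, xt)
    expect_equal(mean(res$pred == y), 1, label = cl)
    expect_equal(aucScore(res$score, y), 1, label = cl)
  }
})

test_that("single informative feature equal to the label gives AUC 1", {
  y <- rep(c("good", "poor"), each = 10)
  x <- cbind(f = as.numeric(y == "poor"))
  res <- fitPredict(classifierSpec("LR"), x, y, x)
  expect_equal(aucScore(res$score, y), 1)
})

test_that("null features give test AUC centered on one half", {
  set.seed(13)
  aucs <- replicate(100, {
    n <- 40
    y <- rep(c("good", "poor"), each = n / 2)
    x <- matrix(rnorm(n * 3), n, 3)
    sp <- splitCohort(y, 0.7, seed = sample.int(1e6, 1))
    res <- fitPredict(classifierSpec("LR"), x[sp$train, ], y[sp$train],
                      x[sp$test, , drop = FALSE])
    aucScore(res$score, y[sp$test])
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 1.96 * se + 0.02)
})

test_that("the experiment matrix is deterministic and reports the best by AUC", {
  set.seed(21)
  n <- 30
  y <- rep(c("good", "poor"), each = n / 2)
  v <- cbind(sig = ifelse(y == "poor", 1.5, 0) + rnorm(n),
             noise = rnorm(n))
  colnames(v) <- paste0("ischemic__Tmax__original__firstorder__F", 1:2)
  sp <- splitCohort(y, 0.7, seed = 5)
  ft <- featureTable(v, y, sp$split)
  gt <- list(Ischemic_radiomics = ft)
  r1 <- runExperimentMatrix(gt, classifiers = c("RF", "NB"), seed = 11)
  r2 <- runExperimentMatrix(gt, classifiers = c("RF", "NB"), seed = 11)
  expect_identical(r1$report, r2$report)
  expect_equal(nrow(r1$report), 2)
  expect_equal(r1$best$auc, max(r1$report$auc))
  expect_error(runExperimentMatrix(list(Bogus_group = ft)), "unknown group")
})
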