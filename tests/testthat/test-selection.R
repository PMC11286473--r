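# Standardization, t-test filter, Lasso selection, group assembly.

toyTable <- function(values, labels, split = NULL) {
  colnames(values) <- colnames(values) %||%
    paste0("region__CBF__original__firstorder__F", seq_len(ncol(values)))
  featureTable(values, labels, split)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("standardization matches hand evaluation and handles constants", {
  v <- cbind(a = c(0, 5, 10), b = c(3, 3, 3), c = c(1, 2, NA)[1:3 - 0])
  v[, "c"] <- c(1, 2, 1.5)
  ft <- featureTable(v, c("good", "poor", "good"))
  expect_warning(st <- standardizeFeatures(ft), "constant")
  z <- featureValues(st)
  expect_equal(unname(z[, "a"]), c(-0.5, 0, 0.5))
  expect_equal(unname(z[, "b"]), c(0, 0, 0))
  ft2 <- featureTable(cbind(f = c(1, 2)), c("good", "poor"))
  z2 <- featureValues(standardizeFeatures(ft2))
  expect_equal(unname(z2[, 1]), c(-0.5, 0.5))
  fit <- metadata(standardizeFeatures(ft2))$fit
  expect_equal(unname(fit$center), 1.5)
  expect_equal(unname(fit$range), 1)
})

test_that("standardization statistics never leak from the test rows", {
  set.seed(1)
  v <- matrix(rnorm(40), 10, 4)
  labels <- rep(c("good", "poor"), 5)
  split <- c(rep("train", 6), rep("test", 4))
  ft <- featureTable(v, labels, split)
  fit1 <- metadata(standardizeFeatures(ft))$fit
  # permute the test rows: the fitted statistics must not move
  v2 <- v; v2[7:10, ] <- v[c(9, 10, 7, 8), ]
  fit2 <- metadata(standardizeFeatures(featureTable(v2, labels, split)))$fit
  expect_identical(fit1$center, fit2$center)
  expect_identical(fit1$range, fit2$range)
})

test_that("t-test filter agrees with stats::t.test and is strict at alpha", {
  set.seed(3)
  v <- matrix(rnorm(30 * 6), 30, 6)
  labels <- rep(c("good", "poor"), each = 15)
  ft <- featureTable(v, labels)
  rep <- ttestFilter(ft, alpha = 0.05)
  for (j in 1:6) {
    ref <- t.test(v[labels == "poor", j], v[labels == "good", j],
                  var.equal = TRUE)
    expect_equal(rep$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(rep$p[j], ref$p.value, tolerance = 1e-12)
  }
  # a feature with the same values in both classes is dropped with p = 1
  half <- rnorm(15)
  vid <- cbind(c(half, half), rnorm(30))
  repid <- ttestFilter(toyTable(vid, labels))
  expect_equal(repid$p[1], 1)
  expect_false(repid$passedTtest[1])
  # huge effect: retained at p < 1e-6
  vbig <- cbind(c(rnorm(15, 0, 0.01), rnorm(15, 1, 0.01)))
  repbig <- ttestFilter(toyTable(vbig, labels))
  expect_lt(repbig$p[1], 1e-6)
  expect_true(repbig$passedTtest[1])
  expect_error(ttestFilter(featureTable(cbind(1:3), c("good", "good", "poor"))),
               "at least 2")
})

test_that("null features are retained at the nominal type-I rate", {
  set.seed(10)
  v <- matrix(rnorm(60 * 1000), 60, 1000)
  labels <- rep(c("good", "poor"), each = 30)
  rep <- ttestFilter(toyTable(v, labels), alpha = 0.05)
  frac <- mean(rep$passedTtest)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / 1000)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
})

test_that("Lasso recovers a planted informative feature among noise", {
  set.seed(8)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(signal = y + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 50), n, 50,
                    dimnames = list(NULL, paste0("noise", 1:50))))
  sel <- lassoSelect(x, y, seed = 4)
  expect_true("signal" %in% sel$retained)
  expect_equal(names(which.max(abs(sel$weights))), "signal")
  # pure noise under a strong penalty may select nothing -- no error
  xn <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("n", 1:5)))
  seln <- lassoSelect(xn, rep(c(0, 1), 15), seed = 2)
  expect_true(is.list(seln))
  expect_true(length(seln$retained) <= 5)
  # duplicated informative columns: at least one of the pair survives
  xd <- cbind(a = y + rnorm(n, 0, 0.05))
  xd <- cbind(xd, b = xd[, "a"], matrix(rnorm(n * 10), n, 10,
                                        dimnames = list(NULL, paste0("z", 1:10))))
  seld <- lassoSelect(xd, y, seed = 5)
  expect_true(any(c("a", "b") %in% seld$retained))
})

test_that("the selection pipeline keeps nested sets and finds planted effects", {
  set.seed(12)
  n <- 60
  labels <- rep(c("good", "poor"), each = n / 2)
  hits <- 0; total <- 0
  for (k in 1:50) {
    planted <- paste0("region__", c("CBF", "MTT", "Tmax"),
                      "__original__firstorder__Mean")
    noise <- matrix(rnorm(n * 17), n, 17,
                    dimnames = list(NULL,
                                    paste0("region__CBV__original__glcm__N", 1:17)))
    eff <- sapply(planted, function(nm) {
      x <- rnorm(n)
      x[labels == "poor"] <- x[labels == "poor"] + 1.5   # d = 1.5
      x
    })
    ft <- featureTable(cbind(eff, noise), labels)
    sel <- selectFeatures(ft, lassoSeed = k)
    # invariant chain: retained subset of t-test survivors subset of all
    surv <- sel$report$feature[sel$report$passedTtest]
    expect_true(all(sel$retained %in% surv))
    expect_true(all(surv %in% sel$report$feature))
    hits <- hits + sum(planted %in% sel$retained)
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.9)   # sensitivity for d = 1.5 at n = 60
})

test_that("group assembly has the documented column arithmetic", {
  n <- 8
  labels <- rep(c("good", "poor"), each = 4)
  mkft <- function(region, p) {
    v <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("S", 1:n),
                                paste0(region, "__Tmax__original__firstorder__F", 1:p)))
    featureTable(v, labels)
  }
  rad <- list(ischemic = mkft("ischemic", 5), infarct = mkft("infarct", 3),
              hypoxic = mkft("hypoxic", 2))
  par4 <- function() {
    m <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(paste0("S", 1:n), c("CBF", "CBV", "MTT", "Tmax")))
    m
  }
  pars <- list(ischemic = par4(), infarct = par4(), hypoxic = par4())
  expect_equal(nrow(assembleGroup(rad, pars, "Ischemic_parameters")), 4)
  expect_equal(nrow(assembleGroup(rad, pars, "Ischemic_infarct_hypoxic_parameters")), 12)
  expect_equal(nrow(assembleGroup(rad, pars, "Ischemic_infarct_radiomics")), 5 + 3)
  expect_length(groupNames(), 14)
  expect_error(assembleGroup(rad, pars, "Ischemic_radiomic"), "Ischemic_radiomics")
})
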