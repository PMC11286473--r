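# First-order and texture feature values, plus extraction invariances.

test_that("first-order features match hand arithmetic", {
  f <- firstOrderFeatures(c(1, 2, 3), c(1L, 2L, 3L))
  expect_equal(unname(f["Mean"]), 2)
  expect_equal(unname(f["Range"]), 2)
  expect_equal(unname(f["Energy"]), 14)
  # two-level histogram with equal mass: 1 bit
  f2 <- firstOrderFeatures(c(1, 1, 2, 2), c(1L, 1L, 2L, 2L))
  expect_equal(unname(f2["Entropy"]), 1)
  # constant region
  fc <- firstOrderFeatures(rep(5, 8), rep(1L, 8))
  expect_equal(unname(fc[c("Variance", "Entropy", "Skewness")]), c(0, 0, 0))
  expect_equal(unname(fc["Uniformity"]), 1)
})

test_that("GLCM features match hand evaluation on known matrices", {
  # identity/2: two levels perfectly correlated -> contrast 0
  id2 <- matrix(c(1, 0, 0, 1), 2, 2)
  f <- perfrad:::glcmFeaturesOne(id2)
  expect_equal(unname(f["Contrast"]), 0)
  # uniform 2x2 -> joint entropy 2 bits
  u <- matrix(1, 2, 2)
  fu <- perfrad:::glcmFeaturesOne(u)
  expect_equal(unname(fu["JointEntropy"]), 2)
  expect_equal(unname(fu["Correlation"]), 0)
})

test_that("GLRLM short-run emphasis on a single run of length 4", {
  L <- array(rep(1L, 4), c(4, 1, 1))
  dirs <- perfrad:::directions13()
  horiz <- which(apply(dirs, 1, function(o) all(o == c(1, 0, 0))))
  m <- glrlmMatrices(L, 1)[[horiz]]
  f <- perfrad:::glrlmFeaturesOne(m, nVoxels = 4)
  expect_equal(unname(f["ShortRunEmphasis"]), 1 / 16)
})

test_that("extraction is deterministic, translation-invariant and complete", {
  set.seed(5)
  img <- array(rnorm(10 * 10 * 6, 50, 10), c(10, 10, 6))
  mask <- array(FALSE, c(10, 10, 6)); mask[3:6, 3:7, 2:4] <- TRUE
  maps <- list(CBF = img, CBV = img / 10, MTT = img / 5, Tmax = img / 8)
  bank <- list(filterSpec("original"), filterSpec("log_sigma", sigma = 2))
  v1 <- extractFeatureVector(maps, mask, filters = bank)
  v2 <- extractFeatureVector(maps, mask, filters = bank)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
  # joint translation of image and mask leaves every feature unchanged
  shift1 <- function(a) {
    out <- array(0, dim(a)); out[2:10, , ] <- a[1:9, , ]; out
  }
  v3 <- extractFeatureVector(lapply(maps, shift1),
                             array(shift1(mask) > 0, dim(mask)),
                             filters = list(filterSpec("original")))
  v0 <- extractFeatureVector(maps, mask, filters = list(filterSpec("original")))
  expect_equal(v3, v0, tolerance = 1e-12)
  # one map, original filter, first order only -> exactly 18 names
  v4 <- extractFeatureVector(maps["CBF"], mask,
                             filters = list(filterSpec("original")),
                             classes = "firstorder")
  expect_length(v4, 18)
  expect_match(names(v4)[1], "^region__CBF__original__firstorder__")
})

test_that("fixed-bin-count features are invariant to affine intensity rescaling", {
  set.seed(11)
  img <- array(rnorm(8 * 8 * 4, 20, 5), c(8, 8, 4))
  mask <- array(FALSE, c(8, 8, 4)); mask[2:7, 2:7, 2:3] <- TRUE
  disc1 <- discretize(img, mask, "fixed_bin_count", bins = 8)
  disc2 <- discretize(3.2 * img + 40, mask, "fixed_bin_count", bins = 8)
  expect_identical(disc1$levels, disc2$levels)
  f1 <- textureFeatures(glcmMatrices(disc1), "glcm")
  f2 <- textureFeatures(glcmMatrices(disc2), "glcm")
  expect_identical(f1, f2)
})

test_that("regions below the voxel floor are flagged, not fabricated", {
  img <- array(1:27 + 0, c(3, 3, 3))
  mask <- array(FALSE, c(3, 3, 3)); mask[1:2, 1, 1] <- TRUE
  maps <- list(CBF = img, CBV = img, MTT = img, Tmax = img)
  v <- extractFeatureVector(maps, mask, filters = list(filterSpec("original")),
                            minVoxels = 10)
  expect_true(attr(v, "flagged"))
  expect_true(all(is.na(v)))
  expect_match(names(v)[1], "__CBF__original__")
})
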