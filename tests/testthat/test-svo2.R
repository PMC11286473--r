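# Upright alignment, hemisphere grid partition, SvO2 arithmetic, hypoxic mask.

symmetricBrain <- function(d = c(40, 40, 6)) {
  perfrad:::ellipsoidMask(d, (d + 1) / 2, c(0.42 * d[1], 0.42 * d[2], d[3]))
}

test_that("a mirror-symmetric phantom recovers angle 0", {
  bm <- symmetricBrain()
  al <- uprightAlign(array(0, dim(bm)), bm)
  expect_lt(abs(al$rotation$angle), 0.5)
})

test_that("a known 10-degree in-plane rotation is recovered", {
  bm <- symmetricBrain(c(48, 48, 6))
  # make the mask anisotropic so the angle is identifiable
  bm <- bm & perfrad:::ellipsoidMask(dim(bm), (dim(bm) + 1) / 2,
                                     c(21, 12, 10))
  rot <- rotateInPlane(bm, 10, fill = FALSE)
  al <- uprightAlign(array(0, dim(bm)), rot)
  expect_lt(abs(al$rotation$angle - 10), 1)
})

test_that("pure translation yields zero angle and the matching shift", {
  bm <- symmetricBrain()
  shifted <- perfrad:::arrayShift(bm, c(4L, -3L, 0L), FALSE)
  al <- uprightAlign(array(0, dim(bm)), shifted)
  expect_equal(abs(al$rotation$angle), 0)
  expect_equal(al$rotation$shift, c(-4L, 3L))
})

test_that("grid units partition each hemisphere slice bounding box", {
  d <- c(104, 104, 2)
  bm <- array(FALSE, d)
  bm[2:51, 3:102, ] <- TRUE    # left hemisphere bbox exactly 50 x 100
  bm[54:103, 3:102, ] <- TRUE
  part <- partitionHemisphereGrid(bm, midline = 52.5, grid = c(10, 10, 1))
  u <- svo2Units(part)
  left1 <- u[u$hemisphere == "left" & u$slice == 1, ]
  expect_equal(nrow(left1), 100)                       # 10 x 10 units
  expect_true(all(left1$xmax - left1$xmin + 1 == 5))   # 5 x 10 voxels
  expect_true(all(left1$ymax - left1$ymin + 1 == 10))
  # units tile the bbox with no overlap
  cover <- matrix(0, 104, 104)
  for (r in seq_len(nrow(left1)))
    cover[left1$xmin[r]:left1$xmax[r], left1$ymin[r]:left1$ymax[r]] <-
      cover[left1$xmin[r]:left1$xmax[r], left1$ymin[r]:left1$ymax[r]] + 1
  expect_equal(unique(as.vector(cover[2:51, 3:102])), 1)
  expect_equal(sum(cover), 50 * 100)
  # i counts away from the midline: unit (1, j) hugs the midline on both sides
  expect_equal(unique(left1$xmax[left1$i == 1]), 51)
  right1 <- u[u$hemisphere == "right" & u$slice == 1, ]
  expect_equal(unique(right1$xmin[right1$i == 1]), 54)
  # grid (1,1,1): one unit per hemisphere per slice spanning the bbox
  p1 <- partitionHemisphereGrid(bm, midline = 52.5, grid = c(1, 1, 1))
  u1 <- svo2Units(p1)
  expect_equal(nrow(u1[u1$slice == 1, ]), 2)
})

test_that("SvO2 follows the contralateral-ratio arithmetic exactly", {
  d <- c(20, 10, 1)
  bm <- array(TRUE, d)
  chi <- array(0, d)
  chi[5, 5, 1] <- 200; chi[16, 5, 1] <- 100
  part <- partitionHemisphereGrid(bm, grid = c(1, 1, 1))
  g <- svo2Units(computeUnitSvO2(chi, bm, part))
  left <- g[g$hemisphere == "left", ]
  right <- g[g$hemisphere == "right", ]
  expect_equal(left$deltaSvO2, 0.3)     # ROI at twice the reference
  expect_equal(left$svo2, 0.4)
  expect_equal(right$deltaSvO2, -0.15)  # ROI at half the reference
  expect_equal(right$svo2, 0.85)
  expect_true(left$isHypoxic); expect_false(right$isHypoxic)
  # equal susceptibility: delta 0, SvO2 = reference, not hypoxic (strict <)
  chi[5, 5, 1] <- 100
  ge <- svo2Units(computeUnitSvO2(chi, bm, part))
  expect_equal(ge$deltaSvO2, c(0, 0))
  expect_equal(ge$svo2, c(0.7, 0.7))
  expect_false(any(ge$isHypoxic))
})

test_that("SvO2 round-trips and is monotone in the ROI susceptibility", {
  ref <- 120
  rois <- seq(95, 295, by = 10)
  sv <- vapply(rois, function(roi) {
    d <- c(20, 10, 1); bm <- array(TRUE, d); chi <- array(0, d)
    chi[5, 5, 1] <- roi; chi[16, 5, 1] <- ref
    part <- partitionHemisphereGrid(bm, grid = c(1, 1, 1))
    u <- svo2Units(computeUnitSvO2(chi, bm, part))
    l <- u[u$hemisphere == "left", ]
    # round trip: delta reconstructed from the returned SvO2
    expect_equal(0.7 - l$svo2, l$deltaSvO2, tolerance = 1e-12)
    l$svo2
  }, numeric(1))
  expect_true(all(diff(sv) < 0))
})

test_that("units without veins or with zero reference are flagged, not infinite", {
  d <- c(20, 10, 1); bm <- array(TRUE, d)
  chi <- array(0, d); chi[5, 5, 1] <- 150  # vein on the left only
  part <- partitionHemisphereGrid(bm, grid = c(1, 1, 1))
  u <- svo2Units(computeUnitSvO2(chi, bm, part))
  expect_true(all(is.na(u$svo2)))
  expect_true(all(is.na(u$isHypoxic)))
  hyp <- segmentHypoxic(computeUnitSvO2(chi, bm, part), bm, "left")
  expect_equal(sum(maskArray(hyp)), 0)     # empty mask is a valid outcome
})

test_that("hypoxic mask covers exactly the flagged units' in-brain voxels", {
  d <- c(20, 10, 2); bm <- array(TRUE, d)
  chi <- array(0, d)
  chi[3:7, 4:6, 1] <- 180    # left unit vein cluster, elevated
  chi[14:18, 4:6, 1] <- 120  # mirrored reference
  part <- partitionHemisphereGrid(bm, grid = c(1, 1, 1))
  g <- computeUnitSvO2(chi, bm, part)
  hyp <- segmentHypoxic(g, bm, "left")
  u <- svo2Units(g)
  l <- u[u$hemisphere == "left" & u$slice == 1, ]
  expect_true(l$isHypoxic)
  expect_equal(sum(maskArray(hyp)),
               (l$xmax - l$xmin + 1) * (l$ymax - l$ymin + 1) *
                 (l$zmax - l$zmin + 1))
})
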