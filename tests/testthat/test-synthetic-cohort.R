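# Phantom generator: determinism, statistical fidelity, internal consistency.

smallConfig <- function(...) {
  cohortConfig(volumeShape = c(32, 32, 8), lesionRadiusRange = c(4, 6),
               hypoxicUnits = 4, ...)
}

test_that("identical seeds give bit-identical phantoms, different seeds differ", {
  cfg <- smallConfig(nGood = 1, nPoor = 1, seed = 3)
  s1 <- generateSubject(cfg, "poor", 3)
  s2 <- generateSubject(cfg, "poor", 3)
  expect_identical(perfusionMaps(s1), perfusionMaps(s2))
  expect_identical(s1@chi, s2@chi)
  expect_identical(s1@truthMasks, s2@truthMasks)
  c1 <- generateCohort(smallConfig(nGood = 1, nPoor = 1, seed = 3))
  c2 <- generateCohort(smallConfig(nGood = 1, nPoor = 1, seed = 4))
  expect_false(identical(perfusionMaps(c1$subjects[[1]]),
                         perfusionMaps(c2$subjects[[1]])))
  expect_error(generateSubject(cfg, "terrible", 3), "label")
})

test_that("cohort sizes and labels follow the configuration", {
  co <- generateCohort(smallConfig(nGood = 3, nPoor = 2, seed = 9))
  expect_length(co$subjects, 5)
  expect_equal(table(co$labels)[["good"]], 3)
  one <- generateCohort(smallConfig(nGood = 1, nPoor = 0, seed = 1))
  expect_length(one$subjects, 1)
  expect_equal(one$labels, "good")
  expect_error(generateCohort(smallConfig(nGood = 0, nPoor = 0)), "zero subjects")
})

test_that("phantom internal consistency: masks nested, DWI physical", {
  s <- generateSubject(smallConfig(seed = 5), "poor", 5)
  bm <- brainMask(s)
  expect_true(all(truthMask(s, "ischemic") <= bm))
  expect_true(all(truthMask(s, "infarct") <= truthMask(s, "ischemic")))
  expect_true(all(truthMask(s, "hypoxic") <= bm))
  expect_true(all(s@dwiB1000[bm] <= s@dwiB0[bm]))
  expect_true(all(vapply(perfusionMaps(s), function(m) all(m >= 0), logical(1))))
  # unilateral: the lesion sits entirely on one side of the midline
  idx <- which(truthMask(s, "ischemic"), arr.ind = TRUE)
  mid <- (dim(bm)[1] + 1) / 2
  expect_true(all(idx[, 1] < mid) || all(idx[, 1] > mid))
})

test_that("generator and segmenter agree voxelwise in the noise-free case", {
  # infarct: ADC inversion of the generated DWI pair recovers the truth mask
  cfg <- smallConfig(nGood = 0, nPoor = 3, seed = 21)
  co <- generateCohort(cfg)
  for (s in co$subjects) {
    adc <- computeADC(s@dwiB0, s@dwiB1000)
    got <- maskArray(segmentInfarct(adc, brainMask(s)))
    expect_identical(got, truthMask(s, "infarct") & TRUE)
  }
  # ischemic: exact when the configured targets clear the 6 s threshold
  ce <- defaultRegionTargets(c("ischemic", "infarct"))
  ce$good_mean[ce$map == "Tmax"] <- c(12, 12.5)
  ce$good_sd[ce$map == "Tmax"] <- c(0.5, 0.5)
  cfg0 <- smallConfig(nGood = 3, nPoor = 0, classEffects = ce,
                      noiseSd = c(CBF = 0, CBV = 0, MTT = 0, Tmax = 0),
                      seed = 31)
  for (s in generateCohort(cfg0)$subjects) {
    got <- maskArray(segmentIschemic(perfusionMaps(s)$Tmax, brainMask(s)))
    expect_identical(got, truthMask(s, "ischemic") & TRUE)
  }
})

test_that("designated hypoxic units are recovered exactly by the SvO2 pipeline", {
  cfg <- smallConfig(nGood = 1, nPoor = 2, seed = 41)
  for (s in generateCohort(cfg)$subjects) {
    m <- segmentSubject(s)
    expect_identical(maskArray(m$hypoxic), truthMask(s, "hypoxic") & TRUE)
  }
})

test_that("regional means converge to the configured targets", {
  # Monte-Carlo fidelity at 200 subjects/class on the ischemic region
  cfg <- smallConfig(nGood = 200, nPoor = 200, seed = 100)
  co <- generateCohort(cfg)
  sm <- summarizeCohort(co, regions = c("ischemic", "infarct"))
  tg <- defaultRegionTargets(c("ischemic", "infarct"))
  for (r in seq_len(nrow(tg))) {
    for (cl in c("good", "poor")) {
      mu <- tg[[paste0(cl, "_mean")]][r]
      sdv <- tg[[paste0(cl, "_sd")]][r]
      got <- sm$mean[sm$region == tg$region[r] & sm$map == tg$map[r] &
                       sm$class == cl]
      n <- sm$n[sm$region == tg$region[r] & sm$map == tg$map[r] &
                  sm$class == cl]
      expect_lt(abs(got - mu), 3 * sdv / sqrt(n),
                label = paste(tg$region[r], tg$map[r], cl, "=", round(got, 2),
                              "target", mu))
    }
  }
  # headline check: ischemic Tmax and CBF class means within 2 SE
  for (chk in list(c("Tmax", "good", 6.24, 4.49), c("Tmax", "poor", 12.18, 6.28),
                   c("CBF", "good", 28.05, 11.90), c("CBF", "poor", 20.34, 9.47))) {
    got <- sm$mean[sm$region == "ischemic" & sm$map == chk[1] & sm$class == chk[2]]
    expect_lt(abs(got - as.numeric(chk[3])), 2 * as.numeric(chk[4]) / sqrt(200))
  }
})

test_that("equal class effects produce no detectable class difference", {
  ce <- defaultRegionTargets("ischemic")
  ce$poor_mean <- ce$good_mean; ce$poor_sd <- ce$good_sd
  co <- generateCohort(smallConfig(nGood = 30, nPoor = 30, classEffects = ce,
                                   seed = 55))
  sm <- lapply(co$subjects, function(s)
    regionMeanParameters(perfusionMaps(s), truthMask(s, "ischemic")))
  tmax <- vapply(sm, `[[`, numeric(1), "Tmax")
  p <- t.test(tmax[co$labels == "good"], tmax[co$labels == "poor"],
              var.equal = TRUE)$p.value
  expect_gt(p, 0.001)
})

test_that("summarizeCohort does hand arithmetic and flags empty regions", {
  d <- c(6, 6, 3)
  bm <- array(TRUE, d)
  mk <- function(val, hyp = TRUE) {
    reg <- array(FALSE, d); reg[2:3, 2:3, 2] <- TRUE
    new("SubjectPhantom",
        maps = list(CBF = array(val, d), CBV = array(val, d),
                    MTT = array(val, d), Tmax = array(val, d)),
        dwiB0 = array(1, d), dwiB1000 = array(1, d), chi = array(0, d),
        brainMask = bm,
        truthMasks = list(ischemic = reg, infarct = reg,
                          hypoxic = if (hyp) reg else array(FALSE, d)),
        label = "good", subjectId = paste0("M", val),
        spacing = c(1, 1, 1), seed = 1L)
  }
  co <- list(subjects = list(mk(1), mk(2), mk(3, hyp = FALSE)), labels = rep("good", 3))
  sm <- summarizeCohort(co, regions = c("ischemic", "hypoxic"))
  isch <- sm[sm$region == "ischemic" & sm$map == "CBF", ]
  expect_equal(isch$mean, 2)
  expect_equal(isch$sd, 1)   # sample SD of {1, 2, 3}
  hyp <- sm[sm$region == "hypoxic" & sm$map == "CBF", ]
  expect_equal(hyp$n, 2)
  expect_equal(hyp$nMissing, 1)   # the empty region is flagged, not zeroed
})

test_that("oversized lesions are rejected by the config validity check", {
  expect_error(cohortConfig(volumeShape = c(20, 20, 8),
                            lesionRadiusRange = c(8, 9)),
               "hemisphere")
})
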