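vertebraMaskSet <- function(zL2, zL3, shape = c(8, 8, 50)) {
  lab <- array(0L, shape)
  lab[3:6, 3:6, zL2] <- 1L
  lab[3:6, 3:6, zL3] <- 2L
  maskSet(lab, c(vertebra_L2 = 1L, vertebra_L3 = 2L))
}

test_that("the L2/L3 slice is the midpoint of the vertebral centroids", {
  ms <- vertebraMaskSet(zL2 = 40, zL3 = 30)
  expect_identical(selectL2L3Slice(ms), 35L)
  # missing L3 -> not evaluable
  lab <- array(0L, c(8, 8, 50)); lab[3:6, 3:6, 40] <- 1L
  expect_true(is.na(selectL2L3Slice(maskSet(lab, c(vertebra_L2 = 1L)))))
})

test_that("the selected slice lies strictly between generated vertebrae", {
  # full-size grid: the intervertebral gap spans at least one slice
  ph <- generatePhantom(phantomSpec(seed = 3))
  z <- selectL2L3Slice(ph$masks)
  l2 <- which(apply(maskRole(ph$masks, "vertebra_L2"), 3, any))
  l3 <- which(apply(maskRole(ph$masks, "vertebra_L3"), 3, any))
  expect_gt(z, max(l3))
  expect_lt(z, min(l2))
})

test_that("fat areas count in-window pixels inside the compartment", {
  shape <- c(20, 20, 3)
  hu <- array(40, shape)  # muscle-like everywhere
  lab <- array(0L, shape)
  lab[1:10, 1:20, 2] <- 1L  # visceral compartment: 200 pixels
  hu[1:10, 1:10, 2] <- -100  # 100 fat pixels inside it
  ms <- maskSet(lab, c(visceral_compartment = 1L))
  vol <- ctVolume(hu)
  fa <- fatAreas(vol, ms, z = 2L)
  expect_equal(fa$VFA, 1.00)
  expect_true(is.na(fa$SFA))  # compartment absent -> not evaluated

  # compartment entirely muscle: area 0
  hu2 <- array(40, shape)
  fa2 <- fatAreas(ctVolume(hu2), ms, z = 2L)
  expect_equal(fa2$VFA, 0)

  # window bounds are inclusive on both ends
  hu3 <- array(0, shape)
  hu3[1, 1, 2] <- -190; hu3[1, 2, 2] <- -30
  hu3[1, 3, 2] <- -190.5; hu3[1, 4, 2] <- -29.5
  fa3 <- fatAreas(ctVolume(hu3), ms, z = 2L)
  expect_equal(fa3$VFA, 2 / 100)
})

test_that("measured disk area converges to the analytic area with pixel size", {
  errs <- vapply(c(2, 1, 0.5), function(px) {
    n <- round(96 / px)
    spec <- phantomSpec(shape = c(n, n, 24), spacing = c(px, px, 2.5),
                        seed = 1,
                        geometry = list(visceral_fat = list(
                          center = c(60.3, 38.7), radius = 10)))
    ph <- generatePhantom(spec)
    fa <- fatAreas(ph$volume, ph$masks, selectL2L3Slice(ph$masks))
    abs(fa$VFA - pi) / pi  # analytic disk area = pi cm^2
  }, numeric(1))
  expect_lt(errs[2], 0.02)
  expect_true(all(diff(errs) < 0))
})

test_that("compartment areas are bounded by the slice's total fat area", {
  ph <- smallPhantom(seed = 5)
  z <- selectL2L3Slice(ph$masks)
  fa <- fatAreas(ph$volume, ph$masks, z)
  hu <- voxels(ph$volume)[, , z]
  total <- sum(hu >= -190 & hu <= -30) * voxelArea(ph$volume) / 100
  expect_lte(fa$VFA + fa$SFA + fa$IMAT, total + 1e-9)
})

test_that("the liver ROI sits in the right lobe and averages correctly", {
  shape <- c(40, 40, 20)
  hu <- array(30, shape)
  lab <- array(0L, shape)
  liver <- sphereMask(24, c(1, 1, 2), shape)
  lab[liver] <- 1L
  hu[liver] <- 54
  ms <- maskSet(lab, c(liver = 1L), spacing = c(1, 1, 2))
  vol <- ctVolume(hu, spacing = c(1, 1, 2))
  la <- liverAttenuation(vol, ms, radius = 5)
  expect_equal(la$mean_hu, 54)

  # a gas pocket in the patient-left half leaves the right-lobe ROI alone
  hu2 <- hu
  hu2[28:31, 18:22, 9:11] <- -500  # left half (x > centroid)
  la2 <- liverAttenuation(ctVolume(hu2, spacing = c(1, 1, 2)), ms,
                          radius = 5)
  expect_equal(la2$mean_hu, 54)

  # empty liver -> not evaluated
  ms0 <- maskSet(array(0L, shape), spacing = c(1, 1, 2))
  expect_true(is.na(liverAttenuation(vol, ms0, radius = 5)$mean_hu))

  # too thin for the ball -> not evaluated
  lab3 <- array(0L, shape); lab3[10:30, 10:30, 10] <- 1L
  ms3 <- maskSet(lab3, c(liver = 1L), spacing = c(1, 1, 2))
  expect_true(is.na(liverAttenuation(vol, ms3, radius = 10)$mean_hu))
})

test_that("liver fat conversion and steatosis grading match the line", {
  expect_equal(liverFatGrade(54)$fat_percent, 7)
  expect_identical(liverFatGrade(54)$grade, "mild")
  # zero crossing of -0.58 * HU + 38.2 near 65.9 HU
  expect_equal(liverFatGrade(65.9)$fat_percent, 0)
  expect_identical(liverFatGrade(65.9)$grade, "none")
  expect_equal(liverFatGrade(10)$fat_percent, 32)
  expect_identical(liverFatGrade(10)$grade, "severe")
  # clipping below zero
  expect_equal(liverFatGrade(120)$fat_percent, 0)
  # contrast-enhanced scans cannot be converted
  cfg <- defaultConfig(list(liver = list(contrast_enhanced = TRUE)))
  expect_true(is.na(liverFatGrade(54, cfg)$fat_percent))
})

test_that("decreasing attenuation never lowers the steatosis grade", {
  ord <- c(none = 0, mild = 1, moderate = 2, severe = 3)
  g <- ord[vapply(seq(80, -40, by = -0.5),
                  function(h) liverFatGrade(h)$grade, character(1))]
  expect_true(all(diff(g) >= 0))
})
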