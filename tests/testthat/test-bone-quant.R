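cylinderMaskSet <- function(radius = 15, spacing = c(1, 1, 1),
                            shape = c(40, 40, 30), zrange = 5:25,
                            role = "vertebra_L1") {
  lab <- array(0L, shape)
  cen <- shape[1:2] * spacing[1:2] / 2
  x <- (seq_len(shape[1]) - 0.5) * spacing[1]
  y <- (seq_len(shape[2]) - 0.5) * spacing[2]
  d2 <- outer((x - cen[1])^2, (y - cen[2])^2, `+`)
  for (z in zrange) lab[, , z][d2 <= radius^2] <- 1L
  maskSet(lab, stats::setNames(1L, role), spacing = spacing)
}

test_that("trabecular extraction erodes by the physical margin", {
  ms <- cylinderMaskSet(radius = 15)
  core <- extractTrabecular(ms, "vertebra_L1", margin = 3)
  mask <- maskRole(ms, "vertebra_L1")
  expect_true(all(!core | mask))  # core subset of mask
  # radial extent of the core is about 12 mm
  w <- which(core[, , 15], arr.ind = TRUE)
  rmax <- max(sqrt((w[, 1] - 0.5 - 20)^2 + (w[, 2] - 0.5 - 20)^2))
  expect_lt(abs(rmax - 12), 1.5)
  # margin 0 is the identity
  expect_identical(extractTrabecular(ms, "vertebra_L1", margin = 0), mask)
  # a body thinner than twice the margin erodes away
  thin <- cylinderMaskSet(radius = 15, zrange = 10:11)
  expect_null(extractTrabecular(thin, "vertebra_L1", margin = 3))
  # absent level warns and skips
  expect_warning(out <- extractTrabecular(ms, "vertebra_T4"), "absent")
  expect_null(out)
})

test_that("a larger margin erodes to a subset of a smaller one", {
  ms <- cylinderMaskSet(radius = 15, spacing = c(1, 1, 2), zrange = 5:12)
  c2 <- extractTrabecular(ms, "vertebra_L1", margin = 2)
  c4 <- extractTrabecular(ms, "vertebra_L1", margin = 4)
  expect_true(all(!c4 | c2))
  expect_lt(sum(c4), sum(c2))
})

rodFixture <- function(meanHU, spacing = c(1, 1, 1)) {
  n <- length(meanHU)
  shape <- c(10 * n, 10, 4)
  hu <- array(0, shape); lab <- array(0L, shape)
  sem <- stats::setNames(seq_len(n), paste0("calibration_rod_", seq_len(n)))
  for (k in seq_len(n)) {
    idx <- (10 * (k - 1) + 2):(10 * (k - 1) + 8)
    hu[idx, 3:8, ] <- meanHU[k]
    lab[idx, 3:8, ] <- k
  }
  list(volume = ctVolume(hu, spacing = spacing),
       masks = maskSet(lab, sem, spacing = spacing))
}

test_that("collinear rods are recovered exactly", {
  fx <- rodFixture(c(0, 200))
  cal <- calibrateBMD(fx$volume, fx$masks,
                      c(calibration_rod_1 = 0, calibration_rod_2 = 200))
  expect_equal(cal@slope, 1, tolerance = 1e-12)
  expect_equal(cal@intercept, 0, tolerance = 1e-9)

  fx3 <- rodFixture(c(10, 110, 210))
  cal3 <- calibrateBMD(fx3$volume, fx3$masks,
                       c(calibration_rod_1 = 0, calibration_rod_2 = 100,
                         calibration_rod_3 = 200))
  expect_equal(cal3@slope, 1, tolerance = 1e-12)
  expect_equal(cal3@intercept, -10, tolerance = 1e-9)
  expect_equal(cal3@residual, 0, tolerance = 1e-9)
  # round trip: density(HU(d)) = d for each rod
  expect_equal(cal3@slope * cal3@rods$hu + cal3@intercept,
               cal3@rods$density, tolerance = 1e-9)
})

test_that("fewer than two distinct rods is an error", {
  fx <- rodFixture(100)
  expect_error(calibrateBMD(fx$volume, fx$masks,
                            c(calibration_rod_1 = 100)),
               "asynchronous calibration")
})

test_that("noisy rods still recover the generating slope", {
  for (seed in 1:10) {
    ph <- generatePhantom(phantomSpec(shape = c(48, 48, 24), seed = seed,
                                      noise_sd = 10))
    man <- manifestValues(ph$manifest)
    cal <- calibrateBMD(ph$volume, ph$masks, stats::setNames(
      man$rods$densities, paste0("calibration_rod_", 1:3)))
    expect_lt(abs(cal@slope - man$rods$slope) / man$rods$slope, 0.05)
  }
})

test_that("T-scores and WHO classification follow the reference", {
  cal <- calibrationFromCoefficients(1, 0)
  r1 <- bmdTscore(85, cal, reference = c(178.5, 27.5), level = "L1")
  expect_equal(r1$t_score, -3.4)
  expect_identical(r1$classification, "osteoporosis")
  r2 <- bmdTscore(52, cal, reference = c(178.5, 27.5))
  expect_equal(r2$t_score, -4.6)
  expect_identical(r2$classification, "osteoporosis")
  # centered value is normal with T = 0
  r3 <- bmdTscore(178.5, cal, reference = c(178.5, 27.5))
  expect_equal(r3$t_score, 0)
  expect_identical(r3$classification, "normal")
  # band edges: -2.5 is osteoporosis, -1.0 is normal
  expect_identical(bmdTscore(178.5 - 2.5 * 27.5, cal,
                             c(178.5, 27.5))$classification, "osteoporosis")
  expect_identical(bmdTscore(178.5 - 27.5, cal,
                             c(178.5, 27.5))$classification, "normal")
  expect_identical(bmdTscore(178.5 - 1.6 * 27.5, cal,
                             c(178.5, 27.5))$classification, "osteopenia")
})

test_that("phantom vertebrae recover the generating calibration end to end", {
  ph <- smallPhantom(seed = 8)
  man <- manifestValues(ph$manifest)
  cal <- calibrateBMD(ph$volume, ph$masks, stats::setNames(
    man$rods$densities, paste0("calibration_rod_", 1:3)))
  ba <- boneAnalysis(ph$volume, ph$masks, cal)
  expect_identical(ba$reported$level, "L1")
  expected <- man$rods$slope * man$trabecular_hu + man$rods$intercept
  expect_equal(ba$reported$bmd_mg_cm3, expected, tolerance = 1e-6)
})
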