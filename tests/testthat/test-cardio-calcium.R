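test_that("a constructed plaque is detected with exact area and peak", {
  px <- lapply(10:19, function(i) c(i, 10, 3))  # 10 contiguous 1 mm^2 pixels
  fx <- coronaryFixture(px, plaqueHU = 250)
  les <- detectLesions(fx$volume, fx$masks)
  expect_length(les, 1)
  expect_identical(les[[1]]$compartment, "coronary")
  expect_equal(sum(les[[1]]$components$area_mm2), 10)
  expect_equal(max(les[[1]]$components$peak_hu), 250)
  # area 10 mm^2, peak 250 -> weight 2 -> score 20
  sc <- agatstonScore(les, fx$masks)
  expect_equal(sc$CAC$score, 20)
  expect_equal(sc$CAC$volume_mm3, 10)
})

test_that("components below the minimum lesion area are discarded", {
  fx <- coronaryFixture(list(c(10, 10, 2)), plaqueHU = 300,
                        spacing = c(0.5, 0.5, 1))
  # one 0.25 mm^2 pixel with the default 1 mm^2 minimum
  expect_length(detectLesions(fx$volume, fx$masks), 0)
  expect_length(detectLesions(fx$volume, fx$masks, minArea = 0.2), 1)
})

test_that("bone-excluded voxels never form lesions", {
  px <- lapply(10:14, function(i) c(i, 12, 2))
  excl <- cbind(10:14, 12, 2)
  fx <- coronaryFixture(px, plaqueHU = 500, boneExclusion = excl)
  expect_length(detectLesions(fx$volume, fx$masks), 0)
})

test_that("detection requires at least one vascular compartment", {
  vol <- ctVolume(array(500, c(8, 8, 4)))
  ms <- maskSet(array(1L, c(8, 8, 4)), c(liver = 1L))
  expect_error(detectLesions(vol, ms), "vascular")
})

test_that("density weights follow the peak-HU bands", {
  for (case in list(c(130, 1), c(199, 1), c(200, 2), c(299, 2),
                    c(300, 3), c(399, 3), c(400, 4), c(900, 4))) {
    px <- lapply(8:11, function(i) c(i, 8, 1))
    fx <- coronaryFixture(px, plaqueHU = case[1])
    sc <- agatstonScore(detectLesions(fx$volume, fx$masks), fx$masks)
    expect_equal(sc$CAC$score, 4 * case[2],
                 info = sprintf("peak %g", case[1]))
  }
})

test_that("adding a lesion never decreases a compartment score", {
  base <- lapply(8:12, function(i) c(i, 8, 1))
  fx1 <- coronaryFixture(base, plaqueHU = 250)
  s1 <- agatstonScore(detectLesions(fx1$volume, fx1$masks), fx1$masks)
  extra <- c(base, lapply(15:18, function(i) c(i, 15, 4)))
  fx2 <- coronaryFixture(extra, plaqueHU = 250)
  s2 <- agatstonScore(detectLesions(fx2$volume, fx2$masks), fx2$masks)
  expect_gte(s2$CAC$score, s1$CAC$score)
  expect_gte(s2$CAC$volume_mm3, s1$CAC$volume_mm3)
})

test_that("raising the threshold never increases lesion count or score", {
  for (seed in 1:8) {
    ph <- generatePhantom(randomCalciumSpec(seed))
    lo <- agatstonScore(detectLesions(ph$volume, ph$masks, threshold = 130),
                        ph$masks)
    hi <- agatstonScore(detectLesions(ph$volume, ph$masks, threshold = 200),
                        ph$masks)
    # a higher threshold can split one 3-D lesion into several (counts
    # may rise) but score and calcified volume can only shrink
    for (nm in c("CAC", "TAC", "AAC")) {
      expect_lte(hi[[nm]]$score, lo[[nm]]$score)
      expect_lte(hi[[nm]]$volume_mm3, lo[[nm]]$volume_mm3)
    }
  }
})

test_that("module scores equal the independent voxel-loop oracle", {
  for (seed in 1:10) {
    ph <- generatePhantom(randomCalciumSpec(seed))
    mod <- agatstonScore(detectLesions(ph$volume, ph$masks), ph$masks)
    orc <- agatstonOracle(ph$volume, ph$masks)
    for (nm in c("CAC", "TAC", "AAC")) {
      expect_equal(mod[[nm]]$score, orc[[nm]]$score)
      expect_equal(mod[[nm]]$volume_mm3, orc[[nm]]$volume_mm3)
    }
  }
})

test_that("CAC categories and statin recommendations follow the bands", {
  mk <- function(s) categorizeCalcium(list(
    CAC = list(score = s), TAC = list(score = NA_real_),
    AAC = list(score = NA_real_)))
  expect_identical(mk(399)$CAC$categoryLabel, "Moderate CAC")
  expect_match(mk(399)$CAC$recommendation, "[Hh]igh-intensity statin")
  expect_identical(mk(237)$CAC$categoryLabel, "Moderate CAC")
  expect_match(mk(237)$CAC$recommendation, "statin")
  expect_no_match(mk(237)$CAC$recommendation, "[Hh]igh-intensity")
  z <- mk(0)$CAC
  expect_identical(z$category, "none")
  expect_identical(z$recommendation, "")
  # escalation happens exactly at 300
  expect_no_match(mk(299)$CAC$recommendation, "[Hh]igh-intensity")
  expect_match(mk(300)$CAC$recommendation, "[Hh]igh-intensity")
  # aortic scores flag "high" above the configured threshold
  hi <- categorizeCalcium(list(CAC = list(score = 0),
                               TAC = list(score = 12284),
                               AAC = list(score = NA_real_)))
  expect_true(hi$TAC$high)
  expect_true(is.na(hi$AAC$high))
})
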