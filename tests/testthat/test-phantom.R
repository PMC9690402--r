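test_that("generation is deterministic for a fixed seed", {
  a <- smallPhantom(seed = 11, noise_sd = 10)
  b <- smallPhantom(seed = 11, noise_sd = 10)
  expect_identical(voxels(a$volume), voxels(b$volume))
  expect_identical(labelmap(a$masks), labelmap(b$masks))
  expect_identical(manifestValues(a$manifest), manifestValues(b$manifest))
  c <- smallPhantom(seed = 12, noise_sd = 10)
  expect_false(identical(voxels(a$volume), voxels(c$volume)))
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(smallPhantom(seed = 5, noise_sd = 3))
  expect_identical(.Random.seed, before)
})

test_that("a known fat disk yields the analytic visceral area", {
  # 10 mm diameter disk at 1 x 1 mm pixels: pi * 25 mm^2 = 0.785 cm^2,
  # recovered within one pixel ring (perimeter * pixel size)
  spec <- phantomSpec(shape = c(96, 96, 24), spacing = c(1, 1, 2.5),
                      seed = 1,
                      geometry = list(visceral_fat = list(
                        center = c(60, 38), radius = 5)))
  man <- manifestValues(generatePhantom(spec)$manifest)
  analytic <- pi * 25 / 100
  ring <- 2 * pi * 5 * 1 / 100
  expect_lt(abs(man$fat_areas_cm2$VFA - analytic), ring)
})

test_that("a phantom without plaques scores zero in every compartment", {
  ph <- generatePhantom(phantomSpec(shape = c(48, 48, 32), seed = 2,
                                    plaques = list()))
  ag <- manifestValues(ph$manifest)$agatston
  expect_equal(ag$CAC$score, 0)
  expect_equal(ag$TAC$score, 0)
  expect_equal(ag$AAC$score, 0)
})

test_that("every analyzer reproduces its manifest entry on a noise-free phantom", {
  ph <- generatePhantom(phantomSpec(seed = 4))
  man <- manifestValues(ph$manifest)
  vol <- ph$volume; ms <- ph$masks

  # fat planimetry: exact agreement with the counting oracle
  z <- selectL2L3Slice(ms)
  expect_identical(z, man$l2l3_slice)
  fa <- fatAreas(vol, ms, z)
  expect_equal(fa$VFA, man$fat_areas_cm2$VFA)
  expect_equal(fa$SFA, man$fat_areas_cm2$SFA)
  expect_equal(fa$IMAT, man$fat_areas_cm2$IMAT)

  # liver mean HU: exact on a uniform liver
  expect_equal(liverAttenuation(vol, ms)$mean_hu, man$liver_mean_hu)

  # calcium scores: exact match with the independent oracle values
  sc <- agatstonScore(detectLesions(vol, ms), ms)
  for (nm in c("CAC", "TAC", "AAC"))
    expect_equal(sc[[nm]]$score, man$agatston[[nm]]$score)

  # lung densitometry: exact
  dm <- densityMetrics(vol, ms)
  expect_equal(dm$lung_volume_cm3, man$lung$lung_volume_cm3)
  expect_equal(dm$mld_hu, man$lung$mld_hu)
  expect_equal(dm$emphysema_index, man$lung$emphysema_index)

  # nodule voxel volume: exact; bounding-box diameters within one voxel
  nm1 <- measureNodule(vol, maskRole(ms, "nodule_1"))
  expect_equal(nm1$voxel_volume_mm3, man$nodules[[1]]$voxel_volume_mm3)
  expect_true(all(abs(nm1$diameters_mm - man$nodules[[1]]$diameters_mm) <=
                    voxelSpacing(vol)))

  # rods: measured means are exactly the generating line's values
  cal <- calibrateBMD(vol, ms, stats::setNames(
    man$rods$densities, paste0("calibration_rod_", 1:3)))
  expect_equal(cal@slope, man$rods$slope, tolerance = 1e-12)
  expect_equal(cal@intercept, man$rods$intercept, tolerance = 1e-9)

  # vertebral trabecular core: uniform at the spec HU
  core <- extractTrabecular(ms, "vertebra_L1", margin = 3)
  expect_equal(maskedStatistics(vol, core)$mean_hu, man$trabecular_hu)
})

test_that("expiratory pairs encode exact PRM class fractions", {
  spec <- phantomSpec(shape = c(64, 64, 40), seed = 6,
                      emphysema_fraction = 0.3, fsad_fraction = 0.1)
  pair <- generateExpiratoryPair(spec)
  man <- manifestValues(pair$manifest)
  pr <- prm(pair$insp, pair$exp, pair$masks)
  expect_equal(pr$prm_emphysema, man$prm$emphysema)
  expect_equal(pr$prm_fsad, man$prm$fsad)
  expect_equal(pr$prm_normal, man$prm$normal)
  expect_equal(pr$prm_emphysema + pr$prm_fsad + pr$prm_normal +
                 pr$prm_uncharacterized, 100)
  # fractions land on the requested values up to count rounding
  expect_equal(man$prm$emphysema, 30, tolerance = 0.05)
  expect_equal(man$prm$fsad, 10, tolerance = 0.05)
})

test_that("fixtures round-trip through disk with exactly the declared files", {
  dir <- withr::local_tempdir()
  spec <- phantomSpec(shape = c(48, 48, 32), seed = 9)
  files <- writePhantomFixture(dir, spec)
  expect_setequal(basename(files),
                  c("ct.nii.gz", "masks.nii.gz", "semantics.yaml",
                    "manifest.json"))
  expect_setequal(list.files(dir), basename(files))
  vol <- loadVolume(file.path(dir, "ct.nii.gz"))
  ms <- loadMaskSet(file.path(dir, "masks.nii.gz"),
                    semantics = file.path(dir, "semantics.yaml"),
                    volume = vol)
  man <- manifestValues(readManifest(file.path(dir, "manifest.json")))
  ph <- generatePhantom(spec)
  expect_equal(voxels(vol), voxels(ph$volume), tolerance = 1e-6)
  expect_identical(labelmap(ms), labelmap(ph$masks))
  expect_equal(man$agatston$CAC$score,
               manifestValues(ph$manifest)$agatston$CAC$score)
  # writing the same seed twice gives identical bytes
  dir2 <- withr::local_tempdir()
  writePhantomFixture(dir2, spec)
  expect_identical(unname(tools::md5sum(file.path(dir, "ct.nii.gz"))),
                   unname(tools::md5sum(file.path(dir2, "ct.nii.gz"))))
})

test_that("emphysema index is noise-robust at sigma 10 HU", {
  for (seed in 1:5) {
    ph <- generatePhantom(phantomSpec(shape = c(64, 64, 40), seed = seed,
                                      emphysema_fraction = 0.3,
                                      noise_sd = 10))
    man <- manifestValues(ph$manifest)
    dm <- densityMetrics(ph$volume, ph$masks)
    expect_lt(abs(dm$emphysema_index - man$lung$emphysema_index), 2)
  }
})
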