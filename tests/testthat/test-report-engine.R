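test_that("banding is total, deterministic, and boundary-greener", {
  r <- meanSdRange("VFA", 150, 75)
  expect_identical(band(338, r), "red")   # beyond two SDs
  expect_identical(band(150, r), "green")
  expect_identical(band(225, r), "green")   # exact green boundary
  expect_identical(band(225.0001, r), "yellow")
  expect_identical(band(300, r), "yellow")  # exact yellow boundary
  expect_identical(band(300.0001, r), "red")
  expect_identical(band(NA, r), "not_evaluated")

  # fine sweep: statuses partition the line with two change points per side
  grid <- seq(-200, 500, by = 0.5)
  st <- vapply(grid, band, character(1), range = r)
  expect_true(all(st %in% c("green", "yellow", "red")))
  changes <- sum(st[-1] != st[-length(st)])
  expect_identical(changes, 4L)
})

test_that("one-sided ranges band correctly", {
  r <- referenceRange("EI", green = c(-Inf, 5), yellow = c(-Inf, 10),
                      direction = "high_bad")
  expect_identical(band(0, r), "green")
  expect_identical(band(5, r), "green")
  expect_identical(band(7, r), "yellow")
  expect_identical(band(33, r), "red")
})

test_that("malformed ranges are rejected", {
  expect_error(referenceRange("x", green = c(5, 1)), "reversed")
  expect_error(referenceRange("x", green = c(0, 10), yellow = c(2, 8)),
               "contain")
})

test_that("section conclusions are keyed on category labels", {
  cfg <- defaultConfig()
  concl <- concludeSection("cardio", list(), list(
    cac_label = "Moderate CAC",
    statin = cfg$templates$statin_high,
    high_vessels = c("TAC", "AAC")), cfg)
  expect_match(concl, "Moderate CAC")
  expect_match(concl, "[Hh]igh-intensity statin")
  expect_match(concl, "TAC and AAC")

  greens <- list(biomarkerResult("MLD", -820, "HU", status = "green"))
  expect_match(concludeSection("lung", greens,
                               list(emphysema_index = 2), cfg),
               "No emphysema")

  lr <- lungRADS(list(noduleFromDiameters(c(1.6, 3.5, 4.6))))
  concl <- concludeSection("nodules", list(), list(lungrads = lr), cfg)
  expect_match(concl, "Lung-RADS 2")
  expect_match(concl, "12 months")

  expect_match(concludeSection("bone", list(),
                               list(bone_class = "osteoporosis"), cfg),
               "osteoporosis with significantly reduced")
})

mkDoc <- function() {
  s1 <- list(title = "Cardiovascular comorbidities",
             results = list(biomarkerResult("CAC", 399, "",
                                            status = "red",
                                            categoryLabel = "Moderate CAC")),
             conclusion = "Moderate CAC.")
  s2 <- list(title = "Osteoporosis",
             results = list(biomarkerResult("T-score", -3.4, "",
                                            status = "red"),
                            biomarkerResult("BMD", NA, "mg/cm^3")),
             conclusion = "Suspicion of osteoporosis.")
  assembleReport(list(cardio = s1, bone = s2),
                 meta = list(study = "fixture-1"))
}

test_that("documents validate, render deterministically and carry sections", {
  doc <- mkDoc()
  expect_true(validateReport(doc))
  js <- renderReport(doc, "json")
  expect_identical(js, renderReport(doc, "json"))  # pure function
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_true(validateReport(parsed))
  expect_named(parsed$sections, c("cardio", "bone"))
  txt <- renderReport(doc, "txt")
  expect_match(txt, "Cardiovascular comorbidities")
  expect_match(txt, "Osteoporosis")
  expect_match(renderReport(doc, "html"), "<h2>Osteoporosis</h2>")
  # not_evaluated results serialize without a value
  expect_null(parsed$sections$bone$results[[2]]$value)
})

test_that("schema violations are caught before writing", {
  doc <- mkDoc()
  bad <- jsonlite::fromJSON(renderReport(doc, "json"),
                            simplifyVector = FALSE)
  bad$sections$cardio$results[[1]]$status <- "purple"
  expect_error(validateReport(bad), "invalid status")
  bad2 <- jsonlite::fromJSON(renderReport(doc, "json"),
                             simplifyVector = FALSE)
  bad2$sections$cardio$conclusion <- NULL
  expect_error(validateReport(bad2), "incomplete")
})

test_that("every phantom biomarker appears exactly once in the report", {
  ph <- smallPhantom(seed = 10)
  doc <- runStudy(ph$volume, ph$masks)
  names <- unlist(lapply(doc@sections, function(s)
    vapply(s$results, function(r) r@name, character(1))))
  expect_identical(anyDuplicated(names), 0L)
  # all core biomarkers present
  for (nm in c("VFA", "SFA", "IMAT", "Liver attenuation",
               "Liver fat content", "CAC", "TAC", "AAC", "Lung volume",
               "MLD", "Emphysema index", "Nodule count", "Lung-RADS",
               "BMD", "T-score"))
    expect_true(nm %in% names, info = nm)
})
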