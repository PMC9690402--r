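# In-process analyzer graph: the desk-scale analogue of a containerized
# DAG workflow. Analyzers are independent given their inputs, so any
# execution order consistent with the dependencies yields an identical
# report; sections are assembled in a fixed canonical order regardless of
# execution order.

.ANALYZERS <- c("adipose", "cardio", "lung", "nodules", "bone")

.SECTION_TITLES <- c(
  adipose = "Adipose tissue and metabolism",
  cardio = "Cardiovascular comorbidities",
  lung = "Pulmonary parenchyma and COPD",
  nodules = "Pulmonary nodules",
  bone = "Osteoporosis")

#' The analyzer dependency graph
#'
#' Nodes are the five comorbidity analyzers plus the report stage; edges
#' are data dependencies (the report depends on every analyzer; the
#' analyzers depend only on the loaded study inputs). The graph is
#' acyclic by construction and [topologicalOrder()] produces a valid
#' execution order.
#'
#' @return list with \code{nodes} and \code{edges} (named list:
#'   node -> prerequisite nodes)
#' @export
analyzerGraph <- function() {
  list(nodes = c(.ANALYZERS, "report"),
       edges = c(stats::setNames(rep(list(character(0)), length(.ANALYZERS)),
                                 .ANALYZERS),
                 list(report = .ANALYZERS)))
}

#' Topological sort of an analyzer graph
#'
#' @param graph a graph from [analyzerGraph()]
#' @param preference optional node ordering used to break ties (lets the
#'   caller exercise different valid execution orders)
#' @return character vector of nodes, every node after its prerequisites
#' @export
topologicalOrder <- function(graph, preference = NULL) {
  nodes <- graph$nodes
  if (!is.null(preference))
    nodes <- c(intersect(preference, nodes), setdiff(nodes, preference))
  done <- character(0)
  while (length(done) < length(graph$nodes)) {
    ready <- nodes[!nodes %in% done &
                     vapply(nodes, function(n)
                       all(graph$edges[[n]] %in% done), logical(1))]
    if (!length(ready)) stop("cycle in analyzer graph")
    done <- c(done, ready[1])
  }
  done
}

# -- individual analyzers -------------------------------------------------
# Each returns list(results = list(BiomarkerResult), conclusion, ...).

.analyzeAdipose <- function(volume, masks, config) {
  ac <- config$adipose
  z <- selectL2L3Slice(masks)
  fa <- suppressWarnings(fatAreas(volume, masks, z,
                                  window = as.numeric(ac$fat_window_hu)))
  prov <- list(analyzer = "body_composition", slice_z = fa$slice_z,
               fat_window_hu = as.numeric(ac$fat_window_hu))
  results <- list(
    biomarkerResult("VFA", fa$VFA, "cm^2",
                    status = band(fa$VFA, meanSdRange("VFA", ac$vfa$mean,
                                                      ac$vfa$sd)),
                    provenance = prov),
    biomarkerResult("SFA", fa$SFA, "cm^2",
                    status = band(fa$SFA, meanSdRange("SFA", ac$sfa$mean,
                                                      ac$sfa$sd)),
                    provenance = prov),
    biomarkerResult("IMAT", fa$IMAT, "cm^2", status = "green",
                    provenance = c(prov, banded = FALSE)))
  la <- liverAttenuation(volume, masks,
                         radius = config$liver$roi_radius_mm)
  lg <- liverFatGrade(la$mean_hu, config)
  gradeStatus <- if (is.na(lg$grade)) "not_evaluated" else
    .statusFromCategory(lg$grade, "none", "mild")
  lprov <- list(analyzer = "body_composition",
                roi_radius_mm = config$liver$roi_radius_mm)
  results <- c(results, list(
    biomarkerResult("Liver attenuation", la$mean_hu, "HU",
                    status = gradeStatus, provenance = lprov),
    biomarkerResult("Liver fat content", lg$fat_percent, "%",
                    status = gradeStatus,
                    categoryLabel = if (is.na(lg$grade)) "" else
                      paste0("Steatosis: ", lg$grade),
                    provenance = lprov)))
  list(results = results,
       conclusion = concludeSection("adipose", results,
                                    list(steatosis_grade = lg$grade),
                                    config))
}

.analyzeCardio <- function(volume, masks, config) {
  cc <- config$cardio
  prov <- list(analyzer = "cardio_calcium", threshold_hu = cc$threshold_hu,
               min_area_mm2 = cc$min_area_mm2)
  vascular <- intersect(c("coronary", "thoracic_aorta", "abdominal_aorta"),
                        roles(masks))
  if (!length(vascular)) {
    results <- lapply(c("CAC", "TAC", "AAC"), function(nm)
      biomarkerResult(nm, NA_real_, provenance = prov))
    return(list(results = results,
                conclusion = concludeSection("cardio", results, list(),
                                             config)))
  }
  lesions <- detectLesions(volume, masks, threshold = cc$threshold_hu,
                           minArea = cc$min_area_mm2)
  scores <- categorizeCalcium(
    agatstonScore(lesions, masks,
                  sliceThicknessNorm = isTRUE(cc$slice_thickness_norm),
                  sliceThickness = voxelSpacing(volume)[3]),
    config)
  mk <- function(nm) {
    s <- scores[[nm]]
    biomarkerResult(nm, s$score, "",
                    status = if (is.na(s$score)) "not_evaluated"
                    else if (nm == "CAC")
                      .statusFromCategory(s$category, "none",
                                          c("minimal", "mild"))
                    else if (isTRUE(s$high)) "red" else "green",
                    categoryLabel = if (nm == "CAC" && !is.na(s$score))
                      s$categoryLabel else "",
                    recommendation = if (nm == "CAC" && !is.na(s$score))
                      s$recommendation else "",
                    provenance = prov)
  }
  results <- lapply(c("CAC", "TAC", "AAC"), mk)
  highs <- c("TAC", "AAC")[c(isTRUE(scores$TAC$high),
                             isTRUE(scores$AAC$high))]
  list(results = results,
       conclusion = concludeSection("cardio", results,
                                    list(cac_label = scores$CAC$categoryLabel,
                                         statin = scores$CAC$recommendation,
                                         high_vessels = highs),
                                    config))
}

.analyzeLung <- function(volume, masks, config, expVolume = NULL,
                         airways = NULL, bronchiectasisIndex = NA_real_) {
  dm <- densityMetrics(volume, masks, config, bronchiectasisIndex)
  prov <- c(list(analyzer = "lung_quant"), dm$provenance)
  lc <- config$lung
  eiRange <- referenceRange("Emphysema index", c(0, lc$ei_green_max),
                            c(0, lc$ei_yellow_max), direction = "high_bad")
  results <- list(
    biomarkerResult("Lung volume", dm$lung_volume_cm3, "cm^3",
                    provenance = prov),
    biomarkerResult("MLD", dm$mld_hu, "HU", provenance = prov),
    biomarkerResult("Emphysema index", dm$emphysema_index, "%",
                    status = band(dm$emphysema_index, eiRange),
                    provenance = prov),
    biomarkerResult("GGO index", dm$ggo_index, "%", provenance = prov),
    biomarkerResult("Fibrosis index", dm$fibrosis_index, "%",
                    provenance = prov))
  if (!is.na(bronchiectasisIndex))
    results <- c(results, list(
      biomarkerResult("Bronchiectasis index", bronchiectasisIndex, "%",
                      provenance = list(analyzer = "external",
                                        pass_through = TRUE))))
  if (!is.null(expVolume)) {
    pr <- prm(volume, expVolume, masks, config)
    pprov <- list(analyzer = "lung_quant", prm_insp_hu = lc$prm_insp_hu,
                  prm_exp_hu = lc$prm_exp_hu)
    results <- c(results, list(
      biomarkerResult("PRM emphysema", pr$prm_emphysema, "%",
                      provenance = pprov),
      biomarkerResult("PRM fSAD", pr$prm_fsad, "%", provenance = pprov),
      biomarkerResult("PRM normal", pr$prm_normal, "%",
                      provenance = pprov),
      biomarkerResult("PRM uncharacterized", pr$prm_uncharacterized, "%",
                      provenance = pprov)))
  }
  p10 <- list(pi10_cm = NA_real_, wall_percentage = NA_real_)
  if (!is.null(airways)) p10 <- pi10(airways)
  if (!is.null(airways))
    results <- c(results, list(
      biomarkerResult("Pi10", p10$pi10_cm, "cm",
                      provenance = list(analyzer = "lung_quant",
                                        source = "airway table")),
      biomarkerResult("Wall percentage", p10$wall_percentage, "%",
                      provenance = list(analyzer = "lung_quant",
                                        source = "airway table"))))
  list(results = results,
       conclusion = concludeSection(
         "lung", results,
         list(emphysema_index = dm$emphysema_index,
              wall_thickening = !is.na(p10$pi10_cm)),
         config))
}

.analyzeNodules <- function(volume, masks, config, detect = FALSE) {
  prov <- list(analyzer = "nodule_quant")
  noduleRoles <- grep("^nodule_", roles(masks), value = TRUE)
  measurements <- list()
  if (length(noduleRoles)) {
    measurements <- lapply(seq_along(noduleRoles), function(i)
      measureNodule(volume, maskRole(masks, noduleRoles[i]), id = i))
    measurements <- Filter(Negate(is.null), measurements)
  } else if (detect) {
    blobs <- detectNodules(volume, masks,
                           threshold = config$nodules$detect_threshold_hu)
    measurements <- lapply(seq_along(blobs), function(i)
      measureNodule(volume, blobs[[i]], id = i))
  }
  lr <- lungRADS(measurements, config = config)
  lrLevels <- c("1", "2", "3", "4A", "4B")
  results <- list(
    biomarkerResult("Nodule count", length(measurements), "",
                    status = if (length(measurements)) "yellow" else "green",
                    provenance = prov))
  for (m in measurements) {
    results <- c(results, list(
      biomarkerResult(sprintf("Nodule %d volume", m$id), m$volume_mm3,
                      "mm^3",
                      status = "yellow",
                      categoryLabel = sprintf(
                        "%.1f mm x %.1f mm x %.1f mm",
                        m$diameters_mm[1], m$diameters_mm[2],
                        m$diameters_mm[3]),
                      provenance = c(prov, list(
                        mean_diameter_mm = m$mean_diameter_mm,
                        voxel_volume_mm3 = m$voxel_volume_mm3)))))
  }
  results <- c(results, list(
    biomarkerResult("Lung-RADS", match(lr$category, lrLevels), "",
                    status = .statusFromCategory(lr$category, "1",
                                                 c("2", "3")),
                    categoryLabel = paste0("Lung-RADS ", lr$category),
                    recommendation = lr$recommendation,
                    provenance = c(prov, list(category = lr$category,
                                              basis = lr$basis)))))
  list(results = results,
       conclusion = concludeSection("nodules", results,
                                    list(lungrads = lr), config))
}

.analyzeBone <- function(volume, masks, config) {
  bc <- config$bone
  prov <- list(analyzer = "bone_quant", margin_mm = bc$margin_mm,
               reference = c(bc$reference_mean, bc$reference_sd))
  cal <- NULL
  rodRoles <- grep("^calibration_rod_", roles(masks), value = TRUE)
  if (length(rodRoles) >= 2 && length(bc$rod_densities) >= length(rodRoles)) {
    dens <- stats::setNames(as.numeric(
      bc$rod_densities[seq_along(rodRoles)]),
      sort(rodRoles))
    cal <- tryCatch(calibrateBMD(volume, masks, dens),
                    error = function(e) NULL)
  }
  if (is.null(cal) && !is.null(bc$calibration)) {
    cal <- calibrationFromCoefficients(bc$calibration$slope,
                                       bc$calibration$intercept)
  }
  if (is.null(cal)) {
    results <- lapply(c("Trabecular density", "BMD", "T-score"),
                      function(nm) biomarkerResult(nm, NA_real_,
                                                   provenance = prov))
    return(list(results = results,
                conclusion = concludeSection("bone", results, list(),
                                             config)))
  }
  ba <- boneAnalysis(volume, masks, cal, config)
  rep <- ba$reported
  if (is.null(rep)) {
    results <- lapply(c("Trabecular density", "BMD", "T-score"),
                      function(nm) biomarkerResult(nm, NA_real_,
                                                   provenance = prov))
    return(list(results = results,
                conclusion = concludeSection("bone", results, list(),
                                             config)))
  }
  prov$level <- rep$level
  prov$calibration <- c(slope = cal@slope, intercept = cal@intercept)
  prov$all_levels <- lapply(ba$levels, function(l)
    l[c("level", "bmd_mg_cm3", "t_score")])
  st <- .statusFromCategory(rep$classification, "normal", "osteopenia")
  results <- list(
    biomarkerResult("Trabecular density", rep$trabecular_mean_hu, "HU",
                    status = st, provenance = prov),
    biomarkerResult("BMD", rep$bmd_mg_cm3, "mg/cm^3", status = st,
                    categoryLabel = sprintf("Level %s", rep$level),
                    provenance = prov),
    biomarkerResult("T-score", rep$t_score, "", status = st,
                    categoryLabel = rep$classification,
                    provenance = prov))
  list(results = results,
       conclusion = concludeSection("bone", results,
                                    list(bone_class = rep$classification),
                                    config))
}

#' Run the full study workflow
#'
#' Executes every comorbidity analyzer on one study (a CT volume plus
#' label maps) in a dependency-consistent order and assembles the
#' structured report. An analyzer whose inputs are missing, or that
#' fails, degrades to a section of \code{not_evaluated} results with a
#' logged diagnostic instead of aborting the study; sections are never
#' silently omitted. The report is a pure function of the inputs:
#' repeated runs, and any valid analyzer ordering, produce identical
#' documents.
#'
#' @param volume a [CTVolume-class] (or path to NIfTI)
#' @param masks a [MaskSet-class] (or path to NIfTI; then
#'   \code{semantics} must be given)
#' @param semantics semantics mapping or YAML path, used when
#'   \code{masks} is a path
#' @param expVolume optional registered expiratory [CTVolume-class] or
#'   path (enables PRM)
#' @param airways optional airway table (data.frame or CSV path) for Pi10
#' @param bronchiectasisIndex optional externally computed value (%),
#'   pass-through
#' @param config configuration list or YAML path (see [defaultConfig()])
#' @param meta list of opaque study identifiers
#' @param order optional analyzer execution order (any permutation of
#'   \code{adipose, cardio, lung, nodules, bone}); the report does not
#'   depend on it
#' @param detectNodulesIfUnlabeled run blob detection when no nodule
#'   labels are present (phantom-scale stand-in for an upstream detector)
#' @return a [ReportDocument-class]
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(48, 48, 32), seed = 1))
#' doc <- runStudy(ph$volume, ph$masks)
#' names(doc@sections)
#' @export
runStudy <- function(volume, masks, semantics = NULL, expVolume = NULL,
                     airways = NULL, bronchiectasisIndex = NA_real_,
                     config = defaultConfig(), meta = list(),
                     order = NULL, detectNodulesIfUnlabeled = FALSE) {
  if (is.character(volume)) volume <- loadVolume(volume)
  if (is.character(masks))
    masks <- loadMaskSet(masks, semantics = semantics, volume = volume)
  if (is.character(expVolume)) expVolume <- loadVolume(expVolume)
  if (is.character(airways)) airways <- readAirwayTable(airways)
  if (is.character(config)) config <- defaultConfig(config)
  if (!identical(dim(masks@labelmap), dim(volume@voxels)))
    stop("masks are not congruent with the volume")

  graph <- analyzerGraph()
  sched <- setdiff(topologicalOrder(graph, preference = order), "report")
  runs <- list()
  for (a in sched) {
    runs[[a]] <- tryCatch(
      switch(a,
        adipose = .analyzeAdipose(volume, masks, config),
        cardio = .analyzeCardio(volume, masks, config),
        lung = .analyzeLung(volume, masks, config, expVolume, airways,
                            bronchiectasisIndex),
        nodules = .analyzeNodules(volume, masks, config,
                                  detect = detectNodulesIfUnlabeled),
        bone = .analyzeBone(volume, masks, config)),
      error = function(e) {
        message(sprintf("analyzer '%s' failed: %s", a, conditionMessage(e)))
        list(results = list(biomarkerResult(
               .SECTION_TITLES[[a]], NA_real_,
               provenance = list(analyzer = a,
                                 diagnostic = conditionMessage(e)))),
             conclusion = "")
      })
  }
  # canonical section order, independent of execution order
  sections <- lapply(stats::setNames(nm = .ANALYZERS), function(a)
    list(title = unname(.SECTION_TITLES[[a]]), results = runs[[a]]$results,
         conclusion = runs[[a]]$conclusion))
  assembleReport(sections, meta = meta,
                 provenance = list(
                   order = "canonical",
                   config_digest = length(unlist(config))))
}
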