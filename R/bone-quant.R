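#' Extract the trabecular core of a labeled vertebral body
#'
#' Erodes the vertebral-body mask by a ball of physical radius
#' \code{margin} (default 3 mm) to strip the cortical shell and partial
#' volume at the surface, leaving a trabecular core for densitometry. A
#' body thinner than twice the margin erodes to nothing and the level is
#' reported not evaluated.
#'
#' @param masks a [MaskSet-class]
#' @param level vertebra role name, e.g. \code{"vertebra_L1"}
#' @param margin erosion radius in mm
#' @return logical core mask, or NULL when the level is absent (with a
#'   warning) or the core is empty
#' @export
extractTrabecular <- function(masks, level, margin = 3) {
  if (!level %in% roles(masks)) {
    warning(sprintf("vertebra level '%s' absent; skipped", level))
    return(NULL)
  }
  m <- maskRole(masks, level)
  if (!any(m)) return(NULL)
  core <- .erodeBall(m, margin, voxelSpacing(masks))
  if (!any(core)) return(NULL)
  core
}

#' Fit the HU-to-density calibration line from reference rods
#'
#' Least-squares line \code{density = slope * HU + intercept} over
#' (rod mean HU, known hydroxyapatite density) pairs measured from the
#' calibration-rod masks. At least two rods with distinct densities are
#' required; with fewer, supply slope/intercept directly in config
#' ("asynchronous" calibration).
#'
#' @param volume a [CTVolume-class]
#' @param masks a [MaskSet-class] with \code{calibration_rod_<k>} roles
#' @param rodDensities named numeric vector: rod role name -> known HA
#'   density in mg/cm^3
#' @return a [Calibration-class]
#' @export
calibrateBMD <- function(volume, masks, rodDensities) {
  present <- intersect(names(rodDensities), roles(masks))
  if (length(present) < 2L || length(unique(rodDensities[present])) < 2L)
    stop("asynchronous calibration values required: need >= 2 rods with ",
         "distinct densities (or supply slope/intercept in config)")
  hu <- vapply(present, function(r)
    maskedStatistics(volume, maskRole(masks, r))$mean_hu, numeric(1))
  if (anyNA(hu))
    stop("empty calibration rod mask")
  dens <- as.numeric(rodDensities[present])
  fit <- stats::lm(dens ~ hu)
  pred <- stats::fitted(fit)
  new("Calibration",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rods = data.frame(density = dens, hu = unname(hu),
                        row.names = present),
      residual = sqrt(mean((dens - pred)^2)))
}

#' Fixed-coefficient calibration
#'
#' @param slope (mg/cm^3)/HU
#' @param intercept mg/cm^3
#' @return a [Calibration-class] with no rod table
#' @export
calibrationFromCoefficients <- function(slope, intercept) {
  new("Calibration", slope = slope, intercept = intercept)
}

#' BMD, T-score and osteoporosis classification for one vertebral level
#'
#' Converts the trabecular mean HU to volumetric bone mineral density
#' (mg/cm^3 hydroxyapatite) through the calibration line, computes the
#' T-score against a young-adult reference (rounded to one decimal) and
#' classifies it by the WHO convention: T at or below -2.5 osteoporosis,
#' between -2.5 and -1.0 osteopenia, at or above -1.0 normal.
#'
#' @param trabecularMean mean HU over the trabecular core
#' @param cal a [Calibration-class]
#' @param reference numeric(2): reference mean and SD in mg/cm^3 (default
#'   taken from config, 178.5 and 27.5)
#' @param level vertebra label carried into the result
#' @return list with \code{level}, \code{trabecular_mean_hu},
#'   \code{bmd_mg_cm3}, \code{t_score}, \code{classification}
#' @examples
#' cal <- calibrationFromCoefficients(1, 0)
#' bmdTscore(85, cal)$t_score  # -3.4
#' @export
bmdTscore <- function(trabecularMean, cal,
                      reference = c(178.5, 27.5), level = NA_character_) {
  bmd <- cal@slope * trabecularMean + cal@intercept
  t <- round((bmd - reference[1]) / reference[2], 1)
  classification <- if (t <= -2.5) "osteoporosis"
    else if (t < -1.0) "osteopenia"
    else "normal"
  list(level = level, trabecular_mean_hu = trabecularMean,
       bmd_mg_cm3 = bmd, t_score = t, classification = classification)
}

#' Bone analysis over all labeled vertebrae
#'
#' Runs trabecular extraction, densitometry and T-scoring for every
#' vertebra role in the mask set. The reported level is L1 when measurable,
#' otherwise the lowest fully measured thoracolumbar level; all measured
#' levels are kept.
#'
#' @param volume a [CTVolume-class]
#' @param masks a [MaskSet-class]
#' @param cal a [Calibration-class]
#' @param config configuration list (erosion margin, reference mean/SD)
#' @return list with \code{reported} (the primary level's result or NULL)
#'   and \code{levels} (named list of per-level results)
#' @export
boneAnalysis <- function(volume, masks, cal, config = defaultConfig()) {
  bc <- config$bone
  vlevels <- grep("^vertebra_", roles(masks), value = TRUE)
  out <- list()
  for (lv in vlevels) {
    core <- extractTrabecular(masks, lv, margin = bc$margin_mm)
    if (is.null(core)) next
    st <- maskedStatistics(volume, core)
    out[[lv]] <- bmdTscore(st$mean_hu, cal,
                           reference = c(bc$reference_mean,
                                         bc$reference_sd),
                           level = sub("^vertebra_", "", lv))
  }
  reported <- NULL
  if ("vertebra_L1" %in% names(out)) {
    reported <- out[["vertebra_L1"]]
  } else if (length(out)) {
    # lowest thoracolumbar level: order T1..T12 then L1..L5, take the last
    ord <- c(paste0("vertebra_T", 1:12), paste0("vertebra_L", 1:5))
    measured <- intersect(ord, names(out))
    reported <- out[[measured[length(measured)]]]
  }
  list(reported = reported, levels = out)
}
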