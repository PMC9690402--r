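# Joint lung mask over whichever of lung_left / lung_right are present.
.lungMask <- function(masks) {
  present <- intersect(c("lung_left", "lung_right"), roles(masks))
  if (!length(present)) return(NULL)
  m <- maskRole(masks, present[1])
  for (r in present[-1]) m <- m | maskRole(masks, r)
  m
}

#' Lung densitometry
#'
#' Over the joint lung-mask voxels: lung volume (voxel count times voxel
#' volume, in cm^3), mean lung density (MLD, mean HU), emphysema index
#' (percent of voxels below -950 HU), ground-glass opacity index (percent
#' in [-800, -500)) and fibrosis index (percent in [-500, -200]). The GGO
#' and fibrosis windows are unvalidated placeholders and are flagged as
#' such in the returned provenance. An externally computed bronchiectasis
#' index may be passed through.
#'
#' @param volume inspiratory [CTVolume-class]
#' @param masks a [MaskSet-class] with lung roles
#' @param config configuration list (HU thresholds)
#' @param bronchiectasisIndex optional externally computed value (%),
#'   reported verbatim
#' @return list with \code{lung_volume_cm3}, \code{mld_hu},
#'   \code{emphysema_index}, \code{ggo_index}, \code{fibrosis_index},
#'   \code{bronchiectasis_index} and \code{provenance}; all NA when the
#'   lung mask is empty or absent
#' @export
densityMetrics <- function(volume, masks, config = defaultConfig(),
                           bronchiectasisIndex = NA_real_) {
  lung <- .lungMask(masks)
  notEval <- list(lung_volume_cm3 = NA_real_, mld_hu = NA_real_,
                  emphysema_index = NA_real_, ggo_index = NA_real_,
                  fibrosis_index = NA_real_,
                  bronchiectasis_index = bronchiectasisIndex,
                  provenance = list())
  if (is.null(lung) || !any(lung)) return(notEval)
  lc <- config$lung
  hu <- volume@voxels[lung]
  n <- length(hu)
  list(
    lung_volume_cm3 = n * voxelVolume(volume) / 1000,
    mld_hu = mean(hu),
    emphysema_index = 100 * sum(hu < lc$emphysema_hu) / n,
    ggo_index = 100 * sum(hu >= lc$ggo_window_hu[1] &
                          hu < lc$ggo_window_hu[2]) / n,
    fibrosis_index = 100 * sum(hu >= lc$fibrosis_window_hu[1] &
                               hu <= lc$fibrosis_window_hu[2]) / n,
    bronchiectasis_index = bronchiectasisIndex,
    provenance = list(
      emphysema_hu = lc$emphysema_hu,
      ggo_window_hu = lc$ggo_window_hu, ggo_window_status = "unvalidated",
      fibrosis_window_hu = lc$fibrosis_window_hu,
      fibrosis_window_status = "unvalidated"))
}

#' Parametric response mapping (PRM) COPD phenotyping
#'
#' Classifies each lung voxel from the voxel-aligned inspiratory and
#' expiratory HU pair: emphysema when inspiratory < -950 and expiratory
#' < -856; functional small-airway disease (fSAD) when inspiratory >= -950
#' and expiratory < -856; normal when both at or above their thresholds;
#' uncharacterized when inspiratory < -950 but expiratory >= -856.
#' Fractions are percentages of lung voxels and always sum to 100.
#' Registration is out of scope: the pair must already be voxel-aligned
#' (congruence is enforced).
#'
#' @param insp inspiratory [CTVolume-class]
#' @param expReg registered expiratory [CTVolume-class], same grid
#' @param masks a [MaskSet-class] with lung roles
#' @param config configuration list (PRM thresholds)
#' @return list with \code{prm_emphysema}, \code{prm_fsad},
#'   \code{prm_normal}, \code{prm_uncharacterized} (percent), or all NA
#'   when the lung mask is empty
#' @export
prm <- function(insp, expReg, masks, config = defaultConfig()) {
  if (!identical(dim(insp@voxels), dim(expReg@voxels)))
    stop("inspiratory and expiratory volumes are not congruent")
  lung <- .lungMask(masks)
  if (is.null(lung) || !any(lung)) {
    return(list(prm_emphysema = NA_real_, prm_fsad = NA_real_,
                prm_normal = NA_real_, prm_uncharacterized = NA_real_))
  }
  ti <- config$lung$prm_insp_hu
  te <- config$lung$prm_exp_hu
  i <- insp@voxels[lung]
  e <- expReg@voxels[lung]
  n <- length(i)
  list(prm_emphysema = 100 * sum(i < ti & e < te) / n,
       prm_fsad = 100 * sum(i >= ti & e < te) / n,
       prm_normal = 100 * sum(i >= ti & e >= te) / n,
       prm_uncharacterized = 100 * sum(i < ti & e >= te) / n)
}

#' Read an airway cross-section measurement table
#'
#' CSV with header \code{airway_id,Pi_mm,lumen_mm2,WA_mm2}: internal
#' perimeter Pi, lumen area and wall area per measured airway. Airway
#' segmentation itself is out of scope; measurements come from an external
#' airway analysis.
#'
#' @param path CSV path
#' @return data.frame with the four columns, validated (Pi and WA positive)
#' @export
readAirwayTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("airway_id", "Pi_mm", "lumen_mm2", "WA_mm2")
  if (!all(need %in% names(tab)))
    stop("airway table must have columns ", paste(need, collapse = ", "))
  if (any(tab$Pi_mm <= 0) || any(tab$WA_mm2 <= 0))
    stop("Pi and WA must be positive")
  tab[need]
}

#' Pi10 and mean wall percentage from airway measurements
#'
#' Fits the standard square-root wall-area regression
#' \code{sqrt(WA) = a + b * Pi} by least squares over the measured airways
#' and evaluates it at an internal perimeter of 10 mm; the resulting
#' square-root wall area (mm) is reported in cm. Wall percentage is the
#' mean over airways of \code{100 * WA / (WA + lumen)}.
#'
#' @param airways data.frame from [readAirwayTable()] (columns
#'   \code{Pi_mm}, \code{lumen_mm2}, \code{WA_mm2})
#' @return list with \code{pi10_cm} and \code{wall_percentage}; both NA
#'   when fewer than two distinct Pi values are available
#' @examples
#' aw <- data.frame(airway_id = 1:3, Pi_mm = c(6, 9, 12),
#'                  WA_mm2 = (0.5 + 0.21 * c(6, 9, 12))^2,
#'                  lumen_mm2 = c(3, 6, 10))
#' pi10(aw)$pi10_cm  # 0.26
#' @export
pi10 <- function(airways) {
  if (nrow(airways) < 2L || length(unique(airways$Pi_mm)) < 2L) {
    return(list(pi10_cm = NA_real_, wall_percentage = NA_real_))
  }
  fit <- stats::lm(sqrt(WA_mm2) ~ Pi_mm, data = airways)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  list(pi10_cm = (a + 10 * b) / 10,
       wall_percentage = mean(100 * airways$WA_mm2 /
                                (airways$WA_mm2 + airways$lumen_mm2)))
}
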