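#' Select the L2/L3 analysis slice
#'
#' Single-slice body-composition planimetry is performed at the lumbar
#' L2/L3 level: the axial slice nearest the midpoint of the L2 and L3
#' vertebral-body centroids along z.
#'
#' @param masks a [MaskSet-class] with \code{vertebra_L2} and
#'   \code{vertebra_L3} roles
#' @return integer slice index, or \code{NA} when either vertebra is
#'   absent (fat areas are then not evaluated)
#' @export
selectL2L3Slice <- function(masks) {
  need <- c("vertebra_L2", "vertebra_L3")
  if (!all(need %in% roles(masks))) return(NA_integer_)
  cz <- vapply(need, function(r) {
    w <- which(maskRole(masks, r), arr.ind = TRUE)
    if (!nrow(w)) return(NA_real_)
    mean(w[, 3])
  }, numeric(1))
  if (anyNA(cz)) return(NA_integer_)
  as.integer(round(mean(cz)))
}

#' Fat-compartment planimetry on one axial slice
#'
#' Per compartment (visceral, subcutaneous, intermuscular), the fat area
#' is the count of pixels whose HU falls inside the fat window (default
#' [-190, -30] HU, inclusive on both ends) within the compartment mask on
#' slice \code{z}, times the pixel area, reported in cm^2.
#'
#' @param volume a [CTVolume-class]
#' @param masks a [MaskSet-class]
#' @param z axial slice index (see [selectL2L3Slice()])
#' @param window HU window, numeric(2) inclusive (default \code{c(-190, -30)})
#' @return list with \code{VFA}, \code{SFA}, \code{IMAT} in cm^2 (\code{NA}
#'   when the compartment role is absent; 0 with a warning when present but
#'   empty on the slice), plus \code{slice_z} and \code{pixel_area_mm2}
#' @export
fatAreas <- function(volume, masks, z, window = c(-190, -30)) {
  if (is.na(z)) {
    return(list(VFA = NA_real_, SFA = NA_real_, IMAT = NA_real_,
                slice_z = NA_integer_, pixel_area_mm2 = voxelArea(volume)))
  }
  stopifnot(z >= 1L, z <= dim(volume@voxels)[3])
  hu <- volume@voxels[, , z]
  inwin <- hu >= window[1] & hu <= window[2]
  pxArea <- voxelArea(volume)
  comp <- c(VFA = "visceral_compartment", SFA = "subcutaneous_compartment",
            IMAT = "intermuscular_compartment")
  out <- lapply(names(comp), function(nm) {
    role <- comp[[nm]]
    if (!role %in% roles(masks)) return(NA_real_)
    m <- maskRole(masks, role)[, , z]
    if (!any(m)) {
      warning(sprintf("compartment '%s' empty on slice %d", role, z))
      return(0)
    }
    sum(inwin & m) * pxArea / 100  # mm^2 -> cm^2
  })
  names(out) <- names(comp)
  c(out, list(slice_z = as.integer(z), pixel_area_mm2 = pxArea))
}

#' Liver attenuation from an automated ball ROI in the right lobe
#'
#' Places a ball-shaped region of interest in the right hepatic lobe
#' (operationally: patient-right of the liver-mask centroid, i.e. the
#' lower-x half under LPS-style axes) at the interior point maximizing
#' distance to the mask boundary, and returns the mean HU over
#' ball-intersect-liver. When the liver is absent or the deepest interior
#' point is shallower than half the requested radius, the measurement is
#' not evaluated.
#'
#' @param volume a [CTVolume-class] (non-contrast; see config flag
#'   \code{liver$contrast_enhanced})
#' @param masks a [MaskSet-class] with a \code{liver} role
#' @param radius ball radius in mm (default 10)
#' @return list with \code{mean_hu} (NA when not evaluated), \code{roi}
#'   (center in mm and radius) and \code{n_voxels}
#' @export
liverAttenuation <- function(volume, masks, radius = 10) {
  notEval <- list(mean_hu = NA_real_, roi = NULL, n_voxels = 0L)
  if (!"liver" %in% roles(masks)) return(notEval)
  liver <- maskRole(masks, "liver")
  if (!any(liver)) return(notEval)
  sp <- voxelSpacing(volume)
  bb <- .bbox(liver, pad = 1L)
  sub <- liver[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  dt <- .interiorDistance(sub, sp)
  # restrict to the patient-right half (lower x of the liver centroid)
  cx <- mean(dt$idx[, 1])
  right <- dt$idx[, 1] <= cx
  if (!any(right)) return(notEval)
  dmax <- max(dt$dist[right])
  if (dmax < radius / 2) return(notEval)
  best <- which(right & dt$dist == dmax)[1]
  center <- dt$idx[best, ] + c(min(bb[[1]]), min(bb[[2]]), min(bb[[3]])) - 1L
  # ball mask around the center, intersected with the liver
  dm <- dim(liver)
  ball <- array(FALSE, dm)
  off <- rbind(c(0L, 0L, 0L), .ballOffsets(radius, sp))
  pts <- sweep(off, 2L, as.integer(center), `+`)
  ok <- pts[, 1] >= 1 & pts[, 1] <= dm[1] & pts[, 2] >= 1 &
        pts[, 2] <= dm[2] & pts[, 3] >= 1 & pts[, 3] <= dm[3]
  pts <- pts[ok, , drop = FALSE]
  ball[cbind(pts[, 1], pts[, 2], pts[, 3])] <- TRUE
  roi <- ball & liver
  st <- maskedStatistics(volume, roi)
  list(mean_hu = st$mean_hu,
       roi = list(center_mm = as.numeric(center - 0.5) * sp,
                  radius_mm = radius),
       n_voxels = st$n_voxels)
}

#' Liver fat percentage and steatosis grade from mean attenuation
#'
#' Converts non-contrast liver attenuation to a fat percentage with the
#' linear form \code{fat\% = slope * HU + intercept} (defaults -0.58 and
#' 38.2), clipped below at zero and rounded to the nearest integer
#' percent, then grades steatosis from the percentage: below 5 none, 5 to
#' below 15 mild, 15 to below 30 moderate, 30 and above severe. On a
#' contrast-enhanced scan the conversion is invalid and the result is not
#' evaluated.
#'
#' @param meanAttenuation mean liver HU (NA allowed)
#' @param config configuration list (slope, intercept, grade thresholds,
#'   contrast flag)
#' @return list with \code{mean_attenuation_hu}, \code{fat_percent}
#'   (integer) and \code{grade} (one of none/mild/moderate/severe), all NA
#'   when not evaluable
#' @examples
#' liverFatGrade(54)$fat_percent  # 7
#' @export
liverFatGrade <- function(meanAttenuation, config = defaultConfig()) {
  lc <- config$liver
  if (is.na(meanAttenuation) || isTRUE(lc$contrast_enhanced)) {
    return(list(mean_attenuation_hu = meanAttenuation,
                fat_percent = NA_real_, grade = NA_character_))
  }
  fat <- lc$fat_slope * meanAttenuation + lc$fat_intercept
  fat <- round(max(0, fat))
  thr <- lc$steatosis_thresholds
  grade <- if (fat < thr[1]) "none"
    else if (fat < thr[2]) "mild"
    else if (fat < thr[3]) "moderate"
    else "severe"
  list(mean_attenuation_hu = meanAttenuation, fat_percent = fat,
       grade = grade)
}
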