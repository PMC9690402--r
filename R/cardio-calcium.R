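.VASCULAR_ROLES <- c(CAC = "coronary", TAC = "thoracic_aorta",
                     AAC = "abdominal_aorta")

#' Detect calcified lesions per vascular compartment
#'
#' Finds calcified plaque candidates as per-slice connected components
#' (8-connectivity in plane) of voxels at or above \code{threshold} HU,
#' intersected with exactly one vascular compartment mask. Voxels inside a
#' \code{bone_exclusion} mask are removed before component labeling, so
#' adjacent bone or dense foreign material cannot produce false positives.
#' Components smaller than \code{minArea} are discarded (classical
#' "three adjacent pixels", about 1 mm^2). Components on adjacent slices
#' that overlap in-plane are grouped into one 3-D lesion for counting;
#' scoring stays per-slice.
#'
#' @param volume a [CTVolume-class]
#' @param masks a [MaskSet-class] with at least one of the roles
#'   \code{coronary}, \code{thoracic_aorta}, \code{abdominal_aorta}
#' @param threshold detection threshold in HU (default 130, non-contrast;
#'   raise it for contrast-enhanced scans)
#' @param minArea minimum per-slice component area in mm^2 (default 1)
#' @return list of lesions; each lesion is a list with \code{compartment},
#'   \code{components} (data.frame \code{z}, \code{area_mm2},
#'   \code{peak_hu}, \code{n_voxels}) and \code{volume_mm3}
#' @seealso [agatstonScore()]
#' @export
detectLesions <- function(volume, masks, threshold = 130, minArea = 1) {
  compartments <- intersect(.VASCULAR_ROLES, roles(masks))
  if (!length(compartments))
    stop("no vascular compartment roles present")
  hu <- volume@voxels
  pxArea <- voxelArea(volume)
  vxVol <- voxelVolume(volume)
  excl <- maskRole(masks, "bone_exclusion", strict = FALSE)
  lesions <- list()
  for (comp in compartments) {
    cand <- (hu >= threshold) & maskRole(masks, comp) & !excl
    if (!any(cand)) next
    comps <- NULL
    pixels <- list()
    for (z in which(apply(cand, 3L, any))) {
      bw <- cand[, , z]
      bb <- .bbox(bw)
      lab <- matrix(0L, nrow(bw), ncol(bw))
      lab[bb[[1]], bb[[2]]] <- .labelComponents2D(bw[bb[[1]], bb[[2]],
                                                     drop = FALSE])
      for (k in seq_len(max(lab))) {
        sel <- lab == k
        n <- sum(sel)
        if (n * pxArea < minArea) next
        comps <- rbind(comps, data.frame(
          z = z, area_mm2 = n * pxArea,
          peak_hu = max(hu[, , z][sel]), n_voxels = n))
        pixels[[length(pixels) + 1L]] <- which(sel)
      }
    }
    if (is.null(comps)) next
    # group z-adjacent, in-plane-overlapping components into 3-D lesions
    g <- seq_len(nrow(comps))
    find <- function(i) { while (g[i] != i) i <- g[i]; i }
    for (a in seq_len(nrow(comps))) for (b in seq_len(nrow(comps))) {
      if (b <= a) next
      if (abs(comps$z[a] - comps$z[b]) == 1L &&
          length(intersect(pixels[[a]], pixels[[b]]))) {
        ra <- find(a); rb <- find(b)
        g[max(ra, rb)] <- min(ra, rb)
      }
    }
    groups <- vapply(seq_len(nrow(comps)), find, integer(1))
    for (id in unique(groups)) {
      rows <- comps[groups == id, , drop = FALSE]
      lesions[[length(lesions) + 1L]] <- list(
        compartment = comp,
        components = rows[order(rows$z), , drop = FALSE],
        volume_mm3 = sum(rows$n_voxels) * vxVol)
    }
  }
  lesions
}

# Agatston density weight from a component's peak HU.
.agatstonWeight <- function(peak) {
  ifelse(peak >= 400, 4L,
  ifelse(peak >= 300, 3L,
  ifelse(peak >= 200, 2L,
  ifelse(peak >= 130, 1L, 0L))))
}

#' Agatston and volume calcium scores per vascular compartment
#'
#' Scores lesions from [detectLesions()]: each per-slice component
#' contributes its area (mm^2) times a density weight keyed to its peak HU
#' (1 for 130-199, 2 for 200-299, 3 for 300-399, 4 at 400 and above); a
#' compartment's Agatston score is the sum over its components. The volume
#' score is the physical volume of supra-threshold lesion voxels. With
#' \code{sliceThicknessNorm = TRUE} each component score is scaled by
#' slice thickness / 3 mm (off by default).
#'
#' @param lesions lesion list from [detectLesions()]
#' @param masks the [MaskSet-class] used for detection (determines which
#'   compartments were evaluable; absent compartments report \code{NA})
#' @param sliceThicknessNorm logical; apply the thickness/3 mm factor
#' @param sliceThickness slice thickness in mm (required when normalizing)
#' @return list with per-compartment entries \code{CAC}, \code{TAC},
#'   \code{AAC}, each a list \code{score}, \code{volume_mm3},
#'   \code{n_lesions} (\code{score = NA} when the compartment mask was
#'   absent)
#' @export
agatstonScore <- function(lesions, masks, sliceThicknessNorm = FALSE,
                          sliceThickness = NULL) {
  factor <- 1
  if (sliceThicknessNorm) {
    if (is.null(sliceThickness))
      stop("sliceThickness required when sliceThicknessNorm = TRUE")
    factor <- sliceThickness / 3
  }
  out <- list()
  for (nm in names(.VASCULAR_ROLES)) {
    role <- .VASCULAR_ROLES[[nm]]
    if (!role %in% roles(masks)) {
      out[[nm]] <- list(score = NA_real_, volume_mm3 = NA_real_,
                        n_lesions = NA_integer_)
      next
    }
    sel <- Filter(function(l) l$compartment == role, lesions)
    score <- 0; vol <- 0
    for (l in sel) {
      w <- .agatstonWeight(l$components$peak_hu)
      score <- score + sum(l$components$area_mm2 * w) * factor
      vol <- vol + l$volume_mm3
    }
    out[[nm]] <- list(score = score, volume_mm3 = vol,
                      n_lesions = length(sel))
  }
  out
}

#' Risk category and statin recommendation from a CAC score
#'
#' Bands the coronary Agatston score (config defaults: 0 none; up to 10
#' minimal; up to 100 mild; up to 400 moderate; above 400 severe) and
#' synthesizes the recommendation: above the "consider" threshold the text
#' advises considering statin therapy, and from the high-intensity
#' threshold (default 300) upward it escalates to high-intensity statin
#' therapy. Thoracic/abdominal aortic scores are flagged "high" above
#' configurable thresholds (no validated default banding exists for them).
#'
#' @param scores result of [agatstonScore()]
#' @param config configuration list (see [defaultConfig()])
#' @return \code{scores} with added \code{category}, \code{categoryLabel}
#'   and \code{recommendation} fields for CAC, and \code{high} flags for
#'   TAC/AAC
#' @examples
#' sc <- list(CAC = list(score = 399), TAC = list(score = NA),
#'            AAC = list(score = NA))
#' categorizeCalcium(sc)$CAC$categoryLabel
#' @export
categorizeCalcium <- function(scores, config = defaultConfig()) {
  cc <- config$cardio
  s <- scores$CAC$score
  if (!is.null(s) && !is.na(s)) {
    bands <- cc$cac_bands  # c(0, 10, 100, 400)
    category <- if (s <= bands[1]) "none"
      else if (s <= bands[2]) "minimal"
      else if (s <= bands[3]) "mild"
      else if (s <= bands[4]) "moderate"
      else "severe"
    label <- if (category == "none") "No CAC"
      else paste0(toupper(substring(category, 1, 1)),
                  substring(category, 2), " CAC")
    rec <- character(0)
    if (s >= cc$statin_high_intensity_at) {
      rec <- config$templates$statin_high
    } else if (s > cc$statin_consider_above) {
      rec <- config$templates$statin_consider
    }
    scores$CAC$category <- category
    scores$CAC$categoryLabel <- label
    scores$CAC$recommendation <- if (length(rec)) rec else ""
  }
  for (nm in c("TAC", "AAC")) {
    v <- scores[[nm]]$score
    thr <- if (nm == "TAC") cc$tac_high_above else cc$aac_high_above
    scores[[nm]]$high <- if (is.null(v) || is.na(v)) NA else v > thr
  }
  scores
}
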