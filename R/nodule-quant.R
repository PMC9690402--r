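#' Measure one pulmonary nodule from a binary mask
#'
#' Bounding-box axis diameters are the physical extents of the nodule mask
#' along x, y and z. The long and short axes come from the axial slice of
#' maximal nodule area: the long axis is that slice's larger in-plane
#' extent, the short axis its perpendicular. Volume is reported as the
#' ellipsoid approximation \code{pi/6 * dx * dy * dz} from the three axis
#' diameters, with the voxel-count volume recorded alongside in
#' provenance.
#'
#' @param volume a [CTVolume-class] (spacing source)
#' @param noduleMask logical array, one connected nodule component
#' @param id identifier carried into the result
#' @param probability optional detector probability in [0, 1], reported
#'   verbatim
#' @param composition one of \code{"solid"}, \code{"part_solid"},
#'   \code{"ggn"}
#' @return list with \code{id}, \code{diameters_mm} (x, y, z),
#'   \code{long_axis_mm}, \code{short_axis_mm}, \code{mean_diameter_mm},
#'   \code{volume_mm3} (ellipsoid), \code{voxel_volume_mm3},
#'   \code{probability}, \code{composition}; NULL for an empty mask
#' @seealso [noduleFromDiameters()], [lungRADS()]
#' @export
measureNodule <- function(volume, noduleMask, id = 1L,
                          probability = NA_real_, composition = "solid") {
  w <- which(noduleMask, arr.ind = TRUE)
  if (!nrow(w)) return(NULL)
  sp <- voxelSpacing(volume)
  ext <- vapply(1:3, function(ax)
    (max(w[, ax]) - min(w[, ax]) + 1L) * sp[ax], numeric(1))
  # axial slice of maximal area
  areas <- table(w[, 3])
  zmax <- as.integer(names(areas)[which.max(areas)])
  wz <- w[w[, 3] == zmax, , drop = FALSE]
  extx <- (max(wz[, 1]) - min(wz[, 1]) + 1L) * sp[1]
  exty <- (max(wz[, 2]) - min(wz[, 2]) + 1L) * sp[2]
  long <- max(extx, exty)
  short <- min(extx, exty)
  .noduleRecord(id, ext, long, short,
                voxelCount = nrow(w) * voxelVolume(volume),
                probability = probability, composition = composition)
}

#' Construct a nodule measurement from reported axis diameters
#'
#' For nodules whose three axis diameters are already known (e.g. from an
#' upstream detector's bounding box) without a mask: the long and short
#' axes are taken as the largest and second-largest of the three
#' diameters, and the classification diameter is their mean.
#'
#' @param diameters numeric(3) axis diameters in mm (x, y, z)
#' @param id identifier
#' @param probability optional detector probability, pass-through
#' @param composition nodule composition attribute
#' @return a nodule measurement list (see [measureNodule()])
#' @examples
#' m <- noduleFromDiameters(c(1.6, 3.5, 4.6))
#' m$volume_mm3        # 13.48 (pi/6 * 1.6 * 3.5 * 4.6)
#' m$mean_diameter_mm  # 4.05
#' @export
noduleFromDiameters <- function(diameters, id = 1L, probability = NA_real_,
                                composition = "solid") {
  stopifnot(length(diameters) == 3L, all(diameters > 0))
  s <- sort(diameters, decreasing = TRUE)
  .noduleRecord(id, diameters, long = s[1], short = s[2],
                voxelCount = NA_real_, probability = probability,
                composition = composition)
}

.noduleRecord <- function(id, diameters, long, short, voxelCount,
                          probability, composition) {
  if (!composition %in% c("solid", "part_solid", "ggn")) {
    warning(sprintf("unknown composition '%s'; treating as solid",
                    composition))
    composition <- "solid"
  }
  list(id = id,
       diameters_mm = as.numeric(diameters),
       long_axis_mm = long, short_axis_mm = short,
       mean_diameter_mm = (long + short) / 2,
       volume_mm3 = pi / 6 * prod(diameters),
       voxel_volume_mm3 = voxelCount,
       probability = probability,
       composition = composition)
}

#' Detect nodule blobs in the lung (phantom-scale stand-in)
#'
#' Plain supra-threshold 3-D connected-component finder inside the lung
#' mask, used to measure phantom nodules when no nodule masks are
#' provided. Real-data nodule detection is performed upstream and is out
#' of scope.
#'
#' @param volume a [CTVolume-class]
#' @param masks a [MaskSet-class] with lung roles
#' @param threshold HU threshold above which lung voxels are nodule
#'   candidates (default -300)
#' @return list of logical nodule masks
#' @export
detectNodules <- function(volume, masks, threshold = -300) {
  lung <- .lungMask(masks)
  if (is.null(lung) || !any(lung)) return(list())
  cand <- lung & volume@voxels >= threshold
  if (!any(cand)) return(list())
  bb <- .bbox(cand, pad = 1L)
  lab <- array(0L, dim(cand))
  lab[bb[[1]], bb[[2]], bb[[3]]] <-
    .labelComponents3D(cand[bb[[1]], bb[[2]], bb[[3]], drop = FALSE])
  lapply(seq_len(max(lab)), function(k) lab == k)
}

#' Lung-RADS categorization of measured nodules
#'
#' Baseline solid-nodule logic (Lung-RADS v1.1 size bands) keyed on the
#' classification diameter (mean of long and short axis): below 6 mm is
#' category 2, 6 to below 8 mm category 3, 8 to below 15 mm category 4A,
#' 15 mm and above 4B; no nodules is category 1. The overall assessment is
#' the maximum category across nodules, with the follow-up recommendation
#' taken from the category's template. Part-solid/ground-glass band tables
#' are carried in config but the default path treats every nodule as
#' solid (with a warning for unknown composition).
#'
#' @param measurements list of nodule measurements ([measureNodule()] /
#'   [noduleFromDiameters()])
#' @param context \code{"baseline"} (default) or \code{"followup"}
#'   (follow-up logic not implemented; baseline bands are applied)
#' @param config configuration list (band edges, recommendation templates)
#' @return list with \code{category} (one of "1", "2", "3", "4A", "4B"),
#'   \code{basis} ("diameter"), \code{per_nodule} character vector and
#'   \code{recommendation}
#' @examples
#' lungRADS(list(noduleFromDiameters(c(1.6, 3.5, 4.6))))$category  # "2"
#' @export
lungRADS <- function(measurements, context = "baseline",
                     config = defaultConfig()) {
  bands <- config$nodules$lungrads_solid_baseline_mm
  levels <- c("1", "2", "3", "4A", "4B")
  catOf <- function(m) {
    d <- m$mean_diameter_mm
    if (d < bands[1]) "2" else if (d < bands[2]) "3"
    else if (d < bands[3]) "4A" else "4B"
  }
  if (!length(measurements)) {
    cat <- "1"
    per <- character(0)
  } else {
    per <- vapply(measurements, catOf, character(1))
    cat <- levels[max(match(per, levels))]
  }
  list(category = cat, basis = "diameter", per_nodule = per,
       recommendation = config$templates$lungrads_followup[[cat]])
}
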