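# Module-independent Agatston oracle.
#
# Kept in the phantom module so the cardio_calcium implementation can be
# checked against a second, independently written scoring path: this one
# labels per-slice components by iterative label min-propagation over the
# 8-neighbourhood (the analyzer uses two-pass union-find) and re-states
# the density weights inline.

# Shift a matrix by (di, dj), padding with `fill`.
.shiftMat <- function(m, di, dj, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- max(1, 1 + di):min(nr, nr + di)
  rj <- max(1, 1 + dj):min(nc, nc + dj)
  if (!length(ri) || !length(rj)) return(out)
  out[ri, rj] <- m[ri - di, rj - dj]
  out
}

# Connected components of a logical matrix (8-connectivity) by repeated
# minimum-label propagation until a fixed point.
.labelPropagate2D <- function(bw) {
  lab <- matrix(seq_along(bw), nrow(bw), ncol(bw))
  lab[!bw] <- 0L
  dirs <- expand.grid(di = -1:1, dj = -1:1)
  dirs <- dirs[!(dirs$di == 0 & dirs$dj == 0), ]
  repeat {
    nxt <- lab
    for (r in seq_len(nrow(dirs))) {
      s <- .shiftMat(lab, dirs$di[r], dirs$dj[r])
      upd <- bw & s > 0L & s < nxt
      nxt[upd] <- s[upd]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab
}

#' Brute-force Agatston scoring oracle
#'
#' Independent per-voxel reference implementation of per-compartment
#' Agatston and volume scoring, used to validate the analyzer and to fill
#' the phantom ground-truth manifest. Same contract as
#' [detectLesions()] + [agatstonScore()]: per-slice 8-connected
#' components of voxels at or above \code{threshold} within one vascular
#' compartment, bone-exclusion voxels removed first, components under
#' \code{minArea} dropped, component score = area times the peak-HU
#' density weight.
#'
#' @param volume a [CTVolume-class]
#' @param masks a [MaskSet-class]
#' @param threshold detection threshold in HU
#' @param minArea minimum component area in mm^2
#' @return list with per-compartment entries \code{CAC}, \code{TAC},
#'   \code{AAC}: \code{score} and \code{volume_mm3} (NA when the
#'   compartment role is absent)
#' @export
agatstonOracle <- function(volume, masks, threshold = 130, minArea = 1) {
  compartments <- c(CAC = "coronary", TAC = "thoracic_aorta",
                    AAC = "abdominal_aorta")
  hu <- volume@voxels
  pxArea <- voxelArea(volume)
  vxVol <- voxelVolume(volume)
  excl <- maskRole(masks, "bone_exclusion", strict = FALSE)
  out <- list()
  for (nm in names(compartments)) {
    role <- compartments[[nm]]
    if (!role %in% roles(masks)) {
      out[[nm]] <- list(score = NA_real_, volume_mm3 = NA_real_)
      next
    }
    region <- maskRole(masks, role) & !excl
    score <- 0; vol <- 0
    for (z in seq_len(dim(hu)[3])) {
      bw <- region[, , z] & hu[, , z] >= threshold
      if (!any(bw)) next
      lab <- .labelPropagate2D(bw)
      for (id in setdiff(unique(as.vector(lab)), 0L)) {
        sel <- lab == id
        area <- sum(sel) * pxArea
        if (area < minArea) next
        peak <- max(hu[, , z][sel])
        w <- if (peak >= 400) 4 else if (peak >= 300) 3 else
             if (peak >= 200) 2 else 1
        score <- score + area * w
        vol <- vol + sum(sel) * vxVol
      }
    }
    out[[nm]] <- list(score = score, volume_mm3 = vol)
  }
  out
}
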