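#' Voxel spacing in millimetres
#' @param x a CTVolume or MaskSet
#' @return numeric(3) spacing in mm along (x, y, z)
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "MaskSet", function(x) x@spacing)

#' In-plane voxel area (mm^2) and voxel volume (mm^3)
#' @param x a CTVolume or MaskSet
#' @return scalar area in mm^2 / volume in mm^3
#' @export
setGeneric("voxelArea", function(x) standardGeneric("voxelArea"))

#' @rdname voxelArea
#' @export
setMethod("voxelArea", "ANY", function(x) prod(voxelSpacing(x)[1:2]))

#' @rdname voxelArea
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname voxelArea
#' @export
setMethod("voxelVolume", "ANY", function(x) prod(voxelSpacing(x)))

#' Voxel HU array of a CTVolume
#' @param x a CTVolume
#' @return 3-D numeric array in HU
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)

#' Label map and semantics of a MaskSet
#' @param x a MaskSet
#' @return integer array / named integer vector
#' @export
setGeneric("labelmap", function(x) standardGeneric("labelmap"))

#' @rdname labelmap
#' @export
setMethod("labelmap", "MaskSet", function(x) x@labelmap)

#' @rdname labelmap
#' @export
setGeneric("semantics", function(x) standardGeneric("semantics"))

#' @rdname labelmap
#' @export
setMethod("semantics", "MaskSet", function(x) x@semantics)

#' Role names present in a MaskSet
#' @param x a MaskSet
#' @return character vector of role names
#' @export
setGeneric("roles", function(x) standardGeneric("roles"))

#' @rdname roles
#' @export
setMethod("roles", "MaskSet", function(x) names(x@semantics))

#' Binary mask for one anatomical role
#'
#' @param x a MaskSet
#' @param role role name (e.g. \code{"liver"}); must be present unless
#'   \code{strict = FALSE}
#' @param strict if FALSE, an absent role returns an all-FALSE mask
#' @return logical array of the labelmap shape
#' @export
setGeneric("maskRole", function(x, role, strict = TRUE)
  standardGeneric("maskRole"))

#' @rdname maskRole
#' @export
setMethod("maskRole", "MaskSet", function(x, role, strict = TRUE) {
  if (!role %in% names(x@semantics)) {
    if (strict) stop(sprintf("role '%s' not present in MaskSet", role))
    return(array(FALSE, dim(x@labelmap)))
  }
  x@labelmap == x@semantics[[role]]
})

#' Traffic-light status of a BiomarkerResult
#' @param x a BiomarkerResult
#' @return character status
#' @export
setGeneric("status", function(x) standardGeneric("status"))

#' @rdname status
#' @export
setMethod("status", "BiomarkerResult", function(x) x@status)

#' Value of a BiomarkerResult
#' @param x a BiomarkerResult
#' @return numeric scalar, NA when not evaluated
#' @export
setGeneric("value", function(x) standardGeneric("value"))

#' @rdname value
#' @export
setMethod("value", "BiomarkerResult", function(x) x@value)

#' Ground-truth values of a manifest
#' @param x a GroundTruthManifest
#' @return named list
#' @export
setGeneric("manifestValues", function(x) standardGeneric("manifestValues"))

#' @rdname manifestValues
#' @export
setMethod("manifestValues", "GroundTruthManifest", function(x) x@values)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "MaskSet", function(object) {
  d <- dim(object@labelmap)
  cat(sprintf("MaskSet %d x %d x %d voxels, %d roles\n",
              d[1], d[2], d[3], length(object@semantics)))
  if (length(object@semantics))
    cat(" ", paste(names(object@semantics), collapse = ", "), "\n")
})

setMethod("show", "BiomarkerResult", function(object) {
  val <- if (is.na(object@value)) "-" else format(object@value)
  cat(sprintf("BiomarkerResult %s: %s %s [%s]%s\n", object@name, val,
              object@units, object@status,
              if (nzchar(object@categoryLabel))
                paste0(" ", object@categoryLabel) else ""))
})

setMethod("show", "Calibration", function(object) {
  cat(sprintf(
    "Calibration: density = %.4g * HU + %.4g mg/cm^3 (%d rods, rms %.3g)\n",
    object@slope, object@intercept, nrow(object@rods), object@residual))
})

setMethod("show", "ReportDocument", function(object) {
  cat(sprintf("ReportDocument with %d sections:\n", length(object@sections)))
  for (nm in names(object@sections)) {
    s <- object@sections[[nm]]
    st <- vapply(s$results, status, character(1))
    cat(sprintf("  %s: %d results (%s)\n", s$title, length(s$results),
                paste(sprintf("%d %s", table(st)[unique(st)], unique(st)),
                      collapse = ", ")))
  }
})

setMethod("show", "PhantomSpec", function(object) {
  p <- object@pars
  cat(sprintf("PhantomSpec %s @ (%s) mm, seed %d, noise sd %g HU\n",
              paste(p$shape, collapse = "x"),
              paste(p$spacing, collapse = ", "), p$seed, p$noise_sd))
})

setMethod("show", "GroundTruthManifest", function(object) {
  cat(sprintf("GroundTruthManifest with %d entries: %s\n",
              length(object@values),
              paste(names(object@values), collapse = ", ")))
})
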