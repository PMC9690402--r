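#' The anatomical role registry
#'
#' Roles that a [MaskSet-class] semantics mapping may use. The registry is
#' shipped as a versioned YAML file under \code{inst/extdata} and consists
#' of exact names (organs, compartments, vascular beds), vertebra levels
#' (\code{vertebra_T1} .. \code{vertebra_L5}) and numbered families
#' (\code{calibration_rod_<k>}, \code{nodule_<k>}).
#'
#' @return list with elements \code{exact}, \code{vertebra_levels},
#'   \code{numbered_prefixes}, \code{version}
#' @examples
#' roleRegistry()$exact
#' @export
roleRegistry <- function() {
  path <- system.file("extdata", "roles.yaml", package = "ctscreen")
  yaml::read_yaml(path)
}

# Return the subset of `role` names not admitted by the registry.
.invalidRoles <- function(role) {
  reg <- roleRegistry()
  ok <- role %in% reg$exact |
    role %in% paste0("vertebra_", reg$vertebra_levels)
  for (pre in reg$numbered_prefixes)
    ok <- ok | grepl(paste0("^", pre, "[0-9]+$"), role)
  role[!ok]
}

#' Construct a CTVolume
#'
#' @param voxels 3-D numeric array of HU values
#' @param spacing numeric(3) voxel spacing in mm
#' @param origin numeric(3) physical origin in mm
#' @return a [CTVolume-class]
#' @examples
#' v <- ctVolume(array(-1000, c(4, 4, 2)), spacing = c(1, 1, 2))
#' voxelVolume(v)
#' @export
ctVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a MaskSet
#'
#' @param labelmap 3-D integer array (0 background)
#' @param semantics named integer vector mapping role name to label
#' @param spacing numeric(3) voxel spacing in mm
#' @return a [MaskSet-class]
#' @export
maskSet <- function(labelmap, semantics = integer(0), spacing = c(1, 1, 1)) {
  storage.mode(labelmap) <- "integer"
  sem <- as.integer(semantics)
  names(sem) <- names(semantics)
  new("MaskSet", labelmap = labelmap, semantics = sem,
      spacing = as.numeric(spacing))
}

#' Construct a BiomarkerResult
#'
#' A missing \code{value} forces status \code{not_evaluated} (a structure
#' outside the field of view is reported as missing, never as zero).
#'
#' @param name biomarker identifier
#' @param value numeric scalar or NA
#' @param units unit string
#' @param status traffic-light status; ignored (forced to
#'   \code{not_evaluated}) when value is NA
#' @param categoryLabel free-text category
#' @param recommendation free-text recommendation
#' @param provenance list of analyzer name and parameters
#' @return a [BiomarkerResult-class]
#' @export
biomarkerResult <- function(name, value = NA_real_, units = "",
                            status = "green", categoryLabel = "",
                            recommendation = "", provenance = list()) {
  if (is.na(value)) {
    value <- NA_real_
    status <- "not_evaluated"
  }
  new("BiomarkerResult", name = name, value = as.numeric(value),
      units = units, status = status, categoryLabel = categoryLabel,
      recommendation = recommendation, provenance = provenance)
}

#' Load a CT volume from NIfTI
#'
#' Reads a NIfTI-1 file (\code{.nii} or \code{.nii.gz}) into a
#' [CTVolume-class], taking voxel spacing from the header. Voxel values are
#' assumed to already be in Hounsfield units (NIfTI scl slope/intercept are
#' applied by the reader). DICOM series input is not supported by this
#' build; convert series to NIfTI upstream, applying the rescale equation
#' (see [applyRescale()]).
#'
#' @param path path to a NIfTI file
#' @return a [CTVolume-class]
#' @seealso [writeVolume()], [loadMaskSet()]
#' @export
loadVolume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file: %s", path))
  if (dir.exists(path))
    stop("directory input (DICOM series) is not supported; convert the ",
         "series to NIfTI with HU rescale applied (see applyRescale)")
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) != 3L)
    stop("expected a 3-D volume")
  ctVolume(a, spacing = RNifti::pixdim(img)[1:3])
}

#' DICOM linear rescale to Hounsfield units
#'
#' Applies \code{HU = slope * stored + intercept}, the DICOM rescale
#' equation, to stored pixel values.
#'
#' @param stored numeric array or vector of stored values
#' @param slope RescaleSlope
#' @param intercept RescaleIntercept
#' @return values in HU
#' @examples
#' applyRescale(1024, 1, -1024)  # 0 HU
#' @export
applyRescale <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}

#' Write a CTVolume to NIfTI
#'
#' @param volume a [CTVolume-class]
#' @param path output path (.nii or .nii.gz)
#' @return \code{path}, invisibly
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@voxels)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Load a label map and semantics into a MaskSet
#'
#' Reads a NIfTI label image and validates it against a companion volume
#' (congruent shape; spacing agreement within \code{tol} mm — no resampling
#' is performed, aligning the maps is the upstream segmenter's job) and the
#' role registry. Every nonzero label must have a role in \code{semantics}.
#'
#' @param path path to a NIfTI label image
#' @param semantics named integer vector (role name -> label), or the path
#'   of a YAML file of \code{role: label} pairs
#' @param volume optional companion [CTVolume-class] for congruence checks
#' @param tol spacing agreement tolerance in mm (default 1e-3)
#' @return a [MaskSet-class]
#' @export
loadMaskSet <- function(path, semantics = integer(0), volume = NULL,
                        tol = 1e-3) {
  if (!file.exists(path))
    stop(sprintf("no such file: %s", path))
  if (is.character(semantics) && length(semantics) == 1L) {
    sl <- yaml::read_yaml(semantics)
    semantics <- stats::setNames(as.integer(unlist(sl)), names(sl))
  }
  img <- RNifti::readNifti(path)
  lm <- array(as.integer(img), dim(img))
  ms <- maskSet(lm, semantics, spacing = RNifti::pixdim(img)[1:3])
  if (!is.null(volume)) {
    if (!identical(dim(lm), dim(volume@voxels)))
      stop("labelmap shape does not match companion volume")
    if (any(abs(ms@spacing - volume@spacing) > tol))
      stop(sprintf("labelmap spacing differs from volume beyond %g mm", tol))
  }
  ms
}

#' Write a MaskSet to NIfTI (plus a YAML semantics file)
#'
#' @param masks a [MaskSet-class]
#' @param path output NIfTI path
#' @param semanticsPath optional YAML path for the role -> label mapping
#' @return \code{path}, invisibly
#' @export
writeMaskSet <- function(masks, path, semanticsPath = NULL) {
  img <- RNifti::asNifti(masks@labelmap)
  RNifti::pixdim(img) <- masks@spacing
  RNifti::writeNifti(img, path, datatype = "int32")
  if (!is.null(semanticsPath)) {
    sem <- as.list(masks@semantics)
    yaml::write_yaml(sem, semanticsPath)
  }
  invisible(path)
}

#' Mean HU, voxel count and physical volume over a masked region
#'
#' @param volume a [CTVolume-class]
#' @param mask logical array congruent with the volume
#' @return list with \code{mean_hu}, \code{n_voxels}, \code{volume_mm3};
#'   an empty mask yields \code{mean_hu = NA} and zero count/volume so
#'   callers can map absent regions to \code{not_evaluated}
#' @export
maskedStatistics <- function(volume, mask) {
  stopifnot(identical(dim(mask), dim(volume@voxels)))
  n <- sum(mask)
  if (n == 0L)
    return(list(mean_hu = NA_real_, n_voxels = 0L, volume_mm3 = 0))
  list(mean_hu = mean(volume@voxels[mask]),
       n_voxels = as.integer(n),
       volume_mm3 = n * voxelVolume(volume))
}
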