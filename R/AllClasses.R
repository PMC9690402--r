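#' @import methods
NULL

#' CTVolume: a CT volume in Hounsfield units
#'
#' Container for a 3-D scalar voxel grid in Hounsfield units (HU) together
#' with its physical voxel spacing and origin. Axial slices are indexed by
#' the third (z) array dimension; voxel indices are interpreted with voxel
#' \code{(i, j, k)} centered at \code{origin + (c(i, j, k) - 0.5) * spacing}
#' millimetres. All analyzers compute physical quantities through the
#' spacing, never through voxel counts alone.
#'
#' @slot voxels 3-D numeric array of HU values (finite).
#' @slot spacing numeric(3), voxel spacing in mm along (x, y, z); strictly
#'   positive.
#' @slot origin numeric(3), physical position of the corner of the first
#'   voxel in mm.
#'
#' @seealso [loadVolume()], [maskedStatistics()], [voxelVolume()]
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("CTVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L)
    return("voxels must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  if (anyNA(v) || any(!is.finite(v)))
    return("voxel HU values must be finite")
  TRUE
})

#' MaskSet: named integer label maps aligned to a CTVolume
#'
#' An integer label map congruent with a companion [CTVolume-class], plus a
#' semantics table mapping each nonzero label to an anatomical role name
#' (e.g. \code{lung_left}, \code{coronary}, \code{vertebra_L1}). Role names
#' are validated against a closed registry (see [roleRegistry()]).
#'
#' @slot labelmap 3-D integer array; 0 is background.
#' @slot semantics named integer vector: names are role names, values are
#'   the corresponding labels.
#' @slot spacing numeric(3) voxel spacing in mm, used for congruence checks
#'   against the companion volume.
#'
#' @seealso [loadMaskSet()], [maskRole()], [roles()]
#' @export
setClass("MaskSet",
  representation(labelmap = "array", semantics = "integer",
                 spacing = "numeric"),
  prototype(spacing = c(1, 1, 1)))

setValidity("MaskSet", function(object) {
  lm <- object@labelmap
  if (length(dim(lm)) != 3L)
    return("labelmap must be a 3-D array")
  if (!is.integer(lm))
    return("labelmap must be integer")
  sem <- object@semantics
  if (length(sem) && (is.null(names(sem)) || any(!nzchar(names(sem)))))
    return("semantics must be a named integer vector (role -> label)")
  if (anyDuplicated(names(sem)))
    return("duplicate role names in semantics")
  if (anyDuplicated(sem))
    return("duplicate labels in semantics")
  present <- setdiff(unique(as.vector(lm)), 0L)
  missing <- setdiff(present, sem)
  if (length(missing))
    return(sprintf("labels present in labelmap but absent from semantics: %s",
                   paste(missing, collapse = ", ")))
  bad <- .invalidRoles(names(sem))
  if (length(bad))
    return(sprintf("role names not in registry: %s",
                   paste(bad, collapse = ", ")))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values (mm)")
  TRUE
})

#' BiomarkerResult: one measured quantity with status and recommendation
#'
#' A single biomarker measurement: value, units, traffic-light status
#' (\code{green}/\code{yellow}/\code{red}/\code{not_evaluated}), a category
#' label (e.g. "Moderate CAC"), recommendation text, and provenance (the
#' analyzer name and parameters that produced it). A missing value always
#' carries status \code{not_evaluated}.
#'
#' @slot name character identifier, e.g. \code{"CAC"}.
#' @slot value numeric scalar or \code{NA} when not evaluated.
#' @slot units character, e.g. \code{"cm^2"}; may be \code{""}.
#' @slot status one of \code{"green"}, \code{"yellow"}, \code{"red"},
#'   \code{"not_evaluated"}.
#' @slot categoryLabel free-text category, e.g. \code{"Moderate CAC"}.
#' @slot recommendation free-text recommendation.
#' @slot provenance list: analyzer name and parameters.
#'
#' @export
setClass("BiomarkerResult",
  representation(name = "character", value = "numeric", units = "character",
                 status = "character", categoryLabel = "character",
                 recommendation = "character", provenance = "list"),
  prototype(value = NA_real_, units = "", status = "not_evaluated",
            categoryLabel = "", recommendation = "", provenance = list()))

setValidity("BiomarkerResult", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a non-empty string")
  if (length(object@value) != 1L)
    return("value must be a scalar (possibly NA)")
  if (!object@status %in% c("green", "yellow", "red", "not_evaluated"))
    return("invalid status")
  if (is.na(object@value) != (object@status == "not_evaluated"))
    return("status must be not_evaluated iff value is missing")
  TRUE
})

#' ReferenceRange: three-way banding of a biomarker value
#'
#' Defines green (normal) and yellow (borderline) intervals for a biomarker;
#' everything else is red. Boundary values belong to the greener band.
#' \code{direction} records whether high values, low values or both are
#' abnormal; one-sided ranges use \code{-Inf}/\code{Inf} bounds.
#'
#' @slot name biomarker name the range applies to.
#' @slot green numeric(2) inclusive interval \code{[lo, hi]}.
#' @slot yellow numeric(2) inclusive outer interval containing the green one.
#' @slot direction one of \code{"high_bad"}, \code{"low_bad"},
#'   \code{"two_sided"}.
#' @slot source free-text note on where the range comes from.
#'
#' @seealso [band()]
#' @export
setClass("ReferenceRange",
  representation(name = "character", green = "numeric", yellow = "numeric",
                 direction = "character", source = "character"),
  prototype(direction = "two_sided", source = ""))

setValidity("ReferenceRange", function(object) {
  if (length(object@green) != 2L || length(object@yellow) != 2L)
    return("green and yellow must be length-2 intervals")
  if (object@green[1] > object@green[2])
    return("green interval reversed")
  if (object@yellow[1] > object@green[1] || object@yellow[2] < object@green[2])
    return("yellow interval must contain the green interval")
  if (!object@direction %in% c("high_bad", "low_bad", "two_sided"))
    return("invalid direction")
  TRUE
})

#' Calibration: HU to hydroxyapatite density conversion line
#'
#' Linear calibration \code{density = slope * HU + intercept} fitted by least
#' squares over reference rods of known hydroxyapatite (HA) density.
#'
#' @slot slope (mg/cm^3)/HU.
#' @slot intercept mg/cm^3.
#' @slot rods data.frame with columns \code{density} (known, mg/cm^3) and
#'   \code{hu} (measured rod mean HU).
#' @slot residual root-mean-square fit residual in mg/cm^3.
#'
#' @seealso [calibrateBMD()], [bmdTscore()]
#' @export
setClass("Calibration",
  representation(slope = "numeric", intercept = "numeric",
                 rods = "data.frame", residual = "numeric"),
  prototype(rods = data.frame(density = numeric(0), hu = numeric(0)),
            residual = NA_real_))

setValidity("Calibration", function(object) {
  if (length(object@slope) != 1L || !is.finite(object@slope))
    return("slope must be a finite scalar")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a finite scalar")
  TRUE
})

#' ReportDocument: structured multi-comorbidity report
#'
#' Ordered collection of per-comorbidity sections, each a list of
#' [BiomarkerResult-class] objects plus a conclusion text; every analyzer
#' that was scheduled contributes exactly one section (analyzers that could
#' not run contribute \code{not_evaluated} results, never a silent omission).
#'
#' @slot meta list of opaque study identifiers.
#' @slot sections named list; each element has \code{title},
#'   \code{results} (list of BiomarkerResult) and \code{conclusion}.
#' @slot thumbnails character vector of image file references.
#' @slot provenance list: package version and merged parameters.
#'
#' @seealso [assembleReport()], [renderReport()], [runStudy()]
#' @export
setClass("ReportDocument",
  representation(meta = "list", sections = "list", thumbnails = "character",
                 provenance = "list"),
  prototype(thumbnails = character(0)))

setValidity("ReportDocument", function(object) {
  if (!length(object@sections))
    return("report must contain at least one section")
  for (nm in names(object@sections)) {
    s <- object@sections[[nm]]
    if (!all(c("title", "results", "conclusion") %in% names(s)))
      return(sprintf("section '%s' missing title/results/conclusion", nm))
    if (!all(vapply(s$results, is, logical(1), class2 = "BiomarkerResult")))
      return(sprintf("section '%s' results must be BiomarkerResult", nm))
  }
  TRUE
})

#' PhantomSpec: parameters of the synthetic CT phantom
#'
#' Validated parameter set for [generatePhantom()]. Use [phantomSpec()] to
#' construct one; the defaults describe a desk-scale chest-abdomen phantom
#' with body, fat compartments, liver, lungs, vessels with calcified
#' plaques, vertebrae, calibration rods and one pulmonary nodule.
#'
#' @slot pars named list of parameters (see [phantomSpec()]).
#' @export
setClass("PhantomSpec", representation(pars = "list"))

#' GroundTruthManifest: analytically known phantom quantities
#'
#' Record of every expected value for a generated phantom: fat areas per
#' compartment, liver mean HU, per-compartment Agatston/volume scores
#' (computed by the module-independent voxel oracle), lung volume, mean lung
#' density and emphysema fraction, PRM fractions where an expiratory pair
#' was generated, nodule diameters/volumes, rod means with the calibration
#' line, and vertebral trabecular HU.
#'
#' @slot values named list of expected quantities.
#' @export
setClass("GroundTruthManifest", representation(values = "list"))
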