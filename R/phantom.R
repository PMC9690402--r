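#' Specify a synthetic chest-abdomen CT phantom
#'
#' Builds a validated [PhantomSpec-class] whose geometry (all in mm,
#' derived from the grid extent) describes a desk-scale phantom: an
#' elliptical body with subcutaneous fat ring, muscle band with
#' intermuscular fat islands, a visceral compartment with a fat disk, a
#' liver sphere, two lung ellipsoids (optionally with an emphysema and an
#' fSAD voxel class), thoracolumbar vertebrae with cortical shell and
#' trabecular core, coronary and aortic vessels carrying calcified
#' plaques, hydroxyapatite calibration rods, and one pulmonary nodule.
#' Every structure's expected measurement is recorded analytically or by
#' the built-in voxel oracle in the [GroundTruthManifest-class] that
#' [generatePhantom()] returns.
#'
#' Overlapping structures are rasterized under the fixed precedence
#' plaques > nodules > rods > vessels > organs > fat > body, so each voxel
#' has one deterministic label and HU. Gaussian noise (sd \code{noise_sd}
#' HU) is applied last, to the volume only, never to the masks.
#'
#' @param shape integer(3) grid shape (default \code{c(96, 96, 84)})
#' @param spacing numeric(3) voxel spacing in mm (default
#'   \code{c(1.5, 1.5, 2.5)})
#' @param seed RNG seed controlling voxel-class sampling and noise
#' @param noise_sd additive Gaussian noise sd in HU (default 0)
#' @param emphysema_fraction fraction of lung voxels set to
#'   \code{emphysema_hu} (default 0)
#' @param fsad_fraction fraction of lung voxels in the fSAD class (only
#'   visible in the expiratory volume; default 0)
#' @param emphysema_hu HU of emphysematous lung voxels (default -980)
#' @param plaques list of plaques, each a list with \code{compartment}
#'   (\code{"coronary"}, \code{"thoracic_aorta"} or
#'   \code{"abdominal_aorta"}), \code{area_mm2}, \code{peak_hu},
#'   \code{n_slices}, and optionally \code{offset_mm} (in-plane offset
#'   from the vessel axis) and \code{z_frac} (position along the vessel);
#'   \code{NULL} gives one default plaque per compartment
#' @param nodules list of nodules, each a list with \code{diameters_mm}
#'   (x, y, z) and \code{hu}; \code{NULL} gives one default nodule
#' @param liver_hu liver attenuation in HU (default 54)
#' @param lung_hu base lung attenuation (default -850)
#' @param trabecular_hu vertebral trabecular HU (default 110)
#' @param rod_densities hydroxyapatite rod densities in mg/cm^3
#' @param rod_slope,rod_intercept generating calibration line
#'   \code{density = slope * HU + intercept} used to set rod HU
#' @param fat_hu adipose tissue HU (default -100)
#' @param geometry named list merged recursively over the derived
#'   geometry (e.g. \code{list(visceral_fat = list(radius = 5))}) for
#'   fixtures with analytically chosen shapes
#' @return a [PhantomSpec-class]
#' @seealso [generatePhantom()], [generateExpiratoryPair()],
#'   [writePhantomFixture()]
#' @export
phantomSpec <- function(shape = c(96, 96, 84), spacing = c(1.5, 1.5, 2.5),
                        seed = 1L, noise_sd = 0,
                        emphysema_fraction = 0, fsad_fraction = 0,
                        emphysema_hu = -980,
                        plaques = NULL, nodules = NULL,
                        liver_hu = 54, lung_hu = -850,
                        trabecular_hu = 110,
                        rod_densities = c(0, 100, 200),
                        rod_slope = 1, rod_intercept = -10,
                        fat_hu = -100, geometry = list()) {
  stopifnot(length(shape) == 3L, all(shape >= 16),
            length(spacing) == 3L, all(spacing > 0),
            noise_sd >= 0,
            emphysema_fraction >= 0, fsad_fraction >= 0,
            emphysema_fraction + fsad_fraction <= 1)
  E <- shape * spacing
  m <- min(E[1], E[2])
  if (is.null(plaques)) {
    plaques <- list(
      list(compartment = "coronary", area_mm2 = 10, peak_hu = 250,
           n_slices = 2),
      list(compartment = "thoracic_aorta", area_mm2 = 20, peak_hu = 450,
           n_slices = 3),
      list(compartment = "abdominal_aorta", area_mm2 = 15, peak_hu = 320,
           n_slices = 2))
  }
  if (is.null(nodules)) {
    nodules <- list(list(diameters_mm = c(5, 6, 7), hu = 20))
  }
  pars <- list(
    shape = as.integer(shape), spacing = as.numeric(spacing),
    seed = as.integer(seed), noise_sd = noise_sd,
    air_hu = -1000, soft_hu = 30, muscle_hu = 45, blood_hu = 40,
    fat_hu = fat_hu, liver_hu = liver_hu, lung_hu = lung_hu,
    emphysema_hu = emphysema_hu,
    emphysema_fraction = emphysema_fraction,
    fsad_fraction = fsad_fraction,
    cortical_hu = 400, trabecular_hu = trabecular_hu,
    body = list(center = c(0.5, 0.48) * E[1:2],
                semiaxes = c(0.42 * E[1], 0.33 * E[2])),
    subcutaneous_scale = 0.85,
    muscle_scale = 0.72,
    visceral_fat = list(center = c(0.62 * E[1], 0.40 * E[2]),
                        radius = 0.12 * m),
    imat = list(radius = 0.035 * m, angles = c(40, 140) * pi / 180,
                band_scale = 0.785),
    liver = list(center = c(0.35 * E[1], 0.40 * E[2], 0.30 * E[3]),
                 radius = 0.11 * min(E)),
    lungs = list(centers = list(c(0.28 * E[1], 0.45 * E[2], 0.75 * E[3]),
                                c(0.72 * E[1], 0.45 * E[2], 0.75 * E[3])),
                 semiaxes = c(0.15 * E[1], 0.21 * E[2], 0.21 * E[3])),
    vertebrae = list(center_xy = c(0.5 * E[1], 0.67 * E[2]),
                     radius = 0.08 * m,
                     shell_mm = min(2, 0.3 * 0.08 * m),
                     levels = c("L3", "L2", "L1", "T12", "T11"),
                     z0_frac = 0.08, height_frac = 0.105,
                     gap_frac = 0.015),
    vessels = list(
      coronary = list(center_xy = c(0.50 * E[1], 0.40 * E[2]),
                      radius = min(3.5, 0.030 * m),
                      z_frac = c(0.55, 0.68)),
      thoracic_aorta = list(center_xy = c(0.50 * E[1], 0.52 * E[2]),
                            radius = min(10, 0.055 * m),
                            z_frac = c(0.52, 0.98)),
      abdominal_aorta = list(center_xy = c(0.50 * E[1], 0.52 * E[2]),
                             radius = min(8, 0.045 * m),
                             z_frac = c(0.02, 0.48))),
    plaques = plaques,
    nodules = nodules,
    rods = list(densities = as.numeric(rod_densities),
                slope = rod_slope, intercept = rod_intercept,
                radius = min(5, 0.035 * m),
                x_frac = seq(0.3, 0.7, length.out = length(rod_densities)),
                y = 0.48 * E[2] + 0.33 * E[2] + min(5, 0.035 * m) + 2),
    abdomen_z_frac = c(0, 0.48),
    extent = E)
  if (length(geometry))
    pars <- utils::modifyList(pars, geometry)
  new("PhantomSpec", pars = pars)
}

# Rasterize the spec into HU/label arrays plus lung voxel classes.
# Deterministic given the current RNG state (class sampling only).
.rasterizePhantom <- function(p) {
  nx <- p$shape[1]; ny <- p$shape[2]; nz <- p$shape[3]
  sp <- p$spacing
  xc <- (seq_len(nx) - 0.5) * sp[1]
  yc <- (seq_len(ny) - 0.5) * sp[2]
  zc <- (seq_len(nz) - 0.5) * sp[3]
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  hu <- array(p$air_hu, c(nx, ny, nz))
  lab <- array(0L, c(nx, ny, nz))
  sem <- integer(0)
  addRole <- function(role) {
    sem[[role]] <<- length(sem) + 1L
    sem[[role]]
  }
  ellipse2 <- function(center, semi)
    ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 <= 1
  disk2 <- function(center, r)
    (X - center[1])^2 + (Y - center[2])^2 <= r^2
  zIdx <- function(zr) which(zc >= zr[1] & zc <= zr[2])
  paint <- function(mask2, zs, huval, label = 0L) {
    for (z in zs) {
      sl <- hu[, , z]; sl[mask2] <- huval; hu[, , z] <<- sl
      if (label > 0L) {
        sl <- lab[, , z]; sl[mask2] <- label; lab[, , z] <<- sl
      }
    }
  }

  allZ <- seq_len(nz)
  abdomenZ <- zIdx(p$abdomen_z_frac * p$extent[3])
  body <- ellipse2(p$body$center, p$body$semiaxes)
  paint(body, allZ, p$soft_hu)

  # fat compartments (abdominal slices)
  sub_in <- ellipse2(p$body$center, p$body$semiaxes * p$subcutaneous_scale)
  paint(body & !sub_in, abdomenZ, p$fat_hu,
        addRole("subcutaneous_compartment"))
  mus_in <- ellipse2(p$body$center, p$body$semiaxes * p$muscle_scale)
  band <- sub_in & !mus_in
  paint(band, abdomenZ, p$muscle_hu, addRole("intermuscular_compartment"))
  for (a in p$imat$angles) {
    c2 <- p$body$center + p$imat$band_scale * p$body$semiaxes *
      c(cos(a), sin(a))
    paint(band & disk2(c2, p$imat$radius), abdomenZ, p$fat_hu)
  }
  paint(mus_in, abdomenZ, p$soft_hu, addRole("visceral_compartment"))
  vf <- mus_in & disk2(p$visceral_fat$center, p$visceral_fat$radius)
  paint(vf, abdomenZ, p$fat_hu)

  # liver sphere
  lv <- p$liver
  liverLab <- addRole("liver")
  for (z in allZ) {
    dz2 <- lv$radius^2 - (zc[z] - lv$center[3])^2
    if (dz2 <= 0) next
    paint(disk2(lv$center[1:2], sqrt(dz2)), z, p$liver_hu, liverLab)
  }

  # lungs; the low-x lung is the patient's right under LPS-style axes
  lungLabs <- c(addRole("lung_right"), addRole("lung_left"))
  lg <- p$lungs
  for (i in 1:2) {
    cen <- lg$centers[[i]]
    for (z in allZ) {
      f <- 1 - ((zc[z] - cen[3]) / lg$semiaxes[3])^2
      if (f <= 0) next
      paint(ellipse2(cen[1:2], sqrt(f) * lg$semiaxes[1:2]), z,
            p$lung_hu, lungLabs[i])
    }
  }

  # vertebrae: cortical shell around trabecular core
  vb <- p$vertebrae
  outer2 <- disk2(vb$center_xy, vb$radius)
  core2 <- disk2(vb$center_xy, vb$radius - vb$shell_mm)
  z0 <- vb$z0_frac * p$extent[3]
  for (i in seq_along(vb$levels)) {
    lo <- z0 + (i - 1) * (vb$height_frac + vb$gap_frac) * p$extent[3]
    hi <- lo + vb$height_frac * p$extent[3]
    zs <- zIdx(c(lo, hi))
    if (!length(zs)) next
    vlab <- addRole(paste0("vertebra_", vb$levels[i]))
    paint(outer2, zs, p$cortical_hu, vlab)
    paint(core2, zs, p$trabecular_hu, vlab)
  }

  # vessels
  for (nm in names(p$vessels)) {
    vs <- p$vessels[[nm]]
    paint(disk2(vs$center_xy, vs$radius), zIdx(vs$z_frac * p$extent[3]),
          p$blood_hu, addRole(nm))
  }

  # calibration rods
  rd <- p$rods
  for (k in seq_along(rd$densities)) {
    cx <- rd$x_frac[k] * p$extent[1]
    huk <- (rd$densities[k] - rd$intercept) / rd$slope
    paint(disk2(c(cx, rd$y), rd$radius), allZ, huk,
          addRole(paste0("calibration_rod_", k)))
  }

  # nodules (inside the low-x lung by default)
  for (k in seq_along(p$nodules)) {
    nd <- p$nodules[[k]]
    cen <- if (!is.null(nd$center_mm)) nd$center_mm else
      lg$centers[[1]] + c(0, 0, 0.07 * p$extent[3])
    nlab <- addRole(paste0("nodule_", k))
    for (z in allZ) {
      f <- 1 - ((zc[z] - cen[3]) / (nd$diameters_mm[3] / 2))^2
      if (f <= 0) next
      paint(ellipse2(cen[1:2], sqrt(f) * nd$diameters_mm[1:2] / 2), z,
            nd$hu, nlab)
    }
  }

  # lung voxel classes (seeded sampling; uses the active RNG stream)
  lungIdx <- which(lab == lungLabs[1] | lab == lungLabs[2])
  classes <- list(emphysema = integer(0), fsad = integer(0),
                  normal = lungIdx)
  nL <- length(lungIdx)
  if (nL && (p$emphysema_fraction > 0 || p$fsad_fraction > 0)) {
    perm <- sample(lungIdx)
    ne <- round(p$emphysema_fraction * nL)
    nf <- round(p$fsad_fraction * nL)
    classes$emphysema <- sort(perm[seq_len(ne)])
    classes$fsad <- if (nf) sort(perm[ne + seq_len(nf)]) else integer(0)
    classes$normal <- sort(perm[setdiff(seq_len(nL), seq_len(ne + nf))])
    hu[classes$emphysema] <- p$emphysema_hu
  }

  # plaques last: highest precedence, HU only (they stay inside the
  # vessel label so detection sees them in their compartment)
  for (pl in p$plaques) {
    vs <- p$vessels[[pl$compartment]]
    if (is.null(vs)) stop("unknown plaque compartment: ", pl$compartment)
    r <- min(sqrt(pl$area_mm2 / pi), vs$radius)
    cen <- vs$center_xy
    if (!is.null(pl$offset_mm)) cen <- cen + pl$offset_mm
    zr <- vs$z_frac * p$extent[3]
    zmid <- if (!is.null(pl$z_frac)) zr[1] + pl$z_frac * diff(zr)
            else mean(zr)
    zs <- zIdx(c(zmid, zmid + (pl$n_slices - 1) * sp[3] + 1e-9))
    zs <- zs[seq_len(min(length(zs), pl$n_slices))]
    vlab <- sem[[pl$compartment]]
    d2 <- disk2(cen, r)
    for (z in zs) {
      sl <- hu[, , z]
      sel <- d2 & (lab[, , z] == vlab)
      sl[sel] <- pl$peak_hu
      hu[, , z] <- sl
    }
  }

  storage.mode(lab) <- "integer"
  list(hu = hu, lab = lab, sem = sem, classes = classes,
       lungLabs = lungLabs)
}

# Ground-truth manifest from the noise-free rasterization.
.phantomManifest <- function(p, ras) {
  sp <- p$spacing
  pxArea <- sp[1] * sp[2]
  vxVol <- prod(sp)
  hu <- ras$hu; lab <- ras$lab; sem <- ras$sem
  man <- list(seed = p$seed, noise_sd = p$noise_sd)

  # L2/L3 slice + fat areas (counting oracle on the labelmap)
  if (all(c("vertebra_L2", "vertebra_L3") %in% names(sem))) {
    cz <- vapply(c("vertebra_L2", "vertebra_L3"), function(r) {
      w <- which(lab == sem[[r]], arr.ind = TRUE)
      mean(w[, 3])
    }, numeric(1))
    z <- as.integer(round(mean(cz)))
    man$l2l3_slice <- z
    inwin <- hu[, , z] >= -190 & hu[, , z] <= -30
    man$fat_areas_cm2 <- list(
      VFA = sum(inwin & lab[, , z] == sem[["visceral_compartment"]]) *
        pxArea / 100,
      SFA = sum(inwin & lab[, , z] == sem[["subcutaneous_compartment"]]) *
        pxArea / 100,
      IMAT = sum(inwin & lab[, , z] == sem[["intermuscular_compartment"]]) *
        pxArea / 100)
  }

  if ("liver" %in% names(sem))
    man$liver_mean_hu <- mean(hu[lab == sem[["liver"]]])

  # calcium scores from the module-independent voxel oracle
  vol <- ctVolume(hu, spacing = sp)
  ms <- maskSet(lab, sem, spacing = sp)
  man$agatston <- agatstonOracle(vol, ms)

  # lung densitometry
  lung <- lab == ras$lungLabs[1] | lab == ras$lungLabs[2]
  if (any(lung)) {
    lhu <- hu[lung]
    man$lung <- list(
      lung_volume_cm3 = sum(lung) * vxVol / 1000,
      mld_hu = mean(lhu),
      emphysema_index = 100 * sum(lhu < -950) / length(lhu))
    ncl <- lengths(ras$classes)
    man$prm <- list(
      emphysema = 100 * ncl[["emphysema"]] / sum(lung),
      fsad = 100 * ncl[["fsad"]] / sum(lung),
      normal = 100 * ncl[["normal"]] / sum(lung))
  }

  # nodules: analytic diameters + rasterized voxel volume
  man$nodules <- lapply(seq_along(p$nodules), function(k) {
    nd <- p$nodules[[k]]
    role <- paste0("nodule_", k)
    list(id = k, diameters_mm = nd$diameters_mm,
         ellipsoid_volume_mm3 = pi / 6 * prod(nd$diameters_mm),
         voxel_volume_mm3 = sum(lab == sem[[role]]) * vxVol)
  })

  # rods and the generating calibration line
  rodRoles <- grep("^calibration_rod_", names(sem), value = TRUE)
  man$rods <- list(
    densities = p$rods$densities,
    mean_hu = vapply(rodRoles, function(r) mean(hu[lab == sem[[r]]]),
                     numeric(1)),
    slope = p$rods$slope, intercept = p$rods$intercept)

  man$trabecular_hu <- p$trabecular_hu
  man
}

#' Generate a synthetic phantom with ground truth
#'
#' Rasterizes a [phantomSpec()] into a noise-free volume and label map,
#' computes the ground-truth manifest (analytic geometry plus the
#' brute-force voxel oracle for areas and calcium scores), then adds
#' seeded Gaussian noise to the volume only. Bit-identical output for a
#' fixed spec (the spec's seed drives both class sampling and noise; the
#' caller's RNG state is left untouched).
#'
#' @param spec a [PhantomSpec-class]
#' @return list with \code{volume} ([CTVolume-class]), \code{masks}
#'   ([MaskSet-class]) and \code{manifest}
#'   ([GroundTruthManifest-class])
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(48, 48, 32), seed = 7))
#' ph$masks
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  p <- spec@pars
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(p$seed)
  ras <- .rasterizePhantom(p)
  man <- .phantomManifest(p, ras)
  hu <- ras$hu
  if (p$noise_sd > 0)
    hu <- hu + stats::rnorm(length(hu), 0, p$noise_sd)
  list(volume = ctVolume(hu, spacing = p$spacing),
       masks = maskSet(ras$lab, ras$sem, spacing = p$spacing),
       manifest = new("GroundTruthManifest", values = man))
}

#' Generate a voxel-aligned inspiratory/expiratory phantom pair
#'
#' The expiratory volume re-maps each lung voxel class to its expiratory
#' HU (defaults: normal -800, emphysema -900, fSAD -880 HU), so the PRM
#' class fractions are known exactly; all other voxels are unchanged.
#' Independent seeded noise is added to each volume.
#'
#' @param spec a [PhantomSpec-class] (its \code{emphysema_fraction} /
#'   \code{fsad_fraction} define the classes)
#' @param shiftRule named list of expiratory HU per class:
#'   \code{normal}, \code{emphysema}, \code{fsad}
#' @return list with \code{insp}, \code{exp} (both [CTVolume-class]),
#'   \code{masks} and \code{manifest}
#' @export
generateExpiratoryPair <- function(spec,
                                   shiftRule = list(normal = -800,
                                                    emphysema = -900,
                                                    fsad = -880)) {
  stopifnot(is(spec, "PhantomSpec"))
  p <- spec@pars
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(p$seed)
  ras <- .rasterizePhantom(p)
  man <- .phantomManifest(p, ras)
  ihu <- ras$hu
  ehu <- ras$hu
  for (cl in c("normal", "emphysema", "fsad"))
    ehu[ras$classes[[cl]]] <- shiftRule[[cl]]
  if (p$noise_sd > 0) {
    ihu <- ihu + stats::rnorm(length(ihu), 0, p$noise_sd)
    ehu <- ehu + stats::rnorm(length(ehu), 0, p$noise_sd)
  }
  list(insp = ctVolume(ihu, spacing = p$spacing),
       exp = ctVolume(ehu, spacing = p$spacing),
       masks = maskSet(ras$lab, ras$sem, spacing = p$spacing),
       manifest = new("GroundTruthManifest", values = man))
}

#' Write a phantom fixture to disk
#'
#' Writes \code{ct.nii.gz}, \code{masks.nii.gz}, \code{semantics.yaml} and
#' \code{manifest.json} (plus \code{exp.nii.gz} for an expiratory pair)
#' into \code{dir}; all re-loadable with [loadVolume()], [loadMaskSet()]
#' and [readManifest()].
#'
#' @param dir output directory (created if needed)
#' @param spec a [PhantomSpec-class]
#' @param expiratory write an expiratory pair as well
#' @return character vector of the files written, invisibly
#' @export
writePhantomFixture <- function(dir, spec, expiratory = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- if (expiratory) generateExpiratoryPair(spec) else
    generatePhantom(spec)
  vol <- if (expiratory) ph$insp else ph$volume
  files <- file.path(dir, c("ct.nii.gz", "masks.nii.gz", "semantics.yaml",
                            "manifest.json"))
  writeVolume(vol, files[1])
  writeMaskSet(ph$masks, files[2], semanticsPath = files[3])
  jsonlite::write_json(manifestValues(ph$manifest), files[4],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (expiratory) {
    files <- c(files, file.path(dir, "exp.nii.gz"))
    writeVolume(ph$exp, files[5])
  }
  invisible(files)
}

#' Read a phantom manifest back from JSON
#'
#' @param path path to \code{manifest.json}
#' @return a [GroundTruthManifest-class]
#' @export
readManifest <- function(path) {
  new("GroundTruthManifest",
      values = jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Random calcium phantom for oracle-equivalence checks
#'
#' Small phantom spec with randomized plaque burden (count, area, peak HU,
#' slice extent and in-plane offset per vascular compartment), used to
#' exercise the Agatston pathway against the independent voxel oracle.
#'
#' @param seed RNG seed
#' @param shape grid shape (default \code{c(48, 48, 24)})
#' @param spacing voxel spacing in mm (default \code{c(1, 1, 2.5)})
#' @return a [PhantomSpec-class]
#' @export
randomCalciumSpec <- function(seed, shape = c(48, 48, 24),
                              spacing = c(1, 1, 2.5)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  plaques <- list()
  for (comp in c("coronary", "thoracic_aorta", "abdominal_aorta")) {
    for (i in seq_len(sample(0:3, 1))) {
      plaques[[length(plaques) + 1L]] <- list(
        compartment = comp,
        area_mm2 = stats::runif(1, 0.5, 25),
        peak_hu = stats::runif(1, 100, 800),
        n_slices = sample(1:3, 1),
        offset_mm = stats::runif(2, -1.5, 1.5),
        z_frac = stats::runif(1, 0.2, 0.8))
    }
  }
  phantomSpec(shape = shape, spacing = spacing, seed = seed,
              plaques = plaques,
              nodules = list(list(diameters_mm = c(4, 4, 5), hu = 20)))
}
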