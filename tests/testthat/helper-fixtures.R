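# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# Small default phantom used by several suites.
smallPhantom <- function(seed = 1, ...) {
  generatePhantom(phantomSpec(shape = c(48, 48, 32),
                              spacing = c(1.5, 1.5, 2.5),
                              seed = seed, ...))
}

# Minimal volume + maskset with a single rectangular coronary vessel and
# hand-placed plaque pixels, for exact-by-construction calcium tests.
coronaryFixture <- function(plaquePixels, plaqueHU = 250,
                            spacing = c(1, 1, 1), shape = c(24, 24, 6),
                            boneExclusion = NULL) {
  hu <- array(40, shape)
  lab <- array(0L, shape)
  lab[5:20, 5:20, ] <- 1L  # coronary compartment
  sem <- c(coronary = 1L)
  for (p in plaquePixels) hu[p[1], p[2], p[3]] <- plaqueHU
  if (!is.null(boneExclusion)) {
    lab[boneExclusion] <- 2L
    sem <- c(sem, bone_exclusion = 2L)
  }
  list(volume = ctVolume(hu, spacing = spacing),
       masks = maskSet(lab, sem, spacing = spacing))
}

# Binary sphere mask of the given diameter (mm) centered in a grid.
sphereMask <- function(diameter, spacing, shape) {
  r <- diameter / 2
  cen <- shape * spacing / 2
  x <- (seq_len(shape[1]) - 0.5) * spacing[1]
  y <- (seq_len(shape[2]) - 0.5) * spacing[2]
  z <- (seq_len(shape[3]) - 0.5) * spacing[3]
  X <- array(rep(x, times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(y, each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(z, each = shape[1] * shape[2]), shape)
  (X - cen[1])^2 + (Y - cen[2])^2 + (Z - cen[3])^2 <= r^2
}
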