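#' Write an axial thumbnail PNG with optional mask overlay
#'
#' Grayscale rendering of one axial slice (window/level applied) with an
#' optional red overlay of a role mask, for attaching flagged findings to
#' the report. Requires the \pkg{png} package; thumbnail generation is
#' optional and reports render without it.
#'
#' @param volume a [CTVolume-class]
#' @param z axial slice index
#' @param path output PNG path
#' @param masks optional [MaskSet-class]
#' @param overlayRole optional role name to overlay in red
#' @param window display window in HU (default \code{c(-1000, 400)})
#' @return \code{path}, invisibly
#' @export
writeThumbnail <- function(volume, z, path, masks = NULL,
                           overlayRole = NULL, window = c(-1000, 400)) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for thumbnails")
  sl <- volume@voxels[, , z]
  g <- pmin(pmax((sl - window[1]) / diff(window), 0), 1)
  img <- array(g, c(dim(g), 3))
  if (!is.null(masks) && !is.null(overlayRole)) {
    m <- maskRole(masks, overlayRole, strict = FALSE)[, , z]
    r <- img[, , 1]; r[m] <- 1; img[, , 1] <- r
    for (ch in 2:3) { c0 <- img[, , ch]; c0[m] <- 0.2; img[, , ch] <- c0 }
  }
  # transpose so image rows run along y
  png::writePNG(aperm(img, c(2, 1, 3)), path)
  invisible(path)
}
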