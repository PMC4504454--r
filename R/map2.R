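# MAP2 dendritic-area measurement.
#
# Dendrite area A is the denominator of every per-area density in the
# pipeline (N5AP, protein fluorescence per area, N_mito in vitro). Batches
# of immunostained images differ in gain and offset, so intensities are
# first aligned to a stored reference histogram via two robust anchors (the
# background level and the bright-dendrite level of the reference CDF), then
# thresholded at a fixed level on the reference scale and cleaned
# morphologically. Anchor-based alignment removes gain/offset differences —
# doubling all intensities leaves A unchanged — while preserving the
# image's actual foreground fraction, which full histogram specification
# would destroy.

map2_env <- new.env(parent = emptyenv())

map2_reference <- function() {
  if (!is.null(map2_env$ref)) return(map2_env$ref)
  path <- system.file("extdata", "map2_reference_hist.csv",
                      package = "mgsynapse")
  h <- utils::read.csv(path)
  cdf <- cumsum(h$density) / sum(h$density)
  qf <- function(p) h$bin_center[which(cdf >= p)[1L]]
  ref <- list(bg = qf(0.20), bright = qf(0.995))
  map2_env$ref <- ref
  ref
}

#' Measure MAP2-positive dendritic area
#'
#' @param map2_img 2D [image_stack()] of the MAP2 (dendrite) channel.
#' @param threshold Segmentation threshold as a fraction of the
#'   background-to-bright range on the reference scale (default 0.08).
#' @param clean_brush Diameter (pixels, odd) of the disc used for the
#'   morphological open/close cleaning step.
#' @return The dendrite area in square micron, with the boolean
#'   segmentation mask attached as attribute `"mask"`. An image with no
#'   measurable foreground returns 0 with a warning.
#' @export
measure_map2_area <- function(map2_img, threshold = 0.08, clean_brush = 5L) {
  stopifnot(inherits(map2_img, "ImageStack"))
  mat <- map2_img$data
  if (length(dim(mat)) != 2L) mat <- max_project(map2_img)$data
  theta <- map2_img$theta

  bg <- stats::quantile(mat, 0.20, names = FALSE)
  bright <- stats::quantile(mat, 0.995, names = FALSE)
  if (!is.finite(bright - bg) || bright - bg < 1e-9) {
    warning("MAP2 image has no measurable foreground; area = 0")
    out <- 0
    attr(out, "mask") <- matrix(FALSE, nrow(mat), ncol(mat))
    return(out)
  }
  ref <- map2_reference()
  matched <- (mat - bg) / (bright - bg) * (ref$bright - ref$bg) + ref$bg
  thr <- ref$bg + threshold * (ref$bright - ref$bg)
  mask <- matched > thr

  if (any(mask)) {
    br <- EBImage::makeBrush(as.integer(clean_brush), "disc")
    m <- EBImage::closing(EBImage::opening(mask * 1, br), br)
    mask <- as.matrix(m) > 0.5
  }
  if (!any(mask)) {
    warning("MAP2 segmentation empty after cleaning; area = 0")
  }
  out <- sum(mask) * theta^2
  attr(out, "mask") <- mask
  out
}
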