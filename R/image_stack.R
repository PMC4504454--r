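#' Calibrated image stack
#'
#' The unit of all imaging I/O in the package: a 2D image (`y` by `x`
#' matrix) or a 3D confocal z-stack (`y` by `x` by `z` array) together with
#' its physical calibration — the lateral resolution `theta` (microns per
#' pixel) and the axial step `rho` (microns between z planes) — and a channel
#' label. Pixel indices are 0-based in physical terms: the centre of matrix
#' element `[1, 1]` sits at `(x, y) = (0, 0)` micron and column `j` sits at
#' `x = (j - 1) * theta`.
#'
#' @param data Numeric matrix (`y`, `x`) or 3D array (`y`, `x`, `z`) of
#'   non-negative finite intensities (arbitrary units).
#' @param theta Lateral resolution in micron/pixel (default the confocal
#'   calibration used throughout, 0.05754).
#' @param rho Axial step in micron (default 1).
#' @param channel Channel label, e.g. `"MgGrn"`, `"FM"`, `"DIC"`, `"MAP2"`,
#'   `"JC1-aggr"`, `"JC1-mono"`, `"IF:SYP"`.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(data, theta = 0.05754, rho = 1, channel = "unknown") {
  check_positive(theta, "theta")
  check_positive(rho, "rho")
  if (!is.numeric(data) || !(length(dim(data)) %in% c(2L, 3L))) {
    stop_mgs("`data` must be a numeric matrix or 3D array",
             class = "mgsynapse_validation_error")
  }
  if (any(!is.finite(data))) {
    stop_mgs("image intensities must all be finite",
             class = "mgsynapse_validation_error")
  }
  structure(list(data = data, theta = theta, rho = rho,
                 channel = as.character(channel)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  kind <- if (length(d) == 3L) sprintf("z-stack [%d x %d x %d]", d[1], d[2], d[3])
          else sprintf("image [%d x %d]", d[1], d[2])
  cat(sprintf("<ImageStack> %s channel=%s theta=%.5f um/px rho=%g um\n",
              kind, x$channel, x$theta, x$rho))
  invisible(x)
}

is_stack_3d <- function(stack) length(dim(stack$data)) == 3L

#' Maximum-intensity projection
#'
#' Compresses a z-stack to a single 2D image by taking, per pixel, the
#' maximum intensity over all z planes — the standard way confocal stacks
#' are reduced before punctum counting and branch intensity measurement.
#'
#' @param stack An [image_stack()]; 3D. A 2D input is returned unchanged
#'   with a warning (projection is the identity there).
#' @return A 2D `ImageStack` with the same `theta` and channel.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!is_stack_3d(stack)) {
    warning("max_project() on a 2D image is the identity")
    return(stack)
  }
  d <- dim(stack$data)
  proj <- apply(stack$data, c(1L, 2L), max)
  image_stack(proj, theta = stack$theta, rho = stack$rho, channel = stack$channel)
}

#' Read a TIFF image or multi-plane stack
#'
#' @param path TIFF file path. Multi-directory files are read as a z-stack.
#' @param theta,rho Physical calibration to attach (TIFF tags are not relied
#'   upon).
#' @param channel Channel label to attach.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path, theta = 0.05754, rho = 1, channel = "unknown") {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  data <- if (length(planes) == 1L) planes[[1L]] else
    array(unlist(planes), dim = c(dim(planes[[1L]]), length(planes)))
  image_stack(data, theta = theta, rho = rho, channel = channel)
}

#' Write an image stack to TIFF
#'
#' Intensities are rescaled to `[0, 1]` (TIFF float range used by
#' [tiff::writeTIFF()]); the scale factor is returned invisibly.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return Invisibly, the intensity scale factor applied.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  mx <- max(stack$data, 1e-12)
  if (is_stack_3d(stack)) {
    planes <- lapply(seq_len(dim(stack$data)[3L]),
                     function(k) stack$data[, , k] / mx)
    tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(stack$data / mx, path, bits.per.sample = 32L)
  }
  invisible(mx)
}
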