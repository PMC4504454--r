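# Rigid and elastic 2D registration.
#
# Rigid: 1-D search over rotation, translation by FFT cross-correlation
# with quadratic sub-pixel peak interpolation. Elastic: rigid first, then a
# regularized coarse displacement grid estimated by block matching and
# interpolated bilinearly — a functional analogue of the usual rigid-body +
# B-spline-unwarping sequence used on multi-round microscopy.
#
# Convention: a Transform2D maps REFERENCE pixel coordinates p = (x, y)
# (0-based, in pixels) to MOVING-image coordinates
#   q = R(angle) (p - c) + c + t + D(p)
# so that warped(p) = mov(q) is aligned with ref. Positive `t` therefore
# means the moving image's content sits at +t relative to the reference.

#' Rigid/elastic transform between two images
#'
#' @param angle Rotation in radians.
#' @param t Translation in pixels, `c(tx, ty)`.
#' @param center Rotation centre in pixels `c(cx, cy)` (0-based).
#' @param theta Pixel size (micron/pixel), for micron-frame point mapping.
#' @param disp Optional elastic term: `list(gx, gy, dx, dy)` — grid node
#'   coordinates (pixels) and per-node displacements (pixels), interpolated
#'   bilinearly between nodes.
#' @param ncc Peak normalized cross-correlation achieved (diagnostic).
#' @return A `Transform2D` object.
#' @export
transform2d <- function(angle = 0, t = c(0, 0), center = c(0, 0),
                        theta = 0.05754, disp = NULL, ncc = NA_real_) {
  structure(list(angle = angle, t = as.numeric(t), center = as.numeric(center),
                 theta = theta, disp = disp, ncc = ncc),
            class = "Transform2D")
}

#' @export
print.Transform2D <- function(x, ...) {
  cat(sprintf("<Transform2D> angle=%.4f deg, t=(%.3f, %.3f) px%s, ncc=%.3f\n",
              x$angle * 180 / pi, x$t[1], x$t[2],
              if (is.null(x$disp)) "" else " + elastic grid", x$ncc))
  invisible(x)
}

# Bilinear sampling of `mat` at continuous 0-based pixel coords (x, y);
# outside pixels return `fill`.
bilinear_sample <- function(mat, x, y, fill = 0) {
  ny <- nrow(mat); nx <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & x0 <= nx - 2 & y0 >= 0 & y0 <= ny - 2
  out <- rep(fill, length(x))
  if (!any(ok)) { dim(out) <- dim(x); return(out) }
  i0 <- y0[ok] + 1L; j0 <- x0[ok] + 1L
  idx <- function(i, j) (j - 1L) * ny + i
  v00 <- mat[idx(i0, j0)];     v01 <- mat[idx(i0, j0 + 1L)]
  v10 <- mat[idx(i0 + 1L, j0)]; v11 <- mat[idx(i0 + 1L, j0 + 1L)]
  fxo <- fx[ok]; fyo <- fy[ok]
  out[ok] <- v00 * (1 - fxo) * (1 - fyo) + v01 * fxo * (1 - fyo) +
    v10 * (1 - fxo) * fyo + v11 * fxo * fyo
  dim(out) <- dim(x)
  out
}

# Evaluate the elastic displacement field at 0-based pixel coords.
disp_at <- function(disp, x, y) {
  if (is.null(disp)) return(list(dx = 0 * x, dy = 0 * y))
  ix <- findInterval(x, disp$gx, all.inside = TRUE)
  iy <- findInterval(y, disp$gy, all.inside = TRUE)
  fx <- (x - disp$gx[ix]) / (disp$gx[ix + 1L] - disp$gx[ix])
  fy <- (y - disp$gy[iy]) / (disp$gy[iy + 1L] - disp$gy[iy])
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  take <- function(m) {
    m[cbind(iy, ix)] * (1 - fx) * (1 - fy) +
      m[cbind(iy, ix + 1L)] * fx * (1 - fy) +
      m[cbind(iy + 1L, ix)] * (1 - fx) * fy +
      m[cbind(iy + 1L, ix + 1L)] * fx * fy
  }
  list(dx = take(disp$dx), dy = take(disp$dy))
}

# Map reference pixel coords to moving-image coords (forward), or back.
transform_coords <- function(tf, x, y, inverse = FALSE) {
  ca <- cos(tf$angle); sa <- sin(tf$angle)
  if (!inverse) {
    dx <- x - tf$center[1]; dy <- y - tf$center[2]
    qx <- ca * dx - sa * dy + tf$center[1] + tf$t[1]
    qy <- sa * dx + ca * dy + tf$center[2] + tf$t[2]
    d <- disp_at(tf$disp, x, y)
    list(x = qx + d$dx, y = qy + d$dy)
  } else {
    # one-step inverse of the (small, smooth) elastic term
    px <- x; py <- y
    for (it in 1:2) {
      d <- disp_at(tf$disp, px, py)
      ux <- x - d$dx - tf$t[1] - tf$center[1]
      uy <- y - d$dy - tf$t[2] - tf$center[2]
      px <- ca * ux + sa * uy + tf$center[1]
      py <- -sa * ux + ca * uy + tf$center[2]
      if (is.null(tf$disp)) break
    }
    list(x = px, y = py)
  }
}

#' Map punctum coordinates (micron) through a transform
#'
#' With `inverse = TRUE`, takes puncta detected on the moving image into
#' the reference frame (the usual direction for colocalization).
#'
#' @param tf A [transform2d()].
#' @param puncta A [puncta_set()].
#' @param inverse Map moving-frame points to the reference frame.
#' @return The punctum table with transformed `x_um`, `y_um`.
#' @export
transform_puncta <- function(tf, puncta, inverse = TRUE) {
  if (nrow(puncta) == 0L) return(puncta)
  p <- transform_coords(tf, puncta$x_um / tf$theta, puncta$y_um / tf$theta,
                        inverse = inverse)
  puncta$x_um <- p$x * tf$theta
  puncta$y_um <- p$y * tf$theta
  puncta
}

#' Resample a moving image into the reference frame
#'
#' @param img 2D [image_stack()] (the moving image).
#' @param tf A [transform2d()] estimated by [register()].
#' @param fill Value for pixels mapping outside the moving image.
#' @return The warped [image_stack()].
#' @export
apply_transform <- function(img, tf, fill = NULL) {
  stopifnot(inherits(img, "ImageStack"))
  mat <- img$data
  ny <- nrow(mat); nx <- ncol(mat)
  if (is.null(fill)) fill <- stats::median(mat)
  gx <- matrix(rep(0:(nx - 1L), each = ny), ny, nx)
  gy <- matrix(rep(0:(ny - 1L), nx), ny, nx)
  q <- transform_coords(tf, gx, gy)
  out <- bilinear_sample(mat, q$x, q$y, fill = fill)
  image_stack(out, theta = img$theta, rho = img$rho, channel = img$channel)
}

# FFT cross-correlation: returns the sub-pixel shift s such that
# mov(p) ~= ref(p - s), plus the normalized peak correlation.
cc_shift <- function(ref, mov) {
  a <- ref - mean(ref); b <- mov - mean(mov)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-9 || nb < 1e-9) return(list(s = c(NA, NA), ncc = 0))
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE)) /
    length(a)
  pk <- which.max(cc)
  ny <- nrow(cc); nx <- ncol(cc)
  pr <- ((pk - 1L) %% ny) + 1L
  pc <- ((pk - 1L) %/% ny) + 1L
  # 3-point parabolic interpolation, cyclic neighbours
  sub1 <- function(v, i) {
    im <- if (i == 1L) length(v) else i - 1L
    ip <- if (i == length(v)) 1L else i + 1L
    den <- v[im] - 2 * v[i] + v[ip]
    if (abs(den) < 1e-12) 0 else 0.5 * (v[im] - v[ip]) / den
  }
  dr <- sub1(cc[, pc], pr)
  dc <- sub1(cc[pr, ], pc)
  sy <- (pr - 1L) + dr; sx <- (pc - 1L) + dc
  if (sy > ny / 2) sy <- sy - ny
  if (sx > nx / 2) sx <- sx - nx
  list(s = c(sx, sy), ncc = cc[pr, pc] / (na * nb))
}

rotate_mat <- function(mat, angle, fill) {
  tf <- transform2d(angle = angle,
                    center = c((ncol(mat) - 1) / 2, (nrow(mat) - 1) / 2))
  ny <- nrow(mat); nx <- ncol(mat)
  gx <- matrix(rep(0:(nx - 1L), each = ny), ny, nx)
  gy <- matrix(rep(0:(ny - 1L), nx), ny, nx)
  q <- transform_coords(tf, gx, gy)
  bilinear_sample(mat, q$x, q$y, fill = fill)
}

decimate_mat <- function(mat, f) {
  if (f <= 1L) return(mat)
  ny <- (nrow(mat) %/% f) * f; nx <- (ncol(mat) %/% f) * f
  m <- mat[seq_len(ny), seq_len(nx)]
  # block mean
  m <- matrix(colMeans(matrix(m, f)), ny %/% f)  # rows averaged
  m <- t(matrix(colMeans(matrix(t(m), f)), nx %/% f))
  m
}

#' Register a moving image to a reference
#'
#' Rigid mode recovers a sub-pixel translation and a small rotation by
#' maximizing cross-correlation; elastic mode follows with a regularized
#' block-matching displacement grid for smooth distortions. Featureless
#' image pairs (correlation peak below `ncc_floor`) raise an
#' `mgsynapse_registration_error`.
#'
#' @param ref,mov 2D [image_stack()]s of the same field and pixel size.
#' @param mode `"rigid"` or `"elastic"`.
#' @param max_rot_deg Rotation search half-range (degrees).
#' @param block_px Elastic block-matching window (pixels).
#' @param ncc_floor Minimum acceptable peak correlation.
#' @return A [transform2d()] mapping `mov` into the frame of `ref`.
#' @export
register <- function(ref, mov, mode = c("rigid", "elastic"),
                     max_rot_deg = 6, block_px = 48L, ncc_floor = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "ImageStack"), inherits(mov, "ImageStack"))
  if (abs(ref$theta - mov$theta) > 1e-9) {
    stop_mgs("ref and mov must share the same pixel size",
             class = "mgsynapse_validation_error")
  }
  a <- ref$data; b <- mov$data
  if (!all(dim(a) == dim(b))) {
    stop_mgs("ref and mov must have identical dimensions",
             class = "mgsynapse_validation_error")
  }
  fill_b <- stats::median(b)
  f <- max(1L, floor(min(dim(a)) / 256))
  a_s <- decimate_mat(a, f); b_s <- decimate_mat(b, f)

  score <- function(ang) {
    r <- cc_shift(a_s, rotate_mat(b_s, ang, fill_b))
    r$ncc
  }
  opt <- stats::optimize(score, interval = c(-1, 1) * max_rot_deg * pi / 180,
                         maximum = TRUE, tol = 0.02 * pi / 180)
  ang <- opt$maximum
  if (abs(score(0) - opt$objective) < 1e-6) ang <- 0  # no rotation signal

  b_rot <- if (abs(ang) > 1e-9) rotate_mat(b, ang, fill_b) else b
  rr <- cc_shift(a, b_rot)
  if (!is.finite(rr$ncc) || rr$ncc < ncc_floor) {
    stop_mgs("images are unregistrable (peak correlation %.3f below %.3f)",
             rr$ncc, ncc_floor, class = "mgsynapse_registration_error")
  }
  ctr <- c((ncol(a) - 1) / 2, (nrow(a) - 1) / 2)
  # rotate_mat warps mov by sampling at R(p), i.e. content rotates by -ang;
  # the composite ref -> mov map is q = R(ang) (p - c) + c + t with t from
  # the translation estimated on the rotated image, carried through R.
  ca <- cos(ang); sa <- sin(ang)
  t_rot <- rr$s
  tf_t <- c(ca * t_rot[1] - sa * t_rot[2], sa * t_rot[1] + ca * t_rot[2])
  tf <- transform2d(angle = ang, t = tf_t, center = ctr, theta = ref$theta,
                    ncc = rr$ncc)

  if (mode == "elastic") {
    ny <- nrow(a); nx <- ncol(a)
    bp <- as.integer(min(block_px, ny %/% 3, nx %/% 3))
    # overlapping blocks: node spacing of half a block keeps the grid dense
    # enough that regularization does not flatten smooth warps
    gx <- unique(round(seq(bp %/% 2, nx - 1 - bp %/% 2,
                           length.out = max(4L, (2L * nx) %/% bp))))
    gy <- unique(round(seq(bp %/% 2, ny - 1 - bp %/% 2,
                           length.out = max(4L, (2L * ny) %/% bp))))
    zero <- matrix(0, length(gy), length(gx))
    tf$disp <- list(gx = gx, gy = gy, dx = zero, dy = zero)
    mov_img <- image_stack(b, theta = mov$theta)
    for (pass in 1:2) {
      warped <- apply_transform(mov_img, tf, fill = fill_b)$data
      dx <- zero; dy <- zero; wt <- zero
      for (iy in seq_along(gy)) for (ix in seq_along(gx)) {
        r0 <- gy[iy] - bp %/% 2 + 1L; c0 <- gx[ix] - bp %/% 2 + 1L
        ra <- a[r0:(r0 + bp - 1L), c0:(c0 + bp - 1L)]
        rb <- warped[r0:(r0 + bp - 1L), c0:(c0 + bp - 1L)]
        loc <- cc_shift(ra, rb)
        if (is.finite(loc$ncc) && loc$ncc > 0.2 && all(abs(loc$s) < bp / 3)) {
          dx[iy, ix] <- loc$s[1]; dy[iy, ix] <- loc$s[2]
          wt[iy, ix] <- loc$ncc
        }
      }
      smooth_grid <- function(m) {
        k <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3)
        num <- as.matrix(EBImage::filter2(m * wt, k))
        den <- as.matrix(EBImage::filter2(wt, k))
        out <- num / pmax(den, 1e-9)
        out[den < 1e-9] <- 0
        out
      }
      tf$disp$dx <- tf$disp$dx + smooth_grid(dx)
      tf$disp$dy <- tf$disp$dy + smooth_grid(dy)
    }
  }
  tf
}
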