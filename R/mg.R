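# Volume-corrected intracellular Mg2+ estimation.
#
# The measured basal MgGrn fluorescence of a dendritic branch scales with
# the local cytoplasmic volume as well as with [Mg2+]i. Modelling the
# branch as a cylinder of diameter d and integrating the fluorescence
# distribution over the detectable volume gives, after numerical
# integration over the z-stack,
#     index_full = 4 / (pi theta^2 d) * sum_z Fbar(z)
# with Fbar(z) the mean per-pixel in-mask intensity of plane z. Because the
# axial profile Fbar(z) is Gaussian with a shape shared across branches,
# sum_z Fbar(z) is proportional to the in-mask mean of the maximal
# projection, giving the simple volume-corrected index
#     index_simple = Fbar(z)_max / d.
# Both are relative (arbitrary-unit) estimators of [Mg2+]i.

mask_background <- function(mat, mask, background) {
  if (is.null(background)) return(0)
  if (identical(background, "auto")) {
    off <- mat[!mask]
    if (length(off) == 0L) return(0)
    return(stats::median(off))
  }
  background
}

#' Full numerical-integration Mg2+ index
#'
#' @param stack 3D MgGrn [image_stack()].
#' @param branch_mask Logical matrix selecting one branch's pixels in the
#'   xy plane.
#' @param d Branch diameter (micron).
#' @param background `NULL` (none), `"auto"` (per-plane off-mask median) or
#'   a number subtracted from each plane before averaging.
#' @return The volume-corrected index (a.u.).
#' @export
mg_index_full <- function(stack, branch_mask, d, background = NULL) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!is_stack_3d(stack)) {
    stop_mgs("mg_index_full() needs a 3D stack",
             class = "mgsynapse_validation_error")
  }
  if (!any(branch_mask)) {
    stop_mgs("branch mask is empty", class = "mgsynapse_validation_error")
  }
  check_positive(d, "d")
  nz <- dim(stack$data)[3L]
  fbar <- vapply(seq_len(nz), function(k) {
    plane <- stack$data[, , k]
    mean(plane[branch_mask]) - mask_background(plane, branch_mask, background)
  }, numeric(1))
  4 / (pi * stack$theta^2 * d) * sum(pmax(fbar, 0))
}

#' Simplified Mg2+ index from the maximal projection
#'
#' @param maxproj 2D [image_stack()] — the maximal z-projection of the
#'   MgGrn stack.
#' @param branch_mask Logical matrix selecting the branch.
#' @param d Branch diameter (micron).
#' @param background As in [mg_index_full()].
#' @return `Fbar(z)_max / d` (a.u. per micron).
#' @export
mg_index_simple <- function(maxproj, branch_mask, d, background = NULL) {
  stopifnot(inherits(maxproj, "ImageStack"))
  mat <- maxproj$data
  if (length(dim(mat)) != 2L) {
    stop_mgs("mg_index_simple() needs a 2D projection",
             class = "mgsynapse_validation_error")
  }
  if (!any(branch_mask)) {
    stop_mgs("branch mask is empty", class = "mgsynapse_validation_error")
  }
  check_positive(d, "d")
  fmax <- mean(mat[branch_mask]) - mask_background(mat, branch_mask, background)
  max(fmax, 0) / d
}

#' Check the Gaussian axial-profile assumption for one branch
#'
#' The simplification from the summed profile to the projection mean
#' requires the per-plane in-mask mean `Fbar(z)` to follow a Gaussian in z
#' with a branch-independent shape. This computes the profile and its
#' Gaussian fit; branches with R^2 below `r2_floor` are flagged as
#' violating the model.
#'
#' @param stack 3D MgGrn [image_stack()] (at least 5 planes).
#' @param branch_mask Logical branch mask.
#' @param background As in [mg_index_full()].
#' @param r2_floor Flagging threshold (default 0.9).
#' @return `list(z_um, profile, fit, r_squared, flagged)`.
#' @export
axial_profile_check <- function(stack, branch_mask, background = NULL,
                                r2_floor = 0.9) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!is_stack_3d(stack) || dim(stack$data)[3L] < 5L) {
    stop_mgs("need a stack with at least 5 z planes",
             class = "mgsynapse_validation_error")
  }
  nz <- dim(stack$data)[3L]
  z <- (seq_len(nz) - (nz + 1) / 2) * stack$rho
  prof <- vapply(seq_len(nz), function(k) {
    plane <- stack$data[, , k]
    mean(plane[branch_mask]) - mask_background(plane, branch_mask, background)
  }, numeric(1))
  fit <- gauss_bell_fit(z, prof)
  list(z_um = z, profile = prof, fit = fit, r_squared = fit$r_squared,
       flagged = !isTRUE(fit$converged) || fit$r_squared < r2_floor)
}

#' Measure branch diameter from a DIC-like image
#'
#' Samples intensity profiles perpendicular to the branch axis and takes
#' the median full width at half maximum.
#'
#' @param dic_img 2D [image_stack()] of the DIC-like channel.
#' @param branch_axis Axis segment `c(x0, y0, x1, y1)` in micron.
#' @param half_width_um Profile half-length perpendicular to the axis.
#' @param n_stations Number of profiles along the central 80% of the axis.
#' @return Diameter in micron.
#' @export
measure_diameter <- function(dic_img, branch_axis, half_width_um = 2.5,
                             n_stations = 15L) {
  stopifnot(inherits(dic_img, "ImageStack"), length(branch_axis) == 4L)
  mat <- dic_img$data
  theta <- dic_img$theta
  p0 <- branch_axis[1:2] / theta; p1 <- branch_axis[3:4] / theta
  if (any(c(p0, p1) < 0) || any(c(p0[1], p1[1]) > ncol(mat) - 1) ||
      any(c(p0[2], p1[2]) > nrow(mat) - 1)) {
    stop_mgs("branch axis lies outside the image",
             class = "mgsynapse_validation_error")
  }
  u <- p1 - p0; len <- sqrt(sum(u^2))
  if (len < 1e-9) stop_mgs("degenerate branch axis",
                           class = "mgsynapse_validation_error")
  u <- u / len
  nvec <- c(-u[2], u[1])
  ts <- seq(0.1, 0.9, length.out = n_stations)
  s <- seq(-half_width_um, half_width_um, by = theta / 2) / theta  # px
  widths <- rep(NA_real_, n_stations)
  for (k in seq_along(ts)) {
    c0 <- p0 + ts[k] * len * u
    xs <- c0[1] + s * nvec[1]
    ys <- c0[2] + s * nvec[2]
    prof <- bilinear_sample(mat, matrix(xs, 1), matrix(ys, 1), fill = NA)
    prof <- as.numeric(prof)
    ok <- is.finite(prof)
    if (sum(ok) < 8L) next
    prof <- prof[ok]; sv <- s[ok]
    ne <- max(3L, round(length(prof) * 0.15))
    bg <- stats::median(c(head(prof, ne), prof[seq(length(prof) - ne + 1L,
                                                   length(prof))]))
    pk <- max(prof)
    if (pk - bg < 6 * max(robust_sd(prof[c(seq_len(ne))]), 1e-9)) next
    half <- bg + (pk - bg) / 2
    above <- which(prof > half)
    if (length(above) == 0L) next
    i1 <- min(above); i2 <- max(above)
    # linear interpolation of the two half-maximum crossings
    left <- if (i1 > 1L) {
      sv[i1 - 1L] + (half - prof[i1 - 1L]) / (prof[i1] - prof[i1 - 1L]) *
        (sv[i1] - sv[i1 - 1L])
    } else sv[i1]
    right <- if (i2 < length(prof)) {
      sv[i2] + (half - prof[i2]) / (prof[i2 + 1L] - prof[i2]) *
        (sv[i2 + 1L] - sv[i2])
    } else sv[i2]
    widths[k] <- (right - left) * theta
  }
  if (all(is.na(widths))) {
    stop_mgs("no measurable branch contrast in the DIC image",
             class = "mgsynapse_contrast_error")
  }
  stats::median(widths, na.rm = TRUE)
}

#' Per-branch measurement table
#'
#' Computes the simple and full indices plus the uncorrected projection
#' mean for a set of branches.
#'
#' @param stack 3D MgGrn [image_stack()].
#' @param masks List of logical branch masks.
#' @param d Numeric vector of branch diameters (micron).
#' @param background As in [mg_index_full()].
#' @return A `BranchMeasure` data frame with columns `d`,
#'   `fbar_max` (uncorrected projection mean), `mg_index` (simple) and
#'   `mg_index_full`.
#' @export
branch_measures <- function(stack, masks, d, background = NULL) {
  stopifnot(length(masks) == length(d))
  proj <- max_project(stack)
  out <- data.frame(d = d, fbar_max = NA_real_, mg_index = NA_real_,
                    mg_index_full = NA_real_)
  for (i in seq_along(masks)) {
    out$fbar_max[i] <- mean(proj$data[masks[[i]]]) -
      mask_background(proj$data, masks[[i]], background)
    out$mg_index[i] <- mg_index_simple(proj, masks[[i]], d[i],
                                       background = background)
    out$mg_index_full[i] <- mg_index_full(stack, masks[[i]], d[i],
                                          background = background)
  }
  class(out) <- c("BranchMeasure", "data.frame")
  out
}

#' Ground-truth footprint mask of one scene branch
#'
#' @param scene A [build_scene()] result.
#' @param i Branch row index.
#' @return Logical matrix.
#' @export
scene_branch_mask <- function(scene, i) {
  br <- as.list(scene$branches[i, ])
  mask <- matrix(FALSE, scene$ny, scene$nx)
  w <- branch_window(br, scene$nx, scene$ny, scene$config$theta)
  if (!is.null(w)) mask[w$rows, w$cols] <- w$inside
  mask
}

#' AOI-level Mg2+ index
#'
#' The AOI level is the unweighted mean of the per-branch indices
#' (typically 50--100 branches per AOI); coverslip level is the mean of its
#' AOIs (see [aggregate_condition()]).
#'
#' @param branches A [branch_measures()] data frame or a numeric vector of
#'   per-branch indices.
#' @return Mean index.
#' @export
aoi_mg_level <- function(branches) {
  v <- if (is.data.frame(branches)) branches$mg_index else branches
  if (length(v) < 1L) {
    stop_mgs("need at least one branch", class = "mgsynapse_validation_error")
  }
  mean(v)
}
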