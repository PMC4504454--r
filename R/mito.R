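# JC-1 ratiometric mitochondrial membrane-potential analysis and
# mitochondrial density (fluorescence and EM).

# Integrated fluorescence at given positions (annulus-median background;
# shares the photometry of detect_puncta so both channels are measured
# identically).
integrate_at <- function(img, x_um, y_um, sigma_um = 0.2) {
  mat <- img$data
  theta <- img$theta
  out <- numeric(length(x_um))
  sig_px <- sigma_um / theta
  for (j in seq_along(x_um)) {
    r0 <- round(y_um[j] / theta) + 1L
    c0 <- round(x_um[j] / theta) + 1L
    out[j] <- sum_signed_disk(mat, r0, c0, sig_px)
  }
  out
}

# Signed disk integral minus annulus background (allows negative results so
# that a vanished channel measures ~0, not clipped noise).
sum_signed_disk <- function(mat, row, col, sig_px) {
  ny <- nrow(mat); nx <- ncol(mat)
  rad <- ceiling(2.5 * sig_px)
  gap <- 2L; ring <- 3L
  W <- rad + gap + ring
  rs <- max(1L, row - W):min(ny, row + W)
  cs <- max(1L, col - W):min(nx, col + W)
  patch <- mat[rs, cs, drop = FALSE]
  dd <- outer((rs - row)^2, rep(1, length(cs))) +
    outer(rep(1, length(rs)), (cs - col)^2)
  disk <- dd <= rad^2
  annulus <- dd > (rad + gap)^2 & dd <= W^2
  bgloc <- if (any(annulus)) stats::median(patch[annulus]) else
    stats::median(patch)
  sum(patch[disk] - bgloc)
}

#' Per-mitochondrion JC-1 aggregate/monomer ratios
#'
#' Puncta are detected on the monomer channel (present in every
#' mitochondrion regardless of potential; the aggregate channel vanishes in
#' depolarized mitochondria and would bias detection), then measured in
#' both registered channels. A mitochondrion's ratio is meaningful only
#' above the FCCP calibration floor (0.26, the fully-collapsed value);
#' sub-floor puncta are excluded from the potential statistic and records
#' with non-positive monomer signal are flagged invalid, never silently
#' dropped.
#'
#' @param aggr,mono Registered 2D [image_stack()]s of the aggregate and
#'   monomer emission channels.
#' @param puncta Optional [puncta_set()]; detected on `mono` when omitted.
#' @param floor Calibration floor (default 0.26).
#' @param ... Passed to [detect_puncta()] when `puncta` is omitted.
#' @return A `MitoRecord` data frame: `id, x_um, y_um, F_aggr, F_mono,
#'   ratio, valid, included`.
#' @export
jc1_ratios <- function(aggr, mono, puncta = NULL, floor = 0.26, ...) {
  stopifnot(inherits(aggr, "ImageStack"), inherits(mono, "ImageStack"))
  if (!all(dim(aggr$data) == dim(mono$data))) {
    stop_mgs("channel shapes differ", class = "mgsynapse_validation_error")
  }
  if (is.null(puncta)) puncta <- detect_puncta(mono, ...)
  n <- nrow(puncta)
  sig <- if ("sigma_um" %in% names(puncta) && n > 0L) {
    stats::median(puncta$sigma_um)
  } else 0.2
  fa <- if (n > 0L) integrate_at(aggr, puncta$x_um, puncta$y_um, sig) else numeric(0)
  fm <- if (n > 0L) integrate_at(mono, puncta$x_um, puncta$y_um, sig) else numeric(0)
  valid <- fm > 0
  ratio <- rep(NA_real_, n)
  ratio[valid] <- fa[valid] / fm[valid]
  rec <- data.frame(id = seq_len(n),
                    x_um = puncta$x_um, y_um = puncta$y_um,
                    F_aggr = fa, F_mono = fm, ratio = ratio,
                    valid = valid,
                    included = valid & !is.na(ratio) & ratio > floor)
  class(rec) <- c("MitoRecord", "data.frame")
  rec
}

#' AOI-level JC-1 summary
#'
#' @param records A [jc1_ratios()] table.
#' @param branch_area_um2 Dendritic branch area of the AOI (square micron).
#' @return `list(n_puncta, N_mito, mean_dpsi, composite, excluded_fraction,
#'   n_invalid)`; `composite = N_mito * mean_dpsi`.
#' @export
jc1_aoi_summary <- function(records, branch_area_um2) {
  check_positive(branch_area_um2, "branch_area_um2")
  inc <- records$included
  mean_dpsi <- if (any(inc)) mean(records$ratio[inc]) else NA_real_
  n_valid <- sum(records$valid)
  excl <- if (n_valid > 0) sum(records$valid & !inc) / n_valid else NA_real_
  n_mito <- nrow(records) / branch_area_um2
  list(n_puncta = nrow(records), N_mito = n_mito, mean_dpsi = mean_dpsi,
       composite = composite_index(n_mito, mean_dpsi),
       excluded_fraction = excl, n_invalid = sum(!records$valid))
}

#' Mitochondrial areal density
#'
#' @param puncta [puncta_set()] of mitochondrial puncta.
#' @param branch_area_um2 Branch area (square micron, positive).
#' @return Density per square micron.
#' @export
mito_density <- function(puncta, branch_area_um2) {
  if (!is.numeric(branch_area_um2) || length(branch_area_um2) != 1L ||
      !is.finite(branch_area_um2) || branch_area_um2 <= 0) {
    stop_mgs("density undefined: branch area must be positive",
             class = "mgsynapse_density_error")
  }
  nrow(puncta) / branch_area_um2
}

#' Composite mitochondrial-function index
#'
#' `N_mito * mean potential` — total mitochondrial function per unit area.
#'
#' @param n_mito Mitochondrial density (>= 0).
#' @param mean_dpsi Mean JC-1 ratio of included puncta (>= 0).
#' @return The product; `NA` if either input is `NA`.
#' @export
composite_index <- function(n_mito, mean_dpsi) {
  if (is.na(n_mito) || is.na(mean_dpsi)) return(NA_real_)
  check_nonnegative(n_mito, "n_mito")
  check_nonnegative(mean_dpsi, "mean_dpsi")
  n_mito * mean_dpsi
}

#' Count mitochondria in an EM-like image
#'
#' Mitochondria appear as dark compact profiles on a textured background:
#' the intensity deficit relative to the median background is thresholded
#' and connected components above a minimum physical area are counted.
#'
#' @param img 2D [image_stack()] (EM field; `theta` is the pixel size).
#' @param deficit_threshold Minimum intensity deficit (default 0.15 on a
#'   0-1 scale).
#' @param min_area_um2 Minimum profile area (default 0.03).
#' @return Integer count.
#' @export
count_em_mitochondria <- function(img, deficit_threshold = 0.15,
                                  min_area_um2 = 0.03) {
  stopifnot(inherits(img, "ImageStack"))
  mat <- img$data
  deficit <- stats::median(mat) - as.matrix(EBImage::gblur(mat, 1))
  mask <- deficit > deficit_threshold
  if (!any(mask)) return(0L)
  # watershed on the distance map splits touching profiles
  lab <- EBImage::watershed(EBImage::distmap(mask), tolerance = 1, ext = 1)
  sizes <- tabulate(as.integer(lab[lab > 0]))
  sum(sizes * img$theta^2 >= min_area_um2)
}

#' Mitochondrial density from EM fields
#'
#' Each element is either a rendered field (counted with
#' [count_em_mitochondria()]) or a precomputed count; the per-animal
#' density is the mean of per-image densities (#mitochondria / area).
#'
#' @param images List of `list(image = ImageStack)` and/or
#'   `list(count =, area_um2 =)` elements. For rendered fields the area is
#'   taken from the image dimensions unless `area_um2` is given.
#' @return `list(per_image = data.frame(count, area_um2, density),
#'   density =)` where `density` is the per-animal mean.
#' @export
em_density <- function(images) {
  if (length(images) < 1L) {
    stop_mgs("need at least one image", class = "mgsynapse_validation_error")
  }
  rows <- lapply(images, function(el) {
    if (!is.null(el$image)) {
      img <- el$image
      area <- if (!is.null(el$area_um2)) el$area_um2 else
        prod(dim(img$data)) * img$theta^2
      cnt <- count_em_mitochondria(img)
    } else {
      cnt <- el$count
      area <- el$area_um2
    }
    if (is.null(area) || !is.finite(area) || area <= 0) {
      stop_mgs("zero or missing field area", class = "mgsynapse_density_error")
    }
    data.frame(count = cnt, area_um2 = area, density = cnt / area)
  })
  per_image <- do.call(rbind, rows)
  list(per_image = per_image, density = mean(per_image$density))
}
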