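# Punctum detection and matching — the unit of all counting and
# colocalization in the pipeline.

#' Construct a punctum table
#'
#' @param x_um,y_um Centroid coordinates (micron, image frame).
#' @param F Integrated background-subtracted fluorescence (a.u.).
#' @param area_um2 Punctum area (square micron).
#' @param ... Further per-punctum columns.
#' @return A `PunctaSet` data frame.
#' @export
puncta_set <- function(x_um = numeric(0), y_um = numeric(0),
                       F = numeric(0), area_um2 = numeric(0), ...) {
  df <- data.frame(x_um = x_um, y_um = y_um, F = F, area_um2 = area_um2, ...)
  class(df) <- c("PunctaSet", "data.frame")
  df
}

#' Detect fluorescent puncta
#'
#' Multi-scale blob detection: the background (estimated by a grey-scale
#' morphological opening wider than any punctum) is subtracted, a
#' difference-of-Gaussians response is computed at three scales spanning
#' `[min_sigma, max_sigma]`, and local response maxima exceeding
#' `threshold_k` robust noise SDs are kept, with a minimum centroid
#' separation. Each punctum's fluorescence `F` is the integral of the
#' background-subtracted image over a disk of 2.5 detected sigmas; its area
#' is the within-disk region above half its peak.
#'
#' @param img A 2D [image_stack()] (or matrix; then `theta` must be given).
#' @param min_sigma,max_sigma Punctum sigma range in micron (defaults
#'   0.10--0.35, matched to near-diffraction-limited confocal puncta).
#' @param threshold_k Detection threshold in robust noise SDs (default 4).
#' @param min_sep_um Minimum centroid separation (default 0.25 micron).
#' @param theta Pixel size, used only when `img` is a bare matrix.
#' @return A [puncta_set()] with columns `x_um, y_um, F, area_um2,
#'   sigma_um, peak`.
#' @export
detect_puncta <- function(img, min_sigma = 0.10, max_sigma = 0.35,
                          threshold_k = 4, min_sep_um = 0.25,
                          theta = NULL) {
  if (inherits(img, "ImageStack")) {
    theta <- img$theta
    mat <- img$data
  } else {
    mat <- img
    if (is.null(theta)) stop_mgs("`theta` required for a bare matrix input",
                                 class = "mgsynapse_validation_error")
  }
  if (length(dim(mat)) != 2L) {
    stop_mgs("detect_puncta() needs a 2D image (max-project stacks first)",
             class = "mgsynapse_validation_error")
  }
  check_positive(min_sigma, "min_sigma")
  check_positive(max_sigma, "max_sigma")
  if (max_sigma < min_sigma) {
    stop_mgs("max_sigma must be >= min_sigma",
             class = "mgsynapse_validation_error")
  }
  ny <- nrow(mat); nx <- ncol(mat)

  # background: opening removes structures smaller than the brush
  brush_d <- 2L * ceiling(3 * max_sigma / theta) + 1L
  brush_d <- min(brush_d, 2L * (min(ny, nx) %/% 2L) - 1L)
  bg <- if (brush_d >= 3L) {
    as.matrix(EBImage::gblur(as.matrix(
      EBImage::opening(mat, EBImage::makeBrush(brush_d, "disc"))), 2))
  } else matrix(stats::median(mat), ny, nx)
  sub <- mat - bg

  # gblur's kernel may not exceed the image; cap the radius on small inputs
  safe_gblur <- function(m, s) {
    r <- min(2L * ceiling(3 * s) + 1L, 2L * ((min(dim(m)) - 1L) %/% 2L) - 1L)
    if (r < 3L) return(m)
    as.matrix(EBImage::gblur(m, s, radius = r))
  }
  sigmas_px <- exp(seq(log(min_sigma / theta), log(max_sigma / theta),
                       length.out = 3L))
  best <- matrix(-Inf, ny, nx)
  best_sig <- matrix(sigmas_px[1L], ny, nx)
  noise <- rep(NA_real_, length(sigmas_px))
  for (s in seq_along(sigmas_px)) {
    g1 <- safe_gblur(sub, sigmas_px[s])
    g2 <- safe_gblur(sub, sigmas_px[s] * 1.6)
    dog <- g1 - g2
    noise[s] <- robust_sd(as.numeric(dog))
    upd <- dog > best
    best[upd] <- dog[upd]
    best_sig[upd] <- sigmas_px[s]
  }
  thr <- threshold_k * max(noise, 1e-12)

  # strict 8-neighbour local maxima of the pooled response
  dil <- as.matrix(EBImage::dilate(best, EBImage::makeBrush(3L, "box")))
  cand <- which(best >= dil & best > thr)
  if (length(cand) == 0L) return(puncta_set(sigma_um = numeric(0), peak = numeric(0)))
  ord <- cand[order(best[cand], decreasing = TRUE)]
  rows <- ((ord - 1L) %% ny) + 1L
  cols <- ((ord - 1L) %/% ny) + 1L

  min_sep_px <- min_sep_um / theta
  keep <- logical(length(ord))
  kr <- numeric(0); kc <- numeric(0)
  for (j in seq_along(ord)) {
    if (length(kr) > 0L &&
        min((kr - rows[j])^2 + (kc - cols[j])^2) < min_sep_px^2) next
    keep[j] <- TRUE
    kr <- c(kr, rows[j]); kc <- c(kc, cols[j])
  }
  rows <- rows[keep]; cols <- cols[keep]
  sig <- best_sig[cbind(rows, cols)]
  n <- length(rows)

  x_um <- numeric(n); y_um <- numeric(n); Fint <- numeric(n)
  area <- numeric(n); peak <- numeric(n)
  for (j in seq_len(n)) {
    m <- punctum_measure(mat, rows[j], cols[j], sig[j])
    x_um[j] <- (m$cc - 1) * theta
    y_um[j] <- (m$rr - 1) * theta
    Fint[j] <- m$F
    peak[j] <- m$peak
    area[j] <- m$area_px * theta^2
  }
  puncta_set(x_um = x_um, y_um = y_um, F = Fint, area_um2 = area,
             sigma_um = sig * theta, peak = peak)
}

# Per-punctum photometry: integrate over a disk of 2.5 sigma with the local
# background taken as the median of a surrounding annulus (unbiased under
# shot noise, robust to neighbouring puncta).
punctum_measure <- function(mat, row, col, sig_px) {
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
  sp <- patch - bgloc
  w <- pmax(sp, 0) * disk
  tot <- sum(w)
  if (tot > 0) {
    rr <- sum(w * rs) / tot
    cc <- sum(w * matrix(cs, length(rs), length(cs), byrow = TRUE)) / tot
  } else { rr <- row; cc <- col }
  pk <- max(sp[disk])
  list(rr = rr, cc = cc, F = max(sum(sp[disk]), 0), peak = pk,
       area_px = sum(disk & sp > pk / 2))
}

#' Match two punctum sets by mutual nearest neighbours
#'
#' Pairs are mutual nearest neighbours with centroid distance at most
#' `radius`; every punctum enters at most one pair. The default radius,
#' 0.5 micron, is about twice the expected registration error and below
#' typical inter-synapse spacing.
#'
#' @param A,B [puncta_set()]s in a common frame (register first).
#' @param radius Maximum pairing distance (micron).
#' @return `list(pairs = data.frame(i, j, dist_um), unmatched_a,
#'   unmatched_b)` with indices into `A` and `B`.
#' @export
match_puncta <- function(A, B, radius = 0.5) {
  check_positive(radius, "radius")
  na <- nrow(A); nb <- nrow(B)
  empty <- list(pairs = data.frame(i = integer(0), j = integer(0),
                                   dist_um = numeric(0)),
                unmatched_a = seq_len(na), unmatched_b = seq_len(nb))
  if (na == 0L || nb == 0L) return(empty)
  d2 <- outer(A$x_um, B$x_um, "-")^2 + outer(A$y_um, B$y_um, "-")^2
  nn_a <- max.col(-d2, ties.method = "first")            # nearest B for each A
  nn_b <- max.col(-t(d2), ties.method = "first")         # nearest A for each B
  i <- which(nn_b[nn_a] == seq_len(na))
  j <- nn_a[i]
  dist <- sqrt(d2[cbind(i, j)])
  ok <- dist <= radius
  pairs <- data.frame(i = i[ok], j = j[ok], dist_um = dist[ok])
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(na), pairs$i),
       unmatched_b = setdiff(seq_len(nb), pairs$j))
}
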