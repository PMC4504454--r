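# Rendering ground-truth scenes into noisy images and stacks.
#
# Physical model: a dendritic branch is a cylinder of diameter d lying in
# the imaging plane. A pixel at perpendicular distance r from the axis sees
# an optical path (chord) of 2*sqrt((d/2)^2 - r^2) through the cytoplasm, so
# the unblurred axial intensity profile is a slab of that thickness whose
# amplitude is proportional to the local fluorophore concentration. Axial
# blur by a Gaussian PSF of sigma_z turns the slab into a difference of
# normal CDFs (closed form, no 3D convolution needed). Punctate channels are
# isotropic Gaussian spots whose *integrated* intensity equals the planted
# quantity. Noise: Poisson shot noise on signal + background, plus additive
# Gaussian read noise.

render_channels <- function() {
  c("MgGrn", "FM", "DIC", "MAP2", "JC1-aggr", "JC1-mono", "IF:<protein>")
}

channel_seed <- function(scene, channel, extra = 0L) {
  base <- substream_seed(scene$seed, "render")
  as.integer((as.numeric(base) + sum(utf8ToInt(channel)) * 131 +
                as.numeric(extra) * 7919) %% 2147483629)
}

# Additive Gaussian spots with unit-integral normalization:
# sum over pixels of one spot ~= q (its planted quantity).
add_spots <- function(mat, x_um, y_um, q, sigma_um, theta) {
  if (length(x_um) == 0L) return(mat)
  ny <- nrow(mat); nx <- ncol(mat)
  sig <- sigma_um / theta
  R <- ceiling(4 * sig)
  norm <- 1 / (2 * pi * sig^2)
  c0 <- x_um / theta + 1   # continuous col position
  r0 <- y_um / theta + 1
  for (j in seq_along(x_um)) {
    cs <- max(1L, floor(c0[j] - R)):min(nx, ceiling(c0[j] + R))
    rs <- max(1L, floor(r0[j] - R)):min(ny, ceiling(r0[j] + R))
    if (length(cs) == 0L || length(rs) == 0L) next
    gx <- exp(-((cs - c0[j])^2) / (2 * sig^2))
    gy <- exp(-((rs - r0[j])^2) / (2 * sig^2))
    mat[rs, cs] <- mat[rs, cs] + (q[j] * norm) * outer(gy, gx)
  }
  mat
}

apply_confocal_noise <- function(mat, config, seed) {
  set.seed(seed)
  sig <- mat + config$background
  if (config$poisson_scale > 0) {
    sig <- stats::rpois(length(sig), pmax(sig, 0) * config$poisson_scale) /
      config$poisson_scale
    dim(sig) <- dim(mat)
  }
  if (config$read_sd > 0) {
    sig <- sig + stats::rnorm(length(sig), 0, config$read_sd)
    dim(sig) <- dim(mat)
  }
  pmax(sig, 0)
}

lateral_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0.3) return(mat)  # sub-resolution blur is a no-op
  as.matrix(EBImage::gblur(mat, sigma = sigma_px))
}

# Noiseless MgGrn z-stack: closed-form axial slab convolution per branch.
render_mgg_planes <- function(scene) {
  cfg <- scene$config
  z <- (seq_len(cfg$n_z) - (cfg$n_z + 1) / 2) * cfg$rho
  planes <- array(0, dim = c(scene$ny, scene$nx, cfg$n_z))
  for (i in seq_len(nrow(scene$branches))) {
    br <- as.list(scene$branches[i, ])
    w <- branch_window(br, scene$nx, scene$ny, cfg$theta)
    if (is.null(w)) next
    chord <- matrix(0, nrow(w$inside), ncol(w$inside))
    chord[w$inside] <- 2 * sqrt(pmax((br$d / 2)^2 - w$perp[w$inside]^2, 0))
    amp <- br$mg * cfg$mgg_gain
    for (k in seq_along(z)) {
      add <- amp * (stats::pnorm((z[k] - br$z_c + chord / 2) / cfg$psf_sigma_z) -
                    stats::pnorm((z[k] - br$z_c - chord / 2) / cfg$psf_sigma_z))
      planes[w$rows, w$cols, k] <- planes[w$rows, w$cols, k] + add
    }
  }
  planes
}

# Dendrite fill channels (DIC-like tube indicator; MAP2 thickness fill).
render_fill_image <- function(scene, weight = c("indicator", "chord"), gain) {
  weight <- match.arg(weight)
  img <- matrix(0, scene$ny, scene$nx)
  for (i in seq_len(nrow(scene$branches))) {
    br <- as.list(scene$branches[i, ])
    w <- branch_window(br, scene$nx, scene$ny, scene$config$theta)
    if (is.null(w)) next
    v <- matrix(0, nrow(w$inside), ncol(w$inside))
    if (weight == "indicator") {
      v[w$inside] <- gain
    } else {
      v[w$inside] <- gain * 2 * sqrt(pmax((br$d / 2)^2 - w$perp[w$inside]^2, 0))
    }
    img[w$rows, w$cols] <- pmax(img[w$rows, w$cols], v)
  }
  img
}

#' Render one channel of a synthetic scene
#'
#' `MgGrn` renders a 3D z-stack (concentration-proportional cylinder fill,
#' Gaussian axial PSF in closed form, lateral Gaussian blur, then noise).
#' `DIC` encodes branch geometry as a tube of uniform contrast (for diameter
#' measurement); `MAP2` fills dendrites in proportion to local thickness.
#' `FM`, `JC1-aggr`, `JC1-mono` and `IF:<protein>` are punctate channels:
#' isotropic Gaussian spots whose integrated intensity equals the planted
#' per-punctum quantity.
#'
#' @param scene A [build_scene()] result.
#' @param channel One of `"MgGrn"`, `"FM"`, `"DIC"`, `"MAP2"`,
#'   `"JC1-aggr"`, `"JC1-mono"`, or `"IF:<protein>"` for a panel protein.
#' @param config Optional override of `scene$config` (e.g. to re-render
#'   noiselessly).
#' @return An [image_stack()]; 3D for `MgGrn`, 2D otherwise.
#' @export
render_zstack <- function(scene, channel, config = scene$config) {
  stopifnot(inherits(scene, "Scene"))
  cfg <- config
  theta <- cfg$theta
  sig_xy_px <- cfg$psf_sigma_xy / theta
  seed <- channel_seed(scene, channel)
  term <- scene$terminals

  if (channel == "MgGrn") {
    planes <- render_mgg_planes(scene)
    for (k in seq_len(dim(planes)[3L])) {
      planes[, , k] <- apply_confocal_noise(
        lateral_blur(planes[, , k], sig_xy_px), cfg,
        channel_seed(scene, channel, k))
    }
    return(image_stack(planes, theta = theta, rho = cfg$rho, channel = channel))
  }

  img <- matrix(0, scene$ny, scene$nx)
  if (channel == "DIC") {
    img <- lateral_blur(render_fill_image(scene, "indicator", cfg$dic_contrast),
                        sig_xy_px)
  } else if (channel == "MAP2") {
    img <- lateral_blur(render_fill_image(scene, "chord", cfg$map2_gain),
                        sig_xy_px)
  } else if (channel == "FM") {
    if (nrow(term) > 0L) {
      img <- add_spots(img, term$x_um, term$y_um, term$pool,
                       cfg$spot_sigma_um, theta)
    }
  } else if (channel %in% c("JC1-aggr", "JC1-mono")) {
    m <- scene$mitochondria
    if (nrow(m) > 0L) {
      q <- if (channel == "JC1-aggr") m$true_ratio * m$mono_q else m$mono_q
      img <- add_spots(img, m$x_um, m$y_um, q, cfg$spot_sigma_um, theta)
    }
  } else if (startsWith(channel, "IF:")) {
    prot <- sub("^IF:", "", channel)
    col <- paste0("q_", prot)
    if (!col %in% names(term)) {
      stop_mgs("unknown protein channel '%s'; panel: %s", channel,
               paste(names(cfg$proteins), collapse = ", "),
               class = "mgsynapse_channel_error")
    }
    if (nrow(term) > 0L) {
      img <- add_spots(img, term$x_um, term$y_um, term[[col]],
                       cfg$spot_sigma_um, theta)
    }
  } else {
    stop_mgs("unknown channel '%s'; valid channels: %s", channel,
             paste(render_channels(), collapse = ", "),
             class = "mgsynapse_channel_error")
  }
  img <- apply_confocal_noise(img, cfg, seed)
  image_stack(img, theta = theta, rho = cfg$rho, channel = channel)
}

#' Render a paired FM loading/unloading image set
#'
#' A terminal loads dye (appears in the loading image F1) iff it responds
#' to the stimulus: under 5AP bursting input only functional terminals
#' respond; under maximal 600AP stimulation every releasable-at-max
#' terminal responds. During unloading a responding terminal releases
#' `releasable_frac` of its loaded pool, so its punctum in F2 retains
#' `(1 - releasable_frac)` of the F1 signal and deltaF = F1 - F2 carries
#' the releasable component. Nonfunctional terminals contribute nothing
#' under 5AP.
#'
#' @param scene A [build_scene()] result.
#' @param protocol A [stimulus_protocol()] (used to label the images).
#' @param stim_kind `"5AP"` or `"600AP"`.
#' @param session_shift_px Optional rigid x/y shift (pixels) of the whole
#'   field, emulating a separate imaging session that must be registered.
#' @param session_rot_deg Optional field rotation (degrees) about the field
#'   centre for the same purpose.
#' @return `list(F1 =, F2 =)` of 2D [image_stack()]s.
#' @export
render_fm_pair <- function(scene, protocol = protocol_5ap(),
                           stim_kind = c("5AP", "600AP"),
                           session_shift_px = c(0, 0),
                           session_rot_deg = 0) {
  stopifnot(inherits(scene, "Scene"), inherits(protocol, "StimulusProtocol"))
  stim_kind <- match.arg(stim_kind)
  cfg <- scene$config
  term <- scene$terminals
  responds <- if (nrow(term) == 0L) logical(0) else
    if (stim_kind == "5AP") term$functional else term$releasable_at_max

  x <- term$x_um[responds]; y <- term$y_um[responds]
  if (session_rot_deg != 0 || any(session_shift_px != 0)) {
    a <- session_rot_deg * pi / 180
    cx <- cfg$field_um[1] / 2; cy <- cfg$field_um[2] / 2
    xr <- cos(a) * (x - cx) - sin(a) * (y - cy) + cx
    yr <- sin(a) * (x - cx) + cos(a) * (y - cy) + cy
    x <- xr + session_shift_px[1] * cfg$theta
    y <- yr + session_shift_px[2] * cfg$theta
  }
  pool <- term$pool[responds]

  base <- matrix(0, scene$ny, scene$nx)
  f1 <- add_spots(base, x, y, pool, cfg$spot_sigma_um, cfg$theta)
  f2 <- add_spots(base, x, y, pool * (1 - cfg$releasable_frac),
                  cfg$spot_sigma_um, cfg$theta)
  f1 <- apply_confocal_noise(f1, cfg, channel_seed(scene, paste0("FM-F1-", stim_kind)))
  f2 <- apply_confocal_noise(f2, cfg, channel_seed(scene, paste0("FM-F2-", stim_kind)))
  list(F1 = image_stack(f1, theta = cfg$theta, rho = cfg$rho,
                        channel = paste0("FM-F1-", stim_kind)),
       F2 = image_stack(f2, theta = cfg$theta, rho = cfg$rho,
                        channel = paste0("FM-F2-", stim_kind)))
}

#' Render a synthetic EM-like field of mitochondria
#'
#' Mitochondria are dark ellipses (random size/orientation, hard-core
#' non-overlap) on a textured grey background, at a Poisson count of
#' `density * field_area`.
#'
#' @param density Areal density (per square micron).
#' @param field_area_um2 Field area (square micron; rendered square).
#' @param seed Integer seed.
#' @param px_um Pixel size (micron; EM counting does not need nm-scale
#'   sampling, default 0.016).
#' @return `list(image =, true_count =)`; `image` is a 2D [image_stack()].
#' @export
render_em_field <- function(density, field_area_um2, seed = 1L,
                            px_um = 0.016) {
  check_nonnegative(density, "density")
  check_positive(field_area_um2, "field_area_um2")
  set.seed(substream_seed(seed, "em"))
  side <- sqrt(field_area_um2)
  npx <- max(8L, round(side / px_um))
  n <- stats::rpois(1L, density * field_area_um2)

  img <- matrix(0.65, npx, npx)
  tex <- as.matrix(EBImage::gblur(matrix(stats::rnorm(npx^2, 0, 1), npx), 3))
  img <- img + tex * (0.04 / max(stats::sd(as.numeric(tex)), 1e-9))

  kept <- 0L
  xs <- numeric(n); ys <- numeric(n)
  if (n > 0L) {
    for (tr in seq_len(50L * n)) {
      cx <- stats::runif(1, 0, side); cy <- stats::runif(1, 0, side)
      if (kept > 0L) {
        if (min((xs[seq_len(kept)] - cx)^2 + (ys[seq_len(kept)] - cy)^2) < 0.45^2) next
      }
      kept <- kept + 1L; xs[kept] <- cx; ys[kept] <- cy
      if (kept == n) break
    }
    for (j in seq_len(kept)) {
      a <- stats::runif(1, 0.13, 0.2); b <- stats::runif(1, 0.24, 0.4)
      phi <- stats::runif(1, 0, pi)
      R <- ceiling(b / px_um)
      c0 <- xs[j] / px_um + 1; r0 <- ys[j] / px_um + 1
      cs <- max(1L, floor(c0 - R)):min(npx, ceiling(c0 + R))
      rs <- max(1L, floor(r0 - R)):min(npx, ceiling(r0 + R))
      dx <- outer(rep(1, length(rs)), (cs - c0) * px_um)
      dy <- outer((rs - r0) * px_um, rep(1, length(cs)))
      u <- (dx * cos(phi) + dy * sin(phi)) / b
      v <- (-dx * sin(phi) + dy * cos(phi)) / a
      inside <- u^2 + v^2 <= 1
      patch <- img[rs, cs]
      patch[inside] <- patch[inside] - 0.35
      img[rs, cs] <- patch
    }
  }
  img <- as.matrix(EBImage::gblur(img, 1))
  img <- pmin(pmax(img + stats::rnorm(npx^2, 0, 0.02), 0), 1)
  list(image = image_stack(img, theta = px_um, rho = 1, channel = "EM"),
       true_count = kept)
}
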