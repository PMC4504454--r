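# Ground-truth scene construction: cylindrical branches, terminals and
# mitochondria living on the dendrite footprint.

# Signed branch-frame coordinates of pixel centres inside a bounding window.
# Returns NULL when the window is empty.
branch_window <- function(br, nx, ny, theta, margin_px = 0L) {
  ux <- cos(br$angle); uy <- sin(br$angle)
  hx <- abs(ux) * br$L / 2 + abs(uy) * br$d / 2
  hy <- abs(uy) * br$L / 2 + abs(ux) * br$d / 2
  m <- margin_px * theta
  c0 <- max(1L, floor((br$x0 - hx - m) / theta) + 1L)
  c1 <- min(nx, ceiling((br$x0 + hx + m) / theta) + 1L)
  r0 <- max(1L, floor((br$y0 - hy - m) / theta) + 1L)
  r1 <- min(ny, ceiling((br$y0 + hy + m) / theta) + 1L)
  if (c0 > c1 || r0 > r1) return(NULL)
  cols <- c0:c1; rows <- r0:r1
  px <- (cols - 1) * theta; py <- (rows - 1) * theta
  dx <- outer(rep(1, length(rows)), px - br$x0)
  dy <- outer(py - br$y0, rep(1, length(cols)))
  along <- dx * ux + dy * uy
  perp <- -dx * uy + dy * ux
  list(rows = rows, cols = cols, along = along, perp = perp,
       inside = abs(along) <= br$L / 2 & abs(perp) <= br$d / 2)
}

# Membership test for points (micron) against one branch footprint.
points_in_branch <- function(x, y, br) {
  ux <- cos(br$angle); uy <- sin(br$angle)
  dx <- x - br$x0; dy <- y - br$y0
  along <- dx * ux + dy * uy
  perp <- -dx * uy + dy * ux
  abs(along) <= br$L / 2 & abs(perp) <= br$d / 2
}

dendrite_mask <- function(branches, nx, ny, theta) {
  mask <- matrix(FALSE, ny, nx)
  for (i in seq_len(nrow(branches))) {
    w <- branch_window(as.list(branches[i, ]), nx, ny, theta)
    if (is.null(w)) next
    mask[w$rows, w$cols] <- mask[w$rows, w$cols] | w$inside
  }
  mask
}

# Hard-core point placement on a pixel mask: uniform over mask pixels with a
# minimum pairwise separation, by dart throwing with retries. Sub-pixel
# jitter makes positions continuous.
place_on_mask <- function(n, mask, theta, min_sep, max_tries = 40L) {
  idx <- which(mask)
  if (n == 0L || length(idx) == 0L) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  }
  ny <- nrow(mask)
  xs <- numeric(n); ys <- numeric(n)
  kept <- 0L
  for (tr in seq_len(max_tries)) {
    need <- n - kept
    if (need == 0L) break
    pick <- idx[sample.int(length(idx), need, replace = TRUE)]
    row <- ((pick - 1L) %% ny) + 1L
    col <- ((pick - 1L) %/% ny) + 1L
    cx <- (col - 1) * theta + stats::runif(need, -0.5, 0.5) * theta
    cy <- (row - 1) * theta + stats::runif(need, -0.5, 0.5) * theta
    for (j in seq_len(need)) {
      if (kept > 0L && min_sep > 0) {
        d2 <- (xs[seq_len(kept)] - cx[j])^2 + (ys[seq_len(kept)] - cy[j])^2
        if (min(d2) < min_sep^2) next
      }
      kept <- kept + 1L
      xs[kept] <- cx[j]; ys[kept] <- cy[j]
      if (kept == n) break
    }
  }
  data.frame(x_um = xs[seq_len(kept)], y_um = ys[seq_len(kept)])
}

#' Build a ground-truth synthetic scene
#'
#' Draws branch geometry, terminal positions/flags/quantities and
#' mitochondrial positions/ratios from the configured distributions.
#' Identical `(config, seed)` pairs give identical scenes.
#'
#' @param config A [scene_config()].
#' @param seed Integer master seed; per-component substreams are derived
#'   from it.
#' @return A `Scene`: list with `branches`, `terminals`, `mitochondria`
#'   data frames, the boolean ground-truth `dendrite_mask`, the dendrite
#'   area `dendrite_area_um2`, pixel grid dims and the config.
#' @export
build_scene <- function(config, seed = 1L) {
  stopifnot(inherits(config, "SceneConfig"))
  nx <- max(1L, round(config$field_um[1] / config$theta))
  ny <- max(1L, round(config$field_um[2] / config$theta))

  set.seed(substream_seed(seed, "scene"))
  if (!is.null(config$branches)) {
    br <- as.data.frame(config$branches)
    if (is.null(br$z_c)) br$z_c <- 0
    if (is.null(br$mg)) br$mg <- config$mg_concentration[1]
  } else {
    nb <- config$n_branches
    margin <- 0.1 * config$field_um
    br <- data.frame(
      x0 = stats::runif(nb, margin[1], config$field_um[1] - margin[1]),
      y0 = stats::runif(nb, margin[2], config$field_um[2] - margin[2]),
      angle = stats::runif(nb, 0, pi),
      L = stats::runif(nb, config$length_range[1], config$length_range[2]),
      d = stats::runif(nb, config$d_range[1], config$d_range[2]),
      z_c = stats::rnorm(nb, 0, config$branch_z_jitter_um))
    br$mg <- if (length(config$mg_concentration) > 1L) {
      stats::runif(nb, config$mg_concentration[1], config$mg_concentration[2])
    } else rep(config$mg_concentration, nb)
  }
  if (nrow(br) > 0L) br$branch_id <- seq_len(nrow(br))

  mask <- if (nrow(br) > 0L) dendrite_mask(br, nx, ny, config$theta) else
    matrix(FALSE, ny, nx)
  area <- sum(mask) * config$theta^2

  # terminals
  set.seed(substream_seed(seed, "terminals"))
  n_term <- stats::rpois(1L, config$terminal_density * area)
  term <- place_on_mask(n_term, mask, config$theta, config$terminal_min_sep_um)
  n_term <- nrow(term)
  if (n_term > 0L) {
    host <- rep(NA_integer_, n_term)
    for (i in seq_len(nrow(br))) {
      hit <- is.na(host) & points_in_branch(term$x_um, term$y_um, as.list(br[i, ]))
      host[hit] <- br$branch_id[i]
    }
    term$branch_id <- host
    term$functional <- stats::runif(n_term) < config$p_fun
    term$releasable_at_max <- TRUE
    term$pool <- rlnorm_mean_cv(n_term, config$pool_mean, config$pool_cv)
    for (p in names(config$proteins)) {
      q <- rlnorm_mean_cv(n_term, config$proteins[[p]]$mean,
                          config$proteins[[p]]$cv) * config$protein_scale
      if (config$nonfunctional_protein_factor != 1 &&
          p %in% ca_sensitivity_proteins()) {
        q[!term$functional] <- q[!term$functional] *
          config$nonfunctional_protein_factor
      }
      term[[paste0("q_", p)]] <- q
    }
    term$terminal_id <- seq_len(n_term)
  } else {
    term$branch_id <- integer(0); term$functional <- logical(0)
    term$releasable_at_max <- logical(0); term$pool <- numeric(0)
    term$terminal_id <- integer(0)
  }

  # mitochondria
  set.seed(substream_seed(seed, "mito"))
  n_mito <- stats::rpois(1L, config$mito_density * area)
  mito <- place_on_mask(n_mito, mask, config$theta, 0.5)
  n_mito <- nrow(mito)
  if (n_mito > 0L) {
    if (config$mito_collapse) {
      ratio <- pmax(0.02, stats::rnorm(n_mito, 0.26, 0.06))
    } else {
      depol <- stats::runif(n_mito) < config$mito_depolarized_frac
      ratio <- rlnorm_mean_cv(n_mito, config$mito_ratio_mean,
                              config$mito_ratio_sd / config$mito_ratio_mean)
      ratio[depol] <- stats::runif(sum(depol), 0.08, 0.25)
    }
    mito$true_ratio <- ratio
    mito$mono_q <- rlnorm_mean_cv(n_mito, config$mito_mono_mean,
                                  config$mito_mono_cv)
    mito$mito_id <- seq_len(n_mito)
  } else {
    mito$true_ratio <- numeric(0); mito$mono_q <- numeric(0)
    mito$mito_id <- integer(0)
  }

  structure(list(branches = br, terminals = term, mitochondria = mito,
                 dendrite_mask = mask, dendrite_area_um2 = area,
                 nx = nx, ny = ny, config = config, seed = as.integer(seed)),
            class = "Scene")
}

#' @export
print.Scene <- function(x, ...) {
  cat(sprintf(
    "<Scene> %.1f x %.1f um, %d branches, %d terminals, %d mitochondria, dendrite area %.1f um^2\n",
    x$config$field_um[1], x$config$field_um[2], nrow(x$branches),
    nrow(x$terminals), nrow(x$mitochondria), x$dendrite_area_um2))
  invisible(x)
}

#' Serialize a scene's ground truth to JSON
#'
#' @param scene A [build_scene()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(scene, path) {
  obj <- list(
    field_um = scene$config$field_um, theta = scene$config$theta,
    rho = scene$config$rho, seed = scene$seed,
    dendrite_area_um2 = scene$dendrite_area_um2,
    branches = scene$branches, terminals = scene$terminals,
    mitochondria = scene$mitochondria)
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
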