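# Shared fixtures: all synthetic, built in code.

# Noiseless single-cylinder scene for Mg-model tests.
single_branch_config <- function(d, conc = 100, noise = FALSE, field = 12,
                                 angle = pi / 7, L = 8) {
  br <- data.frame(x0 = field / 2, y0 = field / 2, angle = angle, L = L,
                   d = d, mg = conc, z_c = 0)
  scene_config(field_um = field, branches = br, terminal_density = 0,
               mito_density = 0, branch_z_jitter_um = 0,
               background = if (noise) 20 else 0,
               poisson_scale = if (noise) 1 else 0,
               read_sd = if (noise) 1.5 else 0)
}

branch_axis_of <- function(scene, i = 1L) {
  br <- scene$branches[i, ]
  c(br$x0 - cos(br$angle) * br$L / 2, br$y0 - sin(br$angle) * br$L / 2,
    br$x0 + cos(br$angle) * br$L / 2, br$y0 + sin(br$angle) * br$L / 2)
}

# Clean image with spots planted at known positions.
planted_spot_image <- function(x_um, y_um, q, sigma_um = 0.11,
                               field_um = 10, theta = 0.05754,
                               noise_sd = 0, seed = 1) {
  n <- round(field_um / theta)
  m <- matrix(0, n, n)
  m <- mgsynapse:::add_spots(m, x_um, y_um, q, sigma_um, theta)
  if (noise_sd > 0) {
    set.seed(seed)
    m <- pmax(m + matrix(rnorm(n^2, 0, noise_sd), n), 0)
  }
  image_stack(m, theta = theta)
}

# Recovered vs planted comparison by mutual matching.
recovery_rate <- function(detected, x_um, y_um, radius = 0.3) {
  truth <- puncta_set(x_um = x_um, y_um = y_um, F = 1, area_um2 = 0.1)
  m <- match_puncta(truth, detected, radius = radius)
  nrow(m$pairs) / max(length(x_um), 1L)
}
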