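#' Synthetic scene configuration
#'
#' Describes the ground truth for one synthetic confocal field: cylindrical
#' dendritic branches filled with a concentration-proportional fluorophore,
#' punctate presynaptic terminals living on the dendrite footprint,
#' mitochondrial puncta with a per-mitochondrion JC-1 aggregate/monomer
#' ratio, the axial/lateral PSF, and the confocal noise model. Rendering any
#' channel from the same `(config, seed)` pair is deterministic.
#'
#' @param field_um Field size in micron, `c(width, height)` or a scalar for a
#'   square field.
#' @param theta Lateral resolution (micron/pixel; default 0.05754, the
#'   confocal calibration used throughout).
#' @param rho Axial z step (micron; default 1).
#' @param n_z Number of z planes rendered for 3D channels.
#' @param n_branches Number of randomly placed straight cylindrical branches.
#' @param d_range Branch diameter range in micron (dendritic calibre
#'   0.3--3 micron).
#' @param length_range Branch length range in micron.
#' @param mg_concentration Intracellular Mg2+ concentration per branch
#'   (arbitrary units); scalar (all branches identical) or range
#'   `c(lo, hi)` sampled uniformly per branch.
#' @param branch_z_jitter_um SD of the branch-centre offset from the stack
#'   mid-plane (cultured dendrites lie nearly in one plane).
#' @param branches Optional explicit branch table overriding random
#'   placement: data.frame with columns `x0, y0` (centre, micron), `angle`
#'   (rad), `L`, `d` (micron), `mg` (a.u.) and optionally `z_c` (micron).
#' @param terminal_density Structural presynaptic terminals per square
#'   micron of dendrite footprint (default 1.5, the structural SYP(+)
#'   density scale).
#' @param p_fun Probability that a terminal is functional, i.e. releases
#'   vesicles under physiological 5AP bursting input.
#' @param releasable_frac Fraction of a loaded terminal's dye released
#'   during the unloading stimulus (sets `deltaF / F1` per punctum).
#' @param pool_mean,pool_cv Mean and coefficient of variation of the
#'   lognormal per-terminal releasable-pool fluorescence (a.u.).
#' @param terminal_min_sep_um Hard-core separation between terminal centres
#'   (physical bouton size; default 0.5 micron).
#' @param proteins Named list of per-protein `list(mean =, cv =)` lognormal
#'   quantity parameters for the immunofluorescence panel.
#' @param protein_scale Global multiplier on all protein quantities (used to
#'   plant between-condition differences).
#' @param nonfunctional_protein_factor Multiplier applied to the six
#'   Ca2+-sensitivity-related protein quantities of nonfunctional terminals
#'   (1 = no coupling between functionality and protein content).
#' @param mito_density Mitochondria per square micron of dendrite footprint.
#' @param mito_ratio_mean,mito_ratio_sd Mean and SD of the healthy
#'   (polarized) per-mitochondrion aggregate/monomer ratio, drawn lognormal.
#' @param mito_depolarized_frac Fraction of mitochondria with collapsed
#'   potential whose ratio falls below the calibration floor (default
#'   17/942, the observed calibration tail).
#' @param mito_collapse If `TRUE`, emulate FCCP treatment: every
#'   mitochondrion's ratio collapses to the floor (0.26) with SD 0.06.
#' @param mito_mono_mean,mito_mono_cv Lognormal parameters of the monomer
#'   channel integrated fluorescence per mitochondrion (a.u.).
#' @param psf_sigma_z Axial Gaussian PSF sigma (micron; default 1.5).
#' @param psf_sigma_xy Lateral Gaussian PSF sigma (micron; default 0.15).
#' @param spot_sigma_um Rendered Gaussian punctum sigma (micron) for FM, IF
#'   and JC-1 channels.
#' @param background Mean background intensity (a.u., added before shot
#'   noise).
#' @param poisson_scale Photons per intensity unit for shot noise (0
#'   disables shot noise).
#' @param read_sd Additive Gaussian read-noise SD (a.u.; 0 disables).
#' @param mgg_gain MgGrn intensity per unit concentration per micron of
#'   optical path.
#' @param map2_gain MAP2 fill intensity per micron of dendrite thickness.
#' @param dic_contrast DIC-like tube contrast above background.
#' @return A validated `SceneConfig` list.
#' @export
scene_config <- function(field_um = 30,
                         theta = 0.05754,
                         rho = 1,
                         n_z = 15,
                         n_branches = 12,
                         d_range = c(0.3, 3.0),
                         length_range = c(8, 20),
                         mg_concentration = 100,
                         branch_z_jitter_um = 0.2,
                         branches = NULL,
                         terminal_density = 1.5,
                         p_fun = 0.513,
                         releasable_frac = 0.6,
                         pool_mean = 2000,
                         pool_cv = 0.4,
                         terminal_min_sep_um = 0.5,
                         proteins = default_protein_panel(),
                         protein_scale = 1,
                         nonfunctional_protein_factor = 1,
                         mito_density = 0.3,
                         mito_ratio_mean = 1.21,
                         mito_ratio_sd = 0.6,
                         mito_depolarized_frac = 17 / 942,
                         mito_collapse = FALSE,
                         mito_mono_mean = 2000,
                         mito_mono_cv = 0.3,
                         psf_sigma_z = 1.5,
                         psf_sigma_xy = 0.15,
                         spot_sigma_um = 0.11,
                         background = 20,
                         poisson_scale = 1,
                         read_sd = 1.5,
                         mgg_gain = 60,
                         map2_gain = 60,
                         dic_contrast = 100) {
  if (length(field_um) == 1L) field_um <- c(field_um, field_um)
  check_positive(field_um[1], "field_um[1]"); check_positive(field_um[2], "field_um[2]")
  check_positive(theta, "theta"); check_positive(rho, "rho")
  check_positive(n_z, "n_z")
  check_probability(p_fun, "p_fun")
  check_probability(releasable_frac, "releasable_frac")
  check_probability(mito_depolarized_frac, "mito_depolarized_frac")
  check_nonnegative(terminal_density, "terminal_density")
  check_nonnegative(mito_density, "mito_density")
  check_nonnegative(c(background, poisson_scale, read_sd), "noise parameters")
  check_positive(psf_sigma_z, "psf_sigma_z")
  check_positive(psf_sigma_xy, "psf_sigma_xy")
  check_positive(spot_sigma_um, "spot_sigma_um")
  if (any(d_range <= 0)) {
    stop_mgs("branch diameters must be positive",
             class = "mgsynapse_validation_error")
  }
  cfg <- list(
    field_um = as.numeric(field_um), theta = theta, rho = rho,
    n_z = as.integer(n_z),
    n_branches = as.integer(n_branches), d_range = d_range,
    length_range = length_range, mg_concentration = mg_concentration,
    branch_z_jitter_um = branch_z_jitter_um, branches = branches,
    terminal_density = terminal_density, p_fun = p_fun,
    releasable_frac = releasable_frac, pool_mean = pool_mean,
    pool_cv = pool_cv, terminal_min_sep_um = terminal_min_sep_um,
    proteins = proteins, protein_scale = protein_scale,
    nonfunctional_protein_factor = nonfunctional_protein_factor,
    mito_density = mito_density, mito_ratio_mean = mito_ratio_mean,
    mito_ratio_sd = mito_ratio_sd,
    mito_depolarized_frac = mito_depolarized_frac,
    mito_collapse = mito_collapse, mito_mono_mean = mito_mono_mean,
    mito_mono_cv = mito_mono_cv,
    psf_sigma_z = psf_sigma_z, psf_sigma_xy = psf_sigma_xy,
    spot_sigma_um = spot_sigma_um,
    background = background, poisson_scale = poisson_scale,
    read_sd = read_sd, mgg_gain = mgg_gain, map2_gain = map2_gain,
    dic_contrast = dic_contrast)
  class(cfg) <- "SceneConfig"
  cfg
}

#' Default immunofluorescence protein panel
#'
#' Structural markers (SYP, Bassoon, VGLUT1) and the six
#' Ca2+-sensitivity-related proteins (SYT1, Rab3a, RIM1, Munc13-1, ELKS,
#' Syntaxin1), each with a lognormal per-terminal quantity.
#'
#' @param mean,cv Common mean and coefficient of variation.
#' @return Named list of `list(mean =, cv =)`.
#' @export
default_protein_panel <- function(mean = 2000, cv = 0.35) {
  nm <- c("SYP", "SYT1", "Rab3a", "RIM1", "Munc13-1", "ELKS",
          "Syntaxin1", "Bassoon", "VGLUT1")
  stats::setNames(lapply(nm, function(p) list(mean = mean, cv = cv)), nm)
}

#' Six Ca2+-sensitivity-related proteins entering the sum-Q index
#' @return Character vector of protein names.
#' @export
ca_sensitivity_proteins <- function() {
  c("SYT1", "Rab3a", "RIM1", "Munc13-1", "ELKS", "Syntaxin1")
}

#' Field-stimulation protocol
#'
#' Either a bursting protocol (`n_bursts` bursts of `aps_per_burst` action
#' potentials at `freq_hz`, separated by `interval_s`) or a continuous train
#' (`n_aps` at `freq_hz`).
#'
#' @param n_bursts,aps_per_burst,freq_hz,interval_s Burst-mode parameters.
#' @param n_aps Continuous-mode AP count (set `n_bursts = NULL`).
#' @return A `StimulusProtocol` with a `total_aps` field.
#' @export
stimulus_protocol <- function(n_bursts = NULL, aps_per_burst = NULL,
                              freq_hz, interval_s = NULL, n_aps = NULL) {
  check_positive(freq_hz, "freq_hz")
  if (!is.null(n_bursts)) {
    check_positive(n_bursts, "n_bursts")
    check_positive(aps_per_burst, "aps_per_burst")
    check_positive(interval_s, "interval_s")
    p <- list(mode = "burst", n_bursts = as.integer(n_bursts),
              aps_per_burst = as.integer(aps_per_burst),
              freq_hz = freq_hz, interval_s = interval_s,
              total_aps = as.integer(n_bursts * aps_per_burst))
  } else {
    check_positive(n_aps, "n_aps")
    p <- list(mode = "continuous", n_aps = as.integer(n_aps),
              freq_hz = freq_hz, total_aps = as.integer(n_aps))
  }
  class(p) <- "StimulusProtocol"
  p
}

#' Physiological bursting protocol: 6 bursts of 5 APs at 100 Hz, 10 s apart
#' @return A `StimulusProtocol`.
#' @export
protocol_5ap <- function() {
  stimulus_protocol(n_bursts = 6, aps_per_burst = 5, freq_hz = 100,
                    interval_s = 10)
}

#' Maximal stimulation: 600 APs at 10 Hz
#' @return A `StimulusProtocol`.
#' @export
protocol_600ap <- function() stimulus_protocol(freq_hz = 10, n_aps = 600)

# Lognormal with a given arithmetic mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
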