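---
title: "Quantifying synaptic function, intracellular magnesium and mitochondrial status from fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic function, intracellular magnesium and mitochondrial status from fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mgsynapse)
```

# Scope

`mgsynapse` implements the quantitative image-analysis layer of a
presynaptic-function study in cultured hippocampal neurons and rat brain
tissue: counting functional presynaptic terminals from FM-dye turnover
images, estimating relative intracellular Mg^2+^ from confocal z-stacks
with a volume correction, ratiometric JC-1 mitochondrial
membrane-potential analysis, mitochondrial density in fluorescence and
electron-microscopy images, and multi-round registered immunofluorescence
("SAFIA") that assembles per-terminal protein profiles. Because the raw
cultures and animals cannot be regenerated from code, every estimator is
validated by parameter recovery on a synthetic-microscopy generator whose
defaults are the imaging conditions the package is built around.

# The measurement models

## FM-dye vesicle turnover

A terminal that recycles vesicles during field stimulation takes up FM dye
(loading image $F_1$) and releases it during the unloading stimulus
($F_2$). The releasable signal is the pixelwise difference
$\Delta F = F_1 - F_2$, clipped at zero. Functional terminal density is

$$N_{5AP} = \#FM_{5AP} / A,$$

the count of $\Delta F$ puncta after the physiological bursting protocol
(6 bursts of 5 APs at 100 Hz, 10 s apart) per area $A$ of MAP2-positive
dendrite. Maximal stimulation (600 APs at 10 Hz) releases essentially
every releasable terminal; matching the 5AP against the 600AP punctum
sets on the same field (after rigid registration between sessions) gives
the fraction of terminals that are functional under physiological input.
A structural (SYP-positive) punctum with no matched $\Delta F$ punctum is
a nonfunctional (silent) terminal.

## Volume-corrected Mg^2+^ index

Basal Magnesium Green fluorescence is proportional to [Mg^2+^]~i~, but the
collected signal also grows with the local cytoplasmic volume. Modelling a
dendritic branch as a cylinder of diameter $d$ and length $L$ and
integrating the fluorescence distribution $F(x,y,z)$ over the detectable
volume gives, after numerical integration over the z-stack (lateral
resolution $\theta$, axial step $\rho$),

$$[\mathrm{Mg}^{2+}]_i \propto \frac{4}{\pi\theta^2 d}\sum_z \bar F(z),$$

with $\bar F(z)$ the mean per-pixel in-mask intensity of plane $z$
(`mg_index_full()`). Because the axial profile $\bar F(z)$ is Gaussian
with a shape shared across branches — a property the generator reproduces
by construction and `axial_profile_check()` verifies per branch — the sum
is proportional to the in-mask mean of the maximal projection, giving the
simple index

$$[\mathrm{Mg}^{2+}]_i \propto \bar F(z)_{max} / d$$

(`mg_index_simple()`), with $d$ measured from the DIC image as the median
perpendicular FWHM (`measure_diameter()`). Both estimators are relative
(arbitrary units); no K~d~-based absolute calibration is attempted. The
assumption that basal Ca^2+^ contributes negligibly to the indicator is a
documented precondition, not modelled. Tests confirm the two estimators
agree up to one global scale (residual < 5%), that the index is linear in
the planted concentration, and that its coefficient of variation across
calibres 0.5–3.0 µm stays below 10% noiseless (15% with noise) while the
uncorrected projection mean spans more than a 6-fold range.

## JC-1 ratiometry

Membrane potential per mitochondrion is the ratio of integrated aggregate
to monomer JC-1 fluorescence. Puncta are detected on the **monomer**
channel — present in every mitochondrion, whereas the aggregate channel
vanishes in depolarized ones and would bias detection — then measured
identically in both channels. Ratios at or below the FCCP-collapse floor
of 0.26 are excluded from the potential statistic; records with
non-positive monomer signal are flagged invalid rather than dropped.
AOI-level outputs are the mean ratio of included puncta, the punctum
density N~mito~, and the composite index N~mito~ × mean potential.

## EM density

Mitochondria in EM-like fields are segmented as connected regions of
intensity deficit, split by a watershed on the distance map (touching
profiles are otherwise merged), and counted per field; the per-animal
density is the mean of per-image densities, and groups are compared with
the two-sample tests below.

## SAFIA and the Q indices

Repeated staining rounds of one field are aligned through their DIC
landmark images (rigid, optionally elastic registration) and the
transforms applied to the protein channels. Structural puncta define the
terminal table rows; each protein's integrated fluorescence is assigned
by mutual-nearest-neighbour matching within 0.5 µm, with unmatched rows
recording zero — a terminal genuinely lacking a protein scores 0, not
missing. Per condition, a protein's quantity index is

$$Q_p = \frac{\text{total punctum fluorescence of } p \text{ per MAP2 area}}
{\text{control-group mean}},$$

so the control mean is exactly 1, and
$\Sigma Q = Q_{SYT1}+Q_{Rab3a}+Q_{RIM1}+Q_{Munc13\text{-}1}+Q_{ELKS}+Q_{Syntaxin1}$
sums the six Ca^2+^-sensitivity-related proteins.
`profile_nonfunctional()` contrasts protein content between functional
and nonfunctional terminals (group means, Cohen's d, Student's t), and
marks a protein "depleted" at a terminal when its quantity falls below
the 25th percentile of the functional distribution (configurable).

# The synthetic generator

`scene_config()` + `build_scene()` draw a ground-truth scene;
`render_zstack()`, `render_fm_pair()` and `render_em_field()` turn it
into images. What it emulates, and the defaults (all changeable):

* **Geometry.** Straight cylindrical branches (diameter 0.3–3.0 µm) in
  the focal plane (z jitter SD 0.2 µm — cultured dendrites lie nearly
  flat on the coverslip). Pixel size θ = 0.05754 µm, z step ρ = 1 µm,
  matching the confocal calibration used for the in vitro work.
* **MgGrn channel.** Voxel intensity ∝ concentration × in-branch
  indicator. The axial PSF (Gaussian, σ~z~ = 1.5 µm) is applied in closed
  form — a slab of thickness equal to the local chord becomes a
  difference of normal CDFs — followed by a lateral Gaussian blur
  (σ~xy~ = 0.15 µm). Only the axial profile shape matters to the Mg
  model, so the PSF is separable by design.
* **Punctate channels** (FM, IF, JC-1). Isotropic Gaussian spots whose
  integrated intensity equals the planted quantity (conservation is
  tested to 1%). Spot σ = 0.11 µm: a 60× NA 1.2 objective at ~510 nm is
  near diffraction limited (FWHM ≈ 0.25 µm). Terminal centres keep a
  0.5 µm hard-core separation (physical bouton size); at the study's
  densities (1.4–1.5 µm^-2^ of dendrite) anything larger than
  diffraction-limited spots would be optically unresolvable for any
  detector.
* **Terminals.** Count ~ Poisson(density × dendrite area); functional
  flags i.i.d. Bernoulli(p~fun~); releasable pools and protein
  quantities lognormal (CV 0.4/0.35). Default p~fun~ = 0.513, the
  low-Mg condition. A responding terminal loads its pool into $F_1$ and
  releases 60% during unloading; nonfunctional terminals load nothing
  under 5AP.
* **Mitochondria.** Healthy ratios lognormal with mean 1.21 and SD 0.6
  plus a small depolarized fraction (17/942 ≈ 1.8%) collapsed below the
  0.26 floor. A Gaussian of that SD would put ~6% of its mass below the
  floor and shift the post-exclusion mean to ~1.28, contradicting the
  observed ~2% exclusion tail; the mixture honours both the mean and the
  tail. `mito_collapse = TRUE` emulates FCCP (all ratios at 0.26 ± 0.06).
* **Noise.** Poisson shot noise on signal + background (20 a.u.) and
  additive Gaussian read noise (SD 1.5) — the standard confocal model.
* **EM fields.** Dark ellipses (semi-axes ~0.13–0.2 × 0.24–0.4 µm,
  non-overlapping) on textured background, count ~ Poisson(density ×
  area), rendered at 16 nm/px — counting does not need the acquisition's
  2 nm sampling.
* **Determinism.** One master seed; per-component and per-channel
  substreams with fixed offsets, so identical (config, seed) re-renders
  byte-identical pixels.

What it does **not** emulate — and what passing tests therefore cannot
show about real data: branching/curved dendrite topology, photobleaching,
chromatic aberration and channel cross-talk (JC-1 emission bands are
ideal), residual-antibody carryover between SAFIA rounds (elution is
modelled as complete; rounds differ only by noise and misalignment),
non-Gaussian PSF tails, and realistic EM ultrastructure.

# Numerical and design choices

* **Punctum detection.** Background by grey-scale opening (wider than any
  punctum), difference-of-Gaussians response at three scales spanning
  0.10–0.35 µm, local maxima above 4 robust (MAD) noise SDs, minimum
  centroid separation 0.25 µm. The scale range is matched to the
  diffraction-limited spot size; a wider upper scale merges neighbouring
  terminals at the study's densities. Photometry integrates the raw image
  over a disk of 2.5σ minus the median of a surrounding annulus — the
  annulus median is unbiased under shot noise, where an opening-based
  background is biased low (erosion tracks noise minima). Note that at
  k = 4 the expected maximum of smoothed noise over a large empty field
  is itself ~4–5 SDs, so a handful of noise maxima per empty
  coverslip-sized field is the designed operating point; sparse-field
  analyses can raise `threshold_k`.
* **MAP2 area.** Batches differ in gain and offset, so intensities are
  aligned to a stored reference histogram via two robust anchors (20th
  percentile background, 99.5th percentile bright level) and thresholded
  at a fixed 8% of the reference range, then cleaned by a 5-px
  morphological open/close. Full histogram *specification* was rejected:
  it pins the above-threshold pixel fraction to the reference's tail
  mass, so the measured area would no longer track actual dendrite
  coverage. Anchor alignment keeps the normalization intent (doubling
  all intensities leaves A unchanged — tested) while preserving the
  coverage signal. The shipped reference histogram
  (`inst/extdata/map2_reference_hist.csv`) is a synthetic
  background+foreground mixture defined by this package.
* **Registration.** Rigid: golden-section search over rotation (±6°) on
  a decimated image, translation by FFT cross-correlation with 3-point
  parabolic sub-pixel interpolation; planted transforms are recovered to
  <0.5 px and <0.2°. Elastic: two passes of block matching (48-px blocks,
  half-block node spacing) with weighted 3×3 grid smoothing, applied on
  top of the rigid map; a functional analogue of the usual rigid-body +
  spline-unwarping sequence, not a bit-exact port. Featureless pairs
  (peak normalized correlation < 0.1) raise an explicit unregistrable
  error.
* **Matching radius.** 0.5 µm default everywhere a punctum is assigned
  to a terminal: about twice the expected registration error and below
  inter-synapse spacing at these densities.
* **Gaussian bell fits.** `y = a·exp(-(x-µ)²/2σ²) + b` via
  Levenberg–Marquardt, initialized at the argmax and the second moment;
  the baseline term is kept because empirical density curves need not
  decay to zero at the range edges. A start exactly on a symmetry point
  makes the initial Jacobian singular, so a nudged restart is tried;
  non-convergence is flagged in the result, never an error. With four
  parameters a bell whose centre lies outside the x range can fit
  monotone data better than a straight line, so no R² ordering against
  the linear fit is asserted.
* **Tests of group differences.** Student's t (pooled variance; Welch
  optional, off by default) and two-sample Kolmogorov–Smirnov, both
  two-tailed; no multiple-testing correction is applied anywhere.
* **Aggregation.** AOI values → coverslip means → condition mean ± SEM,
  at every per-area statistic; per-animal EM densities are means of
  per-image densities.

# Problem sizes

The test suite and the acceptance script run on scaled scenes chosen so
each check keeps sampling error well below its tolerance: coverslip
fields of 20–30 µm (several hundred terminals each, ~5600–7000 puncta per
colocalization condition), JC-1 populations of ~950 mitochondria pooled
over five AOIs per seed (20 seeds), 20 seeds for the FM density, and
9/11 virtual animals × 70 EM fields for the density groups. Statistical
calibration uses 2000 replicates per test.

# Known limitations

* Branch masks for the Mg analyses come from geometry (ground truth) in
  the validation workflows; a fully image-derived branch segmentation is
  only as good as the thresholded projection it starts from.
* The whole-network aggregation of corrected MgGrn fluorescence is
  represented by the branch-wise estimator averaged over branches; the
  field-level procedure is ambiguous and this choice is documented
  rather than resolved.
* The release-probability bound for silent terminals (Pr < 0.04) is a
  label attached to non-detection after 30 APs, not a separate
  computation.
* Elastic registration assumes smooth, small distortions; it will not
  recover tears or large non-rigid deformation.
* All intensities are arbitrary units end to end; nothing in the
  pipeline is calibrated to absolute concentrations or molecule counts.
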