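---
title: "Simulating and reconstructing qOBM phase images of acetowhitened tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing qOBM phase images of acetowhitened tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Quantitative oblique back-illumination microscopy (qOBM) performs
quantitative phase imaging (QPI) in thick, scattering tissue using
epi-illumination: light delivered obliquely from outside the collection
path multiply scatters inside the tissue and re-emerges through the focal
plane, so that each oblique arm acts like a tilted, extended transmission
source. Four arms arranged as two opposing pairs produce two orthogonal
differential phase contrast (DPC) images, which are deconvolved into a
quantitative phase map. `qobmsim` implements this imaging chain as a
forward simulator plus reconstructor, together with a synthetic tissue
phantom whose "acetowhitening" transform emulates the effect of acetic
acid (AA) staining on the phase distribution: higher nuclear phase (from
chromatin condensation raising the nuclear refractive index) alongside a
homogenization of non-nuclear structure. The package's purpose is to make
the reconstruction chain and the statistics used to quantify nuclear
contrast enhancement fully testable at desk scale.

## Image formation model

The object is a thin complex transmittance
$t(\mathbf r) = e^{-\mu(\mathbf r) + i\phi(\mathbf r)}$, with phase
$\phi$ in radians ($\phi > 0$ for refractive index above background) and
absorption $\mu \ge 0$. Under the weak-object approximation
($t \approx 1 - \mu + i\phi$), a partially coherent imager with source
distribution $S(\mathbf u)$ and pupil $P(\mathbf u)$ is linear in
$(\mu, \phi)$:

$$\hat I(\mathbf u) = B\,\delta(\mathbf u)
  + H_{abs}(\mathbf u)\,\hat\mu(\mathbf u)
  + H_{ph}(\mathbf u)\,\hat\phi(\mathbf u),$$

with

$$B = \sum_{\mathbf u'} S\,|P|^2,\qquad
\Gamma(\mathbf u) = \sum_{\mathbf u'} S(\mathbf u')P^*(\mathbf u')
P(\mathbf u' + \mathbf u),$$
$$H_{abs} = -\left[\Gamma(\mathbf u) + \Gamma^*(-\mathbf u)\right],\qquad
H_{ph} = i\left[\Gamma(\mathbf u) - \Gamma^*(-\mathbf u)\right].$$

All sums run over the discrete DFT frequency lattice of the simulation
grid (circular indexing); the lattice resolution is the single source of
discretization error, and the same lattice sums define both the
vectorized implementation and the brute-force oracle the tests compare it
against. Two structural identities follow directly and are enforced
exactly in floating point by constructing $H_{ph}$ from a single
$\Gamma$ array: $H_{ph}(0) = 0$ (DPC systems are blind to the mean phase
— the familiar low-frequency insensitivity of this reconstruction
family), and $H_{ph} \equiv 0$ for a symmetric source (brightfield has no
linear phase contrast).

For one opposing pair the normalized difference
$D = (I_a - I_b)/(I_a + I_b)$ has, for a weak pure-phase object, the
transfer function

$$H_{dpc}(\mathbf u) =
  \frac{H_{ph,a}(\mathbf u) - H_{ph,b}(\mathbf u)}{B_a + B_b},$$

and the two orthogonal DPC images are inverted jointly by Tikhonov-
regularized least squares:

$$\hat\phi =
\frac{H_x^*\hat D_x + H_y^*\hat D_y}{|H_x|^2 + |H_y|^2 + \alpha}.$$

The joint solve (rather than per-axis deconvolution plus averaging) is
standard DPC practice: the zero sets of $H_x$ and $H_y$ intersect only
near the origin, so the pair gives near-isotropic coverage. Note the
one-mode closed form of this inversion carries *both* axes in the
denominator even when only one DPC image is nonzero.

## The effective source

The physical obliquity of the effective source in epi mode arises from
multiple scattering; deriving it requires light-transport simulation,
which is out of scope here. `make_source()` instead uses a parametric
stand-in: a Gaussian in pupil coordinates at radial offset
`offset_frac * f_cutoff` along the arm axis with width
`width_frac * f_cutoff`. The defaults (0.8, 0.35) place most source
weight near the pupil edge with substantial extent — enough obliquity to
produce strong phase contrast (max $|H_{dpc}| \approx 0.96$ for the
default system) while keeping the source inside the modelled passband.
They are a modelling choice, not a tissue calibration, and are exposed in
the configuration. Opposing arms are constructed as exact sample-wise
reflections of each other through the frequency origin, which makes the
mirror identities ($B_a = B_b$, $H_{ph,b} = -H_{ph,a}$, DPC antisymmetry
under arm swap) hold to the last bit rather than to FFT roundoff.

## The tissue phantom and the acetowhitening transform

`generate_phantom()` emulates a single qOBM field of fresh tissue:

* **nuclei** — `n_nuclei = 12` non-overlapping disks with radius uniform
  in 3–6 um, rasterized with a smoothstep edge (plateau phase
  `nucleus_phase = 0.15` rad) on a 512 x 512 grid at 0.25 um/pixel
  (a 128 um field). The modest fresh nuclear level encodes the weak
  native nuclear contrast of QPI in tissue.
* **background texture** — Gaussian-correlated noise (correlation length
  1.5 um) scaled to `background_sd = 0.08` rad, standing in for
  cytoplasmic and extracellular refractive-index texture.
* **inclusions** — a few small bright disks (`inclusion_phase = 0.6`
  rad), emulating the high-phase round lipid-droplet-like objects seen
  outside cells in both fresh and stained tissue.
* **absorption** — a small constant (0.01), keeping the phantom well
  inside the weak-object regime; phantoms exceeding max |phase| of 1 rad
  or absorption 0.2 are flagged `"nonlinear"` in their metadata.

The phase levels are plausible radian-scale choices rather than
calibrated values: absolute nuclear phase in tissue is not available to
calibrate against, so only *relative* effects (ratios, direction of
change) should be read out of simulations.

`apply_aa_transform()` models acetowhitening with three parameters:
`nuclear_gain` (default 1.8) multiplies nuclear phase; `homogenization`
(default 0.7) mixes background pixels toward the background mean
(globally by default; a Gaussian local-mean variant is selectable); and
`inclusion_gain` (default 1) leaves the droplet-like objects alone. The
defaults were chosen once so that the two signature effects hold robustly
with realistic margins: whole-field phase SD *decreases* (default
phantoms: about 0.081 to 0.060 rad after reconstruction, a ratio of
about 0.74) while nuclear contrast-to-noise *increases* (about 1.3 to
7.6). The magnitudes are free parameters of the model; the direction of
both effects is the scientifically anchored content. Geometry is
deliberately kept fixed between the fresh and stained states — real
tissue deforms and nuclei contract under AA, which is exactly what makes
pixel-matched comparisons impossible on real data; keeping the masks
identical is what lets the simulator do supervised checks. Nuclear
shrinkage is therefore not modelled at all.

## Noise model

Shot noise only: each pixel is replaced by a scaled Poisson draw with
`photon_scale` expected photons per pixel at the background intensity
$B$ (`lambda = photon_scale * I / B`), default 10,000. Because the
transfer functions are unnormalized lattice sums, normalizing the rate
by $B$ is what makes `photon_scale` a grid-independent photon budget.
Camera read noise is second-order at these levels and is not modelled.
The photon budget is not calibrated to any particular camera.

## Numerical choices

* Frequencies in cycles/um; the pupil cutoff is NA/lambda; zero frequency
  occupies exactly one lattice sample. Grids are even-sized (>= 16) so
  the reflection index map is well defined; the unpaired Nyquist
  row/column carries negligible source weight for sensible parameters.
* DPC division guard: pixels where $|I_a + I_b|$ falls below $10^{-6}$
  of its maximum are zeroed and counted in the provenance.
* Regularization defaults: $\alpha = 10^{-3}$ for noisy data, $10^{-4}$
  for noiseless work. The noiseless round trip on band-limited weak
  phantoms (peak 0.3 rad, annulus 0.1–0.7 of the cutoff, 256 x 256)
  reconstructs with in-band RMSE about 0.01% of peak at
  $\alpha = 10^{-4}$; the error grows monotonically with $\alpha$.
  No apodization or extra frequency weighting is applied before the
  inversion, and no DC restoration or low-frequency inpainting is
  attempted: constant offsets stay unobservable.
* Under shot noise, the *expected* in-band error (averaged over noise
  realizations) is minimized at a larger $\alpha$ than the noiseless
  error; a single realization's minimizer can sit at either end of a
  fine $\alpha$ grid because the joint $|H_{dpc}|$ is bounded below
  in-band, so the property is asserted on the Monte-Carlo average.
* The Abbe-sum reference simulator (one coherent image per source
  sample, intensities summed with the source weights, the full
  $e^{-\mu+i\phi}$ transmittance) bounds the linearization error: on
  default weak phantoms the linear model agrees within about 0.3%
  relative RMS using 200 source samples per arm. Both routes use the
  same truncated source so the comparison isolates linearization alone.
* Phantom placement uses rejection sampling with a bounded attempt
  budget (200 per disk by default); infeasible packings error out
  reporting the achieved count rather than looping forever.
* All randomness flows through explicit seeds; phantom generation and
  noise draws restore the caller's RNG state. Pipeline stages derive
  their seeds deterministically from the root seed and stage name.

## Replicated statistical studies

The group analysis mirrors the fresh-versus-stained comparison of
per-image whole-field phase SDs (SD over the full image, not over
masked regions) with Welch's unequal-variance t test as the default
(a pooled-variance flag exists; p values are reported raw, with an
optional Bonferroni column). Replicated calibration studies — the type-I
rate of the test under identical generator settings and its power at the
default staining effect — need thousands of full
phantom-to-reconstruction chains, so they run on a scaled-down field
(`small_field_settings()`: 64 x 64 at 0.5 um/pixel, 3 nuclei of 2–3 um,
one inclusion) chosen to keep the same structural ingredients at about
5 ms per field. At these settings the default staining effect is large:
power at 50 images/group is essentially 1, and the null rejection rate
sits at the nominal 5% within binomial error.

## What passing tests do and do not show

The phantom reproduces the *structure* of the measurement problem —
band-limited contrast transfer, opposing-arm symmetry, shot noise,
nuclear/background/inclusion composition, and the direction of the AA
effect — not real tissue. It has no cytoarchitecture, no red-blood-cell
lysis, no tissue deformation between states, no depth sectioning or
inter-slice crosstalk in Z stacks (slices are simulated independently;
the 1.5 um default spacing only annotates the stack), and no model of
penetration depth. Published group statistics from real tissue (and
anything involving learned virtual staining) depend on data and trained
weights that a simulator cannot reproduce; the package's group analysis
demonstrates the *machinery* — SD distributions, Welch tests, CNR — under
known ground truth, where its calibration can actually be verified.
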