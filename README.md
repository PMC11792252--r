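# qobmsim

Simulation and phase reconstruction for quantitative oblique
back-illumination microscopy (qOBM), with a synthetic-tissue model of
acetic-acid (acetowhitening) nuclear contrast enhancement.

## The problem

qOBM is an epi-mode quantitative phase imaging technique for thick,
scattering tissue: four oblique illumination arms (two opposing pairs)
produce two orthogonal differential phase contrast (DPC) images,

$$D = \frac{I_a - I_b}{I_a + I_b},$$

which are deconvolved into a quantitative phase map using the system's
weak-object transfer functions. Phase imaging of tissue has notoriously
weak native nuclear contrast; applying acetic acid condenses chromatin,
raising the nuclear refractive index (and hence phase) while
homogenizing non-nuclear structure — the "acetowhitening" effect used
clinically to highlight (pre)cancerous lesions. Quantitatively this
shows up as a *decrease* in whole-image phase variability together with
an *increase* in nuclear contrast-to-noise.

`qobmsim` is for researchers developing or validating DPC-type phase
reconstruction and stain-emulation analyses: it provides the full
measurement chain under known ground truth, so every step — transfer
functions, forward model, inversion, statistics — can be tested.

## What is implemented

* **Optics** — ideal circular pupil (cutoff NA/λ), parametric offset-
  Gaussian effective sources for the four arms, and the partially
  coherent weak-object transfer functions
  $H_{abs}(u) = -[\Gamma(u)+\Gamma^*(-u)]$,
  $H_{ph}(u) = i[\Gamma(u)-\Gamma^*(-u)]$ with
  $\Gamma(u) = \sum_{u'} S\,P^*\,P(u'+u)$, evaluated as exact lattice
  sums ($H_{ph}(0) = 0$ identically: DPC is blind to the mean phase).
* **Phantom** — seeded tissue fields (nucleus / background / inclusion
  labels, phase in radians) and a parametric acetowhitening transform
  (nuclear gain, background homogenization, inclusion gain).
* **Forward model** — weak-object linear simulation of the four raw
  frames, optional seeded Poisson shot noise, per-slice Z stacks, and a
  partially coherent Abbe-sum reference simulator that bounds the
  linearization error.
* **Reconstruction** — DPC formation with guarded division and joint
  two-axis Tikhonov inversion
  $\hat\phi = (H_x^*\hat D_x + H_y^*\hat D_y)/(|H_x|^2+|H_y|^2+\alpha)$.
* **Metrics** — per-image phase SD, nuclear CNR, Welch two-sample
  t tests, and a grouped fresh-vs-stained analysis with figure.
* **I/O and pipeline** — float32 multi-page TIFF interchange with JSON
  sidecars, YAML configuration, and a reproducible end-to-end pipeline
  (`run_pipeline()`), plus a thin CLI at `inst/cli/qobm.R`.

## Worked example

```r
library(qobmsim)

sys <- optical_system(wavelength_um = 0.72, na_objective = 0.6,
                      pixel_um = 0.25, shape = c(512, 512))
optics <- build_optics(sys)

phantom <- generate_phantom(sys, seed = 1)
stained <- apply_aa_transform(phantom, aa_params())

frames <- simulate_intensities(phantom, optics$tfs)
phase <- reconstruct_field(frames, optics$H_x, optics$H_y, alpha = 1e-3)
phase_aa <- reconstruct_field(simulate_intensities(stained, optics$tfs),
                              optics$H_x, optics$H_y, alpha = 1e-3)

print(phantom)
#> qOBM tissue phantom (fresh, weak regime): 512x512 px, 12 nuclei, 3 inclusions
#>   phase range [-0.27, 0.5608] rad, whole-field SD 0.08604 rad
print(phase)
#> qOBM phase image: 512x512 px, alpha = 0.001, range [-0.27, 0.6205] rad

cat(sprintf("whole-field phase SD: fresh %.4f rad, stained %.4f rad\n",
            phase_std(phase), phase_std(phase_aa)))
#> whole-field phase SD: fresh 0.0812 rad, stained 0.0635 rad
cat(sprintf("nuclear CNR: fresh %.2f, stained %.2f\n",
            nuclear_cnr(phase, phantom$labels),
            nuclear_cnr(phase_aa, phantom$labels)))
#> nuclear CNR: fresh 1.41, stained 7.97
```

The stained field carries *less* overall phase variability (0.0635 vs
0.0812 rad) but *more* nuclear contrast (CNR 7.97 vs 1.41) — the two
signatures of acetowhitening in quantitative phase. A replicated
group comparison of per-image SDs separates the populations:

```r
groups <- aa_sd_groups(n_fields = 20, seed = 7)   # fresh vs stained SDs
welch_ttest(groups$a, groups$b)
#> Two-sample welch t test: t = 5.189, dof = 22.14, p = 3.273e-05
```

`run_pipeline(default_config())` runs the same study end to end (50
fields per group by default), writing phantom/frame/phase TIFFs, metrics
CSVs, a violin figure of the SD distributions and a checksummed
manifest; reruns with the same seed are byte-identical.

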