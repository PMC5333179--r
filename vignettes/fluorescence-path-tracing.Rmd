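---
title: "Spectral path tracing of fluorescent scattering volumes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral path tracing of fluorescent scattering volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluortrace)
```

## The problem

Fluorescence microscopy of thick neural tissue images light that has been
absorbed by a fluorophore at an excitation wavelength $\lambda_x$,
re-emitted at a longer emission wavelength $\lambda_m$, and then scattered
many times on its way to the detector. Simulating such images faithfully
requires a *spectral* volume renderer in which energy can move between
wavelengths at exactly one inelastic event per light path, while every
other interaction is elastic scattering governed by the tissue's optical
coefficients. `fluortrace` implements that renderer, together with a
procedural generator of neuron-like tissue blocks to feed it and
spectral-power-distribution (SPD) tools to validate it.

## Radiative model

The medium is a labeled voxel grid. Each label carries an elastic
scattering coefficient $\sigma_s(\lambda)$, a non-fluorescent absorption
$\sigma_a(\lambda)$, a Henyey–Greenstein anisotropy $g$, and optionally a
dye solution. A dye at concentration $C$ (mol/L) with molar absorptivity
$\varepsilon$ (cm$^{-1}$M$^{-1}$, defined at its excitation maximum) and
peak-normalized excitation spectrum $\hat f_x$ contributes a fluorescence
absorption coefficient in the Beer–Lambert form

$$\mu_a^f(\lambda) = \ln(10)\,\varepsilon\, C\, \hat f_x(\lambda)$$

converted once to mm$^{-1}$. Peak normalization of $\hat f_x$ is a
modeling choice: since $\varepsilon$ is quoted at the excitation maximum,
the spectrum must carry relative shape only (an area-normalized
convention would double-count the band's strength). Total absorption is
$\mu_a = \sigma_a + \mu_a^f$ and total extinction
$\sigma_t = \sigma_s + \mu_a$.

A camera-to-light path contributes only if it contains exactly one
inelastic vertex (its *fluorescence visibility* is set); at that vertex
the wavelength changes from the camera-side $\lambda_m$ to the light-side
$\lambda_x$. The probability machinery at the vertex factorizes into a
photon absorption probability and a photon emission probability,

$$p_x(\lambda_x) = \phi\,\frac{\mu_a^f(\lambda_x)}{\mu_a(\lambda_x)},
\qquad
p_m(\lambda_m) = \frac{f_m(\lambda_m)\,\Delta\lambda}
                      {\int f_m(\lambda)\,d\lambda},$$

with $\phi$ the quantum yield. On the package's uniform wavelength grid
(default 300–800 nm in 1 nm steps) $p_m$ is a per-bin mass that sums to
exactly one. Secondary effects — quenching, photobleaching, saturation,
self-emission of the medium — are outside the model.

## Monte Carlo estimator

Paths start at the camera (pinhole model) and are transported at
$\lambda_m$. Free flight through the heterogeneous grid uses woodcock
(delta) tracking against a per-wavelength majorant
$\bar\mu(\lambda) \ge \sigma_t(\mathbf{x},\lambda)$, which is unbiased for
any majorant that dominates the medium; the majorant table is the
pointwise maximum of $\sigma_t$ over the materials present. At a real
collision the event is classified: elastic scattering with probability
$\sigma_s/\sigma_t$ (the direction is resampled from Henyey–Greenstein,
whose sample/eval pair is self-consistent so the importance weight is 1),
otherwise absorption, which is a fluorescence event with probability
$\mu_a^f(\lambda_m)/\mu_a(\lambda_m)$ and terminal otherwise. Fluorescence
is only possible at dye-bearing voxels, and the walk ends at any
absorption: one inelastic vertex per path.

The light (a one-sided diffuse rectangle, monochromatic in all packaged
experiments) is connected by next-event estimation: a point $x_n$ is
sampled uniformly on its surface (pdf $1/A$), $\lambda_x$ is drawn from a
categorical distribution proportional to $L_e(\lambda)\,\hat
f_x(\lambda)$ (a zero-variance choice within the source band; for a
monochromatic source it is a point mass), and the connection is weighted
by the emitted radiance, the geometry term $G$ (light-side cosine over
squared distance), the phase function at the vertex, and the transmittance
of the connecting segment at $\lambda_x$.

Two estimator variants are provided.

* **`estimator = "collision"` (default).** At *every* real collision the
  expected fluorescence contribution of that vertex is added:
  the classification branch is marginalized analytically, giving a
  contribution $\phi\, p_m(\lambda_m)\,\mu_a^f(\lambda_x)\, f_p\, L_e\, G\,
  \tau_x A / \sigma_t(\lambda_m)$ per vertex, after which the walk
  continues or dies by the same classification. The
  $\mu_a^f(\lambda_m)$ factors cancel.
* **`estimator = "event"`.** The light is sampled only when the
  classified event *is* a fluorescence emission, and the vertex-selection
  probability $\mu_a^f(\lambda_m)/\sigma_t(\lambda_m)$ is divided out of
  the same kernel.

Both are unbiased estimators of the same path integral and both are
tested against an independent deterministic quadrature of the
single-scatter integral. The collision form is the default for two
reasons. First, the event form carries a $1/\mu_a^f(\lambda_m)$ factor
that explodes in the red tail of the emission band, where the dye barely
absorbs: rare events with enormous weights produce single-bin SPD spikes
at realistic sample budgets. Second, the event form has *zero* selection
probability at emission wavelengths where the dye does not absorb at all,
so it cannot populate the portion of the emission band beyond the
excitation band's support; the collision form estimates the full band.

One deliberate simplification: multiple scattering on the light-side
$\lambda_x$ segment is folded into the transmittance of the straight
connection rather than continued as a random walk. Inside the tracer that
transmittance is evaluated exactly — the medium is piecewise constant per
voxel, so the attenuation line integral has a closed form obtained by
voxel marching — while the exported `transmittance()` operation also
offers the unbiased ratio-tracking estimator, cross-checked against the
closed form in the tests.

Per pixel, `spectral_samples` emission wavelengths are drawn stratified
from the scene's combined emission distribution (the equal-weight mixture
of the emission pdfs of the dyes present), `spp` paths are traced for
each, and contributions are accumulated into per-wavelength radiance bins
with the sampling pdf divided out. Russian roulette (configurable start
depth and survival floor, with unbiased reweighting) bounds deep paths.
Random streams are counter-based per (pixel, sample, seed) — splitmix64
seeding of xorshift128+ — so renders are bit-identical for a seed,
independent of evaluation order.

## Synthetic dye spectra

The measured Alexa Fluor excitation/emission curves are distributed under
restrictive terms, so the packaged presets pair the published scalar
photophysics (maximum excitation/emission wavelengths, quantum yield,
molar absorptivity, molecular weight for Alexa Fluor 350, 488, 568 and
633) with synthetic Gaussian band shapes of 60 nm FWHM. The Gaussians are
truncated at $\pm 2$ FWHM from the peak, which makes the spectra genuinely
band-limited: illumination outside an excitation band excites exactly
nothing, and the zero-image invariants hold identically rather than to
within floating-point underflow. Measured two-column CSV spectra can be
dropped in via `read_spectrum()` + `fluorophore()` whenever they are
available; every downstream computation is shape-agnostic.

## The emission-validation phantom

`dye_block_scene()` builds the standard validation scene: a cubic
$16^3$-voxel block homogeneously filled with one dye solution at
0.4 mol/L, illuminated head-on by a monochromatic rectangle at the dye's
excitation maximum and viewed from the same side. Two geometric choices
matter and are worth stating plainly.

* **Optical thinness.** At 0.4 mol/L the fluorescence absorption
  coefficient at the excitation peak is of order $10^3$–$10^4$ mm$^{-1}$;
  any micron-scale block is optically deep and inner-filter reabsorption
  visibly shifts the recorded emission peak. The phantom therefore picks
  its voxel spacing so that the block's optical depth *at the dye's
  emission maximum* is `target_optical_depth` (default 0.25). This is the
  rendering analogue of the short cuvette path length a spectroscopist
  uses for concentrated samples, and it bounds the residual peak bias to
  about 2 nm for dyes with strongly overlapping bands. Thicker blocks are
  perfectly renderable and show the physical red shift of concentrated
  solutions.
* **Isotropic scattering, cortex-like magnitude.** The phantom is a
  stirred solution, not fibrous tissue, so it uses $g = 0$ with
  $\sigma_s = 40$ mm$^{-1}$, $\sigma_a = 0.1$ mm$^{-1}$. (Tissue-like
  forward scattering, $g = 0.9$, remains the default of
  `optical_material()`.) Beyond physical plausibility, $g = 0$ removes a
  variance pathology: with a strongly forward phase function the phase
  weight of a light connection spans four orders of magnitude between
  forward- and back-scattered vertices, and rare backscattered
  connections contaminate single SPD bins.

The excitation scan renders the same phantom once per illumination line
(the packaged set is 300, 346, 495, 532, 555, 578, 632 and 700 nm) and
normalizes each run's SPD maximum to the run at the dye's excitation
maximum; amplitudes then track $\hat f_x$ at the lines.

## Synthetic tissue blocks

The tissue generator emulates the geometry of a dense neural block at
desk scale: somata are uniformly positioned in a bounding block with
uniformly random orientations (Shoemake quaternion sampling), and each
cell grows a breadth-first tree of tapered capsule segments from its soma
with configurable stem count, branching probability, segment length,
taper and depth. It does *not* emulate real morphological statistics —
no cell-type diversity, no layer structure, no contact avoidance — so
passing tests demonstrate the correctness of the rendering and
voxelization machinery on neuron-like geometry, not anatomical realism.
Real morphologies can enter through the SWC interchange format.

Meshing turns the soma into an icosphere and each segment into a closed
capsule (cone frustum plus hemispherical caps; the rasterizer and the
analytic volumes used as test oracles describe the same solid).
Components overlap at joints, and each component is individually
watertight — every undirected edge shared by exactly two consistently
oriented faces, which `check_watertight()` verifies and reports.

Solid voxelization marks a voxel iff its center is inside the solid,
decided by ray-crossing parity along a scan axis. Parity is evaluated
*per connected component* and OR-ed: plain parity on a merged mesh would
unfill regions where two closed components overlap, while per-component
parity is exact for unions of watertight solids and remains
axis-invariant. Scan rays that strike an edge or vertex exactly are
retried from a deterministically jittered origin (a fixed sub-voxel
offset sequence), so results are reproducible. A `conservative` flag
additionally marks every voxel touched by a triangle's bounding box.
Block clipping cuts a watertight mesh against the six box planes,
re-chains the cut segments into loops and ear-clips cap faces with
reversed orientation, so clipped solids stay watertight; vertices that
fall exactly on a plane move the plane by a small deterministic epsilon.
The cluster-scale parallel extraction workflow that a production pipeline
would use is reduced to sequential per-cell processing with later cells
winning on overlap.

## Numerical choices and degenerate inputs

* Wavelengths snap to the nearest 1 nm bin; off-grid evaluation of
  spectra is linear interpolation, zero outside the grid.
* `emission_pdf()` normalizes by the discrete bin sum, so the masses sum
  to 1 exactly (the uniform-grid Riemann factor cancels).
* Vacuum (label 0 without an assigned material) never collides and has
  unit transmittance; a zero majorant over a non-vacuum medium is
  rejected.
* SPD peak ties break toward the smaller wavelength.
* Zero-length morphology segments are skipped with a warning; broken
  (non-watertight) meshes are rejected with the offending edges reported,
  and the pipeline names the morphology that produced them.
* The profile-similarity statistic is Pearson correlation of
  peak-normalized profiles over the union of supports, with 0.95 as the
  package's acceptance threshold for emission-profile reproduction — the
  underlying comparison in the literature is visual, so the statistic is
  our operationalization: scale-free and shape-sensitive.

## Problem sizes

The test suite and the acceptance script run the validation experiments
at desk scale, chosen so the whole suite completes in well under a
minute of rendering: emission-peak reproduction at 32×32 pixels with
64 paths × 64 spectral samples per pixel for each of the four dyes;
the eight-line excitation scan at 32 spp × 32 spectral samples;
statistical suites (woodcock distribution, chi-square of emission
sampling, estimator consistency) at $10^5$ draws; the single-scatter
quadrature comparison at $10^4$ paths. Production-quality images of
scattered tissue blocks simply scale `spp`, `spectral_samples` and the
film resolution.

## Known limitations

* Fluorescence classification happens at the camera-side wavelength, so
  the event-triggered estimator cannot reach emission bins outside the
  excitation band's support (use the default collision estimator).
* The light-side segment is attenuated, not scattered; strongly
  multiple-scattering paths between the inelastic vertex and the source
  are under-represented relative to a bidirectional solution.
* No refraction at the block boundary; the volume floats in vacuum.
* Gaussian stand-in spectra are symmetric, unlike real dye bands with
  vibronic shoulders; conclusions about band asymmetry need measured
  spectra.
* The morphology generator is statistical scenery, not anatomy.
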