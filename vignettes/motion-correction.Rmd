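---
title: "Correcting lung-motion artifacts with conjugate partial-angle images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting lung-motion artifacts with conjugate partial-angle images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(parmoco)
```

## The problem

Even under breath-hold, cardiac-transmitted motion of one to a few
millimetres displaces lung parenchyma, vessels and airways during the
quarter- to half-second a CT gantry needs to collect a half scan. The
resulting artifacts — doubled edges, shading beside vessels, distorted
airway walls, CT-value bias — mimic real pathology and corrupt quantitative
measurements. `parmoco` implements a correction that needs no gating and no
segmentation, plus a moving-phantom simulator and the artifact metrics to
evaluate it, all in 2D axial geometry.

## The correction model

**Conjugate PARs.** After fan-to-parallel rebinning, the half scan centred
on the target angle $\theta_c$ spans $[\theta_c-90^\circ,\,
\theta_c+90^\circ)$. Its leading and trailing segments of width $L$
(default: the fan angle, $50^\circ$) produce two partial-angle
reconstruction (PAR) images centred at $\theta_c-90^\circ$ and
$\theta_c+90^\circ$ — conjugate views of the same ray lines, acquired half a
rotation (0.25 s at 0.5 s/rot) apart. They are incomplete images, but they
are *time-localized*, which makes them usable as the two reference states
for motion estimation.

**Band-pass.** PAR images carry strong limited-angle shading. A
difference-of-Gaussians filter ($\sigma_{\text{fine}} = 1$ px,
$\sigma_{\text{coarse}} = 8$ px) removes the shading and the DC offset while
keeping vessel- and airway-scale edges. This is what makes a plain SSD
similarity valid in the next step. The two $\sigma$ are configurable; the
defaults keep structures larger than ~2 px and smaller than ~16 px, the
scale range of the structures of interest at 0.7–1.4 mm pixels.

**Registration.** The motion between the two band-passed PARs is estimated
by free-form deformation: a uniform cubic B-spline lattice (24 mm control
spacing, refined to 12 mm in a second level) whose coefficients minimize

$$\frac{1}{N}\sum_x \big(m(x + D(x)) - f(x)\big)^2 \;+\;
\lambda\, \mathrm{bend}(D),\qquad \lambda = 0.01,$$

by Barzilai–Borwein–seeded gradient descent with an Armijo safeguard. The
optimizer is deterministic (no sampling, no random initialization), the
accepted cost sequence is non-increasing by construction, and identical
inputs give bit-identical fields — properties the test suite asserts. No
segmentation enters anywhere: all edges present in the PARs contribute,
which is exactly what lets fine lung structures be corrected.

**Linear motion model.** The registration yields the displacement $D$ over
the half rotation between the PAR centres. Each view at angle $\theta$ is
assigned the scaled field $\alpha(\theta)\,D$ with
$\alpha = \mathrm{wrap}(\theta-\theta_c)/180^\circ \in [-\tfrac12,
\tfrac12]$: zero at the target view, $\pm\tfrac12$ at the PAR centres.
Over a 0.25 s window, heart-driven displacement is well approximated as
linear in time; since angle and time are affinely related in an axial scan,
$\alpha$ is evaluated from the view angle (avoiding rebinning time
interpolation).

**Motion-compensated FBP.** Backprojection accumulates, for pixel $X$ and
view $\theta$, the filtered view sampled at
$s = (X + \alpha(\theta)D(X))\cdot \hat n(\theta)$ — the material position
of that pixel at the view's time. Filter, per-view weights and scaling are
identical to half-scan FBP, so a zero field reproduces FBP *bit for bit*
(one shared code path, asserted by `expect_identical`). $D$ is evaluated at
the target-frame position rather than inverted per view; the error of this
one-step explicit warp is $O(\|D\|^2\|\nabla D\|)$, negligible for the
few-mm smooth fields the model targets.

## Artifact metrics

For a region $\Omega$, the CT-value distribution $P(h)$ is a Gaussian-kernel
(Parzen-window) density evaluated as probability masses on a 1-HU grid, by
direct summation (not an FFT approximation). Reported quantities:

* **Entropy** $-\sum_h P(h)\ln P(h)$ in nats. Computed over masses, the
  grid step enters the value additively; it is identical across compared
  conditions, so relative comparisons are unaffected. (Density-value
  entropy differs by that same additive constant.)
* **Threshold** $T = \arg\max_h P(h)$ — the mode of the region; ties break
  toward the lowest HU (recorded decision; ties occur only on synthetic
  data).
* **Positivity** $\sum_{X\in\Omega,\ f(X)\le T}(f(X)-T)^2$ and
  **normalized positivity** NP $=$ positivity$/n(\Omega)$: the power of the
  dark shading that motion artifacts produce below the dominant tissue
  value, made comparable across ROI sizes.

The kernel bandwidth is not prescribed anywhere authoritative; the default
is Silverman's rule per region, floored at 5 HU so near-constant regions do
not degenerate, and the bandwidth used is recorded in every result row.
One documented property matters when sweeping the bandwidth by hand: kernel
smoothing *spreads* the estimated distribution, so entropy is non-decreasing
in the bandwidth on a fixed sample. Comparisons are only meaningful at a
common bandwidth policy, which the pipeline enforces.

## The simulated world

The generator stands in for a physical moving-phantom experiment:

* **Phantom.** The `"copd_like"` preset: a 110 mm soft-tissue body disk, a
  95 mm foam lung disk at −800 HU, six air columns (radii 1.5–6 mm) and six
  polycarbonate airway tubes (+100 HU walls of 0.5–3 mm around air lumina).
  It emulates the *kind* of structure in a commercial COPD lung phantom —
  the real layout is proprietary, and the physical phantom's oblique tube
  angles are simplified to in-plane circular cross-sections.
* **Motion.** A rigid in-plane periodic trajectory with half-strokes
  (20, 7.5) mm — the actuator's ±20 mm vertical and ±7.5 mm axial ranges —
  at 0, 5, 10, 15 rpm. The combined 42.7 mm stroke travels
  3.6 / 7.1 / 10.7 mm per 0.5 s rotation at 5 / 10 / 15 rpm; 5–10 rpm
  matches reported cardiac-transmitted lung motion, 15 rpm is deliberately
  beyond it. The actuator waveform is not documented; a sinusoid is the
  default and a triangle wave is available, and the per-rotation travel
  conversion depends only on stroke × frequency, so the choice is flagged
  rather than load-bearing.
* **Acquisition.** Exact analytic line integrals (chord lengths × µ, with
  µ = µ_water(1 + HU/1000), µ_water = 0.019/mm ≈ 70 keV) at 736 channels
  over a 50° fan, 1200 views per 0.5 s rotation, source 600 mm from the
  isocenter; motion frozen within a view (view duration ≈ 0.4 ms makes
  intra-view blur negligible). Optional Poisson transmission noise, off by
  default, because the metrics here are motion-driven and noise-free runs
  are byte-for-byte reproducible.
* **Slices.** The physical experiment evaluated 17 slices of a sub-volume;
  a 2D simulator has one slice, so "slices" are emulated as evenly spaced
  actuator phase offsets (optionally with fresh noise realizations),
  default 17, configurable. Reports flag this stand-in.

**What a green test does and does not establish.** The simulator produces
the same *mechanism* of artifact (view-inconsistent projections over the
half scan) and reproduces the qualitative and trend behaviour: artifact
power rising with travel per rotation for FBP, staying at the static level
after compensation. It does not reproduce the absolute NP or entropy
magnitudes of any physical experiment — those depend on the physical
phantom's exact structure, scanner noise, reconstruction kernel and an
undisclosed KDE bandwidth — so absolute magnitudes are out of scope by
design, and only printed *arithmetic* (stroke conversions, percent changes)
is checked exactly.

## Numerical choices

* **Rebinning** is bilinear in (β, γ) on the unwrapped β axis, trimmed half
  a fan angle at each end; each parallel view carries the time of its
  central fan view. Closed-form checks (disk Radon transform ≤ 1%,
  conjugacy, mass conservation ≤ 0.5%) pin the implementation.
* **Ramp filter**: band-limited discrete Ram-Lak kernel, zero-padded to the
  next power of two ≥ 2× the radial length; optional Shepp-Logan or Hann
  apodization. Hann is the default for PAR images (stabilizes
  registration); the unapodized kernel is used for final images.
* **Half scan** uses exactly 180° of parallel views with unit weights — a
  parallel half scan is complete, so no short-scan (Parker) weighting is
  needed after rebinning. PARs are raw partial sums with the same per-view
  weights; summing before + middle + after therefore equals the partial
  reconstruction over the same 180° + L window exactly (a partition-of-views
  identity asserted to 1e−10 in the attenuation domain, where the HU map's
  affine offset cancels).
* **Default grids**: 512 × 512 at 0.703 mm for a 360 mm display FOV;
  256 × 256 in tests and experiment configurations to keep desk runtime in
  seconds.
* **Sampling guard**: geometries with fewer than ⌈πn/2⌉ views per rotation
  for n channels warn about angular undersampling (the default geometry
  satisfies the guard).
* **Degenerate inputs**: empty ROIs, zero-variance paired differences,
  non-finite registration inputs, overlapping-but-not-nested analytic
  primitives, and insufficient angular coverage all raise errors naming the
  problem.

## Design choices that were genuinely open

* *Registration direction.* Whether the original formulation registers
  before→after or both→target is not documented. Here the forward
  before→after field is estimated and the target state is interpreted as
  the α = 0 midpoint — symmetric-midpoint convention — because the target
  time sits exactly midway between the PAR centres.
* *Compensation formulation.* View-wise warped backprojection (sample the
  detector at the displaced pixel position) was chosen over
  warp-PAR-blocks-then-sum: it is the standard motion-compensated FBP form,
  exact for per-view rigid motion, and degenerates exactly to FBP.
* *PAR normalization.* PARs are kept as raw partial sums; registration is
  insensitive to a global scale after band-passing, and the scaling is
  recorded in metadata rather than normalized away.
* *Experiment parameterization.* Conditions are specified by rpm but
  reported as displacement per rotation (mm), the quantity that actually
  drives artifact severity, so the stated travel values (3.6/7.1/10.7 mm)
  hold for any waveform.

## Known limitations

* 2D axial, single slice; no helical pitch handling, no z-motion, no
  cone-beam geometry.
* Rigid phantom motion only in the simulator — real lung motion is elastic
  and decays with distance from the heart; the registration is non-rigid
  and does not rely on rigidity, but the simulator cannot demonstrate that.
* Monochromatic projections: no spectra, scatter, bowtie or detector
  physics.
* The estimated field underestimates the displacement component along the
  poorly-resolved direction of the limited-angle PARs by up to ~10–15% at
  large motion; the acceptance trend criterion is met regardless, and the
  ground-truth-field path isolates this as a registration (not
  reconstruction) limitation.
* No diffeomorphic guarantee on the FFD; at the few-mm displacements and
  24/12 mm control spacings used, folding has not been observed.
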