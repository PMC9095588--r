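---
title: "Quantifying polar filament patterns on spherical vesicle surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polar filament patterns on spherical vesicle surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphereglide)
```

## The system and the measurement problem

In a spherical gliding assay, actin filaments are driven by membrane-anchored
myosin motors along the inner surface of a giant unilamellar vesicle (GUV,
radius of order 18 um). Because motors slip on the fluid bilayer, colliding
filaments cannot cross each other: a filament stops at an obstacle and
escapes only by bending its tip and aligning. This stop-and-go interaction
makes collisions effectively polar and drives filaments to assemble into
elongated co-moving structures. On a closed sphere these structures organize
into a small taxonomy of patterns: *streams* (motile elongated groups
covering a fraction of the surface), *vortices* (closed loops circulating at
a latitude between equator and pole), *bands* (surface-spanning rings
circulating at the equator with two +1 defects at the poles),
*partially jammed* states (a persistent, nearly immobile +1/2 defect
coexisting with moving structures) and *globally jammed* states (four
almost frozen +1/2 defects).

`sphereglide` provides the quantitative machinery to analyze such data: the
projections between image space and the sphere, arc-length kinematics,
angular mean squared displacements, topological defect statistics, density
criteria and a rule-based pattern classifier — plus seeded kinematic
generators that produce ground-truth-labelled synthetic scenes for testing
every step.

## Geometry and kinematics

All modules share one convention: colatitude $\theta \in [0, \pi]$ measured
from the $+z$ pole ($\theta = \pi/2$ is the equator) and azimuth
$\phi \in [0, 2\pi)$. A position marked at $(\phi, \theta)$ on an
equirectangular projection lifts to

$$\mathbf r = R(\cos\phi \sin\theta,\ \sin\phi \sin\theta,\ \cos\theta),$$

and a point $(x, y)$ on a confocal plane (relative to the sphere centre)
lifts to $(x, y, \pm\sqrt{R^2 - x^2 - y^2})$, the sign chosen by the imaged
hemisphere. The instantaneous speed of a tracked structure is the
great-circle arc between consecutive positions divided by the frame
interval,

$$v = \frac{R}{\Delta t}\,\cos^{-1}\!\left(\frac{\mathbf r_{i+1}\cdot\mathbf r_i}{R^2}\right).$$

Numerically we evaluate the central angle as
$\mathrm{atan2}(|\mathbf r_1 \times \mathbf r_2|, \mathbf r_1 \cdot \mathbf r_2)$
rather than the bare arccosine: jammed defects move nanometres per minute on
an 18 um sphere, i.e. angles of order $10^{-7}$ rad, where the arccosine of
a dot product loses most of its precision. Both forms agree to within
$10^{-10}$ for well-separated points (this is tested).

Tracked positions are never exactly on the sphere (manual clicks, pixel
centres), so `trajectory()` radially projects positions whose radial
deviation exceeds $10^{-6} R$ and warns; smaller deviations are kept as
given.

## Angular mean squared displacement

For a trajectory sampled at regular intervals the package computes the
time-averaged (overlapping-window) MSD of each angular component
separately, $\langle(\theta(t+\tau)-\theta(t))^2\rangle$ and
$\langle(\phi(t+\tau)-\phi(t))^2\rangle$. Two choices deserve comment:

* **Seam handling and saturation.** The azimuth series is first unwrapped
  across the $0/2\pi$ seam; each lag difference is then reduced to the
  bounded increment in $(-\pi, \pi]$. The first step removes artificial
  $2\pi$ jumps; the second expresses that on a closed surface no two
  positions are more than half a revolution apart, so the MSD must saturate
  at long lags. Before saturation a uniform rotation at rate $\omega$ gives
  exactly $(\omega\tau)^2$ (log-log slope 2); beyond half a period the
  bounded increment shrinks again and the fitted exponent drops below 1.
  Both regimes are asserted in the tests.
* **No metric correction.** The $\phi$-MSD is reported in bare coordinate
  radians, without a $\sin\theta$ factor, exactly as the defining formula
  reads; near-polar trajectories therefore show inflated $\phi$
  displacements. This is a property of the observable, not a bug; use the
  arc-length speeds for metric statements.

`msd_scaling_exponent()` fits $\log \mathrm{MSD}$ against $\log\tau$ by
least squares. The short-time fit range is a genuine user choice — the
defining data do not fix it — so it is an explicit parameter with the first
quartile of available lags as the default. Single-trajectory time-averaged
MSDs of diffusive motion fluctuate strongly at lags beyond a few percent of
the record length; the diffusive-regime tests therefore average the MSD
over ten independent seeded walks before fitting, and fit only lags up to
20 frames of a 1000-frame record.

## Projections

`project_equirectangular()` samples a voxel stack along the radial segment
$[R - h, R + h]$ in each pixel direction with trilinear interpolation and
reduces by the maximum (the mean is available), matching the
maximum-projection style of fluorescence imaging. The shell half-width
default $h = 1$ um is our choice; the imaging depth of the original
projection tool is not documented. The default map resolution,
$n_\phi = 2 n_\theta = 720$ px, puts one pixel at about 0.16 um on the
equator of an 18 um vesicle — finer than tracking noise; tests use coarser
maps purely for speed.

`fit_sphere()` is the algebraic (Coope) least-squares sphere fit on voxels
above the 99th intensity quantile, solved by one linear regression with no
iterative refinement. On 20 seeded noisy synthetic shells (Gaussian radial
profile, SNR 5, 0.5 um voxels) the recovered radius is well within one
voxel of the true 18 um (tested).

`latitude_intensity_profile()` averages each $\theta$ row with equal pixel
weight — i.e. exactly what one reads off an equirectangular image, which is
how band profiles are conventionally presented — and normalizes to unit
trapezoidal integral over $\theta$. A $\sin\theta$-weighted variant gives a
true per-area density when needed.

## Defect statistics

Charges are stored in integer half-units so that sums are exact: four +1/2
defects total +2 with no floating point involved. `validate_poincare_hopf()`
encodes the topological constraint that an orientation field covering the
whole sphere carries total charge +2; whether a configuration covers the
surface is a categorical input flag, not something inferred from images,
because the experimental distinction (confinement-bound versus
topology-bound patterns) is categorical. Defect positions themselves are
input data — in the source experiments they were identified manually — so
automatic defect detection is out of scope.

The four-defect geometry is summarized by the six pair angles
$\theta_{ij}$ between centre-to-defect radii. The regular tetrahedron gives
a mean pair angle $\arccos(-1/3) \approx 109.47^\circ$, four points equally
spaced on a great circle give $120^\circ$, and
`classify_configuration()` separates the two with a tolerance capped below
half the 10.53-degree gap. The jammed-scene generator initializes at any
target mean angle by solving within the tetragonal disphenoid family (two
points at colatitude $\beta$, two at $\pi - \beta$), which interpolates
monotonically between the tetrahedron ($\beta = \arccos(1/\sqrt 3)$) and
the planar square ($\beta = \pi/2$).

A stability note: the regular tetrahedron is a critical configuration of
the mean pair angle, so small positional diffusion perturbs
$\langle\theta_{ij}\rangle$ only at second order. The generated jammed
scenes consequently hold their mean pair angle to a fraction of a degree
over 30 frames — consistent with the experimentally observed stability of
jammed defect configurations, and well inside the 2-degree stability
tolerance the package uses as a default (the experimental account gives no
numeric tolerance; 2 degrees is ours).

## Density criteria

With encapsulated monomer concentration $c_A$, vesicle radius $R$, about
370 monomers per um of filament and effective filament length $L$, assuming
complete polymerization and membrane binding,

$$\rho = \frac{c_A N_A \cdot \tfrac43\pi R^3}{(370\,/\mathrm{um}) \cdot L \cdot 4\pi R^2}
       = \frac{c_A N_A R}{3 \cdot 370 \cdot L},$$

the packing fraction is the rectangle approximation $\phi = \rho L w$ with
filament width $w = 7$ nm, and the passive isotropic-nematic (Onsager)
threshold for hard rods is $\rho^* = 3\pi/(2L^2)$.

Two filament lengths appear as defaults and deserve an explanation. The
length distribution has mode 0.6 um (`L_mode_um`). The effective length
used in the density conversions defaults to 0.55 um (`L_eff_um`), because
the three printed reference values these functions reproduce
($\rho \approx 1.8$–$10.7$ filaments/um^2 for 100–600 nM,
$\phi \approx 0.007$–$0.04$, and $\rho^* \approx 15.6$ filaments/um^2) are
mutually consistent for $L \approx 0.55$ um but not for 0.6 um
($3\pi/(2\cdot 0.6^2) = 13.1$). Both lengths are exposed parameters and
never hard-coded, and `onsager_critical_density(0.6)` is a one-liner for
anyone preferring the mode length. Either way the observed densities sit
well below $\rho^*$: the patterns are activity-induced, not a passive
liquid-crystal transition.

## Pattern classification

The original pattern assignment was by eye; `classify_pattern()` is our
operationalization, and every threshold is exposed in `pattern_config()`:

| parameter | default | meaning |
|---|---|---|
| `c0` | 0.005 | coverage below which a vesicle is empty |
| `c_full` | 0.8 | coverage counting as "full surface" |
| `v_jam` | 15 nm/s | below this, motion counts as jammed |
| `v_move` | 25 nm/s | at or above this, structures count as moving |
| `beta0_deg` | 15 deg | band peak distance from equator (no-defect path) |
| `rel_threshold`, `min_threshold` | 0.05, 0.1 | coverage intensity threshold |
| `ridge_occupancy` | 0.9 | azimuth fraction needed for a closed ridge |

The speed cuts sit between the two observed scales (moving structures
40–50 nm/s, jammed motion below 5–10 nm/s). Decision order: empty; globally
jammed (full coverage, slow, at least four half-charge defects); band (full
coverage, moving, two +1 defects — or, without defect input, an
equator-peaked closed ridge); partially jammed (a slow half-charge defect
among moving structures); vortex (closed constant-latitude ridge at partial
coverage, moving); else stream. The feature vector (coverage, profile peak,
ridge occupancy and latitude spread, speeds, defect counts) is always
returned so a call can be audited. Missing speed or defect inputs relax the
corresponding conditions rather than failing.

`coverage_fraction()` weights pixels by $\sin\theta$, so equirectangular
area distortion does not bias coverage.

## Synthetic scenes: what they emulate, and what they do not

The generators are *kinematic*: prescribed motion, not simulated filament
mechanics. The experiments characterize the collision rules qualitatively
but provide no equations of motion, so a rod-collision simulator would be
invention; prescribed scenes are exactly what is needed to test the
analysis operations, which is their role here.

* Structures move on constant-latitude circles at constant arc speed
  (off-equator circulation is the experimentally distinctive feature);
  the azimuthal rate is $\omega = v/(R\sin\theta_0)$.
* Jammed defects perform tangent-plane Gaussian steps of per-component
  variance $2D\Delta t$, re-projected radially (error $O(\mathrm{step}^2/R^2)$,
  negligible at nanometre steps). With the default $D = 10^{-4}$ um^2/s and
  $\Delta t = 60$ s the mean step speed is
  $\sqrt{\pi D/\Delta t}\approx 2.3$ nm/s, below the 5 nm/s scale of
  jammed defects.
* Rendering draws each structure as a Gaussian-cross-section tube around
  its 3D curve, evaluated in each map pixel's direction, so the
  equirectangular area distortion does not distort tube widths; bands are
  drawn as an equator-peaked Gaussian latitude profile (SD 0.6 rad).
  Additive Gaussian intensity noise (SD 0.05 of unit amplitude) and
  per-frame angular jitter (SD 0.002 rad, i.e. ~36 nm — below map pixel
  size) are the default noise model.
* Voxel stacks carry a radial shell profile: Gaussian (SD 1 um,
  diffraction-blurred membrane) or flat-top (2 um, uniform membrane of
  finite thickness). The flat-top profile is the right oracle for
  shell-uniformity checks because a voxelized Gaussian shell carries
  $O(h^2/\sigma^2)$ trilinear-interpolation anisotropy of order a percent,
  which would measure the interpolation rather than the projection.
* Filament lengths draw from a log-normal with mode 0.6 um; the log-SD is
  not documented in the source material, so the default 0.5 is our choice,
  exposed as a parameter.
* The default fixture suite (`fixture_suite()`) contains stream, vortex,
  double vortex (concentric, opposite handedness), band (with the two +1
  pole defects) and globally jammed scenes; the double vortex carries the
  ground-truth label "vortex" since it is a vortex pattern of the taxonomy.
  Partially jammed scenes are composed in the tests from a stream scene
  plus a slow +1/2 defect.

What the synthetic scenes deliberately do **not** contain: filament-scale
texture, stop-and-go speed fluctuations, photobleaching or blinking,
out-of-focus light, motor-density coupling, pattern formation dynamics
(merging, looping). Passing the classifier and recovery tests on these
scenes therefore demonstrates that the *analysis operations* are correct
and internally consistent at the experimental speed/size scales — it is not
evidence that the classifier reproduces human labels on real micrographs.

## Numerical choices and problem sizes

Determinism: every stochastic generator takes a seed and derives
independent sub-streams for trajectories, diffusion and rendering noise;
identical inputs give bitwise-identical noise and
floating-point-reproducible trigonometry. Degenerate inputs fail loudly:
poles with nonzero circulation speed, nonpositive frame intervals,
off-sphere points beyond tolerance, all-zero maps in normalizations, zero
MSDs in log fits.

The shipped tests and the acceptance script use deliberately modest problem
sizes — 79^3-voxel stacks (0.5 um voxels), 90 x 180 to 180 x 360 maps,
6–30 frame movies, 10 seeds per pattern class, 20 noisy shells for the
sphere-fit recovery — chosen so the whole suite runs in well under a minute
per module while every statistical assertion still has comfortable margin
(e.g. the tracker-versus-manual speed agreement is ~3% against a 10%
criterion). Defaults inside the package are sized for real data instead
(720 px maps).

## Known limitations

* The feature tracker reports integer-pixel positions; per-step speeds are
  quantized at one map pixel per frame interval (~5 nm/s at the default
  map resolution and 60 s interval at the equator). Averaged over a track
  the quantization telescopes away; instantaneous values wobble.
* The tracker follows a single template per feature with no re-detection,
  linking or gap closing; a track simply ends when correlation drops.
* Classification thresholds are calibrated on the synthetic amplitude
  scale (structures of order unity intensity); real data need
  `pattern_config()` adjusted, in particular `min_threshold`.
* `phi`-MSD near the poles mixes coordinate and metric effects by design
  (see above).
* Sphere fitting assumes a single, roughly complete shell; partial caps or
  two touching vesicles will mislead the algebraic fit.
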