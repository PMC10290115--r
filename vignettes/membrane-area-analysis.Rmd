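---
title: "Measuring photoswitchable membrane-area changes in red blood cells"
author: "rbcswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring photoswitchable membrane-area changes in red blood cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcswitch)
```

## The measurement problem

An amphiphilic azobenzene surfactant photoisomerizes between an extended
*E* form (UV-absorbing, membrane-bound) and a bent *Z* form (more
hydrophilic, mostly dissolved). When red blood cells (RBCs) are bathed in
such a surfactant, the *E* isomer intercalates into the outer hemileaflet
of the plasma membrane and inflates the membrane area; switching to the
*Z* isomer deflates it again. This package quantifies that reversible
area change from three kinds of raw data: micropipette aspiration movies,
adherent-cell brightfield movies, and single-cell images of free-floating
RBCs, plus the supporting partitioning assays.

A partially aspirated RBC acts as an area transducer. The cell is held in
a micropipette (inner radius *a* ≈ 1 µm) by a hydrostatic suction
pressure; any change of membrane area moves the "tongue" — the membrane
cap inside the pipette — by a distance δl that is much easier to measure
than the sub-pixel change of the outer cell radius. The analysis chain is
track δl → convert to area via the three-section model → fit the
relaxation kinetics → compute pressure and work.

## Sub-pixel interface tracking

Per frame, a user-supplied rectangular ROI along the pipette (width about
half the pipette width) is averaged across the pipette into a 1-D axial
intensity profile. The profile is differentiated (forward first
difference, assigned to the midpoint between samples — the stencil is a
package choice, the method only requires "the derivative"), the extremum
of the configured polarity is found, and a parabola through the extremum
and its two neighbours gives the interface position as the vertex
abscissa:

x\* = i + (y_{i−1} − y_{i+1}) / (2 (y_{i−1} − 2 y_i + y_{i+1})).

Two numerical choices matter:

* **Axial pre-smoothing** (`smooth_sigma`, default 1.5 px). The ROI
  averaging suppresses noise across the pipette; the same logic applies
  along it. A Gaussian smoothing of the order of the optical edge width
  acts as a matched filter: it leaves a symmetric edge position unbiased
  while reducing the derivative noise several-fold. On synthetic stacks
  this brings the tracking error at a contrast-to-noise ratio of 10 from
  ≈0.6 px RMS to ≈0.15 px, and the noise-free bias stays below 0.01 px.
  Set `smooth_sigma = 0` for the raw textbook estimator.
* **Vertex stencil**: 3 points by default (the minimal quadratic fit); a
  5-point least-squares variant is available but is more sensitive to
  outliers on noisy derivatives since it widens the fitted neighbourhood.

Failure is explicit: frames whose derivative extremum lies on the profile
boundary, or whose parabola has zero curvature, are returned with
`ok = FALSE` and are excluded downstream, never interpolated silently.

Tracked positions increase *into* the pipette. Tracking is invariant
under affine intensity rescaling and equivariant under integer
translations (both are tested properties).

Stabilization (`stabilize_stack`) registers each frame to the first by
whole-pixel translation at the peak of the zero-padded FFT
cross-correlation. It replaces an interactive image-stabilizer plugin
workflow with an equivalent automatic step; it is applied by default in
the autocorrelation workflow (where slow stage drift is the dominant
nuisance) and is optional for aspiration stacks, whose ROI is chosen to
contain the full range of interface motion.

## The three-section geometry model

The aspirated cell is modelled as (I) a hemispherical cap of radius *a*
at the tongue tip, (II) a cylinder of radius *a* and length *l* in the
pipette, and (III) a sphere of radius *r* outside the pipette with the
cap subtended by the pipette mouth removed:

* V_I = (2/3)πa³, V_II = πa²l, V_III = (π/3)(2r³ + (2r² + a²)√(r² − a²))
* A_I = 2πa², A_II = 2πal, A_III = 2πr(r + √(r² − a²))

Only *a* can be read reliably from the images, so (*r*, *l*) are solved
from the canonical RBC volume (90 fL) and surface area (136 µm²). The
area constraint is linear in *l*, so *l* is eliminated and the volume
constraint becomes a 1-D root-finding problem in *r*, solved by bracketed
Brent iteration (tolerance 10⁻¹² µm) on r ∈ (a(1+10⁻⁶), 10 µm]. The
solution is verified in tests against an independent bisection oracle
built on the algebraically distinct sphere-minus-cap formulas, and
against a brute-force 10⁻⁴ µm grid. The system has a physical solution
(r > a, l ≥ 0) only for a ≲ 1.4 µm; larger pipettes raise a "no physical
solution" error with the bracket diagnostics. Experimental pipettes
(a ≈ 0.5–1.1 µm) are comfortably inside the valid range.

A tongue displacement δl at constant cell volume forces
V_III,new = V_III − πa²δl, which is solved for r_new by the same
bracketed iteration. The new total area is

A_new = A_I + 2πa(l + δl) + 2π r_new (r_new + √(r_new² − a²)),

and ΔA = A_new − 136 µm², reported absolutely and as a percentage.
One modelling ambiguity deserves a note: a published form of the
truncated-sphere area after the switch keeps the *old* radius in the
prefactor, 2πr(r_new + √(r_new² − a²)). That mixed form is not the area
of any of the model's surfaces and overstates ΔA by ≈40% at the
cohort-mean displacement; the geometrically consistent form (r_new in
both places) is the default here, with the mixed variant available as
`legacy_area_prefactor = TRUE` for comparison. Volume conservation after
every update is enforced to 10⁻⁹ µm³ and tested, as is the δl → −δl
round trip.

With the cohort-mean inputs (a = 1.058 µm so that πa² = 3.52 µm²,
δl = 0.82 µm) the model yields ΔA ≈ 2.98 µm² ≈ 2.2% of the cell surface
— the number `scripts/acceptance.R` recomputes.

## Switching kinetics

Traces are segmented at the schedule's switch instants (a frame landing
exactly on a switch belongs to the later phase), cycles are aligned on
their UV onset, linearly interpolated onto a common grid and averaged
pointwise. The relaxation model y(t) = a + b·e^(−t/τ) is fitted by
Levenberg–Marquardt least squares on the original (not log-transformed)
scale, because the measurement noise is additive on position. Starting
values are a₀ = last point, b₀ = first − last, τ₀ = duration/5, with
τ bounded in (0, 10 × duration]. Segments with no resolvable amplitude
(|b| below the residual noise) are flagged `identifiable = FALSE`
instead of returning a meaningless τ. Both analysis modes are available:
per-phase fits of each cycle, or one fit to the cycle-averaged trace
(`fit_cycle_average`); the cycle-averaged mode is the default
pipeline route.

The cycle-average grid is exact only when switch instants coincide with
camera frames. With switches off the frame grid, the linear
interpolation of a convex exponential across misaligned cycles biases
the fitted τ upward (≈8% for τ = 240 ms sampled at 75 ms). The
synthetic protocol therefore uses phase durations of 1.95 s = 26 frames
— the frame-synchronized triggering any camera-clocked rig provides.
For data where switches are not synchronized, prefer per-segment fits.

The intensity trend τ(I) = τ_plateau + c·e^(−I/I₀) is fitted as a
descriptive saturation curve; the scientifically meaningful outputs are
the plateau and the monotone-decrease check (Kendall correlation), since
the functional form is a guide to the eye, not a mechanistic model.

## Mechanics

ΔP = ρgΔh with ρ = 1000 kg/m³ and g = 9.81 m/s²; with Δh in µm the
result is in pN/µm², numerically equal to Pa (979 µm → 9.604 pN/µm²).
Work W = A·Δd·ΔP comes out in pN·µm = 10⁻¹⁸ J = 1 aJ and is also
reported in thermal units using kT = 4.11 × 10⁻²¹ J (T ≈ 298 K). A
relative area change maps to surfactant content as
mol% = area% / footprint_ratio, with footprint_ratio = 0.5 (a
single-tail surfactant occupies roughly half a lipid footprint), so a 2%
area change corresponds to 4 mol%.

## Autocorrelation and roughness

For adherent-cell movies, "autocorrelation" means the Pearson
correlation between the pixel vectors of frame 1 and frame t over a
cropped ROI — one scalar per frame, starting at exactly 1. This is the
only reading under which the trace can "drop on switches and recover to
a plateau". Slow decorrelation from focus drift and intracellular motion
is removed by fitting y(t) = a·e^(−t/τ) + b and subtracting it; the
residual square-wave excursions count reversible shape changes
(`count_excursions` compares each opposite-phase interval mean against
the reference-phase baseline, threshold 0.05 correlation units).

Roughness of a free-floating cell is the population standard deviation
of all pixel values strictly inside a user-placed circle within the
cell, avoiding the cell boundary — placing the circle over the rim would
let the smooth cell's dark rim dominate the score and invert the
comparison. Echinocyte versus discocyte cohorts are compared with the
classical pooled-variance two-sample t test (Welch available by flag),
with the conventional three-asterisk annotation at p < 0.001.

## Partitioning and PMF post-processing

Shake-flask absorbances are converted to concentrations through linear
Beer–Lambert calibrations per phase; P_OW = c_oct/c_aq. The cohort
headline is the mean of per-sample log₁₀ P (matching how a 0.88 cohort
mean coexists with a mean P of 8.02, whose log is 0.90); the
log-of-mean is also reported. Outlier samples are excluded only by
explicit, recorded request (an optional >2 sd rule exists but is off by
default).

Density profiles along the membrane normal are converted to potentials
of mean force by PMF(z) = −ln ρ(z) in kT units; non-positive densities
are masked. The Boltzmann-weighted partition ratio of two species is
∫e^(−PMF_A)dz / ∫e^(−PMF_B)dz by trapezoidal quadrature on the common
support. Alignment is deliberately optional: pinning both profiles to
zero at a reference position (e.g. the lipid head-group position)
isolates the *shape* difference inside the membrane, but it also erases
any constant offset between the profiles — and a constant offset ΔW is
exactly what an overall partitioning ratio e^(−ΔW) expresses (0.4 kT ↔
0.67). The default therefore uses the profiles as given and `align_at`
activates the head-group convention. Reproducing a specific simulated
ratio requires the original molecular-dynamics density profiles, which
are consumed as data here, not recomputed.

## The synthetic-data generators

The generators emulate exactly the statistical structure the analysis
assumes, with defaults chosen as the study conditions:

* **Tongue traces**: piecewise exponentials between plateaus
  (τ_UV = 0.24 s, τ_VIS = 0.49 s, amplitude 0.82 µm — the cohort means),
  additive Gaussian noise, 75 ms frame interval; 10 cycles of 1.95 s
  phases.
* **Aspiration scenes**: bright background (1000 counts), dark tongue
  (200 counts), pipette radius 1.05 µm at 0.1 µm/px (the pixel size is
  arbitrary — no magnification is implied by the data), erf-profile edge
  with effective width √(edge² + psf²) so ground truth is analytic,
  optional uniform lateral drift, camera counts clamped non-negative.
  "SNR 10" in tests means edge contrast / pixel noise = 800/80.
* **Cell movies**: a textured disc whose texture is a per-pixel AR(1)
  process with autocorrelation e^(−dt/τ_decay) (so the frame-1 to
  frame-t correlation decays exponentially by construction) and whose
  boundary band expands on VIS phases.
* **Morphology**: a smooth radial relief (dark rim, lighter centre) for
  discocytes; echinocytes add sinusoidal radius modulation and matching
  angular interior ripple from `n_spicules` lobes. With amplitude 0 both
  renders are identical. The default render is noise-free so shape — not
  a noise realisation — drives the roughness comparison.
* **Shake flask**: total solute mass split so c_oct/c_aq = 10^logP,
  observed through the linear calibrations with Gaussian absorbance
  noise.

What the generators deliberately do **not** model: diffraction beyond a
Gaussian blur, hemoglobin absorption, Poisson photon statistics (an
additive-Gaussian camera model is used; a Poisson option would be the
natural extension), membrane tension or bending energetics, and cell
aging heterogeneity. Passing tests on this synthetic data therefore
demonstrates the correctness of the estimators under the assumed noise
model, not robustness to every optical artefact of real microscopy.

## Problem sizes and tolerances

The test battery uses 200-frame stacks (40 × 120 px), 50-seed cohorts
for τ recovery, 10⁴ random geometries for the closed-form identities,
20 pipette radii against the grid oracle, and 20 paired morphology
seeds — sizes at which every Monte-Carlo margin in the assertions is
comfortable. Root finding uses 10⁻¹² µm tolerance; volume conservation
is asserted at 10⁻⁹ µm³; nonlinear fits run up to 200–300
Levenberg–Marquardt iterations and flag non-convergence rather than
falling back.

## Known limitations

* The tracker follows a single interface; multi-interface scenes and
  automatic pipette detection are out of scope (the ROI is supplied by
  the user, mirroring the manual crop of the original workflow).
* Stabilization corrects whole-pixel in-plane translation only (sub-pixel
  estimation is available, correction stays integer).
* The three-section model assumes a spherical outer cell segment; strongly
  non-spherical (e.g. crenated) aspirated cells violate it.
* The τ-versus-intensity fit is descriptive; no photokinetic mechanism
  links intensity to isomerization rates.
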