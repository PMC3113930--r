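---
title: "Measuring nanomaterial VSSA by simulated bright-field electron tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nanomaterial VSSA by simulated bright-field electron tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The European Commission's proposed nanomaterial definition admits a material
as nanostructured when its volume-specific surface area (VSSA) exceeds
60 m²/cm³.  Conventional bright-field electron tomography offers a direct
route to that number: record a single-axis tilt series of particles deposited
on a support film, align and reconstruct the series into a 3D volume, segment
the particles, triangulate their surfaces, and read the surface area `A` and
enclosed volume `V` straight off the mesh.  Then

    VSSA = A / V × 1000        (1 nm⁻¹ ≡ 1000 m²/cm³),

and a perfect sphere of diameter `d` nm has VSSA = 6000/`d` m²/cm³ — 300 for
a 20 nm particle, five times the threshold.

`nanovssa` implements that entire workflow against simulated specimens with
known ground truth, so every stage — acquisition geometry, alignment,
reconstruction, segmentation, metrology, statistics — can be validated
quantitatively.  The validation logic mirrors how spherical colloidal gold is
used as a control in practice: because those particles are known to be
spheres, the 3D-measured areas and volumes can be checked against the
areas `4πr²` and volumes `4/3πr³` calculated from the equivalent circle
diameter (ECD) of each particle's zero-tilt projection, with Spearman rank
correlation quantifying the agreement, and a one-sample t-test comparing the
per-reconstruction VSSA values against the 60 m²/cm³ threshold.

## Phantoms and what they emulate

Three particle classes cover the morphologies of interest:

* **Spheres** (default 20 nm): the colloidal-gold control.  Ground truth is
  analytic.
* **Branched particles**: a core sphere (default 30 nm) with capsule-shaped
  surface extensions (default 12 spikes protruding 10 nm with 3 nm radius,
  overall extent about 50 nm).  Only images of such particles are published;
  the sphere-plus-capsules parameterization is this package's own, chosen for
  analytic tractability and a tunable spike count.
* **Aggregates**: random-walk clusters of overlapping spherical subunits
  (diameters drawn from 8–20 nm) attached at centre distance 0.8 × the sum
  of radii — interconnected subunits with visible necks, emulating
  precipitated/pyrogenic silica.  The overlap factor guarantees a single
  connected component.

Particles are rasterized from signed-distance primitives with 3×3×3 subvoxel
anti-aliasing at the boundary; interiors have unit density (the specimens are
homogeneous metal or silica, so mass thickness is proportional to geometric
thickness).  Ground truth for non-analytic shapes is measured by the same
isosurface metrology on a 4×-finer rasterization of the same implicit
geometry, so truth and measurement never share a grid resolution.

Fields of several particles (`rasterize_field()`) place them, by default, as
grid-deposited specimens actually lie: resting on the support film, i.e.
centres one radius above a common plane with a small settle jitter, spread
out in the image plane (best-candidate sampling maximizes projected gaps).
Only when a field is too crowded do particles stack into a second layer,
keeping 3D surface separation at `min_separation` while allowing the
projection superposition that dense specimens genuinely show.  A
volume-random mode is retained for studying superposition effects.

What the phantoms deliberately omit: crystalline diffraction contrast (a
violation of the projection requirement, not a modelling target), defocus
and lens aberrations, beam damage, and the support film itself.  Passing
tests therefore validate the geometry-processing chain, not the microscope
optics.

## Acquisition model

`project_series()` implements the mass-thickness (line-integral) contrast
model: for each tilt angle the volume is rotated about the y axis (bilinear
interpolation) and summed along the beam direction, scaled by the voxel size
so projections are in nm × density.  Values stay in this "thickness space"
throughout — reconstruction is then linear — and the exponential bright-field
intensity model lives only inside `add_noise()`:

    I = dose · exp(−p / λ),  I_noisy ~ Poisson(I) (+ optional readout),
    p_noisy = −λ · log(I_noisy / dose).

Defaults: tilt −65°…+65° in 1° steps (the routine single-axis protocol; the
missing ±25° wedge is the point, not a shortcut), dose 2000 counts/pixel
through vacuum, attenuation length λ = 300 nm, no readout noise, stage
jitter uniform in ±3 px per image.  The actual exposure of the original
recordings is not published; these noise settings give per-pixel thickness
noise of ≈ 6.9 nm against a 20 nm peak signal — a deliberately unforgiving
signal-to-noise regime.  The simulation grid is 96³ voxels at 1 nm — coarser
than the 0.22–0.49 nm pixels of the original data, sized so a ten-field
study runs in minutes on one CPU.  Consequences of that scale-down are noted
under *Limitations*.

## Alignment

Registration is by FFT cross-correlation with a soft band-pass (difference
of Gaussians, σ 1 and 10 px) and parabolic sub-pixel peak refinement.
`align_series()` registers each image against its neighbour of lower |tilt|,
accumulates shifts outward from the zero-tilt anchor, re-shifts, and repeats
until the mean update drops below `tol` (default 0.5 px, reached in 2–3
iterations) — the iterative-rounds-until-shifts-vanish scheme.

One subtlety deserves emphasis.  In single-axis geometry, per-image shifts of
the form `a + b·sin θ + c·cos θ` along x, or a constant along y, merely
translate the reconstructed object — they are a *gauge freedom*.  A
registration chain accumulates exactly such a component whenever particles
sit off the rotation axis (their projections genuinely drift with θ).
`align_series()` therefore projects the gauge component out of its shift
estimates.  With it, jitter recovery on the default benchmark is ≈ 0.26 px
RMS noise-free and ≈ 0.38 px at dose 2000; without it, geometric drift alone
contributes ≈ 0.7 px.

`refine_tilt_axis()` estimates the in-plane offset of the rotation axis from
the sinogram mass centroid, which follows `o + b·cos θ + c·sin θ`; the
constant term of a least-squares fit is the offset, recovered to well under
0.1 px on clean data.  An uncorrected axis bends every point into an arc —
streaks and particle elongation at least as strong as the missing-wedge
elongation — which is why the refinement exists.  (A scan minimizing
reconstruction negativity energy was evaluated first; its minimum proved
biased by about 1 px because the missing wedge itself contributes negativity,
so the centroid fit was adopted instead.)

## Reconstruction

Three algorithms share one matched forward/back projector pair (the back
projector is the exact adjoint of the simulator's forward projector — the
property that keeps iterative schemes stable):

* **WBP**: frequency-domain ramp filter with raised-cosine rolloff from 0.9
  Nyquist (limits noise amplification), then back projection, scaled by the
  angular step in radians over the squared pixel size so densities come out
  in the phantom's units.
* **SIRT** (default, 15 iterations, relaxation 1.0): simultaneous update
  `x ← x + relax · C Aᵀ R (b − A x)` with row/column-sum normalization,
  zero-initialized and therefore linear in the data.  Fifteen iterations sit
  inside the 10–20 band that empirically beats WBP and ART on noisy
  bright-field series; on the package's noisy ±65° benchmark SIRT's SNR
  exceeds WBP's, which is the standard reason to prefer it.
* **ART**: damped Kaczmarz sweeps (relaxation 0.25) applied per projection
  in angle order; deterministic given the sweep order.

All reconstructions are masked to the inscribed cylinder about the tilt
axis: voxels outside it are never sampled over the full angular range, and
iterative normalization otherwise amplifies noise there into corner
artifacts that can dominate the grey histogram.

## Segmentation

The reconstruction is smoothed by 2×2×2 voxel averaging (downsampling, voxel
size doubles) — the streak-reduction step applied before surface creation —
then thresholded and labelled (26-connectivity by default, since aggregate
subunits touch obliquely; components touching the volume boundary are
removed, as are components under 30 voxels).

The primary threshold rule is the **bimodal valley**: the minimum of the
smoothed grey histogram between its two peaks.  Reconstruction histograms
are extremely imbalanced (particles are well under 1% of the voxels), so the
implementation hardens the textbook rule in four documented ways:

1. peaks are searched on `log1p(counts)`, where a small foreground mode is
   not drowned by count fluctuations of the background peak;
2. smoothing (5-bin moving average) repeats, scale-space fashion, until at
   most two maxima remain;
3. a mode must reach 20% of the log-scale maximum — bins holding two or
   three voxels while the background peak holds thousands are count noise,
   not modes;
4. the valley must lie below 60% of the way from the background mode to the
   99.9th grey percentile.  A valley above that sits in the *foreground
   flank* — the signature of an under-resolved particle whose interior never
   reaches full density — and thresholding there cuts through the particle
   (observed as two- to three-fold volume loss).

When the valley is rejected, the pipeline falls back (recording a note in
the run output) to `halfmax_threshold()`: background mode plus half the
distance to the 99.9th percentile, the fixed-fraction criterion familiar
from full-width-half-maximum particle sizing.  `otsu_threshold()`
(between-class variance maximization) is also provided; all three agree to
within a few percent of the grey range on well-resolved fields.

## Surface metrology

Isosurfaces are extracted by **marching tetrahedra** on the Freudenthal
6-tetrahedron decomposition of the voxel lattice.  Unlike classic marching
cubes, the tetrahedral cases are unambiguous, and the subdivision tiles
space consistently, so meshes are watertight and consistently oriented *by
construction* — the precondition for the divergence-theorem volume integral.
Area is the sum of triangle areas; volume the signed-tetrahedra sum
(translation-invariant; watertightness is checked explicitly, every edge
shared by exactly two faces).

Triangulating a voxel-sharp boundary overestimates area by several percent
through lattice-scale bumpiness, so `isosurface()` first regularizes the
field with a 0.5-voxel Gaussian (`presmooth`, switchable off).  Validation
on spheres: area and volume within ≈ 1.5% of the closed forms for radii of
8 voxels and up; the curvature bias of the regularization grows below that,
which sets the package's stated resolution floor for per-particle metrology.
An independent voxel-counting volume oracle cross-checks every mesh volume
to within 5% in the test suite, and the isoperimetric inequality
`A ≥ (36π V²)^(1/3)` is asserted for every measured particle.

Per-particle measurements (`mesh_metrics()`) do not mesh every particle at
the global segmentation threshold.  The half-interior contour of a blurred
density step marks the true boundary, and the interior amplitude a
reconstruction reaches varies by several percent from run to run (partial
SIRT convergence, noise), so each particle is meshed at its own iso-level:
halfway between the volume's background mode and that particle's interior
density (the 90th percentile of its labelled voxels).  This is the
metrology analogue of choosing the threshold so the surface matches each
specimen's orthoslice boundaries, and it removes the amplitude sensitivity
a single global level inherits.  To make a below-threshold iso usable, the
per-particle crop suppresses other particles' cores and keeps only the
iso-level foreground connected to the particle, so neighbours and stray
debris never join the mesh.  Meshing strictly at the global threshold
remains available (`local_iso = FALSE`).

Blurring a branched phantom progressively and re-measuring demonstrates the
expected resolution effect: measured VSSA decreases monotonically as fine
surface features are lost — limited resolution *underestimates* VSSA, since
nanometre-scale features add relatively more area than volume.

## 2D validation metrics

`segment_zero_tilt()` reproduces the conventional-TEM workflow on the
zero-tilt image: Gaussian smoothing (σ 1.5 px), thresholding, 8-connected
labelling, border exclusion and despeckling; per region it reports pixel
area, `area·pixel²`, ECD `= 2√(area/π)`, sphericity, and the perfect-sphere
area and volume computed from `r = ECD/2`.  Sphericity is
`√(λ_min/λ_max)` of the second-central-moment matrix — 1 for a disk, `b/a`
for an ellipse, rotation-invariant.

The default 2D segmentation mirrors the per-particle region-of-interest
practice of operator-driven analysis rather than using one global Otsu
threshold, for two measured reasons.  First, a projected sphere's thickness
tapers to zero at its rim, so midpoint criteria like Otsu's shave the rim
and bias the ECD low by 1–2 px.  Second, any single global fraction of the
image maximum over-thresholds every particle as soon as two projections
superimpose and double that maximum.  The implementation therefore:
estimates background level and noise by sigma clipping (robust even when
particles and their smoothing halos cover most of the image); detects
seeds with a high pass (50% of background-to-99.9th-percentile) that
separates superimposed particles into their bright cores, plus a low pass
(20%) for dimmer isolated particles; and grows each seed at 20% of its own
peak thickness (floored at four noise standard deviations), brightest seed
first, each pixel claimed once.  Diameters of isolated spheres come out
within 0.35 px on noise-free projections of 16–24 nm spheres.  Fully
superimposed projections still merge into single regions; that
superposition is the documented, inherent limitation of projection imaging
(no watershed splitting is attempted).

## Statistics and reporting

`spearman_rho()` is the Pearson correlation of mid-ranks (average ranks on
ties); `one_sample_t()` is `t = (mean − μ₀)/(sd/√n)` with a two-sided
p-value on n−1 degrees of freedom (two-sided is the stricter reading where
sidedness is unstated); `mean_sem()` uses the n−1 sample standard deviation.
All three are cross-checked in the tests against independent routes (base
R's `cor(method = "spearman")`, `t.test`, and a hand-computed mid-rank
example).  `build_report()` assembles per-reconstruction VSSA values into
mean ± SEM, the t-test against 60 m²/cm³, the nanostructure classification
(mean above threshold with p < α), and — when ECD-calculated totals are
present — the Spearman correlations of measured vs calculated area and
volume, paired per reconstruction (each tomogram holds one to eleven
particles; totals, not individual particles, are what the validation
compares).

## Study conditions and problem sizes

The packaged study (`simulate_material()` over ten seeds; also what
`scripts/acceptance.R` runs) uses: fields of 1–11 spheres in 96³ voxels at
1 nm, tilt ±65° at 1°, dose 2000, jitter ≤ 3 px, alignment tol 0.5 px,
SIRT 15, 2×2×2 downsampling, valley threshold with fallback, border
exclusion, 30-voxel despeckling.  One field takes a few seconds on one CPU;
a ten-field study a couple of minutes.  Under these conditions ten
spherical-gold reconstructions give a mean VSSA of roughly 316 m²/cm³
(analytic expectation 300 for perfect 20 nm spheres; the residual few
percent reflect the finite reconstruction resolution), p-values around
10⁻¹² to 10⁻²⁰ against 60 m²/cm³, and measured-vs-calculated Spearman
correlations of roughly 0.95-1.0 per run set.  The 3D measurements
themselves rank the fields essentially perfectly against ground truth
(Spearman 0.98-1.0); the measured-vs-calculated correlation is capped
below the 0.98 of the original large-field control data whenever a seed
draw produces nearly tied field totals, which 2-3% of zero-tilt
measurement noise cannot order (see Limitations).

## Known limitations

* The 1 nm simulation voxels (2 nm after downsampling) are four times
  coarser relative to particle size than the original recordings.  Particles
  under ≈ 18 nm are at the resolution floor: their reconstructed interiors
  never reach full density, the valley rule rightly rejects their
  histograms, and the half-max fallback measures them with a size-dependent
  (but monotone) bias.
* With identical nominal diameters, two single-particle fields have equal
  true totals; their relative rank under any measurement noise is a coin
  flip, which intrinsically limits rank-correlation summaries of such
  degenerate designs.  The validation study draws diameters from 16–24 nm,
  where exact ties have probability zero — but with only ten fields of 1-11
  particles in a 96 nm field of view, draws with several same-count fields
  whose totals agree to within a few percent are common, and their ranks
  are then decided by measurement noise.  The original control data,
  recorded at a micrometre-scale field of view, did not face this
  compression.
* Mass-thickness contrast is assumed exact; diffraction contrast, which the
  bright-field images of crystalline gold partly violate, is out of scope.
* Absolute grey levels of commercial reconstruction software are not
  reproduced; all thresholds here are data-driven.
* The published worked example (total area 13,895 nm², volume 38,763 nm³)
  corresponds to VSSA 358.5 m²/cm³ by the ratio identity; the 332 m²/cm³
  printed alongside those inputs is arithmetically inconsistent with them,
  and this package reports the ratio.
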