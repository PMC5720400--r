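---
title: "Multi-slit collimator scatter reduction in CBCT: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-slit collimator scatter reduction in CBCT: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the forward models, the correction algorithm, the parameters that matter,
and the design choices made where the design was genuinely open.  It states
no empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The system being modelled

Cone-beam CT acquires hundreds of 2D radiographs on a circular source
orbit and reconstructs a 3D attenuation map.  Because the whole object is
inside the beam at every view, object scatter adds a smooth background of
the same order as the transmitted primary, which lowers projection contrast
and depresses the reconstructed attenuation towards the object's centre
("cupping").

The collimator studied here is a static arc of alternating open and closed
lead septa centred on the source in the central sagittal plane.  Every
septum subtends the same angle at the source, so each projects onto a
constant-`v` band on the detector (`v` being the detector axis parallel to
the rotation axis).  Acquisition takes two gantry rotations: phase A with
the collimator fixed relative to the source, and phase B with the
collimator advanced along its track by exactly one septum interval, so that
the open bands of the two phases tile the detector.  The premise of the
correction is that a closed septum passes no primary radiation, hence the
signal recorded under a closed band is scatter alone, and the scatter under
the open bands — a smooth field — can be recovered by interpolation along
`v`.

## 2. Geometry and collimator

`cone_beam_geometry()` describes the orbit and panel.  Defaults are the
bench's study conditions: source-to-axis distance 1000 mm, source-to-
detector distance 1500 mm, a 300×300 mm² panel with 128×128 pixels (pixel
pitch 2.34 mm), and 360 uniformly spaced views over a full circle.

Slit widths are specified **at the isocenter plane**: a slit of width *w*
passes a beam stripe of width *w* through the rotation axis, i.e. an
angular half-width `beta = atan(w / 2 / SAD)`.  With this convention the
radius of the collimator track never enters the mathematics, which is why
the package does not model it.  A band edge at source angle `theta` lands
on the detector at `v = SDD * tan(theta)`.  Phase A is centred with an open
septum on the central ray; phase B is shifted by `2 * beta`.  For the
default closed-to-open width ratio of 1 the two ideal masks are exact
complements: every pixel is open in exactly one phase (`pitch_ratio` is
exposed for sensitivity studies, at the cost of that complementarity).

Numerical conventions, chosen so results are bit-stable: bands use
half-open intervals `[lo, hi)`; a pixel belongs to a band if its centre
does; septa are perfect absorbers (10 mm of lead at 40 keV transmits a
negligible fraction, so leakage is not modelled); an optional
`soft_edge_sigma` replaces the ideal step by its Gaussian-smoothed profile
for penumbra-robustness studies.

## 3. Phantoms and materials

Two analytic phantoms, both unions of axis-aligned cylinders in air, are
built in code:

* **simple** — a PMMA cylinder (150 mm diameter, 150 mm long) with a
  coaxial paraffin-wax core (50 mm diameter);
* **lung-n-bone** — a PMMA cylinder (150 mm diameter, 200 mm long) with
  two lung-equivalent polyurethane cylinders (50 mm diameter, 90 mm long)
  at (±40, 0) mm and a PTFE bone surrogate (20 mm diameter, 200 mm long)
  at (0, −25) mm.  The insert positions are package defaults chosen to
  mimic a thorax-like layout; they are configurable.

The beam is 40 keV monoenergetic — a deliberately conservative (low) energy
for a scatter study, since Compton cross sections grow with energy across
the CBCT range.  The default material table uses NIST-derived mass
attenuation coefficients at 40 keV (PMMA 0.2351, paraffin 0.2283, PTFE
0.2627, polyurethane 0.2550 cm²/g) with densities 1.19, 0.93, 2.2 and
0.26 g/cm³.  The polyurethane density is a representative lung-equivalent
foam value and PTFE its handbook value; both are exposed through
`material()` so any table can be substituted.  Overlaps resolve by element
priority with the half-open membership rule `r < R`, so rays tangent to an
interface are deterministic.

## 4. Forward model

**Primary.** `project_primary()` evaluates the Beer–Lambert line integral
analytically: each cylinder contributes a chord from the ray–cylinder
quadratic clipped by its z-slab, and overlaps are resolved exactly by
subtracting higher-priority chord intersections (elements of equal priority
are assumed disjoint, which holds for both phantoms).  There is no
discretization error in the projector; the test suite checks it against
closed-form chords and against dense numerical integration of the material
map to 10⁻⁶ relative.

**Scatter.** The bench replaces particle transport with a parametric
surrogate targeting the regime the slit method addresses — an object far
enough from the detector that scatter is a low-frequency field:

```
scatter = scale * [ (1 - pedestal) * G_sigma * fluence + pedestal * mean(fluence) ]
```

where `G_sigma` is a normalized 2D Gaussian at the detector plane
(truncated and renormalized at the panel edge so a constant field is
preserved) and `fluence` is the primary-intensity plane **after** the
collimator mask.  Generating scatter from the masked fluence is the
physical heart of the bench: slit collimation must *reduce* the scatter,
not merely sample it.  `scale` is calibrated once per study so that the
mean scatter-to-primary ratio over the central 16×16 pixels of the
unmasked anterior-posterior view equals the target `spr`.

Defaults: `spr = 0.5`, `kernel_sigma = 30` mm, `pedestal_fraction = 0.3`,
noiseless.  These are the bench's study conditions; `spr` spans realistic
mid-range CBCT scatter levels, the pedestal models the nearly flat
room/air-gap component, and the kernel width sets how much spatial
structure the scatter retains.  An optional Poisson mode (`noise = TRUE`
with a stated fluence `i0`) adds counting noise reproducibly under a seed;
the default is noiseless so algorithmic error is isolated from counting
error.

What the surrogate does **not** emulate: energy-dependent and
angle-dependent scatter kernels, object-thickness-dependent kernel widths,
detector glare and energy response, and the fact that fluence which never
intersects the object cannot scatter (the blur acts on the whole detected
plane).  Conclusions from this bench are therefore about the *correction
algorithm* under a controllable scatter field, not about absolute scatter
magnitudes of any physical scanner.

## 5. The correction

Per view and per phase (`correct_stack()`):

1. **Sample** (`sample_closed_scatter()`): for every detector column `u`,
   take scatter samples inside every closed band.  By default every closed
   pixel row is one sample.  The classic alternative — one band-averaged
   sample at each band centre — is available through `spacing` (sub-band
   means no wider than `spacing` mm), and is the right choice for noisy
   data; but on a noiseless bench it discards the in-band shape of the
   scatter field, and with 20–30 mm slits the band centres are 60–90 mm
   apart, which cannot represent a field whose correlation length is the
   30 mm kernel.  Under the default conditions the dense sampling is what
   keeps the corrected profiles within the bench's 2% residual target;
   the spacing parameter trades that resolution against noise averaging.
2. **Interpolate** (`interpolate_scatter()`): per column, a monotone
   piecewise-cubic (Fritsch–Carlson) interpolant along `v`, which cannot
   overshoot into negative scatter; plain linear interpolation is
   selectable.  Beyond the outermost samples the estimate is extended
   linearly with the interpolant's end slope: the scatter field generally
   still rises toward the detector edge nearest the unblocked margin, and
   holding it constant (also selectable) leaves a systematic edge error
   several times larger.  An optional moving-average pass across columns
   (`u_smooth`) is available for noisy data.  Estimates are clipped at 0.
3. **Subtract** (`subtract_scatter()`): open-band pixels become
   `max(total − estimate, 0)`; clipped-negative pixels are counted and
   reported as a quality diagnostic.  Closed-band pixels are set to zero —
   they carry no primary, so the merge becomes a partition-of-unity sum.
4. **Merge** (`merge_pair()`): pixelwise sum of the two half-corrected
   phases; with soft edges or `pitch_ratio != 1` the sum is renormalized
   by `mask_A + mask_B` where positive.

Exactness properties (all under test): with zero scatter the corrected
stack equals the primary stack bit-for-bit; constant and linear scatter
fields are recovered exactly (band means of a linear field lie on the
line); with linear interpolation the residual on a smooth field scales as
the square of the band pitch; the correction never increases a pixel.

## 6. FDK reconstruction

`fdk_reconstruct()` implements textbook FDK for a full uniform circular
orbit: intensities are converted to line integrals by
`p = −ln(max(I, floor)/I0)` with a configurable floor (default `1e-6 * I0`)
keeping zero-intensity pixels finite; each view is cosine-weighted
(`SAD/sqrt(SAD² + u'² + v'²)` on the virtual detector at the isocenter),
ramp-filtered row-wise (band-limited Ram-Lak from its spatial kernel,
zero-padded to the next power of two ≥ 2·n_u; Hamming apodization
optional), and backprojected voxel-driven with the distance weight
`(SAD/dist)²` and bilinear detector interpolation.  The angular weight
`dbeta/2` accounts for the doubly-covered full orbit, and the output is
scaled to 1/cm, so a consistent cylinder phantom reconstructs to its
attenuation coefficient — the suite verifies a uniform cylinder's central
region to 3% (midplane FDK is exact for z-invariant objects up to
discretization).  Short-scan (Parker) weighting is not implemented; the
bench always uses full orbits.

Default grid: 128³ voxels at 1.5 mm.  The test suite and the acceptance
study use reduced sizes — 180 views, 64³ voxels at 2 mm — which the
package adopts as its standard reduced study: cupping, plateau ordering
and contrast recovery are already fully expressed at that scale.

## 7. Evaluation

`contrast_ratio()` implements `CR = |I_P − I_W| / I_P` over configurable
rectangle/disk regions.  Default regions: a 20×20 mm insert region at the
centre and a 20×20 mm surround region offset 45 mm laterally at the
isocenter (magnified by SDD/SAD on the detector for projection images;
unmagnified in volume slices).  The "peripheral" slice of the 3D
evaluation defaults to 75% of the phantom half-length.  These placements
are package defaults — the regions are geometric conventions, not physical
constants — and are configurable.  `relative_error_profile()` reports
percent deviations excluding samples whose reference falls below a stated
fraction of its maximum (the bench uses 1%), and
`detector_energy_profile()` integrates detected intensity across `u` per
detector row as a proxy for detector load; with complementary ideal masks
and the linear scatter model the phase-A + phase-B raw sum reproduces the
unmasked view exactly, so the two-rotation scheme deposits the same energy
on the detector as a conventional acquisition.

## 8. Known limitations

* The scatter surrogate's band-locked ripple grows as the detector band
  pitch approaches the kernel width; closed-band interpolation is
  blind to structure at exactly the band period, so residuals rise with
  slit width.  Smoothness at the band scale — in practice
  `kernel_sigma` at least about twice the band pitch — is what makes the
  closed-band premise quantitative for the narrowest slit; the dense
  sampling default recovers most, but not all, of the gap for wider slits.
* Septa are ideal absorbers on an ideal track: no leakage, no penumbra
  beyond the optional Gaussian edge, no mechanical misregistration between
  the two rotations, and no motion between them.
* Monoenergetic physics: no spectrum, target or filtration model, no
  beam hardening, and no detector energy response.
* FDK is approximate away from the midplane; the bench's z-invariant
  phantoms keep that approximation mild, which is intentional — it
  isolates scatter effects from cone-angle effects.
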