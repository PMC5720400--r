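# slitcbct

A fully synthetic software bench for **scatter reduction in cone-beam CT
(CBCT) with a static multi-slit collimator (MSC)**.

Scatter is the dominant image-quality problem of flat-panel CBCT: the large
cone of radiation illuminating the whole object generates a smooth, additive
background at the detector that lowers contrast and produces cupping
artifacts in the reconstructed attenuation map.  A multi-slit collimator
places alternating open and closed lead septa on a source-centred arc in the
central sagittal plane, so each septum projects onto a constant-`v` band of
the detector.  One gantry rotation images only the slabs of the object under
the open septa; a second rotation with the collimator shifted by one septum
interval fills in the complement.  Because the closed septa block all primary
radiation, **whatever the detector records under a closed band is scatter**,
and the scatter under the open bands can be estimated by interpolating those
closed-band signals along the detector's `v` axis:

```
S_hat(u, v)  =  interpolate_v { mean signal in closed bands at column u }
P_hat        =  max(T_A - S_hat_A, 0) + max(T_B - S_hat_B, 0)
```

with `T_A`, `T_B` the two phases' recorded totals.  The merged,
scatter-subtracted projections feed a standard Feldkamp–Davis–Kress (FDK)
filtered backprojection, and image quality is scored with the contrast ratio

```
CR = |I_P - I_W| / I_P
```

(`I_P` the mean of the surrounding region, `I_W` the mean of the insert
region) and its improvement factor `CR_corrected / CR_uncorrected`.

The package contains everything needed to study this system without any
external data:

* **Geometry and collimator** — circular-orbit cone-beam geometry
  (defaults: SAD 100 cm, SDD 150 cm, 30×30 cm² panel with 128×128 pixels,
  360 views), equi-angular septa with slit widths defined at the isocenter,
  rasterized into per-phase detector masks (ideal or soft-edged).
* **Phantoms** — analytic cylinder phantoms with 40 keV attenuation
  coefficients: a PMMA/paraffin two-region phantom and a thorax-like
  phantom with two lung-equivalent polyurethane inserts and a PTFE bone
  surrogate.
* **Acquisition** — a ray-traced Beer–Lambert primary projector (exact
  cylinder chords) plus a parametric scatter model: a Gaussian-blurred copy
  of the (masked) fluence with a flat pedestal, calibrated to a target
  scatter-to-primary ratio; optional Poisson noise.
* **Correction** — closed-band sampling, per-column interpolation along
  `v`, subtraction and two-phase merging.
* **Reconstruction** — FDK filtered backprojection (Ram-Lak or Hamming),
  scaled to linear attenuation in 1/cm.
* **Evaluation** — contrast ratios, CR improvement factors, relative-error
  profiles, detector-energy profiles, and an experiment driver that writes
  CSV/JSON/MetaImage/TIFF artifacts.

## Worked example

Simulate the anterior-posterior view of the simple phantom with a 10 mm
slit at scatter-to-primary ratio 0.5, correct it, and score it:

```r
library(slitcbct)

geometry <- cone_beam_geometry()        # SAD 100 cm, SDD 150 cm, 128x128 panel
phantom  <- build_simple_phantom()      # PMMA cylinder with a paraffin core
msc      <- msc_spec(slit_width_iso = 10)
params   <- scatter_params(spr = 0.5, kernel_sigma = 30, pedestal_fraction = 0.3)

bench <- ap_projection_bench(phantom, geometry, msc, params)
prof_corr <- central_column_profile(bench$corrected, geometry)
prof_prim <- central_column_profile(bench$primary, geometry)
rel <- relative_error_profile(prof_corr$values, prof_prim$values, min_ref_frac = 0.01)
cat(sprintf("max |relative error| of the corrected AP z-profile: %.2f%%\n", rel$max_abs))

cc <- detector_coords(geometry)
surround <- region_rect(c(67.5, 0), 20, label = "PMMA")
insert   <- region_rect(c(0, 0), 20, label = "paraffin")
cr_corr <- contrast_ratio(bench$corrected, surround, insert, cc$u, cc$v)
cr_raw  <- contrast_ratio(bench$uncorrected, surround, insert, cc$u, cc$v)
print(cr_corr)
cat(sprintf("CR improvement factor: %.3f\n", cr_improvement(cr_corr, cr_raw)))
```

```
max |relative error| of the corrected AP z-profile: 0.39%
CR = |0.035968 - 0.021108| / 0.035968 = 0.4131
CR improvement factor: 1.075
```

The corrected projection's longitudinal profile sits within a fraction of a
percent of the primary-only truth, and removing the scatter background
raises the PMMA/paraffin contrast ratio by 7.5% relative to the uncorrected
view at this scatter level.

For the full pipeline (all slit widths, FDK reconstruction, reports on
disk) use `run_experiment()` or the command-line driver:

```sh
Rscript inst/cli/slitcbct.R run --out bench_out --seed 1
```

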