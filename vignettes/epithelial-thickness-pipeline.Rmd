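---
title: "Measuring corneal epithelial thickness profiles from long-depth OCT B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring corneal epithelial thickness profiles from long-depth OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

epiOCT measures the thickness profile of the corneal epithelium along the
horizontal and vertical meridians from anterior-segment spectral-domain OCT
B-scans, and quantifies the test-retest repeatability of those profiles.
This vignette is the package's account of the underlying models, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not establish.

## 1. The phantom: a forward model with exact ground truth

No public corpus of long-depth corneal B-scans exists, so validation rests
on a digital phantom whose rendered images contain exactly the distortions
the measurement pipeline must undo.

### Geometry and coordinates

A B-scan is a lateral sequence of A-scans. Scan coordinates are lateral
position `x` (mm from the scan centre; positive is nasal for a right eye on
the horizontal meridian and superior on the vertical meridian) and optical
depth `z` (mm from the image top, increasing downward). The default grid
reproduces a long-depth research instrument: 13.465 mm scan width,
7.281 mm scan depth in air, 2,048 x 4,096 pixels, axial point-spread
function of 4.6 um FWHM in air (4.6/1.389 = 3.3 um in tissue). The probe
beam is telecentric: all A-scans are parallel vertical rays, so there is no
fan-beam geometry to undo.

`reduced_geometry()` gives the same field of view at 512 x 1024 pixels.
Simulation studies in this package default to that grid: at a 7.1-um axial
pitch a ~52-100-um layer is still well resolved, and rendering plus
analysis of a full 168-scan cohort stays in the minutes range.

### The cornea

The anterior surface is a sphere of radius 7.8 mm (a circle in the meridian
plane), apex at a configurable position and tilt. The epithelial layer is
bounded below by the *back* surface, constructed by offsetting the anterior
surface inward along its local normal by the local thickness

T(d) = T0 + c_dir * d^p,

where `d` is the signed lateral distance from the apex measured in the
eye's frame and `c_dir` is a per-direction coefficient. Because the offset
is along the normal, T(d) *is* the perpendicular layer thickness — the
quantity the pipeline is supposed to recover — with no discretization gap
between generator and truth.

Defaults: T0 = 52 um centrally; layer reaching 63 um temporally and
nasally, 58 um superiorly, 72 um inferiorly at d = 5 mm; exponent p = 3.
The cubic is the lowest power for which the layer stays paracentrally thin
(<= 57 um inside 3 mm) while still reaching ~72 um inferiorly at the rim: a
quadratic cannot do both for the inferior direction. These values encode
the published pattern of a normal epithelium: thin centre, limbal
thickening, inferior faster than superior, nasal/temporal symmetric, with
the inferior-superior difference already present at the 2.5-mm chord. The
tear film is not modelled as a separate layer; it is absorbed into T, as it
is in the measurements the pipeline emulates.

### Image formation

For the A-scan at lateral x:

* the front interface produces an echo at optical depth `z_f(x)` — above
  the cornea is air, so optical depth equals physical depth;
* the probe ray refracts at the front surface (Snell's law, n = 1.0 to
  1.389), travels a physical path `s(x)` to the true back surface — found
  by numerical ray-surface intersection: a dense scan of the sampled back
  surface brackets the crossing of the ray-line cross-product, and
  `uniroot()` on the analytic surface refines it to ~1e-12 — and the back
  echo lands at optical depth `z_f(x) + n * s(x)`;
* each echo is spread axially by a Gaussian PSF (back echo width scaled by
  n), its amplitude attenuated by `exp(-z / depth_rolloff_mm)`;
* multiplicative speckle-like noise and a half-normal background floor are
  added;
* on the vertical meridian, A-scans superior to the eyelid occlusion limit
  (+4.5 mm by default) contain background only.

The rendered scan carries full ground truth: boundary depths, refracted
directions, path lengths, true thickness at every A-scan, and a dense
sample of the true back surface. Unit tests verify the forward model
against an independent brute-force ray tracer (agreement ~1e-6 mm), check
the Snell identity `sin(theta_i) = n sin(theta_t)` at every A-scan to
1e-9, and confirm that setting n = 1 collapses the back echo onto the true
back surface.

### Noise defaults

The noise model is the one deliberately invented part of the phantom
(instrument noise is never published alongside scan geometry). Its defaults
— background_sd 0.04, speckle_factor 0.35, surface amplitude 1.0, back
reflectivity 0.6, depth roll-off 1.8 mm — were chosen once, when the module
was built, so that the simulated cohort behaves like a real long-depth
SD-OCT study: per-location CoR of a few micrometres growing from centre to
periphery, zonal ICC dropping peripherally, and occasional missing rim bins
where the roll-off buries the back echo. The sensitivity roll-off is the
physically load-bearing piece: the corneal periphery sits 1.5-2 mm deeper
in the image than the apex, so echo amplitude — and with it boundary
precision and repeatability — degrades toward the limbus, which is the
centre-to-periphery gradient the repeatability analysis must reproduce.

### The cohort

`simulate_cohort()` draws per-subject central thickness from
Normal(52.0, 3.2) um (with a small 0.8-um inter-eye deviation), anterior
radius from Normal(7.8, 0.25) mm, and per-acquisition alignment
(decentration SD 0.2 mm, apex depth SD 0.15 mm, tilt SD 0.5 deg). Test 2 of
each eye re-renders with a fresh noise seed plus rigid retest jitter
(decentration SD 0.1 mm, tilt SD 0.3 deg). The population mean/SD of the
central thickness are the published values; the variance components of the
alignment and retest jitter are not published anywhere and were set to
magnitudes typical of slit-lamp-mounted anterior-segment imaging. A
manifest records every scan's true parameters.

## 2. Segmentation

Both interfaces are traced as laterally continuous minimum-cost paths
through the negative smoothed intensity, by dynamic programming over the
A-scan sequence. Design points:

* **Why a path, not per-A-scan peaks.** Independent peak-picking fails
  exactly where the data get interesting — the low-SNR periphery. A
  continuity-constrained global path degrades gracefully there instead of
  crashing, which is a prerequisite for *measuring* peripheral
  repeatability rather than aborting on it.
* **Jump limit** (`jump_limit_um`, default 60 um per A-scan step): must
  exceed the steepest surface slope times the lateral pitch; at the default
  grids the corneal surface needs ~45 um/step at the extreme image edge.
  A small per-pixel jump penalty (0.02) regularizes the path in noise.
* **Tie-break**: equal-cost predecessors resolve to the smallest axial
  index — deterministic output.
* **Back-boundary band**: the back path is searched 20-250 um (optical)
  below the front path, which both enforces the ordering contract and
  shrinks the DP to a narrow band.
* **Sub-pixel refinement**: a parabola through the three samples around
  each path node; on noiseless phantoms boundaries land within ~0.1 pixel
  of truth.
* **Validity**: an A-scan is invalid when its ridge SNR
  ((peak - median) / (1.4826 MAD) of the smoothed column) falls below 6.
  The maximum of a pure-noise column reaches ~4-5 on this scale, so
  occluded A-scans are rejected; a scan in which fewer than 5% of columns
  pass raises `NoSurfaceFound`. Validity is additionally eroded by 0.15 mm
  next to any invalid run, because the continuity constraint drags the path
  for a few columns where it enters or leaves a signal-free region (the
  eyelid edge, in practice).
* The tracer is fully automatic. `jitter_seg_params()` emulates a second
  human operator of semi-automatic software by log-normal perturbation of
  the tunable thresholds.

## 3. Refraction correction

Above the tissue, optical depth is physical depth, so the front trace
passes through unchanged. For each jointly valid A-scan the in-tissue
physical path is `s = (z_back - z_front) / n` with n = 1.389 applied
uniformly to tear + epithelium, and the corrected back point is placed at
distance s from the entry point along the Snell-refracted direction of the
vertical probe ray. The correction is 2-D, in the meridian plane only —
the analysed scans *are* meridian planes — and reduces to the identity when
n = 1.

Surface normals come from local quadratic fits of `z_f(x)` in a sliding
+/-0.25 mm window (matching the profiling bin half-width) rather than
finite differences, whose noise amplification would otherwise dominate the
thickness error budget. At the trace edges the window shrinks one-sidedly;
windows with fewer than three valid nodes yield invalid normals, which
propagate.

The central correctness property of the whole package — forward distortion
and correction are exact inverses up to discretization — is tested
end-to-end: on a noiseless default phantom the corrected back surface lies
within 1 um of the generator's true back surface at every valid A-scan.

## 4. Profiling

* **Apex anchoring.** Profiles are expressed relative to the corneal apex
  (quadratic fit to the shallowest front-surface region; a surface too flat
  for a minimum — fitted curvature radius beyond ~1 km — returns 0 with a
  `flat` flag). Anchoring at the apex rather than the scan centre makes
  profiles comparable across acquisitions with different fixation; the
  choice is isolated behind the `anchor` argument.
* **Perpendicular thickness** is the minimum distance from each front point
  to the piecewise-linear corrected back curve. Points whose perpendicular
  foot falls beyond the back curve's lateral support are dropped rather
  than clamped. One known consequence: on *noisy* data the minimum over a
  jagged polyline is biased slightly low (~0.3 um at default noise), since
  the minimum preferentially finds local noise excursions. The bias is
  visible in cohort recovery but well inside the 1.5-um recovery
  tolerance; smoothing the corrected curve before measuring would remove it
  at the cost of no longer measuring the surface the dewarping actually
  produced.
* **Binning**: 0.5-mm grid, boxcar mean over +/-0.25 mm (the "average
  matrix"); empty bins are *missing*, never imputed, and missingness
  propagates explicitly through averaging and reporting.
* **Mirroring**: left-eye horizontal profiles are index-reversed into
  right-eye orientation (an involution; vertical profiles are never
  flipped).
* **Zones**: the 0-3 / 3-6 / 6-10 mm zone names are read as *diameters* on
  the 10-mm analysis zone, i.e. radii 0-1.5 / 1.5-3.0 / 3.0-5.0 mm —
  required for internal consistency with a 10-mm-wide scan. Inner zones
  are half-open `[lo, hi)`; the peripheral zone is closed at 5.0 mm so the
  rim grid points belong to a zone at all.

## 5. Repeatability statistics

* CoR = 2 x sample SD (n-1 denominator) of the between-test differences;
  CoR% = 100 x CoR / mean of all measurements pooled. The sample SD is a
  choice — the definition "two standard deviations" leaves the denominator
  open.
* ICC is ICC(2,1): two-way random effects, absolute agreement, single
  measures, computed from the two-way ANOVA mean squares. This is the
  standard form for test-retest agreement of a single measurement; tests
  verify it against an independent `anova(lm())` route to 1e-10.
* Paired t is the standard two-tailed test (delegated to `t.test()`), with
  explicit degenerate rules: identical pairs give t = 0, p = 1;
  zero-variance nonzero differences give p = 0 flagged degenerate.
* The report computes all three per meridian x grid location across
  subject-eye units, then aggregates into the central 6-mm (|x| <= 3 mm)
  and peripheral 4-mm (|x| > 3 mm) zones. No multiple-testing correction is
  applied across grid locations — per-location p values are reported raw, a
  documented limitation of the emulated analysis.

## 6. Numerical choices and degenerate inputs

* Ray-surface intersection: 2,048-point bracketing scan + `uniroot`
  (tol 1e-12); A-scans whose refracted ray misses the back surface inside
  the grid are flagged invalid, never extrapolated.
* Rendering uses an effective axial PSF sigma of at least 0.8 pixels so a
  ridge is always resolvable by the parabolic sub-pixel estimator, even on
  downsampled grids where the nominal 4.6-um PSF would fall inside one
  pixel.
* TIFFs are written as 16-bit grayscale with the scale factor stored in the
  JSON sidecar, so quantized intensities round-trip exactly.
* All randomness is seeded: the cohort seed drives parameter draws and
  per-scan noise seeds; renders with equal spec and seed are bit-identical.
  RNG state of the caller is always restored.

## 7. Problem sizes

Simulation studies in this package use deliberately chosen sizes: the
reduced 512 x 1024 grid for accuracy-critical checks and the full
21-subject, 168-scan cohort for population recovery (a few minutes of
compute); behavioural and structural tests use a 256 x 512 grid, where
sub-pixel accuracy is coarser but contracts (ordering, occlusion,
determinism, monotone degradation) are unchanged. The repeatability
gradient is assessed as the median over five cohort seeds of the zonal mean
CoR of 6-subject cohorts.

## 8. What the synthetic validation does not show

The phantom establishes *computational* correctness: segmentation finds the
boundaries it was shown, dewarping inverts the forward distortion exactly,
profiling recovers the generating thickness field, and the statistics match
their definitions. It cannot establish clinical accuracy on real eyes. In
particular the phantom omits: non-spherical and pathological corneal
shapes; tear-film dynamics (the tear film is folded into the layer);
axial/lateral motion during the scan beyond rigid retest jitter; speckle
correlation structure and detector artefacts of a real spectrometer; the
16-line radial scan pattern beyond the two analysed meridians; and operator
behaviour beyond parameter jitter. Passing recovery tests here therefore
means the algorithms are faithful to their specification, not that a
particular clinical CoR should be expected on a particular instrument.
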