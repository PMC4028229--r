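# epiOCT

Corneal epithelial thickness profiling from long-scan-depth anterior-segment
OCT B-scans, with a physically forward-modelled digital phantom for
validation.

## The problem

The corneal epithelium (~50–55 µm thick centrally) thins or thickens in
keratoconus, dry eye and after refractive surgery, so mapping its thickness
profile across the whole cornea — not just the central 6 mm — matters
clinically. Long-scan-depth spectral-domain OCT can image the full 10-mm
horizontal and 9-mm vertical meridians in a single B-scan, but extracting a
thickness profile requires several non-trivial steps:

1. **Boundary segmentation.** The air–tear (front) and epithelium–Bowman
   (back) interfaces are traced with sub-pixel precision as laterally
   continuous minimum-cost paths through the smoothed image (dynamic
   programming with a per-step jump limit), with low-SNR A-scans — e.g.
   those under the upper eyelid on the vertical meridian — flagged invalid.
2. **Refraction correction (Snell dewarping).** OCT measures optical path
   length; below the front surface the probe ray is refracted and the image
   of the back boundary is distorted. With front-surface normals from local
   quadratic fits, each back point is repositioned along the Snell-refracted
   ray direction at physical distance `s = Δz_optical / n`, using a group
   index `n = 1.389` for tear film + epithelium.
3. **Thickness profiling.** Epithelial thickness is the perpendicular
   distance from each front-surface point to the corrected back surface,
   averaged into 0.5-mm bins from −5.0 to +5.0 mm (horizontal; ±4.5 mm
   vertical) relative to the corneal apex, with left-eye horizontal profiles
   mirrored into right-eye orientation and zonal summaries over the central
   (0–3 mm), paracentral (3–6 mm) and peripheral (6–10 mm) zone diameters.
4. **Repeatability statistics.** For a cohort imaged twice, per-location and
   zonal coefficients of repeatability (CoR = 2 × SD of the between-test
   differences, CoR% = CoR / overall mean), intraclass correlation
   ICC(2,1) (two-way random effects, absolute agreement, single measures)
   and paired t tests.

Because no public dataset of such scans exists, the package ships a
first-class synthetic-data module: a digital corneal phantom with a
spherical anterior surface, an epithelial layer whose thickness grows from
52 µm centrally as `T(d) = T₀ + c_dir·d³` toward the limbus (faster
inferiorly than superiorly, nasal/temporal symmetric), a physically exact
refraction forward model (brute-force ray–surface intersection of the
Snell-refracted probe ray), depth-dependent sensitivity roll-off, speckle
noise, superior eyelid occlusion, and test–retest alignment jitter. Every
rendered scan carries its ground truth, so the whole pipeline can be
validated by parameter recovery.

## Worked example

```r
library(epiOCT)

spec <- phantom_spec(geometry = reduced_geometry())   # 512 x 1024 grid
scan <- render_bscan(spec, session_spec("horizontal", "OD"))
scan
#> OCT B-scan: horizontal meridian, OD, test 1, 1024 x 512 pixels (synthetic, ground truth attached)

prof <- profile_bscan(scan)    # segment -> dewarp -> thickness -> bin
round(zonal_means(prof), 1)
#>     central paracentral  peripheral
#>        51.9        53.0        56.6

head(as.data.frame(prof)[, 1:4], 4)
#>   position_mm thickness_um  n missing
#> 1        -5.0           NA  0    TRUE
#> 2        -4.5     58.96273 17   FALSE
#> 3        -4.0     57.39901 19   FALSE
#> 4        -3.5     54.69257 19   FALSE
```

The central zone recovers the phantom's 52 µm layer to within a fraction of
a micron; the profile thickens toward the limbus; and at this noise level
the dimmest rim bin of this particular scan is reported *missing* rather
than guessed — deep peripheral A-scans lose SNR to the sensitivity
roll-off, exactly where repeatability is worst on the real instrument.

For a full cohort use the file-based pipeline:

```r
cfg <- run_config(out_dir = "run1", n_subjects = 21, seed = 1)
cmd_simulate(cfg)   # 168 TIFF B-scans + JSON sidecars + manifest.csv
cmd_profile(cfg)    # profiles.csv: binned thickness per scan
cmd_repeat(cfg)     # per-location and zonal CoR / CoR% / ICC / paired t
```

## Package layout

- `R/phantom.R` — phantom spec, thickness field, forward renderer, cohort
  simulator
- `R/segmentation.R` — preprocessing, dynamic-programming boundary tracer
- `R/refraction.R` — surface normals, Snell refraction, dewarping
- `R/profiling.R` — apex detection, perpendicular thickness, binning,
  mirroring, zonal means
- `R/repeatability.R` — CoR, ICC(2,1), paired t, cohort report
- `R/io.R`, `R/pipeline.R` — TIFF/JSON/CSV/YAML round-tripping and the
  `cmd_*` pipeline entry points
- `vignettes/epithelial-thickness-pipeline.Rmd` — the methods vignette
  (model, assumptions, parameter choices, limitations)
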