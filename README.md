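# divecurate

Curation of underwater photo-transect imagery: from raw AUV dive output
(hundreds of thousands of fisheye frames plus navigation/CTD telemetry on
separate clocks) to a quality-controlled, geo-referenced, publishable image
data set — with every transformation recorded in a machine-readable
protocol.

The package is written for marine-imaging groups operating camera platforms
(AUVs, towed cameras, stationary landers) who need the steps between "the
vehicle is back on deck" and "the data are analyzable and archivable":

* **Naming + schema** — the machine-readable file-name scheme
  `<cruise>_<station>_<camera>_<YYYYMMDD>_<hhmmss>_IMG_<index>` and a
  lowercase, blank-free metadata tag set (`SUB_*` platform state, `CAM_*`
  camera/mounting, `ENV_*` environment), with one-pass schema auditing.
* **Clock synchronization** — the camera and navigation computers keep
  separate clocks. Because the strobe is the only light source, image
  brightness anti-correlates with altitude *h*; the static offset δ is
  estimated by grid search
  `δ* = argmin_δ  corr( log B(t − δ), log h(t) )`
  where *B* is the mean gray value of each image's main diagonal and *h*
  is linearly interpolated to the shifted image times (inverse-square
  illumination makes the relation log-linear).
* **Telemetry QC** — spike detection by modified z-score
  (`0.6745 |x − med| / MAD`) on running-median residuals, reconstruction
  of gaps by cubic-spline interpolation (never extrapolated), and merging
  of multi-sensor streams by timecode onto the navigation clock.
* **Image QC** — flag-then-filter verdicts per frame: water-column frames
  (fused altitude > 10 m, strict), dark frames (mean gray below a
  survey-specific threshold), black frames (flash misfire, all-zero),
  condensation subsequences (operator-specified time windows). Nothing is
  deleted; exports select on verdicts.
* **Optics** — equidistant fisheye model `r = f·θ`, un-distortion to the
  view of an ideal perspective camera (`r = f·tan θ`, 90° HFOV) by inverse
  ray mapping with bilinear resampling, per-pixel geo-referencing on a
  flat-seafloor model, and survey calculators: center ground resolution
  `f_px / h`, along-track overlap `1 − (v/f_rate)/(2h·tan(HFOV/2))`, and
  storage scaling `coverage · area · resolution² · bytes/px`.
* **Fusion + organization** — EXIF GPS tags + a full `tag:value` metadata
  block written into each JPEG (pixels untouched, byte-for-byte), ASCII
  sidecar tables, half-hour folder splits, and pooling into uncompressed
  50 GB tar archives with MD5 manifests.
* **Synthetic dives** — a seeded generator that renders a complete
  mow-the-lawn deployment (trajectory, 1 Hz telemetry with injected
  spikes/gaps, fisheye frames over a world-anchored nodule field, a known
  clock offset, black frames, condensation windows) with ground truth for
  every pipeline stage.

## Worked example

```r
library(divecurate)

# a 160 s mow-the-lawn survey with a 2.5 s camera-clock offset and defects
scenario <- dive_scenario(seed = 7, clock_offset_ms = 2500,
                          condensation_windows = list(c(120, 140)))
dive <- generate_dive(scenario)
print(dive)
#> <synthetic_dive> seed 7
#>   230 frames (48 x 48 px), 230 nav rows, 115 env rows
#>   truth: offset 2500 ms, 5 black, 20 condensation, 60 water-column
write_synthetic_dive(dive, "demo/dive")

config <- list(
  input  = list(dir = "demo/dive"),
  output = list(dir = "demo/curated"),
  camera = list(width_px = 48, height_px = 48, focal_mm = 15),
  thresholds = list(darkness_min_mean_gray = 12.75),  # mandatory, per survey
  exclude_windows = list(scenario$t0_ms + c(120, 140) * 1000 + 2500),
  organize = list(dive = "SYN1_001"))
report <- run_pipeline(config)
print(report)
#> <pipeline_report>
#>   images read: 230; nav rows: 230
#>   estimated clock offset: 2500 ms (r = -0.980)
#>   metadata: 6 outliers repaired, 6 gaps filled
#>   image QC: condensation_excluded=20, black_frame=4, dark_filtered=50,
#>             altitude_filtered=10, keep=146
#>   curated output: demo/curated (1 folders)
```

The estimated offset equals the injected 2,500 ms; the 6 repaired spikes
and 6 filled gaps are exactly the generator's injected telemetry defects;
and the QC verdicts match the ground-truth corruption labels (one injected
black frame falls inside the condensation window and takes the
higher-precedence condensation verdict). The curated tree contains the
un-distorted, EXIF-fused frames in half-hour folders, a sidecar metadata
table, and `curation_log.jsonl` — the dynamic protocol of everything that
was done, with parameters.

Survey geometry helpers print the familiar numbers for the reference
camera (15 mm fisheye, 6.58 µm pixels):

```r
100 * along_track_overlap(7.5, 1.5, 1, 90)   # 90 (% overlap at 7.5 m)
m <- ray_model("equidistant", focal_mm = 15, pitch_mm = 6.58e-3,
               width = 5472, height = 3648)
ground_resolution(10, m)                      # 0.228 px/mm at 10 m
```

A thin command-line wrapper with `synth`, `validate`, `sync`, `run` and
`report` subcommands lives at `inst/cli/divecurate.R`.

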