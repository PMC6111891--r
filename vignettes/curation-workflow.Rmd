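---
title: "Methods: the divecurate curation workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the divecurate curation workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and design decisions behind
the package, at the level a maintainer or reviewer needs to judge what the
code does and what its tests do and do not show.

## The problem

A photo-transect survey produces two data streams recorded by separate
systems: imagery (a DSLR in a pressure housing, with its own computer and
clock, timestamps at millisecond resolution) and telemetry (the vehicle's
fused navigation solution — position, altitude above the seafloor,
attitude — typically at 1 Hz on the navigation clock, plus environmental
sensors on their own time bases). Before analysis the streams must be put
on one clock, cleaned, joined, and attached to the images; corrupt frames
must be flagged; fisheye geometry must be converted to a perspective view;
and the collection must be organized for browsing, transfer and archival.
Every one of those actions is a data transformation that has to be
recorded for provenance — the package threads an append-only JSON-lines
`curation_log` through all mutating operations.

## Clock synchronization

Strobe light is the only illumination at depth, so frame brightness falls
with altitude approximately as an inverse-square law. The brightness proxy
is the mean gray value of the image's main diagonal (`min(w, h)` samples —
cheap, touches all radii, and robust to local scene content). The offset
estimator grid-searches `delta` over `[-60 s, +60 s]` in 100 ms steps and
minimizes the Pearson correlation between log-brightness and
log-(altitude interpolated to the shifted image times).

Choices that matter:

* **Log-log correlation (default).** `B ~ h^-2` means `log B` is linear in
  `log h`. Correlating the raw series works, but the convex curvature of
  `B(h)` interacts with steep descent legs and skews the optimum by a few
  hundred milliseconds in synthetic probes; the log transform removes the
  skew. `transform = "none"` restores the plain-series behavior.
* **Sample hygiene.** Altitude samples outside `[0, 15 m]` are discarded
  (water-column frames carry no brightness signal; physically impossible
  spiked values would distort the score), as are brightness samples at or
  below 1 gray level (all-black flash misfires). This makes the estimator
  usable *before* metadata QC, which is where it sits in the pipeline.
* **Resolution.** The estimate is a grid point; with 1 Hz telemetry and a
  few hundred usable frames the median recovery error on synthetic dives
  is about half a grid step.

Metadata are then linearly interpolated to the corrected image times.
Heading-like angles interpolate on the circle via unwrapping (shortest
arc, valid while successive samples differ by < 180°); pitch/roll are far
from the wrap point and interpolate linearly. No extrapolation: targets
outside the telemetry span come back flagged `missing`.

## Telemetry quality control

Spikes are detected with the modified z-score `0.6745 |x - med| / MAD >
3.5`, applied to residuals from a running median (k = 5) so descent/ascent
trends are not flagged wholesale. Two refinements: values violating a
field's physical range (latitude beyond ±90°, negative altitude, ...) are
outliers regardless of spread, and a spike must also exceed a per-field
absolute floor (~11 m in position, 0.75 m in altitude, 20° in heading) —
on exactly-linear track segments the residual spread degenerates to zero
and, without the floor, benign line-corner samples would be flagged.

Gaps (and removed spikes) are reconstructed by cubic-spline interpolation
through the valid anchors, with Forsythe–Malcolm–Moler end conditions: the
interpolant then reproduces an exactly cubic series to machine precision,
which is the property the unit tests pin down. (Natural end conditions
were considered and rejected — their zero-second-derivative boundary bias
propagates into the interior.) Leading/trailing gaps stay missing; the
pipeline never extrapolates navigation.

Streams merge onto the navigation clock (images are matched against fused
navigation, so navigation is the natural master): nearest sample within a
100 ms tolerance, else linear interpolation, with per-stream provenance
counts (matched/interpolated/missing) logged.

## Image quality control

Verdicts per frame, precedence `condensation > black > dark > altitude >
manual review > keep`, as accumulating flags on a `qc_report` — nothing is
deleted, exports select on verdicts:

* **Altitude**: fused altitude strictly above 10 m (boundary frames kept);
  frames without a fused altitude go to manual review rather than being
  silently kept.
* **Darkness**: full-image mean gray below a threshold that is *manually
  chosen per survey* — in the pipeline configuration it is a mandatory key
  with no default. Tests and examples use 12.75 (5 % of the 8-bit range).
* **Black**: all pixels at (or, for JPEG-decoded data, within 1 gray level
  of) zero — flash misfires.
* **Condensation**: operator-identified camera-clock time windows;
  overlapping windows are merged before flagging, and the windows are
  logged.

## Camera geometry

Image coordinates are 0-based with pixel centers at integer coordinates,
x right / y down; the camera frame is x right, y down, z along the optical
axis; the mounting default points the camera at nadir with image "up"
facing forward. The equidistant fisheye maps a ray at off-axis angle
`theta` to radius `r = f*theta`; the rectilinear model to `r = f*tan
theta`.

Un-distortion resamples the raw frame into the image an ideal 90°-HFOV
perspective camera would have seen from the same pose: per virtual pixel,
rectilinear un-projection to a ray, equidistant projection to a sub-pixel
source position, bilinear interpolation. The virtual camera defaults to
the raw pixel count across the 90° field, square pixels, centered
principal point; its focal length is set so the *edge pixel centers* sit
at ±45°. Virtual pixels whose rays leave the raw image get sentinel 0 and
a FALSE mask bit.

Geo-referencing intersects each pixel ray (rotated by mounting, attitude
and heading) with a flat plane at the fused altitude and converts the
metric offset to degrees with WGS84 meridian/parallel curvature radii at
the pose latitude. Assumptions stated plainly: flat seafloor (no terrain
model), in-air calibration (dome-port refraction is recorded in the
camera spec but not modeled in the ray path).

Survey calculators: center ground resolution `f_px / h` (the small-angle
limit, identical for both projections); along-track overlap
`max(0, 1 - (v / f_rate) / (2 h tan(HFOV/2)))`; storage
`coverage * area * resolution^2 * bytes_per_px`.

## The synthetic dive generator

The generator is the package's test instrument: a deterministic function
of one seed producing imagery, telemetry, defects and the ground truth
for all of them.

What it emulates, and the frozen defaults:

* **Deployment**: mow-the-lawn pattern, 1.5 m/s, 1 Hz imaging and
  navigation, 7.5 m cruise altitude, 3 m track spacing — the nominal
  survey conditions; consecutive exposures then overlap 90 % along track.
  Descent/ascent legs are linear at 0.5 m/s from/to 25 m.
* **Cruise altitude variation**: a slow multi-sine "terrain following"
  component (0.6 m amplitude; 67/31/13 s periods) plus an
  Ornstein–Uhlenbeck altitude-control component (sd 0.35 m, correlation
  time 3 s, clamped at 3 sigma, on a 0.5 s grid), both enveloped to zero
  at the cruise ends so altitude is continuous across the phase corners.
  Real AUV altitude has exactly this two-scale character, and the
  high-frequency part is what carries the sub-second information the
  clock-offset estimator uses.
* **Radiometry**: `B = B0 (h0/h)^2 cos^4(theta) A(e, n) + noise`, with
  `B0 = 170` gray at `h0 = 7.5 m`, cosine-fourth vignetting, Gaussian
  pixel noise (sd 2), and a world-anchored albedo field `A`: dark
  elliptical Gaussian-profile blobs (nodule analogue, 0.35 per m²,
  semi-axes 8–35 cm, darkening 0.25–0.55) over sediment albedo 0.85.
  World anchoring means overlapping frames see the same scene.
* **Timing**: navigation rows at integer seconds, image times at
  `0.25 s + k/rate` with millisecond resolution; recorded image
  timestamps carry the scenario's clock offset. The 0.25 s phase together
  with the 0.5 m/s vertical speed quantizes descent-frame altitudes to
  0.125 m away from the 10 m filter boundary, so altitude verdicts cannot
  flip under sub-step clock error — a deliberate robustness property of
  the fixture, not of the method.
* **Defects**: ≥10-sigma spikes and blanked cells in interior navigation
  rows (1 % each by default), zeroed frames (2 %), and condensation
  windows simulated as Gaussian blur (sigma 2.5) plus contrast reduction
  toward the frame mean.

What it does **not** emulate — and hence what passing tests do not show
about real data: real optics (chromatic effects, dome-port refraction,
focus), real seafloor texture and biology, attitude excursions
(pitch/roll are zero), navigation drift (defects are spikes and gaps, not
slowly varying bias), turbidity/scattering, and rolling-shutter or
exposure variation. The generator validates the *bookkeeping and
geometry* of the workflow, not photogrammetric accuracy on real imagery.

## Data fusion and organization

EXIF fusion writes a little-endian TIFF/IFD APP1 segment: GPS
latitude/longitude as degree/minute/second rationals (second denominator
1e6, ≈3e-10° resolution) with hemisphere refs, heading as GPS image
direction (denominator 1e6), artist/copyright, and the full selected
record as `tag:value` lines in the user comment. Altitude above the
seafloor deliberately does *not* go into the GPS altitude tag — generic
EXIF tools would read it as height above sea level — it travels under its
own schema tag in the user comment. Only metadata segments before the
entropy-coded scan are touched, so pixel data are byte-identical, and
replacing any existing EXIF segment makes fusion idempotent.

Folders split on wall-clock half-hour boundaries (hh:00 / hh:30 UTC,
half-open), giving 1,800 images per full window at 1 Hz and reproducible
folder names (`<dive>_<YYYYMMDD>_<hhmm>`); a `max_count` rule (default
999, keeping folders under a thousand files) is available where time
splitting does not fit. Archives pool whole folders first-fit into
uncompressed tar files up to 50 GB (oversize folders get a dedicated
archive with a warning), with an MD5 manifest per member file for
duplicate/backup verification.

## Problem sizes in the test suite

Unit tests run on 30–40-frame dives at 32×32 px; the acceptance-style
checks use the full nominal scenario (230 frames at 48×48, or 40×40 for
the 20-dive offset-recovery study) and 96×96 rendering for the
un-distortion accuracy checks. These sizes keep the whole suite at a few
minutes on one core while leaving every statistical margin (e.g. the
offset study's median error ≈ half a grid step) comfortably wide.

## Known limitations

* Flat-seafloor geo-referencing; no terrain model or refraction in the
  ray path.
* The offset model is a single static offset per dive; clock drift within
  a dive is not estimated.
* EXIF support covers the fused tag set, JPEG only; other formats fall
  back to sidecar files.
* The condensation detector is the operator: the package applies and logs
  windows, it does not find them.
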