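## Synthetic AUV dive generator.
##
## Emulates a deep-sea photo-transect deployment end to end: a mow-the-lawn
## trajectory with linear descent/ascent phases, 1 Hz navigation rows,
## millisecond image acquisition times on a camera clock with a known
## static offset, and rendered fisheye frames whose brightness follows an
## inverse-square altitude law with cosine-fourth vignetting over a
## world-anchored field of dark nodule-like blobs. Injected defects
## (navigation spikes, blank cells, black frames, condensation-like blur
## windows) are all labeled in a ground-truth record so every downstream
## curation stage can be verified exactly.

#' Fisheye frame container
#'
#' @param pixels Numeric matrix of gray values in `[0, 255]`
#'   (rows = image y, cols = image x).
#' @param timestamp_ms Acquisition time, epoch milliseconds (camera clock).
#' @param model The [ray_model()] the frame was imaged through.
#' @param metadata Optional named list (pose, identifiers, QC flags).
#' @return An object of class `fisheye_frame`.
#' @export
fisheye_frame <- function(pixels, timestamp_ms = NA_real_, model = NULL,
                          metadata = NULL) {
  stopifnot(is.matrix(pixels), length(pixels) > 0)
  structure(list(pixels = pixels, timestamp_ms = timestamp_ms,
                 model = model, metadata = metadata),
            class = "fisheye_frame")
}

#' @export
print.fisheye_frame <- function(x, ...) {
  cat(sprintf("<fisheye_frame> %d x %d px, t = %s, mean gray %.1f\n",
              ncol(x$pixels), nrow(x$pixels),
              if (is.na(x$timestamp_ms)) "?" else ms_to_subtime(x$timestamp_ms),
              mean(x$pixels)))
  invisible(x)
}

#' Synthetic survey camera
#'
#' A small equidistant fisheye camera for synthetic rendering: 15 mm focal
#' length with the sensor size chosen so the horizontal edge of the image
#' sits at `edge_theta_deg` off-axis (default 65 degrees, comfortably
#' covering a 90-degree-HFOV virtual view).
#'
#' @param width_px,height_px Image size in pixels.
#' @param focal_mm Focal length (mm).
#' @param edge_theta_deg Off-axis angle at the horizontal edge pixel.
#' @param CAM_id Camera identifier token.
#' @return A [camera_spec()].
#' @export
synth_camera <- function(width_px = 48, height_px = 48, focal_mm = 15,
                         edge_theta_deg = 65, CAM_id = "AUV9") {
  pitch <- focal_mm * (edge_theta_deg * pi / 180) / ((width_px - 1) / 2)
  camera_spec(CAM_model = "synthetic DSC", CAM_id = CAM_id,
              CAM_lensmodel = "synthetic 15mm fisheye",
              CAM_focallength = focal_mm, projection = "equidistant",
              sensor_width_mm = pitch * width_px,
              sensor_height_mm = pitch * height_px,
              image_width_px = width_px, image_height_px = height_px)
}

#' Scene/radiometry parameters for synthetic rendering
#'
#' Mean gray value is modeled as
#' `B = ambient + B0 * (h0 / h)^2 * cos(theta)^4 * A(x, y) + noise`:
#' an inverse-square altitude law anchored at `B0` gray levels for the
#' nominal albedo at the reference altitude `h0`, a cosine-fourth
#' vignetting profile in the off-axis angle theta, and a world-anchored
#' albedo field `A` of dark elliptical nodule-like blobs on a brighter
#' sediment background.
#'
#' @param B0 Gray level of unit-albedo seafloor at `h0` (default 170).
#' @param h0 Reference altitude in m (default 7.5, the operating altitude).
#' @param ambient Altitude-independent gray offset (default 0; the strobe
#'   is the only light source in the deep sea).
#' @param albedo_base Sediment albedo factor (default 0.85).
#' @param vignetting Apply the cosine-fourth profile? (default TRUE)
#' @param noise_sd Gaussian pixel noise, gray levels (default 2).
#' @param blob_density Nodule blobs per square meter (default 0.35).
#' @param blob_radius_m Range of blob semi-major axes (m).
#' @param blob_depth Range of blob darkening factors in `(0, 1)`.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(B0 = 170, h0 = 7.5, ambient = 0,
                         albedo_base = 0.85, vignetting = TRUE,
                         noise_sd = 2, blob_density = 0.35,
                         blob_radius_m = c(0.08, 0.35),
                         blob_depth = c(0.25, 0.55)) {
  structure(list(B0 = B0, h0 = h0, ambient = ambient,
                 albedo_base = albedo_base, vignetting = vignetting,
                 noise_sd = noise_sd, blob_density = blob_density,
                 blob_radius_m = blob_radius_m, blob_depth = blob_depth),
            class = "scene_params")
}

#' Generate a world-anchored blob field
#'
#' Seeded point process of dark elliptical blobs over a fixed ground
#' extent. Because blobs live in world coordinates, overlapping frames see
#' the same seafloor content.
#'
#' @param extent `c(east_min, east_max, north_min, north_max)` in meters.
#' @param scene [scene_params()].
#' @param seed Integer seed.
#' @return Data frame of blob centers, axes, orientation and darkening.
#' @export
make_blob_field <- function(extent, scene = scene_params(), seed = 1) {
  area <- (extent[2] - extent[1]) * (extent[4] - extent[3])
  n <- max(0L, round(area * scene$blob_density))
  with_seed(child_seed(seed, "blobs"), {
    data.frame(
      east = runif(n, extent[1], extent[2]),
      north = runif(n, extent[3], extent[4]),
      r_major = runif(n, scene$blob_radius_m[1], scene$blob_radius_m[2]),
      ratio = runif(n, 0.5, 1),
      angle = runif(n, 0, pi),
      depth = runif(n, scene$blob_depth[1], scene$blob_depth[2])
    )
  })
}

#' Albedo of the synthetic seafloor at ground points
#'
#' @param blobs Blob field from [make_blob_field()].
#' @param east,north Ground coordinates (m).
#' @param base Background albedo.
#' @return Numeric albedo values.
#' @export
albedo_at <- function(blobs, east, north, base = 0.85) {
  a <- rep(base, length(east))
  if (is.null(blobs) || nrow(blobs) == 0L) return(a)
  # only blobs near the queried points can matter
  reach <- 3.5 * blobs$r_major
  near <- blobs$east + reach >= min(east) & blobs$east - reach <= max(east) &
    blobs$north + reach >= min(north) & blobs$north - reach <= max(north)
  # range-search blobs against the points through one sort in east
  ord <- order(east)
  es <- east[ord]
  for (b in which(near)) {
    lo <- findInterval(blobs$east[b] - reach[b], es) + 1L
    hi <- findInterval(blobs$east[b] + reach[b], es)
    if (hi < lo) next
    cand <- ord[lo:hi]
    dn <- north[cand] - blobs$north[b]
    cand <- cand[abs(dn) <= reach[b]]
    if (!length(cand)) next
    de <- east[cand] - blobs$east[b]
    dn <- north[cand] - blobs$north[b]
    ca <- cos(blobs$angle[b]); sa <- sin(blobs$angle[b])
    u <- (de * ca + dn * sa) / blobs$r_major[b]
    v <- (-de * sa + dn * ca) / (blobs$r_major[b] * blobs$ratio[b])
    a[cand] <- a[cand] * (1 - blobs$depth[b] * exp(-(u^2 + v^2) / 2))
  }
  a
}

## ---- scenario ------------------------------------------------------------

#' Describe a synthetic dive scenario
#'
#' Defaults reproduce the nominal deployment conditions of a deep-sea AUV
#' photo survey: 1.5 m/s vehicle speed, 1 Hz image acquisition, 7.5 m
#' cruise altitude and 3 m track spacing, preceded/followed by linear
#' descent/ascent legs (0.5 m/s vertical) from/to `start_altitude_m`.
#' Cruise altitude carries a smooth multi-sine "terrain following" wobble
#' so image brightness carries a usable altitude signal.
#'
#' @param pattern `"mow_the_lawn_2d"`, `"transect_1d"` or `"stationary"`.
#' @param track_length_m Length of each survey line (m).
#' @param track_spacing_m Across-track spacing of adjacent lines (m).
#' @param n_lines Number of survey lines (mow-the-lawn only).
#' @param speed_mps Vehicle speed (m/s).
#' @param image_rate_hz,nav_rate_hz Image and navigation rates (Hz).
#' @param cruise_altitude_m Nominal cruise altitude above seafloor (m).
#' @param start_altitude_m Altitude at dive start (descent leg top, m).
#' @param vertical_speed_mps Descent/ascent rate (m/s).
#' @param altitude_wobble_m Amplitude of the slow (terrain-following)
#'   cruise altitude variation (m).
#' @param altitude_rough_m Standard deviation of the high-frequency
#'   altitude-control component (m); see `rough_tau_s`.
#' @param rough_tau_s Correlation time of the high-frequency altitude
#'   component (s).
#' @param stationary_duration_s Cruise duration for `"stationary"`.
#' @param clock_offset_ms Ground-truth camera-minus-navigation clock
#'   offset (ms): recorded image times = true times + offset.
#' @param outlier_fraction Fraction of navigation rows receiving a
#'   >=10-sigma spike in one position/altitude field.
#' @param gap_fraction Fraction of cells blanked per corruptible field.
#' @param black_frame_prob Probability a frame is zeroed (flash misfire).
#' @param condensation_windows List of `c(start_s, end_s)` intervals
#'   (relative to dive start) of condensation-like blur.
#' @param cruise,station Identifier tokens for the naming scheme.
#' @param start_time_utc Dive start (UTC, `POSIXct` or parseable string).
#' @param origin_lat,origin_lon Geographic origin of the local survey
#'   frame (decimal degrees).
#' @param image_phase_s Offset of the first image after dive start (s);
#'   image times are deliberately off the integer-second navigation grid.
#' @param seed Integer master seed; a fixed seed makes the entire dive
#'   (trajectory, imagery, corruption) reproducible.
#' @return An object of class `dive_scenario`.
#' @examples
#' s <- dive_scenario(track_length_m = 30, n_lines = 2, seed = 7)
#' s$clock_offset_ms
#' @export
dive_scenario <- function(pattern = c("mow_the_lawn_2d", "transect_1d",
                                      "stationary"),
                          track_length_m = 60, track_spacing_m = 3,
                          n_lines = 4, speed_mps = 1.5,
                          image_rate_hz = 1, nav_rate_hz = 1,
                          cruise_altitude_m = 7.5, start_altitude_m = 25,
                          vertical_speed_mps = 0.5, altitude_wobble_m = 0.6,
                          altitude_rough_m = 0.35, rough_tau_s = 3,
                          stationary_duration_s = 120,
                          clock_offset_ms = 2500,
                          outlier_fraction = 0.01, gap_fraction = 0.01,
                          black_frame_prob = 0.02,
                          condensation_windows = list(),
                          cruise = "SYN1", station = "001",
                          start_time_utc = "2015-04-07 17:50:00",
                          origin_lat = -7.07, origin_lon = -88.45,
                          image_phase_s = 0.25, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(track_length_m > 0, track_spacing_m > 0, n_lines >= 1,
            speed_mps > 0, image_rate_hz > 0, nav_rate_hz > 0,
            cruise_altitude_m > 0, start_altitude_m > cruise_altitude_m,
            vertical_speed_mps > 0, altitude_wobble_m >= 0,
            outlier_fraction >= 0, outlier_fraction <= 1,
            gap_fraction >= 0, gap_fraction <= 1,
            black_frame_prob >= 0, black_frame_prob <= 1)
  t0 <- as.POSIXct(start_time_utc, tz = "UTC")
  s <- list(pattern = pattern, track_length_m = track_length_m,
            track_spacing_m = track_spacing_m, n_lines = as.integer(n_lines),
            speed_mps = speed_mps, image_rate_hz = image_rate_hz,
            nav_rate_hz = nav_rate_hz,
            cruise_altitude_m = cruise_altitude_m,
            start_altitude_m = start_altitude_m,
            vertical_speed_mps = vertical_speed_mps,
            altitude_wobble_m = altitude_wobble_m,
            altitude_rough_m = altitude_rough_m, rough_tau_s = rough_tau_s,
            stationary_duration_s = stationary_duration_s,
            clock_offset_ms = clock_offset_ms,
            outlier_fraction = outlier_fraction,
            gap_fraction = gap_fraction,
            black_frame_prob = black_frame_prob,
            condensation_windows = condensation_windows,
            cruise = cruise, station = station,
            t0_ms = round(as.numeric(t0) * 1000),
            origin_lat = origin_lat, origin_lon = origin_lon,
            image_phase_s = image_phase_s, seed = as.integer(seed))
  s$t_descent_s <- (start_altitude_m - cruise_altitude_m) / vertical_speed_mps
  s$t_cruise_s <- switch(pattern,
                         mow_the_lawn_2d = n_lines * track_length_m / speed_mps,
                         transect_1d = track_length_m / speed_mps,
                         stationary = stationary_duration_s)
  s$t_total_s <- s$t_descent_s + s$t_cruise_s + s$t_descent_s
  class(s) <- "dive_scenario"
  s
}

#' @export
print.dive_scenario <- function(x, ...) {
  cat(sprintf("<dive_scenario> %s, %d x %g m lines @ %g m spacing\n",
              x$pattern, x$n_lines, x$track_length_m, x$track_spacing_m))
  cat(sprintf("  %g m/s, images %g Hz, nav %g Hz, cruise %g m (start %g m)\n",
              x$speed_mps, x$image_rate_hz, x$nav_rate_hz,
              x$cruise_altitude_m, x$start_altitude_m))
  cat(sprintf("  duration %gs, clock offset %g ms, seed %d\n",
              x$t_total_s, x$clock_offset_ms, x$seed))
  invisible(x)
}

# smooth cruise altitude variation; zero at cruise start, incommensurate
# periods so the brightness autocorrelation has a unique peak at lag 0
cruise_wobble <- function(scenario, tc) {
  if (scenario$altitude_wobble_m == 0) return(rep(0, length(tc)))
  ph <- with_seed(child_seed(scenario$seed, "wobble"), runif(2, 0, 2 * pi))
  # envelope pins the wobble to zero at both cruise ends, keeping altitude
  # continuous across the descent and ascent corners
  env <- sin(pi * clamp(tc, 0, scenario$t_cruise_s) / scenario$t_cruise_s)
  slow <- scenario$altitude_wobble_m * env *
    (0.6 * sin(2 * pi * tc / 67) +
     0.3 * sin(2 * pi * tc / 31 + ph[1]) +
     0.25 * sin(2 * pi * tc / 13 + ph[2]))
  slow + env * rough_altitude(scenario, tc)
}

# high-frequency altitude-control/terrain-following component: an
# Ornstein-Uhlenbeck path (correlation time ~tau) on a 0.5 s grid,
# clamped at 3 sigma, linearly interpolated in between. Real AUV altitude
# is nowhere near band-limited to the slow terrain undulation; this is
# also what gives the brightness series enough bandwidth for sub-second
# clock alignment.
rough_altitude <- function(scenario, tc) {
  sdev <- scenario$altitude_rough_m
  if (sdev == 0) return(rep(0, length(tc)))
  dt <- 0.5
  tg <- seq(0, scenario$t_cruise_s + dt, by = dt)
  a <- exp(-dt / scenario$rough_tau_s)
  x <- with_seed(child_seed(scenario$seed, "rough"), {
    e <- rnorm(length(tg), 0, sdev * sqrt(1 - a^2))
    as.numeric(stats::filter(e, a, method = "recursive"))
  })
  x <- clamp(x, -3 * sdev, 3 * sdev)
  stats::approx(tg, x, xout = clamp(tc, 0, scenario$t_cruise_s),
                rule = 2)$y
}

#' Evaluate the true dive trajectory at arbitrary times
#'
#' Continuous-time ground truth: local east/north position, altitude,
#' heading and dive phase at any instant. Navigation rows and per-image
#' poses are both sampled from this function, so interpolation errors can
#' be measured exactly.
#'
#' @param scenario A [dive_scenario()].
#' @param t_s Numeric vector of times since dive start (seconds).
#' @return Data frame with `t_s`, `east_m`, `north_m`, `altitude_m`,
#'   `heading_deg`, `pitch_deg`, `roll_deg`, `speed_mps`, `phase`.
#' @export
pose_at <- function(scenario, t_s) {
  s <- scenario
  t_s <- as.numeric(t_s)
  stopifnot(all(t_s >= 0), all(t_s <= s$t_total_s + 1e-9))
  tc <- t_s - s$t_descent_s
  phase <- ifelse(t_s < s$t_descent_s, "descent",
                  ifelse(tc < s$t_cruise_s, "cruise", "ascent"))
  altitude <- ifelse(
    phase == "descent", s$start_altitude_m - s$vertical_speed_mps * t_s,
    ifelse(phase == "ascent",
           s$cruise_altitude_m +
             s$vertical_speed_mps * (t_s - s$t_descent_s - s$t_cruise_s),
           s$cruise_altitude_m + cruise_wobble(s, tc)))
  tcc <- clamp(tc, 0, s$t_cruise_s)
  if (s$pattern == "stationary") {
    east <- rep(0, length(t_s)); north <- rep(0, length(t_s))
    heading <- rep(0, length(t_s))
    speed <- rep(0, length(t_s))
  } else if (s$pattern == "transect_1d") {
    east <- rep(0, length(t_s))
    north <- s$speed_mps * tcc
    heading <- rep(0, length(t_s))
    speed <- ifelse(phase == "cruise", s$speed_mps, 0)
  } else {
    t_line <- s$track_length_m / s$speed_mps
    line <- pmin(floor(tcc / t_line), s$n_lines - 1)
    along <- s$speed_mps * (tcc - line * t_line)
    north <- ifelse(line %% 2 == 0, along, s$track_length_m - along)
    east <- line * s$track_spacing_m
    heading <- ifelse(line %% 2 == 0, 0, 180)
    speed <- ifelse(phase == "cruise", s$speed_mps, 0)
  }
  data.frame(t_s = t_s, east_m = east, north_m = north,
             altitude_m = altitude, heading_deg = heading,
             pitch_deg = 0, roll_deg = 0, speed_mps = speed,
             phase = phase, stringsAsFactors = FALSE)
}

#' Generate the navigation/trajectory table of a scenario
#'
#' Samples the true trajectory at the navigation rate and converts it to
#' schema records (UTC timestamps, decimal-degree positions, altitude,
#' heading, attitude).
#'
#' @param scenario A [dive_scenario()].
#' @return Data frame of schema records with `t_ms` and `phase` columns.
#' @export
generate_trajectory <- function(scenario) {
  s <- scenario
  # half-open sampling: one row per nav interval from t = 0
  n <- floor(s$t_total_s * s$nav_rate_hz)
  t_s <- (0:(n - 1)) / s$nav_rate_hz
  p <- pose_at(s, t_s)
  ll <- offset_to_lonlat(p$north_m, p$east_m, s$origin_lat, s$origin_lon)
  t_ms <- s$t0_ms + round(t_s * 1000)
  data.frame(SUB_datetime = ms_to_subtime(t_ms),
             SUB_latitude = ll[, "lat"], SUB_longitude = ll[, "lon"],
             SUB_distance = p$altitude_m, SUB_heading = p$heading_deg,
             SUB_forwardvelocity = p$speed_mps,
             SUB_yawangle = p$heading_deg, SUB_pitchangle = p$pitch_deg,
             SUB_rollangle = p$roll_deg,
             quality_flag = "raw", t_ms = t_ms, phase = p$phase,
             stringsAsFactors = FALSE)
}

## ---- rendering -----------------------------------------------------------

#' Render one synthetic fisheye frame
#'
#' Renders what the survey camera sees from a pose over the flat synthetic
#' seafloor: rays are cast per pixel through the camera model, intersected
#' with the ground plane, and shaded with the scene's radiometric model
#' (see [scene_params()]). Same pose + same seed gives an identical frame.
#'
#' @param pose One row of [pose_at()] output (or a list with `east_m`,
#'   `north_m`, `altitude_m`, `heading_deg`, `pitch_deg`, `roll_deg`).
#' @param camera A [camera_spec()].
#' @param scene A [scene_params()].
#' @param blobs Blob field ([make_blob_field()]); `NULL` for bare sediment.
#' @param seed Integer seed for the pixel noise.
#' @param timestamp_ms Acquisition time attached to the frame.
#' @return A [fisheye_frame()].
#' @export
render_fisheye_image <- function(pose, camera, scene = scene_params(),
                                 blobs = NULL, seed = 1L,
                                 timestamp_ms = NA_real_) {
  stopifnot(pose$altitude_m > 0)
  model <- camera_ray_model(camera)
  w <- model$width; h <- model$height
  grid <- expand.grid(u = 0:(w - 1), v = 0:(h - 1))
  dirs <- unproject_pixel(model, grid$u, grid$v)
  theta <- acos(clamp(dirs[, 3], -1, 1))
  R <- attitude_matrix(pose$heading_deg %||% 0, pose$pitch_deg %||% 0,
                       pose$roll_deg %||% 0) %*% camera$CAM_orientation
  wd <- dirs %*% t(R)
  down <- wd[, 3]
  hits <- down > 0.05  # rays steeper than ~87 deg off nadir miss usefully
  albedo <- numeric(nrow(grid))
  albedo[hits] <- scene$albedo_base
  # blob detail is only resolvable (and visible through the vignetting)
  # within ~70 degrees of nadir; farther rays keep the bare sediment albedo
  detail <- down > 0.34
  if (any(detail)) {
    srange <- pose$altitude_m / down[detail]
    east <- pose$east_m + srange * wd[detail, 2]
    north <- pose$north_m + srange * wd[detail, 1]
    albedo[detail] <- albedo_at(blobs, east, north, scene$albedo_base)
  }
  vig <- if (scene$vignetting) cos(pmin(theta, pi / 2))^4 else 1
  b <- scene$ambient +
    scene$B0 * (scene$h0 / pose$altitude_m)^2 * vig * albedo
  if (scene$noise_sd > 0)
    b <- b + with_seed(seed, rnorm(length(b), 0, scene$noise_sd))
  px <- matrix(clamp(b, 0, 255), nrow = h, ncol = w, byrow = TRUE)
  fisheye_frame(px, timestamp_ms = timestamp_ms, model = model,
                metadata = list(pose = as.list(pose)))
}

# separable Gaussian blur with edge replication (condensation simulator)
gaussian_blur <- function(img, sigma = 2) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) {
    xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
    as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + length(x))]
  }
  out <- apply(img, 2, conv1)          # along columns (y)
  t(apply(out, 1, conv1))              # along rows (x)
}

## ---- corruption ----------------------------------------------------------

#' Inject realistic defects into a clean synthetic dive
#'
#' Applies, in order: the camera-clock offset to all image timestamps,
#' >=10-sigma spikes to a fraction of navigation position/altitude cells,
#' blanked (empty) cells, zeroed frames (flash misfires) and
#' condensation-like blur windows (Gaussian blur + contrast reduction).
#' Every corruption is recorded in the returned ground truth.
#'
#' @param frames List of [fisheye_frame()]s with true timestamps.
#' @param nav Navigation table from [generate_trajectory()].
#' @param scenario The [dive_scenario()].
#' @return List with elements `frames`, `nav` and `truth`. `truth` holds
#'   `clock_offset_ms`, a per-frame data frame (`frames`) with true pose,
#'   corruption labels and post-corruption mean gray, and per-cell
#'   navigation corruption masks (`nav_outliers`, `nav_gaps`).
#' @export
corrupt_stream <- function(frames, nav, scenario) {
  s <- scenario
  nf <- length(frames)
  stopifnot(nf > 0, nrow(nav) > 0)

  t_true <- vapply(frames, function(f) f$timestamp_ms, numeric(1))
  t_rec <- t_true + s$clock_offset_ms

  black <- with_seed(child_seed(s$seed, "black"),
                     runif(nf) < s$black_frame_prob)
  t_rel <- (t_true - s$t0_ms) / 1000
  condensed <- rep(FALSE, nf)
  for (win in s$condensation_windows)
    condensed <- condensed | (t_rel >= win[1] & t_rel < win[2])

  for (i in seq_len(nf)) {
    frames[[i]]$timestamp_ms <- t_rec[i]
    if (condensed[i] && !black[i]) {
      px <- gaussian_blur(frames[[i]]$pixels, sigma = 2.5)
      m <- mean(px)
      frames[[i]]$pixels <- clamp(m + 0.45 * (px - m), 0, 255)
    }
    if (black[i]) frames[[i]]$pixels[] <- 0
  }

  # navigation spikes and gaps: interior rows only (no extrapolation repair
  # at the ends), disjoint per field
  fields <- c("SUB_distance", "SUB_latitude", "SUB_longitude")
  interior <- if (nrow(nav) >= 6L) 3:(nrow(nav) - 2L) else integer(0)
  nav_outliers <- matrix(FALSE, nrow(nav), length(fields),
                         dimnames = list(NULL, fields))
  nav_gaps <- nav_outliers
  with_seed(child_seed(s$seed, "navdefects"), {
    for (f in fields) {
      n_out <- round(s$outlier_fraction * nrow(nav))
      n_gap <- round(s$gap_fraction * nrow(nav))
      pick <- sample(interior, min(length(interior), n_out + n_gap))
      rows_out <- utils::head(pick, n_out)
      rows_gap <- utils::tail(pick, length(pick) - length(rows_out))
      if (length(rows_out)) {
        scale <- max(stats::sd(nav[[f]], na.rm = TRUE), 1e-4)
        sign <- sample(c(-1, 1), length(rows_out), replace = TRUE)
        nav[[f]][rows_out] <- nav[[f]][rows_out] +
          sign * (10 + runif(length(rows_out), 0, 5)) *
          max(scale, if (f == "SUB_distance") 3 else 0)
        nav_outliers[rows_out, f] <- TRUE
      }
      if (length(rows_gap)) {
        nav[[f]][rows_gap] <- NA_real_
        nav_gaps[rows_gap, f] <- TRUE
      }
    }
  })

  mean_gray <- vapply(frames, function(f) mean(f$pixels), numeric(1))
  truth_frames <- data.frame(
    index = seq_len(nf),
    t_true_ms = t_true, t_recorded_ms = t_rec,
    black = black, condensation = condensed,
    water_column = vapply(frames, function(f)
      f$metadata$pose$altitude_m, numeric(1)) > 10,
    altitude_m = vapply(frames, function(f)
      f$metadata$pose$altitude_m, numeric(1)),
    east_m = vapply(frames, function(f) f$metadata$pose$east_m, numeric(1)),
    north_m = vapply(frames, function(f) f$metadata$pose$north_m, numeric(1)),
    heading_deg = vapply(frames, function(f)
      f$metadata$pose$heading_deg, numeric(1)),
    phase = vapply(frames, function(f) f$metadata$pose$phase, character(1)),
    mean_gray = mean_gray,
    stringsAsFactors = FALSE)

  list(frames = frames, nav = nav,
       truth = list(clock_offset_ms = s$clock_offset_ms,
                    frames = truth_frames,
                    nav_outliers = nav_outliers, nav_gaps = nav_gaps))
}

## ---- whole-dive generation -----------------------------------------------

#' Generate a complete synthetic dive
#'
#' Produces navigation and environment tables, rendered fisheye frames
#' named by the cruise/station/timestamp scheme, injected defects and the
#' full ground truth. Everything is a deterministic function of the
#' scenario seed.
#'
#' @param scenario A [dive_scenario()].
#' @param camera A [camera_spec()] (default [synth_camera()]).
#' @param scene A [scene_params()].
#' @param corrupt Apply [corrupt_stream()]? (default TRUE)
#' @return An object of class `synthetic_dive`: list with `scenario`,
#'   `camera`, `scene`, `blobs`, `nav`, `env`, `frames`, `names`
#'   (file-name stems, from recorded camera-clock times), `image_times`
#'   (data frame name/t_ms as a camera log) and `truth`.
#' @examples
#' \donttest{
#' dive <- generate_dive(dive_scenario(track_length_m = 15, n_lines = 2,
#'                                     start_altitude_m = 12, seed = 3))
#' length(dive$frames)
#' }
#' @export
generate_dive <- function(scenario, camera = synth_camera(),
                          scene = scene_params(), corrupt = TRUE) {
  s <- scenario
  nav <- generate_trajectory(s)

  # world extent: trajectory bounding box + imaging margin at cruise FOV
  margin <- 2.2 * s$cruise_altitude_m + 2
  ext <- c(min(0, 0) - margin,
           (if (s$pattern == "mow_the_lawn_2d")
             (s$n_lines - 1) * s$track_spacing_m else 0) + margin,
           -margin,
           (if (s$pattern == "stationary") 0 else s$track_length_m) + margin)
  blobs <- make_blob_field(ext, scene, seed = s$seed)

  n_img <- floor((s$t_total_s - s$image_phase_s) * s$image_rate_hz) + 1L
  t_img_s <- s$image_phase_s + (0:(n_img - 1L)) / s$image_rate_hz
  poses <- pose_at(s, t_img_s)
  frames <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    frames[[i]] <- render_fisheye_image(
      poses[i, , drop = FALSE], camera, scene, blobs,
      seed = child_seed(s$seed, paste0("frame", i)),
      timestamp_ms = s$t0_ms + round(t_img_s[i] * 1000))
  }

  # environment stream at half the navigation rate (merged later by timecode)
  n_env <- floor(s$t_total_s * s$nav_rate_hz / 2)
  t_env_s <- (0:(n_env - 1)) * 2 / s$nav_rate_hz + 0.5
  env_ms <- s$t0_ms + round(t_env_s * 1000)
  env <- with_seed(child_seed(s$seed, "env"), data.frame(
    SUB_datetime = ms_to_subtime(env_ms),
    ENV_temperaturewater = 1.45 + 0.05 * sin(2 * pi * t_env_s / 300) +
      rnorm(n_env, 0, 0.002),
    ENV_scattering = 0.12 + rnorm(n_env, 0, 0.004),
    quality_flag = "raw", t_ms = env_ms, stringsAsFactors = FALSE))

  if (corrupt) {
    cr <- corrupt_stream(frames, nav, s)
    frames <- cr$frames; nav <- cr$nav; truth <- cr$truth
  } else {
    cr <- corrupt_stream(frames, nav,
                         within_scenario_clean(s))
    frames <- cr$frames; nav <- cr$nav; truth <- cr$truth
  }

  # file names from the recorded (camera-clock) acquisition times
  names <- character(length(frames))
  for (i in seq_along(frames)) {
    ms <- frames[[i]]$timestamp_ms
    secs <- floor(ms / 1000)
    day <- as.Date(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"))
    tod <- secs - round(as.numeric(as.POSIXct(day, tz = "UTC")))
    id <- image_identifier(s$cruise, s$station, camera$CAM_id,
                           day, tod, i, index_width = 4L)
    names[i] <- format_image_name(id)
  }
  truth$frames$name <- names

  structure(list(scenario = s, camera = camera, scene = scene,
                 blobs = blobs, nav = nav, env = env, frames = frames,
                 names = names,
                 image_times = data.frame(
                   name = names,
                   SUB_datetime = ms_to_subtime(truth$frames$t_recorded_ms),
                   t_ms = truth$frames$t_recorded_ms,
                   stringsAsFactors = FALSE),
                 truth = truth),
            class = "synthetic_dive")
}

# a copy of the scenario with all corruption switched off
within_scenario_clean <- function(s) {
  s$clock_offset_ms <- 0
  s$outlier_fraction <- 0
  s$gap_fraction <- 0
  s$black_frame_prob <- 0
  s$condensation_windows <- list()
  s
}

#' @export
print.synthetic_dive <- function(x, ...) {
  cat("<synthetic_dive> seed", x$scenario$seed, "\n")
  cat(sprintf("  %d frames (%d x %d px), %d nav rows, %d env rows\n",
              length(x$frames), x$camera$image_width_px,
              x$camera$image_height_px, nrow(x$nav), nrow(x$env)))
  tf <- x$truth$frames
  cat(sprintf("  truth: offset %g ms, %d black, %d condensation, %d water-column\n",
              x$truth$clock_offset_ms, sum(tf$black), sum(tf$condensation),
              sum(tf$water_column)))
  invisible(x)
}

#' Write a synthetic dive to disk
#'
#' Materializes a dive as the pipeline's on-disk inputs: JPEG frames under
#' `raw/` named by the naming scheme, tab-separated `nav.tsv` and
#' `env.tsv` metadata tables, a camera-log `images.tsv` with millisecond
#' acquisition times, and machine-readable ground truth
#' (`truth_frames.tsv`, `truth.json`).
#'
#' @param dive A [generate_dive()] result.
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory?
#' @param quality JPEG quality in `(0, 1]`.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dive <- function(dive, dir, force = FALSE, quality = 0.95) {
  stopifnot(inherits(dive, "synthetic_dive"))
  if (dir.exists(dir) && length(dir(dir, all.files = TRUE, no.. = TRUE)) &&
      !force)
    stop("output directory ", dir, " is not empty (use force = TRUE)",
         call. = FALSE)
  dir.create(file.path(dir, "raw"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dive$frames))
    jpeg::writeJPEG(dive$frames[[i]]$pixels / 255,
                    file.path(dir, "raw", paste0(dive$names[i], ".jpg")),
                    quality = quality)
  write_metadata_table(dive$nav[, setdiff(names(dive$nav), "phase")],
                       file.path(dir, "nav.tsv"))
  write_metadata_table(dive$env, file.path(dir, "env.tsv"))
  write_metadata_table(dive$image_times, file.path(dir, "images.tsv"))
  tf <- dive$truth$frames
  utils::write.table(tf, file.path(dir, "truth_frames.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(clock_offset_ms = dive$truth$clock_offset_ms,
         seed = dive$scenario$seed,
         scenario = dive$scenario[setdiff(names(dive$scenario), "")]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
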