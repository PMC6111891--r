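## Camera geometry: equidistant fisheye and rectilinear (pinhole) models,
## un-distortion by inverse ray mapping, flat-seafloor geo-referencing and
## survey footprint/overlap/resolution/storage calculators.
##
## Conventions: image coordinates are 0-based with pixel centers at integer
## coordinates, x right / y down; camera frame is x right, y down, z along
## the optical axis; the local world frame is x North, y East, z Down.

#' Ray model of a camera
#'
#' The equidistant fisheye maps a ray at off-axis angle theta to image
#' radius `r = f * theta`; the rectilinear (pinhole) model maps it to
#' `r = f * tan(theta)`. Radii are in mm on the sensor and converted to
#' pixels by the pixel pitch.
#'
#' @param projection `"equidistant"` or `"rectilinear"`.
#' @param focal_mm Focal length in mm.
#' @param pitch_mm Pixel pitch in mm/px.
#' @param width,height Image size in pixels.
#' @param cx,cy Principal point in pixel coordinates (default: image
#'   center, `(width-1)/2`, `(height-1)/2`).
#' @return An object of class `ray_model`.
#' @seealso [camera_ray_model()] to derive one from a [camera_spec()].
#' @export
ray_model <- function(projection = c("equidistant", "rectilinear"),
                      focal_mm, pitch_mm, width, height,
                      cx = NULL, cy = NULL) {
  projection <- match.arg(projection)
  stopifnot(focal_mm > 0, pitch_mm > 0, width > 0, height > 0)
  structure(list(projection = projection, focal_mm = focal_mm,
                 pitch_mm = pitch_mm, width = as.integer(width),
                 height = as.integer(height),
                 cx = cx %||% ((width - 1) / 2),
                 cy = cy %||% ((height - 1) / 2),
                 f_px = focal_mm / pitch_mm),
            class = "ray_model")
}

#' @rdname ray_model
#' @param spec A [camera_spec()].
#' @export
camera_ray_model <- function(spec) {
  stopifnot(inherits(spec, "camera_spec"))
  ray_model(spec$projection, spec$CAM_focallength, pixel_pitch_of(spec),
            spec$image_width_px, spec$image_height_px)
}

#' @export
print.ray_model <- function(x, ...) {
  cat(sprintf("<ray_model> %s, f = %g mm (%.2f px), %d x %d px, pp (%.1f, %.1f)\n",
              x$projection, x$focal_mm, x$f_px, x$width, x$height, x$cx, x$cy))
  invisible(x)
}

#' Project rays into the image / un-project pixels to rays
#'
#' `project_ray` maps unit direction vectors in the camera frame to pixel
#' coordinates; `unproject_pixel` is its inverse. Both are vectorized.
#'
#' @param model A [ray_model()].
#' @param dirs Numeric matrix with columns x, y, z (camera frame); rows
#'   need not be normalized.
#' @param u,v Pixel coordinates (0-based, pixel centers at integers).
#' @return `project_ray`: matrix with columns `u`, `v`.
#'   `unproject_pixel`: matrix of unit direction vectors (columns x, y, z).
#' @export
project_ray <- function(model, dirs) {
  dirs <- matrix(as.numeric(dirs), ncol = 3)
  nrm <- sqrt(rowSums(dirs^2))
  d <- dirs / nrm
  theta <- acos(clamp(d[, 3], -1, 1))
  r_px <- switch(model$projection,
                 equidistant = model$f_px * theta,
                 rectilinear = model$f_px * tan(theta))
  rxy <- sqrt(d[, 1]^2 + d[, 2]^2)
  # on-axis rays have undefined azimuth; their radius is 0 anyway
  cphi <- ifelse(rxy > 0, d[, 1] / rxy, 1)
  sphi <- ifelse(rxy > 0, d[, 2] / rxy, 0)
  cbind(u = model$cx + r_px * cphi, v = model$cy + r_px * sphi)
}

#' @rdname project_ray
#' @export
unproject_pixel <- function(model, u, v) {
  dx <- (u - model$cx)
  dy <- (v - model$cy)
  r_px <- sqrt(dx^2 + dy^2)
  theta <- switch(model$projection,
                  equidistant = r_px / model$f_px,
                  rectilinear = atan(r_px / model$f_px))
  cphi <- ifelse(r_px > 0, dx / r_px, 1)
  sphi <- ifelse(r_px > 0, dy / r_px, 0)
  st <- sin(theta)
  cbind(x = st * cphi, y = st * sphi, z = cos(theta))
}

#' Bilinear sampling of an image
#'
#' @param img Numeric matrix (rows = y, cols = x).
#' @param u,v 0-based pixel coordinates.
#' @return List with `value` (NA where any of the four neighbors falls
#'   outside the image) and logical `inside`.
#' @noRd
bilinear_sample <- function(img, u, v) {
  h <- nrow(img); w <- ncol(img)
  j0 <- floor(u); i0 <- floor(v)
  fu <- u - j0; fv <- v - i0
  inside <- j0 >= 0 & i0 >= 0 & (j0 + 1) <= (w - 1) & (i0 + 1) <= (h - 1)
  val <- rep(NA_real_, length(u))
  if (any(inside)) {
    j0i <- j0[inside]; i0i <- i0[inside]
    fui <- fu[inside]; fvi <- fv[inside]
    idx <- function(di, dj) img[cbind(i0i + di + 1, j0i + dj + 1)]
    val[inside] <-
      idx(0, 0) * (1 - fui) * (1 - fvi) + idx(0, 1) * fui * (1 - fvi) +
      idx(1, 0) * (1 - fui) * fvi + idx(1, 1) * fui * fvi
  }
  list(value = val, inside = inside)
}

#' Un-distort a fisheye frame to a virtual perspective camera
#'
#' Resamples a raw wide-angle frame into the image an ideal rectilinear
#' (pinhole) camera with the given horizontal field of view would have
#' captured from the same pose. For each virtual pixel the associated ray
#' is computed by rectilinear un-projection, projected into the raw image
#' through the raw camera model (equidistant by default), and the color
#' bilinearly interpolated from the neighboring source pixels. Virtual
#' pixels whose ray falls outside the raw image are set to the sentinel
#' value 0 and masked. Frame metadata are retained in the output.
#'
#' @param frame A [fisheye_frame()] or plain numeric matrix (gray values).
#' @param raw_model [ray_model()] of the raw camera; defaults to the model
#'   attached to `frame`.
#' @param out_hfov_deg Horizontal field of view of the virtual camera
#'   (degrees; default 90).
#' @param out_size `c(width, height)` of the virtual image; defaults to
#'   the raw size, i.e. the same pixel count across the virtual field of
#'   view, square pixels, centered principal point.
#' @return A `rectilinear_frame`: list with `pixels`, logical `mask`
#'   (TRUE where valid), `model` (the virtual camera), `timestamp_ms`,
#'   `metadata`.
#' @export
undistort <- function(frame, raw_model = NULL, out_hfov_deg = 90,
                      out_size = NULL) {
  if (inherits(frame, "fisheye_frame")) {
    raw_model <- raw_model %||% frame$model
    px <- frame$pixels
    meta <- frame$metadata
    ts <- frame$timestamp_ms
  } else {
    px <- frame
    meta <- NULL
    ts <- NA_real_
  }
  stopifnot(inherits(raw_model, "ray_model"), is.matrix(px))
  out_size <- out_size %||% c(ncol(px), nrow(px))
  w <- as.integer(out_size[1]); h <- as.integer(out_size[2])
  # edge pixel centers sit at +-HFOV/2: f = half-width / tan(HFOV/2)
  f_v <- ((w - 1) / 2) / tan(out_hfov_deg / 2 * pi / 180)
  vmodel <- ray_model("rectilinear", focal_mm = f_v, pitch_mm = 1,
                      width = w, height = h)
  grid <- expand.grid(u = 0:(w - 1), v = 0:(h - 1))
  dirs <- unproject_pixel(vmodel, grid$u, grid$v)
  uv <- project_ray(raw_model, dirs)
  s <- bilinear_sample(px, uv[, "u"], uv[, "v"])
  mask <- matrix(s$inside, nrow = h, ncol = w, byrow = TRUE)
  vals <- s$value
  vals[!s$inside] <- 0  # sentinel
  out <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  structure(list(pixels = out, mask = mask, model = vmodel,
                 timestamp_ms = ts, metadata = meta,
                 hfov_deg = out_hfov_deg),
            class = "rectilinear_frame")
}

#' @export
print.rectilinear_frame <- function(x, ...) {
  cat(sprintf("<rectilinear_frame> %d x %d px, HFOV %g deg, %.1f%% valid\n",
              ncol(x$pixels), nrow(x$pixels), x$hfov_deg,
              100 * mean(x$mask)))
  invisible(x)
}

## ---- local tangent plane -------------------------------------------------

# WGS84 meridian (M) and prime-vertical (N) radii of curvature, m/degree
wgs84_m_per_deg <- function(lat_deg) {
  a <- 6378137.0
  e2 <- 0.00669437999014
  s2 <- sin(lat_deg * pi / 180)^2
  m_lat <- pi / 180 * a * (1 - e2) / (1 - e2 * s2)^1.5
  m_lon <- pi / 180 * a * cos(lat_deg * pi / 180) / sqrt(1 - e2 * s2)
  c(lat = m_lat, lon = m_lon)
}

#' Convert local North/East offsets to geographic coordinates and back
#'
#' Small-offset conversion on the local tangent plane at `lat0`/`lon0`,
#' using WGS84 meridian and parallel radii of curvature.
#'
#' @param north_m,east_m Offsets in meters.
#' @param lat0,lon0 Reference position in decimal degrees.
#' @param lat,lon Positions to convert back to meters.
#' @return `offset_to_lonlat`: matrix with columns `lat`, `lon`;
#'   `lonlat_to_offset`: matrix with columns `north_m`, `east_m`.
#' @export
offset_to_lonlat <- function(north_m, east_m, lat0, lon0) {
  k <- wgs84_m_per_deg(lat0)
  cbind(lat = lat0 + north_m / k[["lat"]],
        lon = lon0 + east_m / k[["lon"]])
}

#' @rdname offset_to_lonlat
#' @export
lonlat_to_offset <- function(lat, lon, lat0, lon0) {
  k <- wgs84_m_per_deg(lat0)
  cbind(north_m = (lat - lat0) * k[["lat"]],
        east_m = (lon - lon0) * k[["lon"]])
}

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' Attitude rotation matrix (platform to world)
#'
#' Yaw/pitch/roll in degrees, applied in z-y-x order in the local
#' North/East/Down world frame. Heading 0 is North, 90 East.
#' @noRd
attitude_matrix <- function(heading_deg, pitch_deg = 0, roll_deg = 0) {
  rot_z(heading_deg * pi / 180) %*% rot_y(pitch_deg * pi / 180) %*%
    rot_x(roll_deg * pi / 180)
}

#' Geo-reference image pixels on a flat seafloor
#'
#' Computes the geographic position of the seafloor point seen by a pixel:
#' the pixel ray is rotated through the camera mounting and the platform
#' attitude/heading, intersected with a flat ground plane at the given
#' altitude, and the metric offset converted to degrees on the local
#' tangent plane. Assumes a flat seafloor and altitude > 0.
#'
#' @param px Matrix or vector of pixel coordinates (columns u, v).
#' @param pose List/row with `latitude`, `longitude`, `altitude_m`,
#'   `heading_deg` and optional `pitch_deg`, `roll_deg`.
#' @param model [ray_model()] of the (raw or virtual) camera.
#' @param mounting Camera-to-platform rotation (default
#'   [cam_mounting_default()]).
#' @return Matrix with columns `lat`, `lon` (`NA` for rays that do not
#'   intersect the ground plane in front of the camera).
#' @export
georeference_pixel <- function(px, pose, model,
                               mounting = cam_mounting_default()) {
  px <- matrix(as.numeric(px), ncol = 2)
  stopifnot(pose$altitude_m > 0)
  dirs <- unproject_pixel(model, px[, 1], px[, 2])
  R <- attitude_matrix(pose$heading_deg %||% 0, pose$pitch_deg %||% 0,
                       pose$roll_deg %||% 0) %*% mounting
  w <- dirs %*% t(R)  # rows: world-frame directions (N, E, D)
  down <- w[, 3]
  ok <- down > 1e-12
  s <- ifelse(ok, pose$altitude_m / down, NA_real_)
  offset_to_lonlat(s * w[, 1], s * w[, 2], pose$latitude, pose$longitude)
}

## ---- survey-scale calculators --------------------------------------------

#' Ground resolution at the image center
#'
#' For a nadir camera the center of the image resolves
#' `f_px / altitude` pixels per unit ground length (small-angle limit,
#' identical for equidistant and rectilinear models).
#'
#' @param altitude_m Altitude above the seafloor in meters.
#' @param model A [ray_model()].
#' @param at Currently only `"center"`.
#' @return Resolution in px/mm.
#' @examples
#' m <- ray_model("equidistant", focal_mm = 15, pitch_mm = 6.58e-3,
#'                width = 5472, height = 3648)
#' ground_resolution(10, m)  # ~0.23 px/mm
#' @export
ground_resolution <- function(altitude_m, model, at = "center") {
  stopifnot(altitude_m > 0, at == "center")
  model$f_px / (altitude_m * 1000)
}

#' Along-track overlap of consecutive image footprints
#'
#' A nadir camera with horizontal field of view `hfov_deg` at altitude `h`
#' images a footprint of length `2 h tan(hfov/2)` along track. Consecutive
#' frames taken `speed / rate` meters apart overlap by
#' `1 - (speed/rate) / (2 h tan(hfov/2))`, clamped at 0.
#'
#' @param altitude_m Altitude above seafloor (m).
#' @param speed_mps Vehicle speed (m/s).
#' @param rate_hz Image acquisition rate (Hz).
#' @param hfov_deg Horizontal field of view (degrees, default 90).
#' @return Overlap fraction in `[0, 1)`.
#' @examples
#' along_track_overlap(7.5, 1.5, 1)   # 0.90
#' @export
along_track_overlap <- function(altitude_m, speed_mps, rate_hz,
                                hfov_deg = 90) {
  stopifnot(altitude_m > 0, speed_mps > 0, rate_hz > 0, hfov_deg > 0)
  footprint <- 2 * altitude_m * tan(hfov_deg / 2 * pi / 180)
  max(0, 1 - (speed_mps / rate_hz) / footprint)
}

#' Storage required to image an area at a given resolution
#'
#' Survey-planning arithmetic: bytes needed for an uncompressed ortho-photo
#' of `area_km2` at `resolution_px_per_mm`, `bytes_per_px` per pixel,
#' covering `coverage_fraction` of the area. Imaging the global seafloor
#' (71% of 5.10e8 km^2) at 1 px/mm in 3-byte color comes to ~1.09e21
#' bytes — about a zettabyte.
#'
#' @param area_km2 Area in square kilometers.
#' @param resolution_px_per_mm Resolution in pixels per millimeter.
#' @param bytes_per_px Bytes per pixel (3 for 8-bit color).
#' @param coverage_fraction Fraction of the area actually imaged.
#' @return Storage requirement in bytes.
#' @examples
#' storage_estimate(5.10e8, 1, 3, 0.71)  # ~1.09e21
#' @export
storage_estimate <- function(area_km2, resolution_px_per_mm, bytes_per_px,
                             coverage_fraction = 1) {
  stopifnot(area_km2 > 0, resolution_px_per_mm > 0, bytes_per_px > 0,
            coverage_fraction > 0)
  coverage_fraction * area_km2 * 1e12 * resolution_px_per_mm^2 * bytes_per_px
}
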