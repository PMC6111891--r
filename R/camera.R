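## Camera/deployment configuration: intrinsics, mounting, port description.

#' Default camera mounting orientation
#'
#' Rotation matrix mapping camera-frame direction vectors (x right in the
#' image, y down in the image, z along the optical axis) to platform-frame
#' vectors (x forward, y starboard, z down). The default is a nadir-looking
#' camera with image "up" pointing forward.
#'
#' @return A 3x3 rotation matrix.
#' @export
cam_mounting_default <- function() {
  # columns are the platform-frame images of the camera axes
  matrix(c(0, 1, 0,    # camera x (image right) -> starboard
           -1, 0, 0,   # camera y (image down)  -> aft
           0, 0, 1),   # camera z (optical axis) -> down
         nrow = 3, byrow = FALSE)
}

#' Camera specification
#'
#' Bundles the camera-related metadata fields stored alongside a
#' deployment: make/model, mounting offset and orientation in platform
#' coordinates, pressure-port description, lens model and intrinsics. The
#' mounting orientation must be a proper rotation ([validate_rotation()]).
#' Port refraction is recorded for provenance but not modeled in the ray
#' path (in-air calibration is assumed).
#'
#' @param CAM_model,CAM_id,CAM_lensmodel Free-text/token descriptors.
#' @param CAM_position Camera center offset in platform coordinates (mm).
#' @param CAM_orientation 3x3 rotation, camera frame to platform frame.
#' @param CAM_refraction List: `port` ("dome" or "flat"),
#'   `glass_thickness_mm`, `refractive_index`.
#' @param CAM_alignment Optional port offset/normal in camera coordinates.
#' @param CAM_focallength Focal length in mm.
#' @param CAM_fnumber Aperture f-number.
#' @param projection `"equidistant"` (fisheye) or `"rectilinear"`.
#' @param sensor_width_mm,sensor_height_mm Sensor size in mm.
#' @param image_width_px,image_height_px Image size in pixels.
#' @return An object of class `camera_spec`.
#' @examples
#' spec <- camera_spec(image_width_px = 64, image_height_px = 64,
#'                     sensor_width_mm = 24, sensor_height_mm = 24)
#' pixel_pitch(spec)
#' @export
camera_spec <- function(CAM_model = "synthetic DSC",
                        CAM_id = "CAM0",
                        CAM_position = c(0, 0, 0),
                        CAM_orientation = cam_mounting_default(),
                        CAM_refraction = list(port = "dome",
                                              glass_thickness_mm = 10,
                                              refractive_index = 1.49),
                        CAM_alignment = NULL,
                        CAM_lensmodel = "synthetic fisheye",
                        CAM_focallength = 15,
                        CAM_fnumber = 8,
                        projection = c("equidistant", "rectilinear"),
                        sensor_width_mm = 35.9,
                        sensor_height_mm = 24,
                        image_width_px = 5472,
                        image_height_px = 3648) {
  projection <- match.arg(projection)
  if (!validate_rotation(CAM_orientation))
    stop("CAM_orientation is not a proper rotation matrix", call. = FALSE)
  stopifnot(length(CAM_position) == 3, CAM_focallength > 0,
            sensor_width_mm > 0, image_width_px > 0, image_height_px > 0)
  spec <- list(CAM_model = CAM_model, CAM_id = CAM_id,
               CAM_position = CAM_position,
               CAM_orientation = CAM_orientation,
               CAM_refraction = CAM_refraction,
               CAM_alignment = CAM_alignment,
               CAM_lensmodel = CAM_lensmodel,
               CAM_focallength = CAM_focallength,
               CAM_fnumber = CAM_fnumber,
               projection = projection,
               sensor_width_mm = sensor_width_mm,
               sensor_height_mm = sensor_height_mm,
               image_width_px = as.integer(image_width_px),
               image_height_px = as.integer(image_height_px))
  if (pixel_pitch_of(spec) <= 0)
    stop("pixel pitch must be positive", call. = FALSE)
  class(spec) <- "camera_spec"
  spec
}

pixel_pitch_of <- function(spec) spec$sensor_width_mm / spec$image_width_px

#' Pixel pitch of a camera
#'
#' @param spec A [camera_spec()].
#' @return Pixel pitch in mm/px (`sensor_width_mm / image_width_px`).
#' @export
pixel_pitch <- function(spec) {
  stopifnot(inherits(spec, "camera_spec"))
  pixel_pitch_of(spec)
}

#' @export
print.camera_spec <- function(x, ...) {
  cat("<camera_spec> ", x$CAM_model, " + ", x$CAM_lensmodel, "\n", sep = "")
  cat(sprintf("  projection: %s, f = %g mm, pitch = %.4g mm/px, %d x %d px\n",
              x$projection, x$CAM_focallength, pixel_pitch_of(x),
              x$image_width_px, x$image_height_px))
  cat("  port:", x$CAM_refraction$port %||% "?", "\n")
  invisible(x)
}
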