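test_that("projection and un-projection are mutual inverses below 85 deg", {
  set.seed(61)
  for (proj in c("equidistant", "rectilinear")) {
    m <- ray_model(proj, focal_mm = 15, pitch_mm = 0.5, width = 201,
                   height = 201)
    theta <- runif(300, 0, 84.9) * pi / 180
    phi <- runif(300, -pi, pi)
    dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    uv <- project_ray(m, dirs)
    back <- unproject_pixel(m, uv[, "u"], uv[, "v"])
    expect_lt(max(abs(back - dirs)), 1e-9)
  }
})

test_that("the principal point is a fixed point of un-distortion", {
  m <- ray_model("equidistant", 15, 0.5, 64, 64)
  uv <- project_ray(m, cbind(0, 0, 1))
  expect_equal(unname(uv), cbind(m$cx, m$cy))
  # undistort maps the center pixel from the center pixel
  img <- matrix(0, 64, 64)
  img[round(m$cy) + 1, round(m$cx) + 1] <- 200
  rf <- undistort(img, m)
  expect_gt(rf$pixels[round(m$cy) + 1, round(m$cx) + 1], 100)
})

test_that("a 45-degree ray lands on the horizontal edge of a 90-deg view", {
  w <- 101
  f_v <- ((w - 1) / 2) / tan(pi / 4)
  vm <- ray_model("rectilinear", focal_mm = f_v, pitch_mm = 1,
                  width = w, height = w)
  uv <- project_ray(vm, cbind(sin(pi / 4), 0, cos(pi / 4)))
  expect_equal(unname(uv[, "u"]), w - 1, tolerance = 1e-9)  # right edge
  expect_equal(unname(uv[, "v"]), (w - 1) / 2, tolerance = 1e-9)
})

test_that("un-distortion recovers the latent rectilinear scene", {
  scene <- scene_params(noise_sd = 0)
  blobs <- make_blob_field(c(-20, 25, -20, 80), scene, seed = 62)
  pose <- list(east_m = 3, north_m = 20, altitude_m = 7.5, heading_deg = 0,
               pitch_deg = 0, roll_deg = 0)
  fish <- render_fisheye_image(pose, synth_camera(96, 96), scene, blobs,
                               seed = 1)
  rf <- undistort(fish)
  # latent scene: the same world rendered through an ideal 90-deg-HFOV
  # rectilinear camera from the same pose
  w <- 96
  f_px <- ((w - 1) / 2) / tan(pi / 4)
  pitch <- 15 / f_px
  rect_cam <- camera_spec(projection = "rectilinear", CAM_focallength = 15,
                          sensor_width_mm = pitch * w,
                          sensor_height_mm = pitch * w,
                          image_width_px = w, image_height_px = w)
  ref <- render_fisheye_image(pose, rect_cam, scene, blobs, seed = 1)
  expect_true(all(rf$mask))  # raw model covers the whole virtual view
  rms <- sqrt(mean((rf$pixels - ref$pixels)^2))
  expect_lt(rms, 2)
})

test_that("a straight seafloor line is straight after un-distortion", {
  scene <- scene_params(noise_sd = 0)
  # a dark band along north at east = -2.5, well off the optical axis
  line_blobs <- data.frame(north = seq(-40, 100, by = 0.1), east = -2.5,
                           r_major = 0.15, ratio = 1, angle = 0, depth = 0.8)
  pose <- list(east_m = 1, north_m = 20, altitude_m = 7.5, heading_deg = 0,
               pitch_deg = 0, roll_deg = 0)
  cam <- synth_camera(96, 96)
  fish <- render_fisheye_image(pose, cam, scene, line_blobs, seed = 1)
  bg <- render_fisheye_image(pose, cam, scene, NULL, seed = 1)
  # the fisheye renders the line visibly curved ...
  rms_raw <- line_fit_rms(line_centroids(fish$pixels, bg$pixels))
  expect_gt(rms_raw, 0.5)
  # ... and un-distortion makes it straight to sub-pixel accuracy
  rf <- undistort(fish)
  rb <- undistort(bg)
  rms_out <- line_fit_rms(line_centroids(rf$pixels, rb$pixels, rf$mask))
  expect_lt(rms_out, 0.5)
})

test_that("geo-referencing places pixels on the flat seafloor", {
  m <- ray_model("equidistant", 15, 0.5, 101, 101)
  pose <- list(latitude = -7.07, longitude = -88.45, altitude_m = 10,
               heading_deg = 0, pitch_deg = 0, roll_deg = 0)
  # nadir pixel at zero attitude returns the pose's own position
  ll <- georeference_pixel(c(m$cx, m$cy), pose, m)
  expect_equal(unname(ll[, "lat"]), pose$latitude, tolerance = 1e-12)
  expect_equal(unname(ll[, "lon"]), pose$longitude, tolerance = 1e-12)

  # a 45-deg forward ray at 10 m altitude lands ~10 m due north,
  # i.e. about +9.0e-5 degrees of latitude
  f_px <- m$f_px
  px45 <- c(m$cx, m$cy - f_px * pi / 4)  # image up = forward
  ll45 <- georeference_pixel(px45, pose, m)
  dlat <- ll45[, "lat"] - pose$latitude
  expect_equal(unname(dlat), 9.0e-5, tolerance = 0.01)
  expect_equal(unname(ll45[, "lon"]), pose$longitude, tolerance = 1e-10)
  en <- lonlat_to_offset(ll45[, "lat"], ll45[, "lon"], pose$latitude,
                         pose$longitude)
  expect_equal(unname(en[, "north_m"]), 10, tolerance = 1e-6)

  # heading 90 rotates the same displacement to due east
  pose_e <- utils::modifyList(pose, list(heading_deg = 90))
  ll_e <- georeference_pixel(px45, pose_e, m)
  en_e <- lonlat_to_offset(ll_e[, "lat"], ll_e[, "lon"], pose$latitude,
                           pose$longitude)
  expect_equal(unname(en_e[, "east_m"]), 10, tolerance = 1e-6)
  expect_equal(unname(en_e[, "north_m"]), 0, tolerance = 1e-6)

  # a ray pointing away from the ground yields NA
  up <- georeference_pixel(c(m$cx + m$f_px * pi * 0.55, m$cy), pose, m)
  expect_true(all(is.na(up)))
})

test_that("footprint corners span the tangent-of-half-FOV rectangle", {
  w <- 201
  f_v <- ((w - 1) / 2) / tan(pi / 4)
  vm <- ray_model("rectilinear", f_v, 1, w, w)
  pose <- list(latitude = 11.5, longitude = 142.2, altitude_m = 7.5,
               heading_deg = 0, pitch_deg = 0, roll_deg = 0)
  corners <- rbind(c(0, 0), c(w - 1, 0), c(0, w - 1), c(w - 1, w - 1))
  ll <- georeference_pixel(corners, pose, vm)
  en <- lonlat_to_offset(ll[, "lat"], ll[, "lon"], pose$latitude,
                         pose$longitude)
  span_e <- diff(range(en[, "east_m"]))
  span_n <- diff(range(en[, "north_m"]))
  expect_equal(span_e, 2 * 7.5 * tan(pi / 4), tolerance = 1e-6)
  expect_equal(span_n, 2 * 7.5 * tan(pi / 4), tolerance = 1e-6)
})

test_that("center ground resolution follows f_px / altitude", {
  m <- ray_model("equidistant", focal_mm = 15, pitch_mm = 6.58e-3,
                 width = 5472, height = 3648)
  r10 <- ground_resolution(10, m)
  expect_equal(r10, (15 / 6.58e-3) / 1e4, tolerance = 1e-12)  # ~0.228 px/mm
  expect_lt(abs(r10 - 0.2) / 0.2, 0.15)  # "roughly 0.2 px/mm" at 10 m
  # halving the altitude doubles the resolution exactly
  expect_equal(ground_resolution(4.5, m), ground_resolution(9, m) * 2)
  expect_lt(ground_resolution(1e12, m), 1e-8)  # vanishes at large altitude
})

test_that("along-track overlap follows the footprint geometry", {
  expect_equal(along_track_overlap(7.5, 1.5, 1, 90), 0.9, tolerance = 1e-15)
  expect_equal(along_track_overlap(10, 1.5, 1, 90), 1 - 1.5 / 20,
               tolerance = 1e-15)
  # frame spacing beyond the footprint clamps at zero overlap
  expect_equal(along_track_overlap(1, 30, 1, 90), 0)
})

test_that("survey storage arithmetic scales with area and resolution", {
  expect_equal(storage_estimate(5.10e8, 1, 3, 0.71), 1.0863e21)
  expect_equal(signif(storage_estimate(5.10e8, 1, 3, 0.71), 3), 1.09e21)
  expect_equal(storage_estimate(1, 1, 3), 3e12)
  expect_equal(storage_estimate(1, 2, 3), 4 * storage_estimate(1, 1, 3))
})
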