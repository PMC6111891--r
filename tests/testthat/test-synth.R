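test_that("trajectory sampling matches the survey arithmetic", {
  # 2 lines x 30 m at 1.5 m/s, 1 Hz -> 20 s per line -> 40 cruise poses
  s <- dive_scenario(track_length_m = 30, n_lines = 2, seed = 2)
  nav <- generate_trajectory(s)
  expect_equal(sum(nav$phase == "cruise"), 40)
  # heading alternates by 180 degrees between adjacent lines
  cruise <- nav[nav$phase == "cruise", ]
  expect_setequal(unique(cruise$SUB_heading), c(0, 180))
  expect_equal(unique(cruise$SUB_heading[1:20]), 0)
  expect_equal(unique(cruise$SUB_heading[21:40]), 180)
  # descent starts above the 10 m filter ceiling and is linear in time
  desc <- nav[nav$phase == "descent", ]
  expect_gt(desc$SUB_distance[1], 10)
  expect_equal(diff(desc$SUB_distance),
               rep(-s$vertical_speed_mps, nrow(desc) - 1), tolerance = 1e-12)
  # a 10-minute cruise at 1 Hz yields 600 cruise-phase samples
  s10 <- dive_scenario(track_length_m = 225, n_lines = 4, seed = 2)
  expect_equal(s10$t_cruise_s, 600)
  expect_equal(sum(generate_trajectory(s10)$phase == "cruise"), 600)
})

test_that("stationary pattern holds position and heading", {
  s <- dive_scenario(pattern = "stationary", stationary_duration_s = 30,
                     seed = 3)
  nav <- generate_trajectory(s)
  expect_equal(length(unique(nav$SUB_latitude)), 1)
  expect_equal(length(unique(nav$SUB_longitude)), 1)
  expect_equal(unique(nav$SUB_heading), 0)
})

test_that("the whole dive is a deterministic function of the seed", {
  d1 <- tiny_dive(seed = 9)
  d2 <- tiny_dive(seed = 9)
  expect_identical(d1$nav, d2$nav)
  expect_identical(d1$names, d2$names)
  expect_identical(lapply(d1$frames, `[[`, "pixels"),
                   lapply(d2$frames, `[[`, "pixels"))
  d3 <- tiny_dive(seed = 10)
  expect_false(identical(d1$frames[[20]]$pixels, d3$frames[[20]]$pixels))
})

test_that("rendered brightness falls with altitude and towards corners", {
  scene <- scene_params(noise_sd = 0)
  blobs <- make_blob_field(c(-25, 25, -25, 25), scene, seed = 4)
  pose <- function(h) list(east_m = 0, north_m = 0, altitude_m = h,
                           heading_deg = 0, pitch_deg = 0, roll_deg = 0)
  f45 <- render_fisheye_image(pose(4.5), tiny_camera(), scene, blobs, seed = 1)
  f10 <- render_fisheye_image(pose(10), tiny_camera(), scene, blobs, seed = 1)
  expect_gt(mean(f45$pixels), mean(f10$pixels))
  # vignetting: corner patches darker than the center patch
  px <- f45$pixels
  n <- nrow(px)
  ctr <- mean(px[(n/2 - 2):(n/2 + 2), (n/2 - 2):(n/2 + 2)])
  crn <- mean(c(px[1:4, 1:4], px[1:4, (n-3):n],
                px[(n-3):n, 1:4], px[(n-3):n, (n-3):n]))
  expect_lt(crn, ctr)
  # determinism of the renderer
  f45b <- render_fisheye_image(pose(4.5), tiny_camera(), scene, blobs,
                               seed = 1)
  expect_identical(f45$pixels, f45b$pixels)
})

test_that("overlapping frames see the same world-anchored scene", {
  scene <- scene_params(noise_sd = 0)
  blobs <- make_blob_field(c(-25, 25, -25, 25), scene, seed = 5)
  p1 <- list(east_m = 0, north_m = 0, altitude_m = 7.5, heading_deg = 0,
             pitch_deg = 0, roll_deg = 0)
  p2 <- utils::modifyList(p1, list(north_m = 1.5))
  f1 <- render_fisheye_image(p1, tiny_camera(), scene, blobs, seed = 1)
  f2 <- render_fisheye_image(p2, tiny_camera(), scene, blobs, seed = 1)
  # the same ground point seen from both poses has the same albedo, so the
  # two frames correlate strongly after shifting by the footprint motion,
  # but are not identical
  expect_false(identical(f1$pixels, f2$pixels))
  a1 <- albedo_at(blobs, c(0.3, 1.1), c(2.2, -0.7))
  a2 <- albedo_at(blobs, c(0.3, 1.1), c(2.2, -0.7))
  expect_identical(a1, a2)
})

test_that("corruption is applied exactly as labeled in the ground truth", {
  dive <- tiny_dive(seed = 6, clock_offset_ms = 2500)
  tf <- dive$truth$frames
  # recorded timestamps differ from true timestamps by exactly the offset
  expect_equal(tf$t_recorded_ms - tf$t_true_ms,
               rep(2500, nrow(tf)))
  # black frames are all-zero, and only those
  zeroed <- vapply(dive$frames, function(f) all(f$pixels == 0), logical(1))
  expect_equal(unname(zeroed), tf$black)
  # nav corruption masks match what is in the table
  expect_true(all(is.na(dive$nav$SUB_distance[
    dive$truth$nav_gaps[, "SUB_distance"]])))
  expect_true(all(abs(dive$nav$SUB_distance[
    dive$truth$nav_outliers[, "SUB_distance"]] - 7.5) > 10 |
      dive$nav$SUB_distance[dive$truth$nav_outliers[, "SUB_distance"]] < 0))

  # zero corruption probabilities mean zero labels
  clean <- tiny_dive(seed = 6, clock_offset_ms = 0, outlier_fraction = 0,
                     gap_fraction = 0, black_frame_prob = 0)
  expect_false(any(clean$truth$frames$black))
  expect_false(any(clean$truth$nav_outliers))
  expect_equal(clean$truth$frames$t_recorded_ms,
               clean$truth$frames$t_true_ms)

  # probability one blacks out every frame
  allblack <- tiny_dive(seed = 6, black_frame_prob = 1)
  expect_true(all(vapply(allblack$frames, function(f) all(f$pixels == 0),
                         logical(1))))
})

test_that("ground-truth labels partition the frames", {
  dive <- tiny_dive(seed = 8, condensation_windows = list(c(12, 18)))
  tf <- dive$truth$frames
  corrupted <- tf$black | tf$condensation | tf$water_column
  clean <- !corrupted
  expect_equal(sum(corrupted) + sum(clean), nrow(tf))
  expect_true(any(tf$condensation))
})

test_that("default cruise geometry reproduces the 90% along-track overlap", {
  s <- dive_scenario(seed = 1)
  nav <- generate_trajectory(s)
  cruise <- nav[nav$phase == "cruise", ]
  step <- abs(diff(lonlat_to_offset(cruise$SUB_latitude, cruise$SUB_longitude,
                                    s$origin_lat, s$origin_lon)[, 1]))
  step <- step[is.finite(step) & step > 0]  # skip gap cells and line turns
  # consecutive exposures advance speed/rate = 1.5 m along track
  expect_equal(stats::median(step), s$speed_mps / s$image_rate_hz,
               tolerance = 1e-6)
  expect_equal(along_track_overlap(s$cruise_altitude_m, s$speed_mps,
                                   s$image_rate_hz, 90), 0.9,
               tolerance = 1e-12)
})

test_that("a dive written to disk can be read back faithfully", {
  dive <- tiny_dive(seed = 12)
  dir <- withr::local_tempdir()
  write_synthetic_dive(dive, dir)
  expect_error(write_synthetic_dive(dive, dir), "not empty")
  expect_silent(write_synthetic_dive(dive, dir, force = TRUE))
  frames <- read_image_dir(file.path(dir, "raw"),
                           times = read_metadata_table(
                             file.path(dir, "images.tsv")))
  expect_length(frames, length(dive$frames))
  # JPEG round trip keeps frames close and black frames exactly black
  i_black <- which(dive$truth$frames$black)[1]
  if (!is.na(i_black))
    expect_true(all(frames[[dive$names[i_black]]]$pixels == 0))
  i_ok <- which(!dive$truth$frames$black)[1]
  expect_lt(max(abs(frames[[dive$names[i_ok]]]$pixels -
                      dive$frames[[i_ok]]$pixels)), 12)
  nav <- read_metadata_table(file.path(dir, "nav.tsv"))
  expect_equal(nav$SUB_distance, dive$nav$SUB_distance, tolerance = 1e-9)
})
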