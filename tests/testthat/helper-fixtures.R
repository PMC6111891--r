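# Shared fixtures: a fast low-resolution dive for unit tests. All fixtures
# are generated in code; nothing binary ships with the package.

tiny_camera <- function(width = 32) synth_camera(width_px = width,
                                                 height_px = width)

# a short two-line survey: 10 s descent from 12.5 m, 20 s cruise, 10 s ascent
tiny_scenario <- function(seed = 1, ...) {
  args <- list(track_length_m = 15, n_lines = 2, start_altitude_m = 12.5,
               clock_offset_ms = 1500, outlier_fraction = 0.05,
               gap_fraction = 0.05, black_frame_prob = 0.05, seed = seed)
  do.call(dive_scenario, utils::modifyList(args, list(...)))
}

tiny_dive <- function(seed = 1, ...) {
  generate_dive(tiny_scenario(seed = seed, ...), camera = tiny_camera())
}

# expected single verdict per frame from generator ground truth, using the
# same precedence as the QC report (condensation > black > dark > altitude)
truth_verdicts <- function(truth_frames, darkness_threshold) {
  ifelse(truth_frames$condensation, "condensation_excluded",
  ifelse(truth_frames$black, "black_frame",
  ifelse(truth_frames$mean_gray < darkness_threshold, "dark_filtered",
  ifelse(truth_frames$altitude_m > 10, "altitude_filtered", "keep"))))
}

# a fully populated, in-range metadata record
clean_record <- function(...) {
  utils::modifyList(list(
    SUB_datetime = "20150407 17:50:01.250", SUB_latitude = -7.07,
    SUB_longitude = -88.45, SUB_distance = 7.5, SUB_heading = 90,
    SUB_forwardvelocity = 1.5, SUB_yawangle = 90, SUB_pitchangle = 0.5,
    SUB_rollangle = -0.3, ENV_temperaturewater = 1.5,
    quality_flag = "raw"), list(...))
}

# per-row centroid of a dark line, using a line-free rendering of the same
# scene as background so vignetting gradients cannot bias the estimate
line_centroids <- function(px, bg_px, mask = NULL) {
  w <- ncol(px)
  sapply(seq_len(nrow(px)), function(i) {
    wgt <- pmax(bg_px[i, ] - px[i, ], 0)
    if (!is.null(mask)) wgt <- wgt * mask[i, ]
    if (sum(wgt) < 1) return(NA_real_)
    sum((0:(w - 1)) * wgt) / sum(wgt)
  })
}

line_fit_rms <- function(cent) {
  ok <- is.finite(cent)
  fit <- stats::lm(cent[ok] ~ seq_along(cent)[ok])
  sqrt(mean(stats::resid(fit)^2))
}

random_identifier <- function() {
  image_identifier(
    cruise = paste0("SO", sample(100:999, 1)),
    station = as.character(sample(1:999, 1)),
    camera_id = paste0("AUV", sample(1:99, 1)),
    date = as.Date("2015-01-01") + sample(0:3000, 1),
    time = sample(0:86399, 1),
    index = sample(0:99999, 1),
    index_width = sample(4:6, 1))
}
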