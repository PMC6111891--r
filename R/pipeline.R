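## End-to-end curation pipeline: read -> validate -> sync -> metadata QC ->
## merge -> image QC -> undistort -> fuse -> organize, with a curation-log
## entry per stage and a summary report of per-stage input/output counts.

#' Read a directory of survey images
#'
#' @param dir Directory of JPEG frames named by the naming scheme.
#' @param times Optional camera-log data frame `name`/`t_ms` assigning
#'   millisecond acquisition times (file names carry seconds only).
#' @param dialect Naming dialect for [parse_image_name()].
#' @return Named list of [fisheye_frame()]s (names = file-name stems).
#' @export
read_image_dir <- function(dir, times = NULL, dialect = "underscore") {
  files <- sort(list.files(dir, pattern = "\\.(jpe?g)$", ignore.case = TRUE))
  if (!length(files)) stop("no JPEG images found in ", dir, call. = FALSE)
  frames <- list()
  for (f in files) {
    id <- parse_image_name(f, dialect = dialect)  # validates the name
    px <- jpeg::readJPEG(file.path(dir, f))
    if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
    stem <- sub("\\.[A-Za-z0-9]+$", "", f)
    t_ms <- if (!is.null(times) && stem %in% times$name)
      times$t_ms[match(stem, times$name)]
    else (as.numeric(as.POSIXct(id$date, tz = "UTC")) + id$time) * 1000
    frames[[stem]] <- fisheye_frame(px * 255, timestamp_ms = t_ms,
                                    metadata = list(identifier = id))
  }
  frames
}

#' Validate a pipeline configuration
#'
#' The configuration mirrors the schema tags plus pipeline thresholds.
#' Thresholds that must be chosen per survey — notably the darkness
#' threshold — are mandatory keys with no silent default.
#'
#' @param config Named list, or path to a YAML file.
#' @return The normalized config list (invisibly validated).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- function(key, sub = NULL) {
    v <- if (is.null(sub)) config[[key]] else config[[key]][[sub]]
    if (is.null(v))
      stop("pipeline config is missing mandatory key '",
           paste(c(key, sub), collapse = "$"), "'", call. = FALSE)
    v
  }
  need("input")
  need("input", "dir")
  need("output")
  need("output", "dir")
  need("thresholds")
  need("thresholds", "darkness_min_mean_gray")
  cam <- need("camera")
  if (!dir.exists(config$input$dir))
    stop("input directory ", config$input$dir, " does not exist",
         call. = FALSE)
  config$camera <- synth_camera(
    width_px = cam$width_px %||% 48,
    height_px = cam$height_px %||% cam$width_px %||% 48,
    focal_mm = cam$focal_mm %||% 15,
    edge_theta_deg = cam$edge_theta_deg %||% 65,
    CAM_id = cam$CAM_id %||% "AUV9")
  th <- config$thresholds
  config$thresholds <- list(
    darkness_min_mean_gray = th$darkness_min_mean_gray,
    max_altitude_m = th$max_altitude_m %||% 10,
    black_tol = th$black_tol %||% 1,
    outlier_threshold = th$outlier_threshold %||% 3.5)
  sy <- config$sync %||% list()
  config$sync <- list(window_ms = sy$window_ms %||% 60000,
                      step_ms = sy$step_ms %||% 100,
                      altitude_ceiling_m = sy$altitude_ceiling_m %||% 15)
  config$exclude_windows <- config$exclude_windows %||% list()
  config$organize <- config$organize %||% list()
  config$organize$split <- config$organize$split %||% "half_hour"
  config$organize$dive <- config$organize$dive %||% "dive"
  config$authorship <- config$authorship %||%
    list(artist = "unknown", copyright = "unknown")
  config$undistort <- config$undistort %||% list()
  config$undistort$hfov_deg <- config$undistort$hfov_deg %||% 90
  config
}

#' Run the full curation pipeline
#'
#' Executes the stages in fixed order — read, validate, clock sync,
#' metadata QC, stream merge, image QC, un-distortion, EXIF/sidecar
#' fusion, folder organization — appending one curation-log entry per
#' stage. Any stage failure aborts with the log flushed through the
#' failing entry.
#'
#' The input directory must contain `raw/` (JPEG frames named by the
#' naming scheme), `nav.tsv` and optionally `env.tsv` (tab-separated
#' schema tables) and `images.tsv` (camera log with millisecond
#' acquisition times) — the layout produced by [write_synthetic_dive()].
#'
#' @param config Config list or YAML path (see [validate_config()]).
#' @return A `pipeline_report`: per-stage counts, the offset estimate,
#'   the QC report, folder plan and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  log <- curation_log()
  out_dir <- cfg$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "curation_log.jsonl")
  on.exit(write_curation_log(log, log_path))
  counts <- list()

  ## read
  times <- if (file.exists(file.path(cfg$input$dir, "images.tsv")))
    read_metadata_table(file.path(cfg$input$dir, "images.tsv"))
  frames <- read_image_dir(file.path(cfg$input$dir, "raw"), times = times)
  nav <- read_metadata_table(file.path(cfg$input$dir, "nav.tsv"))
  env_path <- file.path(cfg$input$dir, "env.tsv")
  env <- if (file.exists(env_path)) read_metadata_table(env_path) else NULL
  counts$read <- c(images = length(frames), nav_rows = nrow(nav),
                   env_rows = if (is.null(env)) 0L else nrow(env))
  log_append(log, "read", list(input = cfg$input$dir),
             n_in = NA, n_out = length(frames))

  ## validate
  violations <- validate_records(nav)
  counts$validate <- c(violations = nrow(violations))
  log_append(log, "validate", list(), n_in = nrow(nav),
             n_out = nrow(nav) - length(unique(violations$row)))

  ## clock sync
  bright <- brightness_series(frames)
  est <- estimate_offset(bright, nav, window_ms = cfg$sync$window_ms,
                         step_ms = cfg$sync$step_ms,
                         altitude_ceiling_m = cfg$sync$altitude_ceiling_m)
  t_corr <- vapply(frames, function(f) f$timestamp_ms, numeric(1)) -
    est$offset_ms
  counts$sync <- c(offset_ms = est$offset_ms)
  log_append(log, "estimate_offset",
             list(offset_ms = est$offset_ms, score = est$score,
                  window_ms = cfg$sync$window_ms,
                  step_ms = cfg$sync$step_ms),
             n_in = length(frames), n_out = length(frames))

  ## metadata QC
  qcm <- qc_metadata_table(nav, threshold = cfg$thresholds$outlier_threshold,
                           log = log)
  nav <- qcm$records
  counts$metadata_qc <- c(outliers = sum(qcm$outliers),
                          gaps = sum(qcm$gaps))

  ## merge
  streams <- list(nav = nav)
  if (!is.null(env)) streams$env <- env
  fused <- merge_streams(streams, log = log)
  counts$merge <- c(rows = nrow(fused))

  ## image QC
  at_img <- interpolate_metadata(fused, t_corr)
  rep <- qc_report(frames)
  rep <- altitude_filter(rep, at_img$SUB_distance,
                         max_altitude_m = cfg$thresholds$max_altitude_m,
                         log = log)
  rep <- darkness_filter(rep, cfg$thresholds$darkness_min_mean_gray,
                         black_tol = cfg$thresholds$black_tol, log = log)
  if (length(cfg$exclude_windows))
    rep <- exclude_subsequences(rep, lapply(cfg$exclude_windows, as.numeric),
                                log = log)
  verdicts <- stats::setNames(verdict(rep), names(frames))
  keep <- verdicts == "keep"
  counts$image_qc <- summary(rep)

  ## undistort kept frames
  proc_dir <- file.path(out_dir, "processed")
  dir.create(proc_dir, showWarnings = FALSE)
  raw_model <- camera_ray_model(cfg$camera)
  kept_names <- names(frames)[keep]
  for (nm in kept_names) {
    rf <- undistort(frames[[nm]], raw_model,
                    out_hfov_deg = cfg$undistort$hfov_deg)
    jpeg::writeJPEG(clamp(rf$pixels, 0, 255) / 255,
                    file.path(proc_dir, paste0(nm, ".jpg")), quality = 0.95)
  }
  log_append(log, "undistort",
             list(hfov_deg = cfg$undistort$hfov_deg),
             n_in = length(frames), n_out = length(kept_names))
  counts$undistort <- c(written = length(kept_names))

  ## fuse metadata (EXIF + sidecar)
  kept_records <- at_img[keep, , drop = FALSE]
  for (i in seq_along(kept_names))
    fuse_exif(file.path(proc_dir, paste0(kept_names[i], ".jpg")),
              kept_records[i, , drop = FALSE], cfg$authorship)
  log_append(log, "fuse_exif", list(authorship = cfg$authorship),
             n_in = length(kept_names), n_out = length(kept_names))
  write_sidecar(paste0(kept_names, ".jpg"), kept_records,
                file.path(out_dir, "sidecar.tsv"))
  counts$fuse <- c(fused = length(kept_names))

  ## organize
  plan <- organize_folders(paste0(kept_names, ".jpg"),
                           t_corr[keep], split = cfg$organize$split,
                           dive = cfg$organize$dive,
                           max_count = cfg$organize$max_count %||% 999L,
                           log = log)
  apply_folder_plan(plan, proc_dir, file.path(out_dir, "curated"),
                    action = "move")
  unlink(proc_dir, recursive = TRUE)
  counts$organize <- c(folders = length(unique(plan$folder)))

  report <- structure(list(counts = counts, offset = est, qc = rep,
                           verdicts = verdicts, folder_plan = plan,
                           violations = violations,
                           output = out_dir, log = log,
                           config = cfg),
                      class = "pipeline_report")
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  images read: %d; nav rows: %d\n",
              x$counts$read[["images"]], x$counts$read[["nav_rows"]]))
  cat(sprintf("  estimated clock offset: %g ms (r = %.3f)\n",
              x$offset$offset_ms, x$offset$score))
  cat(sprintf("  metadata: %d outliers repaired, %d gaps filled\n",
              x$counts$metadata_qc[["outliers"]],
              x$counts$metadata_qc[["gaps"]]))
  s <- x$counts$image_qc
  cat("  image QC:", paste(names(s)[s > 0], s[s > 0], sep = "=",
                           collapse = ", "), "\n")
  cat(sprintf("  curated output: %s (%d folders)\n", x$output,
              x$counts$organize[["folders"]]))
  invisible(x)
}

#' Curation bookkeeping arithmetic
#'
#' Totals removed and remaining images over per-cruise removal counts —
#' the audit a curation protocol must support ("how many images did QC
#' remove, how many are published?").
#'
#' @param acquired_total Total images acquired over all cruises.
#' @param removed_by_cruise Named numeric vector of per-cruise removals.
#' @return List with `removed_total`, `remaining`, `removed_by_cruise`.
#' @examples
#' curation_summary(1000, c(A = 100, B = 50))
#' @export
curation_summary <- function(acquired_total, removed_by_cruise) {
  stopifnot(acquired_total >= 0, all(removed_by_cruise >= 0))
  removed <- sum(removed_by_cruise)
  if (removed > acquired_total)
    stop("more images removed than acquired", call. = FALSE)
  list(removed_total = removed,
       remaining = acquired_total - removed,
       removed_by_cruise = removed_by_cruise)
}

#' Published per-cruise image counts of the reference AUV surveys
#'
#' Acquisition and curation-removal counts of the two deep-sea AUV
#' photo-survey cruises (SO239, SO242/1) shipped with the package as a
#' worked bookkeeping example.
#'
#' @return Data frame `key` / `value`.
#' @export
cruise_image_counts <- function() {
  utils::read.delim(system.file("extdata", "cruise_image_counts.tsv",
                                package = "divecurate", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
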