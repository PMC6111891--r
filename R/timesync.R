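## Camera-versus-navigation clock synchronization.
##
## Imagery and telemetry are recorded by separate systems on separate
## clocks. Because the strobe is the only light source, image brightness
## anti-correlates with altitude; the static offset between the two clocks
## is found by grid-searching the time shift that makes the brightness
## series maximally negatively correlated with the altitude series.

#' Mean gray value of the main image diagonal
#'
#' The brightness proxy used for clock synchronization: the mean gray
#' value over `min(width, height)` pixels spaced along the main diagonal
#' (top-left to bottom-right). Color arrays are converted to gray as the
#' channel mean first. Cheap enough to run over hundreds of thousands of
#' frames.
#'
#' @param frame A [fisheye_frame()], a numeric matrix, or a 3-d array
#'   (height x width x channels).
#' @return Scalar mean gray value.
#' @examples
#' diagonal_brightness(matrix(128, 8, 8))
#' @export
diagonal_brightness <- function(frame) {
  px <- if (inherits(frame, "fisheye_frame")) frame$pixels else frame
  if (is.array(px) && length(dim(px)) == 3L)
    px <- apply(px, c(1, 2), mean)
  stopifnot(is.matrix(px), length(px) > 0)
  n <- min(dim(px))
  i <- round(seq(1, nrow(px), length.out = n))
  j <- round(seq(1, ncol(px), length.out = n))
  mean(px[cbind(i, j)])
}

#' Build a brightness series from frames
#'
#' @param frames List of [fisheye_frame()]s with timestamps.
#' @return Data frame `t_ms`, `brightness`, sorted by time.
#' @export
brightness_series <- function(frames) {
  out <- data.frame(
    t_ms = vapply(frames, function(f) f$timestamp_ms, numeric(1)),
    brightness = vapply(frames, diagonal_brightness, numeric(1)))
  out <- out[order(out$t_ms), , drop = FALSE]
  if (anyDuplicated(out$t_ms))
    stop("brightness series has duplicate timestamps", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Estimate the camera-minus-navigation clock offset
#'
#' Grid search over candidate offsets in `[-window_ms, +window_ms]` at
#' `step_ms` resolution: for each candidate the altitude series is
#' linearly interpolated to the shifted image times and the Pearson
#' correlation with image brightness computed; the estimate is the offset
#' with the most negative correlation (bright images belong to low
#' altitudes). Altitude samples outside `[0, altitude_ceiling_m]` are
#' discarded before correlating — water-column images carry no brightness
#' signal and physically impossible values (spikes) would distort the
#' score.
#'
#' By default both series are log-transformed before correlating: strobe
#' illumination follows an inverse-square law, so log-brightness is linear
#' in log-altitude and the Pearson score is unbiased by the curvature of
#' the brightness/altitude relation (which otherwise skews the optimum
#' across steep descent legs). `transform = "none"` correlates the raw
#' series.
#'
#' @param brightness Data frame `t_ms`/`brightness` (camera clock), e.g.
#'   from [brightness_series()].
#' @param altitude Data frame `t_ms`/`altitude_m` (navigation clock), or a
#'   schema table with `t_ms` and `SUB_distance`.
#' @param window_ms Half-width of the searched offset window (default
#'   60000: observed offsets range from tens of milliseconds to tens of
#'   seconds).
#' @param step_ms Search grid step (default 100).
#' @param altitude_ceiling_m Cruise-phase ceiling (default 15 m).
#' @param min_brightness Brightness samples at or below this are dropped
#'   (default 1 gray level): all-black frames — flash misfires — carry no
#'   illumination signal and would act as gross outliers.
#' @param min_overlap Minimum number of usable sample pairs per candidate.
#' @param transform `"log"` (default) or `"none"`; see Details.
#' @return An object of class `offset_estimate`: `offset_ms`, `score`
#'   (Pearson r at the optimum), and the full `profile` data frame.
#' @export
estimate_offset <- function(brightness, altitude, window_ms = 60000,
                            step_ms = 100, altitude_ceiling_m = 15,
                            min_brightness = 1, min_overlap = 10,
                            transform = c("log", "none")) {
  transform <- match.arg(transform)
  if ("SUB_distance" %in% names(altitude))
    altitude <- data.frame(t_ms = altitude$t_ms,
                           altitude_m = altitude$SUB_distance)
  stopifnot(all(c("t_ms", "brightness") %in% names(brightness)),
            all(c("t_ms", "altitude_m") %in% names(altitude)),
            window_ms > 0, step_ms > 0)
  alt <- altitude[is.finite(altitude$t_ms) & is.finite(altitude$altitude_m), ]
  alt <- alt[alt$altitude_m >= 0 & alt$altitude_m <= altitude_ceiling_m, ]
  b <- brightness[is.finite(brightness$t_ms) &
                    is.finite(brightness$brightness) &
                    brightness$brightness > min_brightness, ]
  if (nrow(alt) < min_overlap || nrow(b) < min_overlap)
    stop("insufficient overlapping samples for offset estimation",
         call. = FALSE)
  if (stats::sd(b$brightness) == 0)
    stop("brightness series is constant; correlation undefined",
         call. = FALSE)
  if (stats::sd(alt$altitude_m) == 0)
    stop("altitude series is constant; correlation undefined", call. = FALSE)

  y <- if (transform == "log") log(b$brightness) else b$brightness
  offsets <- seq(-window_ms, window_ms, by = step_ms)
  scores <- rep(NA_real_, length(offsets))
  for (k in seq_along(offsets)) {
    tt <- b$t_ms - offsets[k]
    a <- stats::approx(alt$t_ms, alt$altitude_m, xout = tt,
                       method = "linear", rule = 1, ties = "ordered")$y
    use <- is.finite(a) & a <= altitude_ceiling_m & a > 0
    if (sum(use) < min_overlap) next
    av <- if (transform == "log") log(a[use]) else a[use]
    if (stats::sd(av) == 0 || stats::sd(y[use]) == 0) next
    scores[k] <- stats::cor(y[use], av)
  }
  if (all(is.na(scores)))
    stop("insufficient overlapping samples at every candidate offset",
         call. = FALSE)
  best <- which.min(scores)
  structure(list(offset_ms = offsets[best], score = scores[best],
                 profile = data.frame(offset_ms = offsets, score = scores),
                 step_ms = step_ms, window_ms = window_ms),
            class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf(
    "<offset_estimate> %g ms (anti-correlation r = %.3f, window +-%g ms, step %g ms)\n",
    x$offset_ms, x$score, x$window_ms, x$step_ms))
  invisible(x)
}

#' @export
plot.offset_estimate <- function(x, ...) {
  plot(x$profile$offset_ms / 1000, x$profile$score, type = "l",
       xlab = "candidate offset [s]", ylab = "Pearson r",
       main = "brightness-altitude cross-anti-correlation", ...)
  graphics::abline(v = x$offset_ms / 1000, lty = 2)
  invisible(x)
}

#' Interpolate metadata records to image acquisition times
#'
#' Linear interpolation of every numeric field to millisecond target
#' times; heading-like fields are interpolated on the circle (shortest
#' arc). Targets outside the record span are returned with all fields
#' missing (no extrapolation). Targets coinciding exactly with a record
#' time copy that record and keep its flag; all interpolated rows are
#' flagged `interpolated`.
#'
#' @param records Schema table with `t_ms` (sorted, no duplicates).
#' @param target_ms Numeric target times (epoch ms).
#' @param circular_fields Fields interpolated on the circle (degrees).
#' @return Data frame with one row per target, `t_ms` set to the target
#'   times and `quality_flag` updated.
#' @examples
#' recs <- data.frame(t_ms = c(1000, 2000), SUB_distance = c(10, 12),
#'                    quality_flag = "raw")
#' interpolate_metadata(recs, 1500)$SUB_distance  # 11
#' @export
interpolate_metadata <- function(records, target_ms,
                                 circular_fields = c("SUB_heading",
                                                     "SUB_yawangle")) {
  stopifnot("t_ms" %in% names(records), nrow(records) >= 1)
  if (is.unsorted(records$t_ms)) records <- records[order(records$t_ms), ]
  if (anyDuplicated(records$t_ms))
    stop("records have duplicate timestamps", call. = FALSE)
  t <- records$t_ms
  inside <- target_ms >= t[1] & target_ms <= t[length(t)]
  exact_idx <- match(target_ms, t)

  numfields <- names(records)[vapply(records, is.numeric, logical(1))]
  numfields <- setdiff(numfields, "t_ms")
  out <- data.frame(t_ms = target_ms)
  for (f in numfields) {
    y <- records[[f]]
    ok <- is.finite(y)
    vals <- rep(NA_real_, length(target_ms))
    if (sum(ok) >= 2) {
      if (f %in% circular_fields) {
        # unwrap, interpolate, wrap: linear on the shortest arc as long as
        # successive samples differ by < 180 degrees
        yu <- y[ok]
        yu <- c(yu[1], yu[1] + cumsum(((diff(yu) + 180) %% 360) - 180))
        vals <- stats::approx(t[ok], yu, xout = target_ms, rule = 1,
                              ties = "ordered")$y %% 360
      } else {
        vals <- stats::approx(t[ok], y[ok], xout = target_ms, rule = 1,
                              ties = "ordered")$y
      }
    } else if (sum(ok) == 1) {
      vals[target_ms == t[ok]] <- y[ok]
    }
    out[[f]] <- vals
  }
  if ("SUB_datetime" %in% names(records))
    out$SUB_datetime <- ms_to_subtime(target_ms)
  flags <- ifelse(!inside, "missing", "interpolated")
  if ("quality_flag" %in% names(records)) {
    hit <- !is.na(exact_idx)
    flags[hit] <- records$quality_flag[exact_idx[hit]]
  }
  out$quality_flag <- flags
  out[!inside, numfields] <- NA_real_
  rownames(out) <- NULL
  out
}
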