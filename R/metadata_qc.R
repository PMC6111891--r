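## Quality control of navigation/environment telemetry: robust outlier
## detection, reconstruction of missing values, merging of multi-sensor
## streams by timecode, and provenance-logged smoothing.

#' Detect outliers in a metadata series
#'
#' A sample is an outlier if its modified z-score — `0.6745 * |x - med| /
#' MAD`, the median/MAD analogue of the z-score, robust on spiky
#' navigation data — exceeds `threshold`, or if it violates the field's
#' physical range ([field_range()]) regardless of spread. With a
#' degenerate MAD of zero (majority-constant series) any deviating sample
#' is flagged.
#'
#' For strongly trending series (altitude across a descent) apply the
#' detector to residuals from a running median rather than raw values;
#' [qc_metadata_table()] does exactly that.
#'
#' @param x Numeric series (`NA` = missing, never flagged).
#' @param field Optional schema tag enabling the physical-range rule.
#' @param threshold Modified z-score threshold (default 3.5).
#' @return Logical mask, `TRUE` where outlying.
#' @examples
#' detect_outliers(c(1, 1, 1, 50, 1, 1))
#' @export
detect_outliers <- function(x, field = NULL, threshold = 3.5) {
  ok <- is.finite(x)
  if (sum(ok) < 5)
    stop("need at least 5 valid samples for outlier detection", call. = FALSE)
  med <- stats::median(x[ok])
  dev <- abs(x - med)
  mad <- stats::median(dev[ok]) * 1.4826
  mask <- rep(FALSE, length(x))
  if (mad > 0) {
    mask[ok] <- 0.6745 * dev[ok] / (mad / 1.4826) > threshold
  } else {
    tol <- .Machine$double.eps^0.5 * max(1, abs(med))
    mask[ok] <- dev[ok] > tol
  }
  if (!is.null(field)) {
    rng <- field_range(field)
    hi_ok <- if (identical(field, "SUB_heading")) x < rng[2] else x <= rng[2]
    mask[ok] <- mask[ok] | (x[ok] < rng[1] | !hi_ok[ok])
  }
  mask
}

#' Reconstruct missing values in a series
#'
#' Interior missing positions are replaced by cubic-spline (default) or
#' linear interpolation through the valid anchor points; anchors are left
#' untouched and leading/trailing gaps remain missing — navigation is
#' never extrapolated. Spline end conditions follow Forsythe-Malcolm-Moler
#' (exact cubic through the four end points), so an exactly cubic series
#' is reconstructed to machine precision.
#'
#' @param x Numeric series with `NA` gaps.
#' @param t Sample positions (default equispaced).
#' @param method `"spline"` or `"linear"`.
#' @return List with `values` (filled series) and `filled` (logical mask
#'   of reconstructed positions).
#' @examples
#' fill_gaps(c(1, 2, NA, 4, 5))$values
#' @export
fill_gaps <- function(x, t = seq_along(x), method = c("spline", "linear")) {
  method <- match.arg(method)
  ok <- is.finite(x)
  if (!any(ok)) stop("all values missing; nothing to anchor on", call. = FALSE)
  need_anchors <- if (method == "spline") 4L else 2L
  if (sum(ok) < need_anchors)
    stop("need at least ", need_anchors, " valid anchor points for ",
         method, " interpolation", call. = FALSE)
  fill <- !ok & t >= min(t[ok]) & t <= max(t[ok])
  out <- x
  if (any(fill)) {
    out[fill] <- if (method == "spline")
      stats::spline(t[ok], x[ok], xout = t[fill], method = "fmm")$y
    else
      stats::approx(t[ok], x[ok], xout = t[fill], ties = "ordered")$y
  }
  list(values = out, filled = fill)
}

#' Merge multi-sensor metadata streams by timecode
#'
#' Produces one record per master-clock timestamp (the navigation stream:
#' images are later matched against fused navigation). Fields from other
#' streams are taken from the nearest sample within `tolerance_ms`,
#' otherwise linearly interpolated; targets outside a stream's span stay
#' missing. Cell provenance counts (matched / interpolated / missing per
#' stream) are appended to the curation log.
#'
#' @param streams Named list of data frames, each with `t_ms`; the first
#'   is the master. Non-master field sets should not overlap the master's.
#' @param tolerance_ms Exact-match tolerance (default 100).
#' @param log Optional [curation_log()].
#' @return Unified data frame on the master time base.
#' @export
merge_streams <- function(streams, tolerance_ms = 100, log = NULL) {
  stopifnot(is.list(streams), length(streams) >= 1,
            all(vapply(streams, function(s) "t_ms" %in% names(s),
                       logical(1))))
  for (nm in names(streams)) {
    tt <- streams[[nm]]$t_ms
    if (is.unsorted(tt)) stop("stream '", nm, "' is not time-sorted",
                              call. = FALSE)
    if (anyDuplicated(tt)) stop("stream '", nm,
                                "' has duplicate timestamps", call. = FALSE)
  }
  master <- streams[[1L]]
  out <- master
  provenance <- list()
  for (nm in names(streams)[-1L]) {
    st <- streams[[nm]]
    fields <- setdiff(names(st),
                      c("t_ms", "SUB_datetime", "quality_flag"))
    fields <- fields[vapply(st[fields], is.numeric, logical(1))]
    if (nrow(st) == 0L) {
      for (f in fields) out[[f]] <- NA_real_
      provenance[[nm]] <- list(matched = 0, interpolated = 0,
                               missing = nrow(out) * length(fields))
      next
    }
    # nearest sample per master timestamp
    idx <- findInterval(out$t_ms, st$t_ms, all.inside = FALSE)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, nrow(st))
    d_lo <- abs(out$t_ms - st$t_ms[lo])
    d_hi <- abs(st$t_ms[hi] - out$t_ms)
    nearest <- ifelse(d_hi < d_lo, hi, lo)
    d_near <- pmin(d_lo, d_hi)
    matched <- d_near <= tolerance_ms
    inside <- out$t_ms >= st$t_ms[1] & out$t_ms <= st$t_ms[nrow(st)]
    n_m <- 0L; n_i <- 0L; n_x <- 0L
    for (f in fields) {
      vals <- rep(NA_real_, nrow(out))
      vals[matched] <- st[[f]][nearest[matched]]
      interp <- !matched & inside
      if (any(interp) && sum(is.finite(st[[f]])) >= 2) {
        okk <- is.finite(st[[f]])
        vals[interp] <- stats::approx(st$t_ms[okk], st[[f]][okk],
                                      xout = out$t_ms[interp],
                                      rule = 1, ties = "ordered")$y
      }
      out[[f]] <- vals
      n_m <- n_m + sum(matched & is.finite(vals))
      n_i <- n_i + sum(interp & is.finite(vals))
      n_x <- n_x + sum(!is.finite(vals))
    }
    provenance[[nm]] <- list(matched = n_m, interpolated = n_i,
                             missing = n_x)
  }
  if (!is.null(log))
    log_append(log, "merge_streams",
               list(tolerance_ms = tolerance_ms, master = names(streams)[1],
                    provenance = provenance),
               n_in = sum(vapply(streams, nrow, integer(1))),
               n_out = nrow(out))
  out
}

#' Smooth a metadata series (with provenance)
#'
#' Moving-average or smoothing-spline noise reduction. The method and its
#' parameters are appended to the curation log: a published dive protocol
#' must record any smoothing applied.
#'
#' @param x Numeric series.
#' @param method `"moving_average"` or `"spline"`.
#' @param window Moving-average window (odd, default 5).
#' @param spar Smoothing-spline parameter (see [stats::smooth.spline()]).
#' @param log Optional [curation_log()].
#' @return Smoothed numeric series.
#' @export
smooth_series <- function(x, method = c("moving_average", "spline"),
                          window = 5L, spar = NULL, log = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), length(x) >= 1)
  if (method == "moving_average") {
    window <- as.integer(window)
    if (window > length(x))
      stop("smoothing window (", window, ") larger than series (",
           length(x), ")", call. = FALSE)
    if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
    out <- if (window == 1L) x else {
      sm <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
      # shrink the window near the edges instead of dropping samples
      half <- window %/% 2L
      for (i in seq_len(half)) {
        sm[i] <- mean(x[1:(i + half)])
        sm[length(x) - i + 1L] <- mean(x[(length(x) - i + 1L - half):length(x)])
      }
      sm
    }
  } else {
    fit <- stats::smooth.spline(seq_along(x), x, spar = spar)
    out <- stats::predict(fit, seq_along(x))$y
  }
  if (!is.null(log))
    log_append(log, "smooth_series",
               list(method = method, window = if (method == "moving_average")
                 window else NULL, spar = spar),
               n_in = length(x), n_out = length(out))
  out
}

#' Quality-control a metadata table
#'
#' Pipeline wrapper: for each numeric schema field, detects spikes as
#' modified-z-score outliers of the residual from a running median
#' (robust to descent/ascent trends), blanks them, reconstructs all
#' interior gaps by spline interpolation, and flags repaired rows
#' `interpolated` / spiked rows that could not be repaired `outlier`.
#'
#' A spike must also exceed the field's `spike_floor` — an absolute
#' deviation below which navigation noise is plausible (default: ~11 m in
#' position, 0.75 m in altitude, 20 degrees in heading). Without the
#' floor, exactly-linear track segments give a degenerate (near-zero)
#' residual spread and benign corner samples would be flagged.
#'
#' @param records Schema table with `t_ms`.
#' @param fields Fields to QC (default: position, altitude, heading).
#' @param threshold Modified z-score threshold.
#' @param spike_floor Named minimum absolute residual per field.
#' @param log Optional [curation_log()].
#' @return List: `records` (repaired table), `outliers` and `gaps`
#'   (logical row x field masks of what was repaired).
#' @export
qc_metadata_table <- function(records,
                              fields = c("SUB_distance", "SUB_latitude",
                                         "SUB_longitude", "SUB_heading"),
                              threshold = 3.5,
                              spike_floor = c(SUB_distance = 0.75,
                                              SUB_latitude = 1e-4,
                                              SUB_longitude = 1e-4,
                                              SUB_heading = 20),
                              log = NULL) {
  stopifnot("t_ms" %in% names(records))
  fields <- intersect(fields, names(records))
  outliers <- matrix(FALSE, nrow(records), length(fields),
                     dimnames = list(NULL, fields))
  gaps <- outliers
  for (f in fields) {
    x <- records[[f]]
    gaps[, f] <- !is.finite(x)
    ok <- is.finite(x)
    if (sum(ok) >= 7) {
      ref <- x
      ref[ok] <- stats::runmed(x[ok], k = 5, endrule = "median")
      resid <- x - ref
      spikes <- rep(FALSE, length(x))
      spikes[ok] <- detect_outliers(resid[ok], threshold = threshold)
      floor_f <- if (f %in% names(spike_floor)) spike_floor[[f]] else 0
      spikes <- spikes & abs(resid) > floor_f
      # physical-range violations are outliers regardless of spread
      rng <- field_range(f)
      hi_ok <- if (identical(f, "SUB_heading")) x < rng[2] else x <= rng[2]
      spikes[ok] <- spikes[ok] | x[ok] < rng[1] | !hi_ok[ok]
      outliers[, f] <- spikes
      x[spikes] <- NA_real_
    }
    filled <- fill_gaps(x, t = records$t_ms, method = "spline")
    records[[f]] <- filled$values
    repaired <- filled$filled
    records$quality_flag[repaired] <- "interpolated"
    records$quality_flag[!is.finite(filled$values) &
                           (gaps[, f] | outliers[, f])] <- "missing"
  }
  if (!is.null(log))
    log_append(log, "qc_metadata_table",
               list(fields = fields, threshold = threshold,
                    n_outliers = sum(outliers), n_gaps = sum(gaps)),
               n_in = nrow(records), n_out = nrow(records))
  list(records = records, outliers = outliers, gaps = gaps)
}
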