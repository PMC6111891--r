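## Metadata schema, image naming scheme and record validation.
##
## Field tags follow the marine-imaging convention of lowercase, blank-free
## names with a prefix for the carrier: SUB_ (submersible platform state),
## CAM_ (camera), ENV_ (environment), REF_ (scale reference). Lengths are
## millimeters, positions decimal degrees (WGS84), angles decimal degrees,
## timestamps UTC with millisecond precision.

SUB_TIMESTAMP_FORMAT <- "^\\d{8} \\d{2}:\\d{2}:\\d{2}\\.\\d{3}$"

# numeric per-row fields of the platform/environment record, with physical
# ranges used both by validate_record() and by the outlier range rule
SCHEMA_RANGES <- list(
  SUB_latitude        = c(-90, 90),
  SUB_longitude       = c(-180, 180),
  SUB_heading         = c(0, 360),     # half-open: 360 itself is invalid
  SUB_distance        = c(0, Inf),
  SUB_forwardvelocity = c(-Inf, Inf),
  SUB_yawangle        = c(-360, 360),
  SUB_pitchangle      = c(-90, 90),
  SUB_rollangle       = c(-180, 180),
  ENV_temperaturewater = c(-5, 50),
  ENV_absorption      = c(0, Inf),
  ENV_scattering      = c(0, Inf),
  ENV_refractiveindex = c(1, 2),
  REF_laserdistances  = c(0, Inf)
)

RECORD_FIELDS <- c("SUB_datetime", names(SCHEMA_RANGES))

QUALITY_FLAGS <- c("raw", "interpolated", "smoothed", "outlier", "missing")

#' Physical range of a metadata field
#'
#' @param field Schema tag, e.g. `"SUB_latitude"`.
#' @return Numeric `c(min, max)`, or `c(-Inf, Inf)` for unconstrained fields.
#' @export
field_range <- function(field) {
  SCHEMA_RANGES[[field]] %||% c(-Inf, Inf)
}

#' Schema field names
#'
#' The per-row metadata tags understood by the pipeline.
#' @return Character vector of tags.
#' @export
record_fields <- function() RECORD_FIELDS

## ---- timestamp handling --------------------------------------------------

#' Convert between schema timestamps and epoch milliseconds
#'
#' Schema timestamps are UTC strings `"YYYYMMDD hh:mm:ss.sss"`. Internally
#' the pipeline works in integer-valued milliseconds since the Unix epoch
#' (stored as doubles, exact far beyond any cruise date).
#'
#' @param x Character vector of timestamps (`subtime_to_ms`) or numeric
#'   epoch milliseconds (`ms_to_subtime`).
#' @return Numeric milliseconds, or character timestamps. Unparseable
#'   strings yield `NA`.
#' @examples
#' ms_to_subtime(subtime_to_ms("20150407 17:50:01.250"))
#' @export
subtime_to_ms <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & grepl(SUB_TIMESTAMP_FORMAT, x)
  if (any(ok)) {
    base <- strptime(substr(x[ok], 1L, 17L), "%Y%m%d %H:%M:%S", tz = "UTC")
    frac <- as.numeric(substr(x[ok], 19L, 21L))
    out[ok] <- round(as.numeric(base) * 1000) + frac
  }
  out
}

#' @rdname subtime_to_ms
#' @export
ms_to_subtime <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- is.finite(x)
  if (any(ok)) {
    ms <- round(x[ok])
    secs <- floor(ms / 1000)
    frac <- ms - secs * 1000
    base <- as.POSIXct(secs, origin = "1970-01-01", tz = "UTC")
    out[ok] <- paste0(format(base, "%Y%m%d %H:%M:%S", tz = "UTC"),
                      sprintf(".%03d", frac))
  }
  out
}

## ---- image naming scheme -------------------------------------------------

#' Image identifiers
#'
#' Survey images carry a machine-readable name encoding cruise, station,
#' camera, UTC acquisition date/time (seconds resolution) and a running
#' index — only numbers, characters, dashes and underscores. Two dialects
#' are supported: `"underscore"` (default; components joined by `_` with an
#' `IMG` infix before the index, as used on real AUV data sets, e.g.
#' `SO239_115_AUV9_20150407_175001_IMG_0001`) and `"dash"` (components
#' joined by `-`, no infix). Sub-second acquisition time lives in the
#' metadata record, not the file name; the index disambiguates frames
#' within a second.
#'
#' @param cruise,station,camera_id Identifier tokens (letters, digits and,
#'   in the underscore dialect, dashes).
#' @param date `Date` (UTC) of acquisition.
#' @param time Seconds since midnight UTC (integer, `0..86399`).
#' @param index Non-negative frame index.
#' @param index_width Zero-padding width used when formatting.
#' @return An object of class `image_identifier`.
#' @examples
#' id <- parse_image_name("SO239_115_AUV9_20150407_175001_IMG_0001")
#' id$cruise
#' format_image_name(id)
#' @export
image_identifier <- function(cruise, station, camera_id, date, time, index,
                             index_width = 4L) {
  for (tok in c(cruise = cruise, station = station, camera_id = camera_id)) {
    if (!grepl("^[A-Za-z0-9-]+$", tok))
      stop("identifier token '", tok,
           "' contains characters outside [A-Za-z0-9-]", call. = FALSE)
  }
  date <- as.Date(date)
  time <- as.integer(time)
  index <- as.integer(index)
  stopifnot(!is.na(date), time >= 0L, time < 86400L, index >= 0L)
  structure(list(cruise = cruise, station = station, camera_id = camera_id,
                 date = date, time = time, index = index,
                 index_width = as.integer(index_width)),
            class = "image_identifier")
}

#' Parse an image file name into its identifier components
#'
#' @param name File name (an image extension such as `.jpg` is ignored).
#' @param dialect `"underscore"` (default) or `"dash"`.
#' @return An [image_identifier()].
#' @export
parse_image_name <- function(name, dialect = c("underscore", "dash")) {
  dialect <- match.arg(dialect)
  stem <- sub("\\.[A-Za-z0-9]+$", "", name)
  if (grepl("[^A-Za-z0-9_-]", stem)) {
    bad <- regmatches(stem, regexpr("[^A-Za-z0-9_-]", stem))
    stop("image name '", name, "' contains forbidden character '", bad,
         "' (only numbers, characters, dashes and underscores are allowed)",
         call. = FALSE)
  }
  sep <- if (dialect == "underscore") "_" else "-"
  parts <- strsplit(stem, sep, fixed = TRUE)[[1L]]
  want <- if (dialect == "underscore")
    c("cruise", "station", "camera_id", "date", "time", "infix", "index")
  else
    c("cruise", "station", "camera_id", "date", "time", "index")
  if (length(parts) != length(want))
    stop("image name '", name, "' has ", length(parts), " '", sep,
         "'-separated components, expected ", length(want),
         " (first missing component: ",
         want[min(length(parts) + 1L, length(want))], ")", call. = FALSE)
  names(parts) <- want
  check <- function(field, pattern, what) {
    if (!grepl(pattern, parts[[field]]))
      stop("image name '", name, "': component ", field, " ('",
           parts[[field]], "') is not ", what, call. = FALSE)
  }
  tokpat <- if (dialect == "underscore") "^[A-Za-z0-9-]+$" else "^[A-Za-z0-9]+$"
  check("cruise", tokpat, "a valid token")
  check("station", tokpat, "a valid token")
  check("camera_id", tokpat, "a valid token")
  check("date", "^\\d{8}$", "an 8-digit UTC date (YYYYMMDD)")
  check("time", "^\\d{6}$", "a 6-digit UTC time (hhmmss)")
  if (dialect == "underscore") check("infix", "^IMG$", "the literal 'IMG'")
  check("index", "^\\d+$", "a non-negative integer index")
  date <- as.Date(parts[["date"]], "%Y%m%d")
  if (is.na(date))
    stop("image name '", name, "': component date ('", parts[["date"]],
         "') is not a calendar date", call. = FALSE)
  hh <- as.integer(substr(parts[["time"]], 1, 2))
  mm <- as.integer(substr(parts[["time"]], 3, 4))
  ss <- as.integer(substr(parts[["time"]], 5, 6))
  if (hh > 23L || mm > 59L || ss > 59L)
    stop("image name '", name, "': component time ('", parts[["time"]],
         "') is not a valid time of day", call. = FALSE)
  id <- image_identifier(parts[["cruise"]], parts[["station"]],
                         parts[["camera_id"]], date,
                         hh * 3600L + mm * 60L + ss,
                         as.integer(parts[["index"]]),
                         index_width = nchar(parts[["index"]]))
  attr(id, "dialect") <- dialect
  id
}

#' Format an image identifier as a file name stem
#'
#' @param id An [image_identifier()].
#' @param dialect Naming dialect; defaults to the one `id` was parsed with.
#' @return Character file name stem (no extension).
#' @export
format_image_name <- function(id, dialect = NULL) {
  stopifnot(inherits(id, "image_identifier"))
  dialect <- dialect %||% attr(id, "dialect") %||% "underscore"
  tstr <- sprintf("%02d%02d%02d", id$time %/% 3600L,
                  (id$time %% 3600L) %/% 60L, id$time %% 60L)
  idx <- formatC(id$index, width = id$index_width, flag = "0", format = "d")
  if (dialect == "underscore")
    paste(id$cruise, id$station, id$camera_id,
          format(id$date, "%Y%m%d"), tstr, "IMG", idx, sep = "_")
  else
    paste(id$cruise, id$station, id$camera_id,
          format(id$date, "%Y%m%d"), tstr, idx, sep = "-")
}

#' @export
print.image_identifier <- function(x, ...) {
  cat("<image_identifier> ", format_image_name(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.image_identifier <- function(x, ...) format_image_name(x, ...)

## ---- record validation ---------------------------------------------------

#' Validate a metadata record
#'
#' Checks one timestamped platform record against the schema's physical
#' ranges and the timestamp format. Violations are returned as data rather
#' than thrown, so a whole table can be audited in one pass.
#'
#' @param r Named list or one-row data frame with schema tags as names.
#' @return Character vector of violations (empty if the record is valid),
#'   each naming the field and the rule violated.
#' @examples
#' validate_record(list(SUB_latitude = 91))
#' @export
validate_record <- function(r) {
  r <- as.list(r)
  out <- character(0)
  if (!is.null(r$SUB_datetime) && !is.na(r$SUB_datetime) &&
      !grepl(SUB_TIMESTAMP_FORMAT, r$SUB_datetime))
    out <- c(out, sprintf(
      "SUB_datetime: '%s' does not match 'YYYYMMDD hh:mm:ss.sss'",
      r$SUB_datetime))
  for (field in names(SCHEMA_RANGES)) {
    v <- r[[field]]
    if (is.null(v) || !is.finite(v)) next
    rng <- SCHEMA_RANGES[[field]]
    # SUB_heading lives on the half-open interval [0, 360)
    hi_ok <- if (field == "SUB_heading") v < rng[2] else v <= rng[2]
    if (v < rng[1] || !hi_ok)
      out <- c(out, sprintf("%s: value %g out of range [%g, %g%s", field, v,
                            rng[1], rng[2],
                            if (field == "SUB_heading") ")" else "]"))
  }
  if (!is.null(r$quality_flag) && !is.na(r$quality_flag) &&
      !(r$quality_flag %in% QUALITY_FLAGS))
    out <- c(out, sprintf("quality_flag: '%s' is not one of {%s}",
                          r$quality_flag, paste(QUALITY_FLAGS, collapse = ", ")))
  out
}

#' Validate a table of metadata records
#'
#' @param records Data frame of records.
#' @return Data frame with columns `row` and `violation` (zero rows if the
#'   table is clean).
#' @export
validate_records <- function(records) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    v <- validate_record(records[i, , drop = FALSE])
    if (length(v)) data.frame(row = i, violation = v) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(row = integer(0), violation = character(0))
  else out
}

#' Test whether a matrix is a proper rotation
#'
#' A camera mounting orientation must be an orthonormal 3x3 matrix with
#' determinant +1 (a rotation, not a reflection).
#'
#' @param m A 3x3 matrix.
#' @param tol Numerical tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
validate_rotation <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)) || !all(is.finite(m)))
    return(FALSE)
  max(abs(crossprod(m) - diag(3))) <= tol && abs(det(m) - 1) <= tol
}

## ---- table I/O -----------------------------------------------------------

#' Read a tab-separated metadata table
#'
#' Navigation/CTD logs are tab-separated tables with a header row, one row
#' per timestamp. Columns can be renamed to schema tags through
#' `column_map`. Rows with an unparseable timestamp or empty cells in
#' mapped fields are flagged `missing`, never silently dropped.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping schema tags to
#'   file column names, e.g. `c(SUB_distance = "altitude_m")`.
#' @return Data frame of records with a `quality_flag` column and a
#'   numeric `t_ms` column (epoch milliseconds).
#' @export
read_metadata_table <- function(path, column_map = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (tag in names(column_map)) {
    src <- column_map[[tag]]
    if (!src %in% names(df))
      stop("mapped column '", src, "' (for ", tag, ") not found in ", path,
           call. = FALSE)
    names(df)[names(df) == src] <- tag
  }
  if (!"SUB_datetime" %in% names(df))
    stop("mandatory column SUB_datetime missing from ", path, call. = FALSE)
  if (nrow(df) == 0L) {
    df$t_ms <- numeric(0)
    df$quality_flag <- character(0)
    return(df)
  }
  df$SUB_datetime <- as.character(df$SUB_datetime)
  df$t_ms <- subtime_to_ms(df$SUB_datetime)
  if (!"quality_flag" %in% names(df)) df$quality_flag <- "raw"
  present <- intersect(names(SCHEMA_RANGES), names(df))
  holey <- if (length(present))
    rowSums(is.na(df[, present, drop = FALSE])) > 0L
  else rep(FALSE, nrow(df))
  df$quality_flag[holey | is.na(df$t_ms)] <- "missing"
  df
}

#' Write a metadata table
#'
#' Inverse of [read_metadata_table()]: tab-separated, header row of schema
#' tags, empty string for missing values. Numeric values are written with
#' full precision so a read/write round trip is exact to well below 1e-9.
#'
#' @param records Data frame of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(records, path) {
  out <- records
  out$t_ms <- NULL
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    s <- formatC(x, format = "g", digits = 17)
    s[is.na(x)] <- NA
    trimws(s)
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
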