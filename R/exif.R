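## Minimal EXIF support for JPEG: a little-endian TIFF/IFD APP1 segment
## writer and a reader for the tags the pipeline fuses. Only metadata
## segments before the entropy-coded scan are touched, so pixel data stay
## byte-for-byte identical.
##
## Written tags: GPSLatitude/Longitude (+hemisphere refs, degree-minute-
## second rationals), GPSImgDirection (+ref "T"), Artist, Copyright,
## ImageDescription, and a UserComment block carrying the full selected
## metadata record as "tag:value" lines (including altitude above
## seafloor, which deliberately does NOT go into the GPS altitude tag —
## generic EXIF tools would misread it as height above sea level).

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L, `7` = 1L)

exif_ascii <- function(s) c(charToRaw(enc2utf8(s)), as.raw(0L))
exif_rational <- function(num, den) {
  out <- raw(0)
  for (i in seq_along(num)) out <- c(out, u32le(num[i]), u32le(den[i]))
  out
}

# decimal degrees -> degree/minute/second rationals (second denom 1e6)
dms_rationals <- function(deg) {
  a <- abs(deg)
  d <- floor(a)
  m <- floor((a - d) * 60)
  s <- (a - d) * 3600 - m * 60
  exif_rational(c(d, m, round(s * 1e6)), c(1, 1, 1e6))
}

exif_entry <- function(tag, type, data) {
  list(tag = tag, type = type,
       count = length(data) %/% TIFF_TYPE_SIZE[[as.character(type)]],
       data = data)
}

# serialize one IFD; external payloads are appended to `blob`, with offsets
# relative to the TIFF header
serialize_ifd <- function(entries, next_off, blob_off, blob) {
  entries <- entries[order(vapply(entries, `[[`, numeric(1), "tag"))]
  out <- u16le(length(entries))
  for (e in entries) {
    out <- c(out, u16le(e$tag), u16le(e$type), u32le(e$count))
    if (length(e$data) <= 4L) {
      out <- c(out, e$data, raw(4L - length(e$data)))
    } else {
      out <- c(out, u32le(blob_off + length(blob)))
      blob <- c(blob, e$data)
    }
  }
  list(bytes = c(out, u32le(next_off)), blob = blob)
}

ifd_size <- function(entries) 2L + 12L * length(entries) + 4L

#' Build an EXIF APP1 segment for a metadata record
#' @noRd
build_exif_app1 <- function(record, authorship = list()) {
  r <- as.list(record)
  lat <- r$SUB_latitude
  lon <- r$SUB_longitude
  heading <- r$SUB_heading

  gps <- list(exif_entry(0x0000, 1, as.raw(c(2, 3, 0, 0))))
  if (!is.null(lat) && is.finite(lat)) {
    gps <- c(gps, list(
      exif_entry(0x0001, 2, exif_ascii(if (lat >= 0) "N" else "S")),
      exif_entry(0x0002, 5, dms_rationals(lat))))
  }
  if (!is.null(lon) && is.finite(lon)) {
    gps <- c(gps, list(
      exif_entry(0x0003, 2, exif_ascii(if (lon >= 0) "E" else "W")),
      exif_entry(0x0004, 5, dms_rationals(lon))))
  }
  if (!is.null(heading) && is.finite(heading)) {
    gps <- c(gps, list(
      exif_entry(0x0010, 2, exif_ascii("T")),
      exif_entry(0x0011, 5, exif_rational(round(heading * 1e6), 1e6))))
  }

  # full selected-field block as tag:value lines
  keep <- intersect(c("SUB_datetime", names(SCHEMA_RANGES)), names(r))
  lines <- vapply(keep, function(f) {
    v <- r[[f]]
    if (is.numeric(v)) paste0(f, ":", trimws(formatC(v, format = "g",
                                                     digits = 17)))
    else paste0(f, ":", as.character(v))
  }, character(1))
  comment <- c(charToRaw("ASCII"), raw(3),
               charToRaw(paste(lines, collapse = "\n")))
  exif_ifd <- list(exif_entry(0x9286, 7, comment))

  ifd0 <- list(
    exif_entry(0x010E, 2, exif_ascii("curated seafloor survey image")),
    exif_entry(0x013B, 2, exif_ascii(authorship$artist %||% "unknown")),
    exif_entry(0x8298, 2, exif_ascii(authorship$copyright %||% "unknown")))

  ifd0_off <- 8L
  exif_off <- ifd0_off + ifd_size(ifd0) + 2L * 12L  # + pointer entries below
  gps_off <- exif_off + ifd_size(exif_ifd)
  blob_off <- gps_off + ifd_size(gps)
  ifd0 <- c(ifd0, list(
    exif_entry(0x8769, 4, u32le(exif_off)),
    exif_entry(0x8825, 4, u32le(gps_off))))

  blob <- raw(0)
  s0 <- serialize_ifd(ifd0, 0L, blob_off, blob)
  s1 <- serialize_ifd(exif_ifd, 0L, blob_off, s0$blob)
  s2 <- serialize_ifd(gps, 0L, blob_off, s1$blob)
  tiff <- c(charToRaw("II"), u16le(42L), u32le(ifd0_off),
            s0$bytes, s1$bytes, s2$bytes, s2$blob)
  payload <- c(charToRaw("Exif"), raw(2), tiff)
  c(as.raw(c(0xFF, 0xE1)), writeBin(length(payload) + 2L, raw(), size = 2,
                                    endian = "big"), payload)
}

#' Split a JPEG byte stream into metadata segments and scan
#' @noRd
jpeg_segments <- function(bytes) {
  n <- length(bytes)
  if (n < 4 || bytes[1] != as.raw(0xFF) || bytes[2] != as.raw(0xD8))
    stop("not a JPEG stream (missing SOI marker)", call. = FALSE)
  segs <- list()
  i <- 3L
  while (i + 1L <= n) {
    if (bytes[i] != as.raw(0xFF))
      stop("corrupt JPEG segment structure at byte ", i, call. = FALSE)
    marker <- as.integer(bytes[i + 1L])
    if (marker == 0xDA) break  # start of scan: pixel data from here on
    len <- 256L * as.integer(bytes[i + 2L]) + as.integer(bytes[i + 3L])
    segs[[length(segs) + 1L]] <- list(marker = marker, start = i,
                                      end = i + 1L + len)
    i <- i + 2L + len
  }
  list(segments = segs, scan_start = i)
}

is_exif_app1 <- function(bytes, seg) {
  seg$marker == 0xE1 && seg$end >= seg$start + 9L &&
    identical(bytes[(seg$start + 4L):(seg$start + 9L)],
              c(charToRaw("Exif"), raw(2)))
}

#' Fuse curated metadata into an image file's EXIF header
#'
#' Writes the standard GPS latitude/longitude tags (degree-minute-second
#' rationals with hemisphere refs), the heading as GPS image direction,
#' author/copyright tags, and the full selected metadata record —
#' including altitude above the seafloor under its schema tag — as a
#' `tag:value` block in the EXIF user comment. Any existing EXIF segment
#' is replaced, so fusing the same record twice is byte-identical; the
#' compressed pixel data are never touched.
#'
#' @param path Path to a JPEG file (formats without EXIF support fall back
#'   to a `<path>.meta.tsv` sidecar with a warning).
#' @param record Named list / one-row data frame of schema fields.
#' @param authorship List with `artist` and `copyright`.
#' @param log Optional [curation_log()].
#' @return `path`, invisibly.
#' @seealso [read_exif()]
#' @export
fuse_exif <- function(path, record, authorship = list(), log = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("jpg", "jpeg")) {
    warning("format '", ext, "' does not support EXIF; writing sidecar only")
    rec <- as.data.frame(as.list(record), stringsAsFactors = FALSE)
    rec$name <- basename(path)
    write_metadata_table(rec, paste0(path, ".meta.tsv"))
    return(invisible(path))
  }
  bytes <- readBin(path, "raw", file.size(path))
  js <- jpeg_segments(bytes)
  keep <- Filter(function(s) !is_exif_app1(bytes, s), js$segments)
  app1 <- build_exif_app1(record, authorship)
  # insert after any JFIF APP0 block, else directly after SOI
  app0 <- Filter(function(s) s$marker == 0xE0, keep)
  rest <- Filter(function(s) s$marker != 0xE0, keep)
  seg_bytes <- function(s) bytes[s$start:s$end]
  out <- c(bytes[1:2],
           unlist(lapply(app0, seg_bytes)),
           app1,
           unlist(lapply(rest, seg_bytes)),
           bytes[js$scan_start:length(bytes)])
  writeBin(out, path)
  if (!is.null(log))
    log_append(log, "fuse_exif", list(file = basename(path)), 1L, 1L)
  invisible(path)
}

## ---- reading -------------------------------------------------------------

rd_u16 <- function(bytes, pos, le) {
  b <- as.integer(bytes[pos:(pos + 1L)])
  if (le) b[1] + 256L * b[2] else b[2] + 256L * b[1]
}
rd_u32 <- function(bytes, pos, le) {
  b <- as.numeric(as.integer(bytes[pos:(pos + 3L)]))
  if (le) sum(b * 256^(0:3)) else sum(b * 256^(3:0))
}

parse_ifd <- function(tiff, off, le) {
  n <- rd_u16(tiff, off + 1L, le)
  entries <- list()
  for (k in seq_len(n)) {
    e <- off + 2L + (k - 1L) * 12L
    tag <- rd_u16(tiff, e + 1L, le)
    type <- rd_u16(tiff, e + 3L, le)
    count <- rd_u32(tiff, e + 5L, le)
    if (!as.character(type) %in% names(TIFF_TYPE_SIZE)) next
    size <- TIFF_TYPE_SIZE[[as.character(type)]] * count
    payload <- if (size <= 4) tiff[(e + 9L):(e + 8L + max(size, 1L))]
    else {
      p <- rd_u32(tiff, e + 9L, le)
      tiff[(p + 1L):(p + size)]
    }
    val <- switch(as.character(type),
      `2` = rawToChar(payload[payload != as.raw(0)]),
      `5` = {
        num <- vapply(seq_len(count), function(i)
          rd_u32(payload, (i - 1L) * 8L + 1L, le), numeric(1))
        den <- vapply(seq_len(count), function(i)
          rd_u32(payload, (i - 1L) * 8L + 5L, le), numeric(1))
        num / den
      },
      `3` = vapply(seq_len(count), function(i)
        rd_u16(payload, (i - 1L) * 2L + 1L, le), numeric(1)),
      `4` = vapply(seq_len(count), function(i)
        rd_u32(payload, (i - 1L) * 4L + 1L, le), numeric(1)),
      payload)
    entries[[sprintf("0x%04X", tag)]] <- val
  }
  entries
}

#' Read the EXIF metadata fused by [fuse_exif()]
#'
#' @param path Path to a JPEG file.
#' @return List with `latitude`, `longitude`, `heading_deg` (decimal
#'   degrees, signed by hemisphere), `artist`, `copyright`, and `fields`
#'   (named character vector decoded from the user-comment block), or
#'   `NULL` if the file has no EXIF segment.
#' @export
read_exif <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  js <- jpeg_segments(bytes)
  seg <- Filter(function(s) is_exif_app1(bytes, s), js$segments)
  if (!length(seg)) return(NULL)
  s <- seg[[1]]
  tiff <- bytes[(s$start + 10L):s$end]
  le <- identical(tiff[1:2], charToRaw("II"))
  ifd0 <- parse_ifd(tiff, rd_u32(tiff, 5L, le), le)
  out <- list(artist = ifd0[["0x013B"]], copyright = ifd0[["0x8298"]],
              description = ifd0[["0x010E"]],
              latitude = NULL, longitude = NULL, heading_deg = NULL,
              fields = NULL)
  if (!is.null(ifd0[["0x8825"]])) {
    gps <- parse_ifd(tiff, ifd0[["0x8825"]], le)
    if (!is.null(gps[["0x0002"]])) {
      d <- gps[["0x0002"]]
      v <- d[1] + d[2] / 60 + d[3] / 3600
      out$latitude <- if (identical(gps[["0x0001"]], "S")) -v else v
    }
    if (!is.null(gps[["0x0004"]])) {
      d <- gps[["0x0004"]]
      v <- d[1] + d[2] / 60 + d[3] / 3600
      out$longitude <- if (identical(gps[["0x0003"]], "W")) -v else v
    }
    if (!is.null(gps[["0x0011"]])) out$heading_deg <- gps[["0x0011"]]
  }
  if (!is.null(ifd0[["0x8769"]])) {
    exif <- parse_ifd(tiff, ifd0[["0x8769"]], le)
    uc <- exif[["0x9286"]]
    if (!is.null(uc) && length(uc) > 8L) {
      txt <- rawToChar(uc[-(1:8)])
      kv <- strsplit(strsplit(txt, "\n", fixed = TRUE)[[1]], ":")
      vals <- vapply(kv, function(p) paste(p[-1], collapse = ":"),
                     character(1))
      names(vals) <- vapply(kv, `[[`, character(1), 1)
      out$fields <- vals
    }
  }
  out
}
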