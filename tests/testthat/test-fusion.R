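write_test_jpeg <- function(path, seed = 1, n = 32) {
  set.seed(seed)
  jpeg::writeJPEG(matrix(runif(n * n), n), path, quality = 0.95)
  path
}

test_that("EXIF fusion round-trips coordinates without touching pixels", {
  path <- write_test_jpeg(withr::local_tempfile(fileext = ".jpg"))
  px_before <- jpeg::readJPEG(path)
  rec <- clean_record(SUB_latitude = 52.5123456, SUB_longitude = 9.87654321,
                      SUB_heading = 123.456, SUB_distance = 7.531)
  fuse_exif(path, rec, authorship = list(artist = "AUV team",
                                         copyright = "CC-BY"))
  out <- read_exif(path)
  expect_equal(out$latitude, 52.5123456, tolerance = 1e-6)
  expect_equal(out$longitude, 9.87654321, tolerance = 1e-6)
  expect_equal(out$heading_deg, 123.456, tolerance = 1e-6)
  expect_equal(as.numeric(out$fields[["SUB_distance"]]), 7.531,
               tolerance = 1e-9)
  expect_equal(out$artist, "AUV team")
  expect_equal(out$copyright, "CC-BY")
  expect_identical(jpeg::readJPEG(path), px_before)
})

test_that("southern/western hemispheres get S and W reference tags", {
  path <- write_test_jpeg(withr::local_tempfile(fileext = ".jpg"), seed = 2)
  fuse_exif(path, clean_record(SUB_latitude = -14.0, SUB_longitude = -88.5))
  out <- read_exif(path)
  expect_equal(out$latitude, -14.0, tolerance = 1e-9)
  expect_equal(out$longitude, -88.5, tolerance = 1e-9)
})

test_that("fusing the same record twice is byte-identical (idempotent)", {
  path <- write_test_jpeg(withr::local_tempfile(fileext = ".jpg"), seed = 3)
  rec <- clean_record()
  fuse_exif(path, rec)
  b1 <- readBin(path, "raw", file.size(path))
  fuse_exif(path, rec)
  b2 <- readBin(path, "raw", file.size(path))
  expect_identical(b1, b2)
})

test_that("formats without EXIF fall back to a sidecar with a warning", {
  skip_if_not_installed("png")
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 8, 8), path)
  expect_warning(fuse_exif(path, clean_record()), "sidecar")
  expect_true(file.exists(paste0(path, ".meta.tsv")))
})

test_that("sidecar tables carry one row per image", {
  recs <- do.call(rbind, lapply(1:3, function(i)
    as.data.frame(clean_record(SUB_distance = i))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sidecar(paste0("img", 1:3, ".jpg"), recs, path)
  expect_length(readLines(path), 4)  # header + 3
  back <- read_metadata_table(path)
  expect_equal(back$SUB_distance, 1:3)
  expect_equal(back$name, paste0("img", 1:3, ".jpg"))
  # empty set gives a header-only file
  write_sidecar(character(0), recs[0, ], path)
  expect_length(readLines(path), 1)
  expect_error(write_sidecar("a.jpg", recs, path), "exactly one record")
})

test_that("half-hour folders split on wall-clock boundaries", {
  # a 1 Hz stream across one full half-hour window plus neighbors
  t0 <- subtime_to_ms("20150407 16:45:00.000")
  t <- t0 + (0:5399) * 1000  # 16:45:00 .. 18:14:59
  plan <- organize_folders(sprintf("img%04d.jpg", seq_along(t)), t,
                           dive = "SO239_115")
  tab <- table(plan$folder)
  expect_equal(unname(tab[["SO239_115_20150407_1700"]]), 1800)
  expect_equal(sum(tab), length(t))  # partition: every image in one folder
  # the image at exactly 17:30:00.000 opens the new folder
  b <- subtime_to_ms("20150407 17:30:00.000")
  expect_equal(unique(plan$folder[plan$t_ms == b]),
               "SO239_115_20150407_1730")
  expect_equal(unique(plan$folder[plan$t_ms == b - 1000]),
               "SO239_115_20150407_1700")
})

test_that("max-count folders pack in time order", {
  t <- seq_len(2000) * 1000
  plan <- organize_folders(sprintf("i%04d.jpg", 1:2000), t,
                           split = "max_count", max_count = 999)
  expect_equal(unname(c(table(plan$folder))), c(999, 999, 2))
})

test_that("archive pooling is first-fit with oversize warnings", {
  p <- pool_archives(c(a = 30e9, b = 30e9, c = 30e9),
                     target_size_bytes = 50e9)
  expect_equal(length(unique(p$archive)), 3)  # 30+30 overflows 50
  p2 <- pool_archives(c(a = 20e9, b = 20e9, c = 25e9, d = 9e9),
                      target_size_bytes = 50e9)
  # first fit: a+b fill archive 1 to 40, c opens 2, d still fits 1
  expect_equal(p2$archive[p2$folder %in% c("a", "b", "d")],
               rep("archive001", 3))
  expect_equal(p2$archive[p2$folder == "c"], "archive002")
  expect_warning(pool_archives(c(big = 70e9), 50e9), "oversize")
  # nothing is lost in pooling
  expect_equal(sum(p2$size_bytes), 74e9)
})

test_that("manifests expose any flipped byte in archived members", {
  root <- withr::local_tempdir()
  out <- withr::local_tempdir()
  for (f in c("f1", "f2")) {
    dir.create(file.path(root, f))
    writeLines(paste("payload", f, 1:50), file.path(root, f, "data.txt"))
  }
  sizes <- vapply(c("f1", "f2"), function(f)
    sum(file.size(list.files(file.path(root, f), full.names = TRUE))),
    numeric(1))
  plan <- pool_archives(sizes, target_size_bytes = 1e6)
  manifest <- create_archives(plan, root, out)
  expect_equal(nrow(manifest), 2)
  expect_true(all(file.exists(file.path(out, unique(paste0(plan$archive,
                                                           ".tar"))))))
  expect_equal(nrow(verify_manifest(manifest, root)), 0)
  # flip one byte in a member file
  victim <- file.path(root, manifest$member[1])
  bytes <- readBin(victim, "raw", file.size(victim))
  bytes[10] <- xor(bytes[10], as.raw(0xFF))
  writeBin(bytes, victim)
  bad <- verify_manifest(manifest, root)
  expect_equal(bad$member, manifest$member[1])
})
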