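test_that("the published example file name parses into its components", {
  id <- parse_image_name("SO239_115_AUV9_20150407_175001_IMG_0001")
  expect_equal(id$cruise, "SO239")
  expect_equal(id$station, "115")
  expect_equal(id$camera_id, "AUV9")
  expect_equal(id$date, as.Date("2015-04-07"))
  expect_equal(id$time, 17 * 3600 + 50 * 60 + 1)
  expect_equal(id$index, 1L)
})

test_that("naming round-trips for randomly generated identifiers", {
  set.seed(101)
  for (k in 1:1000) {
    id <- random_identifier()
    name <- format_image_name(id)
    expect_match(name, "^[A-Za-z0-9_-]+$")  # machine-readable charset
    back <- parse_image_name(name)
    expect_equal(back$cruise, id$cruise)
    expect_equal(back$date, id$date)
    expect_equal(back$time, id$time)
    expect_equal(back$index, id$index)
    expect_identical(format_image_name(back), name)
  }
})

test_that("malformed names are rejected, naming the offending part", {
  expect_error(parse_image_name("SO239 115 AUV9.jpg"), "forbidden character")
  expect_error(parse_image_name("SO239_115_AUV9_2015_175001_IMG_0001"),
               "date")
  expect_error(parse_image_name("SO239_115_AUV9_20150407_256001_IMG_0001"),
               "time")
  expect_error(parse_image_name("SO239_115_AUV9_20150407_175001_0001"),
               "components")
  expect_error(image_identifier("SO 239", "115", "AUV9",
                                "2015-04-07", 0, 1), "token")
})

test_that("the dash dialect works and extensions are ignored", {
  id <- parse_image_name("SO239-115-AUV9-20150407-175001-0001",
                         dialect = "dash")
  expect_equal(id$station, "115")
  expect_equal(format_image_name(id), "SO239-115-AUV9-20150407-175001-0001")
  id2 <- parse_image_name("SO239_115_AUV9_20150407_175001_IMG_0001.jpg")
  expect_equal(id2$index, 1L)
})

test_that("record validation collects violations instead of throwing", {
  expect_length(validate_record(clean_record()), 0)
  v <- validate_record(clean_record(SUB_latitude = 91))
  expect_length(v, 1)
  expect_match(v, "SUB_latitude")
  # heading lives on the half-open interval [0, 360)
  v <- validate_record(clean_record(SUB_heading = 360))
  expect_match(v, "SUB_heading")
  expect_length(validate_record(clean_record(SUB_heading = 0)), 0)
  v <- validate_record(clean_record(SUB_datetime = "2015-04-07 17:50:01"))
  expect_match(v, "SUB_datetime")
  v <- validate_record(clean_record(SUB_distance = -1,
                                    SUB_longitude = -190))
  expect_length(v, 2)
})

test_that("rotation validation accepts rotations and rejects the rest", {
  expect_true(validate_rotation(diag(3)))
  expect_false(validate_rotation(diag(c(1, 1, -1))))  # reflection
  m <- diag(3); m[1, ] <- m[1, ] * 1.1
  expect_false(validate_rotation(m))
  expect_false(validate_rotation(matrix(0, 3, 3)))
  expect_false(validate_rotation(diag(2)))
  # compositions of rotations about the axes are always accepted
  set.seed(7)
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  for (k in 1:100) {
    m <- rz(runif(1, 0, 2 * pi)) %*% rx(runif(1, 0, 2 * pi)) %*%
      rz(runif(1, 0, 2 * pi))
    expect_true(validate_rotation(m))
  }
})

test_that("schema timestamps convert to epoch ms and back exactly", {
  x <- c("20150407 17:50:01.250", "19991231 23:59:59.999")
  expect_identical(ms_to_subtime(subtime_to_ms(x)), x)
  expect_true(is.na(subtime_to_ms("2015-04-07 17:50:01.250")))
})

test_that("metadata tables round-trip and flag incomplete rows", {
  tab <- do.call(rbind, lapply(1:3, function(i)
    as.data.frame(clean_record(SUB_datetime =
                                 sprintf("20150407 17:50:0%d.000", i)))))
  tab$SUB_distance[2] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata_table(tab, path)
  back <- read_metadata_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$quality_flag, c("raw", "missing", "raw"))
  expect_equal(back$SUB_latitude, tab$SUB_latitude, tolerance = 1e-12)
  expect_equal(back$SUB_distance[c(1, 3)], tab$SUB_distance[c(1, 3)],
               tolerance = 1e-12)

  # header-only file reads as an empty sequence
  writeLines("SUB_datetime\tSUB_distance", path)
  expect_equal(nrow(read_metadata_table(path)), 0)

  # missing mandatory column and bad column map are hard errors
  writeLines(c("altitude", "5"), path)
  expect_error(read_metadata_table(path), "SUB_datetime")
  expect_error(read_metadata_table(path, c(SUB_distance = "alt")), "alt")
})

test_that("the curation log is append-only JSON-lines", {
  log <- curation_log()
  log_append(log, "stage_a", list(x = 1), 10, 9)
  log_append(log, "stage_b", list(), 9, 9)
  expect_length(log_entries(log), 2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_curation_log(log, path)
  expect_length(readLines(path), 2)
  back <- read_curation_log(path)
  expect_equal(log_entries(back)[[1]]$operation, "stage_a")
  expect_equal(log_entries(back)[[2]]$n_in, 9)
})
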