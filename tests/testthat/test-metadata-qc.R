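test_that("modified z-score flags spikes and only spikes", {
  # constant series with one spike: median 5, MAD 0 -> degenerate branch
  x <- c(5, 5, 5, 5, 55, 5, 5)
  expect_equal(which(detect_outliers(x)), 5L)
  # hand MAD arithmetic: x = (1..7) with a 100 at position 4
  y <- c(1, 2, 3, 100, 5, 6, 7)
  med <- median(y)                       # 5
  madu <- median(abs(y - med))           # unscaled MAD = 2
  z <- 0.6745 * abs(y - med) / madu
  expect_equal(detect_outliers(y), z > 3.5)
  # a clean linear ramp has no outliers
  expect_false(any(detect_outliers(seq(0, 10, length.out = 50))))
  # physical range violations are flagged regardless of spread
  lat <- c(-7.01, -7.02, 95, -7.03, -7.02, -7.01)
  expect_true(detect_outliers(lat, field = "SUB_latitude")[3])
  expect_error(detect_outliers(c(1, 2, NA, NA, NA)), "5 valid")
})

test_that("gap filling reconstructs smooth series without extrapolating", {
  # spline reproduces an exactly cubic series to machine precision
  t <- 1:20
  cubic <- 0.5 * t^3 - 2 * t^2 + t - 7
  x <- cubic; x[c(8, 9, 14)] <- NA
  f <- fill_gaps(x, t, method = "spline")
  expect_lt(max(abs(f$values - cubic)), 1e-9)
  expect_equal(which(f$filled), c(8L, 9L, 14L))
  # anchors untouched
  expect_identical(f$values[-c(8, 9, 14)], cubic[-c(8, 9, 14)])

  # both methods are exact on a linear series
  lin <- 2 * t + 1; xl <- lin; xl[10] <- NA
  expect_equal(fill_gaps(xl, t, "linear")$values, lin)
  expect_equal(fill_gaps(xl, t, "spline")$values, lin, tolerance = 1e-12)

  # leading/trailing gaps stay missing
  xe <- lin; xe[c(1, 20)] <- NA
  fe <- fill_gaps(xe, t)
  expect_true(all(is.na(fe$values[c(1, 20)])))

  expect_error(fill_gaps(rep(NA_real_, 5)), "all values missing")
  expect_error(fill_gaps(c(1, 2, NA, NA, 3), method = "spline"), "anchor")
})

test_that("outlier detection then gap filling is the identity on clean data", {
  set.seed(41)
  t <- 1:100
  x <- 7.5 + 0.5 * sin(t / 9) + 0.1 * cos(t / 3)
  mask <- detect_outliers(x)
  expect_false(any(mask))
  x2 <- x; x2[mask] <- NA
  expect_equal(fill_gaps(x2, t)$values, x)
})

test_that("streams merge on the master clock with provenance counts", {
  nav <- data.frame(t_ms = c(0, 1000, 2000), SUB_distance = c(7, 8, 9),
                    quality_flag = "raw")
  ctd <- data.frame(t_ms = c(500, 1500), ENV_temperaturewater = c(1.5, 1.7))
  log <- curation_log()
  out <- merge_streams(list(nav = nav, ctd = ctd), tolerance_ms = 100,
                       log = log)
  expect_equal(nrow(out), 3)
  # no exact matches: interior cells interpolated, ends missing
  expect_equal(out$ENV_temperaturewater[2], 1.6)
  expect_true(is.na(out$ENV_temperaturewater[1]))
  e <- log_entries(log)[[1]]
  expect_equal(e$operation, "merge_streams")
  expect_equal(e$parameters$provenance$ctd$interpolated, 1)

  # identical time bases reduce to column concatenation
  ctd2 <- data.frame(t_ms = nav$t_ms, ENV_temperaturewater = c(1, 2, 3))
  out2 <- merge_streams(list(nav = nav, ctd = ctd2))
  expect_equal(out2$ENV_temperaturewater, c(1, 2, 3))

  # an empty stream leaves its fields missing but keeps all rows
  out3 <- merge_streams(list(nav = nav,
                             ctd = ctd[0, , drop = FALSE]))
  expect_equal(nrow(out3), 3)
  expect_true(all(is.na(out3$ENV_temperaturewater)))

  dup <- data.frame(t_ms = c(0, 0), ENV_scattering = c(1, 2))
  expect_error(merge_streams(list(nav = nav, dup = dup)), "duplicate")
})

test_that("merging is insensitive to the order of non-overlapping streams", {
  nav <- data.frame(t_ms = seq(0, 5000, 1000), SUB_distance = 7:12)
  a <- data.frame(t_ms = seq(250, 5250, 1000), ENV_temperaturewater = 1:6)
  b <- data.frame(t_ms = seq(500, 5500, 1000), ENV_scattering = 11:16)
  m1 <- merge_streams(list(nav = nav, a = a, b = b))
  m2 <- merge_streams(list(nav = nav, b = b, a = a))
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("smoothing behaves like a convolution and logs its parameters", {
  x <- c(0, 0, 0, 3, 3, 3)
  expect_identical(smooth_series(x, window = 1L), x)
  const <- rep(4, 10)
  expect_equal(smooth_series(const, window = 5L), const)
  sm <- smooth_series(x, window = 3L)
  expect_equal(sm[2:5], c(0, 1, 2, 3))  # hand-computed 3-tap means
  expect_error(smooth_series(x, window = 7L), "larger than series")
  log <- curation_log()
  smooth_series(x, window = 3L, log = log)
  expect_length(log_entries(log), 1)
  expect_equal(log_entries(log)[[1]]$parameters$window, 3)
})

test_that("table-level QC repairs exactly the injected defects", {
  dive <- tiny_dive(seed = 44)
  log <- curation_log()
  qc <- qc_metadata_table(dive$nav, log = log)
  fields <- colnames(dive$truth$nav_outliers)
  expect_equal(qc$outliers[, fields], dive$truth$nav_outliers)
  expect_equal(qc$gaps[, fields], dive$truth$nav_gaps)
  expect_false(any(qc$outliers[, "SUB_heading"]))
  # repaired altitude is close to the true trajectory
  t_rel <- (dive$nav$t_ms - dive$scenario$t0_ms) / 1000
  truth_alt <- pose_at(dive$scenario, t_rel)$altitude_m
  repaired <- qc$outliers[, "SUB_distance"] | qc$gaps[, "SUB_distance"]
  expect_true(any(repaired))
  expect_lt(max(abs(qc$records$SUB_distance[repaired] -
                      truth_alt[repaired])), 0.5)
  expect_length(log_entries(log), 1)
})

test_that("every mutating operation appends exactly one log entry", {
  dive <- tiny_dive(seed = 45)
  log <- curation_log()
  qc_metadata_table(dive$nav, log = log)
  merge_streams(list(nav = dive$nav, env = dive$env), log = log)
  smooth_series(dive$nav$SUB_distance, window = 3L, log = log)
  rep <- qc_report(dive$frames, names = dive$names)
  rep <- altitude_filter(rep, dive$truth$frames$altitude_m, log = log)
  rep <- darkness_filter(rep, 12.75, log = log)
  rep <- exclude_subsequences(rep, list(), log = log)
  ops <- vapply(log_entries(log), `[[`, character(1), "operation")
  expect_equal(ops, c("qc_metadata_table", "merge_streams", "smooth_series",
                      "altitude_filter", "darkness_filter",
                      "exclude_subsequences"))
})
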