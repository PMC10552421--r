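test_that("a sorted single-individual file ingests identically", {
  f <- make_fixes(x = c(0, 10, 20), y = c(0, 0, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_csv(f, path)
  g <- read_tracking_csv(path)
  expect_equal(nrow(g), 3)
  expect_equal(g$x, f$x, tolerance = 1e-9)
  expect_identical(g$timestamp, f$timestamp)
})

test_that("write/read round trip preserves fields exactly", {
  f <- make_fixes(x = c(1234.123456, 99.000001), y = c(-5.5, 7.25),
                  t = c(0, 240), altitude = c(100, 110), burst = c("b1", "b2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_csv(f, path)
  g <- read_tracking_csv(path)
  expect_equal(g$x, f$x, tolerance = 1e-7)
  expect_equal(g$y, f$y, tolerance = 1e-7)
  expect_identical(as.numeric(g$timestamp), as.numeric(f$timestamp))
  expect_identical(g$burst_id, f$burst_id)
  expect_equal(g$altitude_hae, f$altitude_hae)
})

test_that("repeated timestamps are flagged duplicate, first kept", {
  f <- make_fixes(x = c(0, 1, 2), y = c(0, 0, 0), t = c(0, 0, 240))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_csv(f, path)
  g <- read_tracking_csv(path)
  expect_equal(sum(has_flag(g$outlier_flags, "duplicate")), 1)
  kept <- drop_outliers(g)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$x[1], 0)  # first occurrence retained
})

test_that("missing required columns raise a schema error naming them", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(individual_id = "a", x = 1), path)
  expect_error(read_tracking_csv(path, columns = msms_columns()),
               "timestamp", class = "msms_schema_error")
})

test_that("unparseable timestamps raise a row-level error", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    individual_id = "a", species = "sp",
    timestamp = c("2016-01-01 00:00:00", "not-a-time"),
    x = c(0, 1), y = c(0, 1)), path)
  expect_error(read_tracking_csv(path, columns = msms_columns()),
               "row", class = "msms_parse_error")
})

test_that("lon/lat input is projected; planar geometry matches geodesic oracle", {
  skip_if_not_installed("geosphere")
  # Movebank-dialect file around the BCI study site
  lon <- c(-79.851, -79.846, -79.852)
  lat <- c(9.151, 9.155, 9.160)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    "individual-local-identifier" = "a",
    "individual-taxon-canonical-name" = "sp",
    timestamp = format(as.POSIXct("2016-01-01", tz = "UTC") + 240 * (0:2),
                       "%Y-%m-%d %H:%M:%S"),
    "location-long" = lon, "location-lat" = lat,
    "height-above-ellipsoid" = 100), path)
  g <- read_tracking_csv(path)
  crs <- attr(g, "crs")
  expect_equal(crs$zone, 17L)
  # pairwise planar distances agree with geodesic distances times the local
  # point scale (within 2 cm over ~1 km, far better than GPS error)
  for (i in 1:2) {
    d_pl <- sqrt(diff(g$x)[i]^2 + diff(g$y)[i]^2)
    d_geo <- geosphere::distGeo(c(lon[i], lat[i]), c(lon[i + 1], lat[i + 1]))
    scale <- 0.9996 * (1 + ((g$x[i] - 5e5) / (0.9996 * 6367449))^2 / 2)
    expect_equal(d_pl, d_geo * scale, tolerance = 0.02 / d_pl)
  }
})

test_that("UTM forward projection matches anchors and inverts exactly", {
  skip_if_not_installed("geosphere")
  # equator on the central meridian of zone 17
  p0 <- project_utm(-81, 0, zone = 17)
  expect_equal(p0$x, 5e5, tolerance = 1e-6)
  expect_equal(p0$y, 0, tolerance = 1e-6)
  # northing along the central meridian = scaled meridian arc length
  p9 <- project_utm(-81, 9, zone = 17)
  arc <- geosphere::distGeo(c(-81, 0), c(-81, 9))
  expect_equal(p9$y, 0.9996 * arc, tolerance = 1e-6)
  # round trip to sub-millimeter in degrees
  lon <- runif(50, -83.9, -78.1); lat <- runif(50, -10, 60)
  p <- project_utm(lon, lat, zone = 17)
  rt <- unproject_utm(p$x, p$y, zone = 17)
  expect_equal(rt$lon, lon, tolerance = 1e-9)
  expect_equal(rt$lat, lat, tolerance = 1e-9)
})

test_that("burst selection keeps exactly the latest fix per burst", {
  # 10 bursts of 6 fixes at 1 Hz, 4 minutes apart
  t <- as.vector(outer(0:5, 240 * (0:9), "+"))
  f <- make_fixes(x = seq_along(t), y = rep(0, length(t)), t = t,
                  burst = rep(sprintf("b%02d", 1:10), each = 6))
  g <- select_burst_last_fix(f)
  expect_equal(nrow(g), 10)
  # group-by-max oracle
  oracle <- tapply(as.numeric(f$timestamp), f$burst_id, max)
  expect_setequal(as.numeric(g$timestamp), as.vector(oracle))
  expect_false(is.unsorted(g$timestamp))
  # idempotent; size-1 bursts and missing bursts pass through
  expect_identical(select_burst_last_fix(g), g)
  f2 <- make_fixes(x = 1:3, y = 1:3)
  expect_equal(nrow(select_burst_last_fix(f2)), 3)
})

test_that("diurnal fixes assemble into one daily path keyed to that date", {
  # 06:00-18:00 local = 11:00-23:00 UTC at UTC-5
  t0 <- as.POSIXct("2016-01-05 11:00:00", tz = "UTC")
  f <- make_fixes(x = 1:10, y = 1:10, t = 0, species = "capuchin")
  f$timestamp <- t0 + 240 * (0:9)
  d <- assemble_daily_paths(f)
  expect_equal(nrow(d), 10)
  expect_equal(unique(d$period_date), as.Date("2016-01-05"))
  expect_true(all(d$complete))
})

test_that("nocturnal paths spanning midnight key to the start date", {
  # kinkajou window 23:00-06:30 local; 23:30 Jan 5 local = 04:30 Jan 6 UTC
  t0 <- as.POSIXct("2016-01-06 04:30:00", tz = "UTC")
  f <- make_fixes(x = 1:20, y = 1:20, species = "kinkajou")
  f$timestamp <- t0 + 1800 * (0:19)  # crosses local midnight
  d <- assemble_daily_paths(f)
  expect_equal(unique(d$period_date), as.Date("2016-01-05"))
  # half-hourly fixes from 23:30: the 15 up to 06:30 are in-window
  expect_equal(nrow(d), 15)
})

test_that("a two-hour hole marks the day incomplete; out-of-window fixes drop", {
  t0 <- as.POSIXct("2016-01-05 11:00:00", tz = "UTC")
  tt <- c(0, 240, 480, 480 + 7200, 480 + 7440)
  f <- make_fixes(x = 1:5, y = 1:5, species = "capuchin")
  f$timestamp <- t0 + tt
  d <- assemble_daily_paths(f)
  expect_false(any(d$complete))
  # fix at local 03:00 (outside 06:00-18:00) is excluded
  f2 <- f
  f2$timestamp[1] <- as.POSIXct("2016-01-05 08:00:00", tz = "UTC")
  d2 <- assemble_daily_paths(f2)
  expect_equal(nrow(d2), 4)
})

test_that("daily assembly partitions in-window fixes exactly once", {
  set.seed(42)
  study <- simulate_individual(sim_config(species = "kinkajou",
                                          activity_window = c("23:00", "06:30"),
                                          days = 3, acc_dropout = 0))
  f <- select_burst_last_fix(study$fixes)
  d <- assemble_daily_paths(f, activity_windows = c("23:00", "06:30"))
  # every simulated fix lies in the window, so counts conserve
  expect_equal(nrow(d), nrow(f))
  expect_equal(anyDuplicated(d$timestamp), 0)
  expect_equal(length(unique(d$period_date)), 3)
})
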