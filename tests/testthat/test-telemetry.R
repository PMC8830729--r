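make_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("telemetry reader preserves animals, projects lon/lat, passes through km", {
  ts <- format(seq(as.POSIXct("2018-01-01 12:00", tz = "UTC"), by = "day",
                   length.out = 5), "%Y-%m-%dT%H:%M:%SZ")
  d <- data.frame(animal_id = rep(c("a", "b", "c"), each = 5),
                  timestamp = rep(ts, 3),
                  x_km = rnorm(15), y_km = rnorm(15), crs = "plane-km")
  tracks <- read_telemetry(make_csv(d))
  expect_length(tracks, 3)
  expect_equal(tracks[["b"]]$fixes$x, d$x_km[6:10])
  # lon/lat input: 1 degree of latitude at the dataset center ~ 111.2 km
  d2 <- data.frame(animal_id = "a", timestamp = ts[1:2],
                   longitude = c(-120, -120), latitude = c(59.5, 60.5))
  tr2 <- read_telemetry(make_csv(d2))[["a"]]
  dist <- sqrt(diff(tr2$fixes$x)^2 + diff(tr2$fixes$y)^2)
  expect_equal(dist, 111.2, tolerance = 0.5 / 111.2)
  # geodesic oracle for an off-meridian pair
  skip_if_not_installed("geosphere")
  d3 <- data.frame(animal_id = "a", timestamp = ts[1:2],
                   longitude = c(-121, -119.4), latitude = c(59.1, 60.2))
  tr3 <- read_telemetry(make_csv(d3))[["a"]]
  got <- sqrt(diff(tr3$fixes$x)^2 + diff(tr3$fixes$y)^2)
  ref <- geosphere::distHaversine(c(-121, 59.1), c(-119.4, 60.2),
                                  r = 6371008.8) / 1000
  expect_equal(got, ref, tolerance = 0.005)
  expect_error(read_telemetry(make_csv(d[, -1])), "schema error")
})

test_that("daily thinning keeps the noon-nearest fix, earlier on ties, idempotently", {
  base <- as.POSIXct("2018-03-01 00:00", tz = "UTC")
  ts <- base + rep(0:9, each = 24) * 86400 + (0:23) * 3600
  tr <- telemetry_track("a", data.frame(timestamp = ts, x = seq_along(ts),
                                        y = 0))
  th <- thin_daily(tr)
  expect_equal(nrow(th$fixes), 10)
  expect_true(all(format(th$fixes$timestamp, "%H") == "12"))
  # kept coordinates are untouched originals
  expect_true(all(th$fixes$x %in% tr$fixes$x))
  expect_identical(thin_daily(th), th)
  # 11:00 vs 13:00 tie goes to the earlier fix
  tr2 <- telemetry_track("b", data.frame(
    timestamp = base + c(11, 13) * 3600, x = c(1, 2), y = 0))
  expect_equal(thin_daily(tr2)$fixes$x, 1)
})

test_that("season assignment uses the stated windows and winter-year keying", {
  d <- as.Date(c("2010-12-15", "2011-02-01", "2011-08-01", "2011-09-15",
                 "2011-09-16", "2011-11-01", "2011-04-30", "2011-05-01"))
  se <- assign_seasons(d)
  expect_equal(se$season,
               c("winter", "winter", "summer", "summer", "none", "none",
                 "winter", "none"))
  # December fixes key to the following January's season-year
  expect_equal(se$season_year[1], 2011)
  expect_equal(se$season_year[2], 2011)
  expect_equal(se$season_year[3], 2011)
  # partition: every fix gets exactly one label
  expect_true(all(se$season %in% c("summer", "winter", "none")))
})

test_that("IO screening enforces 30 locations per season and 1 year monitoring", {
  mk <- function(id, dates) {
    telemetry_track(id, data.frame(
      timestamp = as.POSIXct(paste(dates, "12:00"), tz = "UTC"),
      x = 0, y = 0))
  }
  full_year <- seq(as.Date("2018-01-01"), as.Date("2018-12-31"), by = "day")
  # a: complete year -> eligible; b: only 29 winter fixes -> excluded;
  # c: short monitoring -> dropped
  b_days <- c(seq(as.Date("2018-01-01"), by = "day", length.out = 29),
              seq(as.Date("2018-07-01"), by = "day", length.out = 40),
              as.Date("2018-12-31"))
  tracks <- list(a = mk("a", full_year), b = mk("b", b_days),
                 c = mk("c", full_year[1:100]))
  sc <- screen_for_io(tracks)
  expect_true(sc$eligible[sc$animal_id == "a" & sc$season_year == 2018])
  expect_false(any(sc$eligible[sc$animal_id == "b"]))
  expect_false(any(sc$eligible[sc$animal_id == "c"]))
  expect_match(sc$reason[sc$animal_id == "c"], "one year")
  # exactly 30/30 is eligible (boundary)
  d_days <- c(seq(as.Date("2018-01-01"), by = "day", length.out = 30),
              seq(as.Date("2018-07-01"), by = "day", length.out = 30),
              as.Date("2018-12-31"))
  sc2 <- screen_for_io(list(d = mk("d", d_days)))
  expect_true(any(sc2$eligible))
})

test_that("NSD screening applies the configurable gap rule", {
  mk <- function(dates) telemetry_track("x", data.frame(
    timestamp = as.POSIXct(paste(dates, "12:00"), tz = "UTC"), x = 0, y = 0))
  full <- seq(as.Date("2018-01-01"), as.Date("2018-12-31"), by = "day")
  expect_true(screen_for_nsd(list(mk(full)))$eligible)
  gap3 <- full[-(50:52)]   # 3 missing days
  expect_false(screen_for_nsd(list(mk(gap3)), max_gap_days = 1)$eligible)
  expect_true(screen_for_nsd(list(mk(gap3)), max_gap_days = 7)$eligible)
})
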