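synthetic_track <- function(xy, start = "2018-01-01") {
  telemetry_track("t", data.frame(
    timestamp = as.POSIXct(paste(seq(as.Date(start), by = "day",
                                     length.out = nrow(xy)), "12:00"),
                           tz = "UTC"),
    x = xy[, 1], y = xy[, 2]))
}

test_that("NSD series follows its closed forms", {
  tr <- synthetic_track(cbind(rep(1, 10), rep(2, 10)))
  nsd <- compute_nsd(tr, 1)
  expect_true(all(nsd$nsd == 0))
  # straight-line motion at v km/day: NSD = (v (t-1))^2 from the first fix
  v <- 3
  tr2 <- synthetic_track(cbind(v * (0:99), rep(0, 100)))
  nsd2 <- compute_nsd(tr2, 1)
  expect_equal(nsd2$nsd, (v * (nsd2$day - 1))^2)
  expect_error(compute_nsd(tr, 99), "reference")
})

test_that("date_to_numeric counts days from 1 January", {
  expect_equal(date_to_numeric("2017-01-01"), 1)
  expect_equal(date_to_numeric("2017-04-10"), 100)
  expect_equal(date_to_numeric("2017-12-31"), 365)
  expect_equal(date_to_numeric("2016-02-29"), 60)   # leap year
  expect_equal(date_to_numeric("2016-04-10"), 101)
  expect_error(date_to_numeric("not-a-date"), "invalid")
})

test_that("model fits recover noiseless parameters and rank shapes correctly", {
  t <- 1:365
  # constant series: resident wins
  const <- data.frame(day = t, nsd = 100 + rnorm(365, 0, 1))
  sc <- fit_movement_models(const)
  expect_equal(sc$best, "resident")
  # linear series: nomad wins
  lin <- data.frame(day = t, nsd = 12 * t + rnorm(365, 0, 5))
  expect_equal(fit_movement_models(lin)$best, "nomad")
  # noiseless migrant curve: parameters recovered within 1%
  truth <- c(delta = 2500, theta = 150, phi = 5, rho = 60, phi2 = 5)
  y <- truth["delta"] / (1 + exp((truth["theta"] - t) / truth["phi"])) -
    truth["delta"] / (1 + exp((truth["theta"] + 2 * truth["phi"] + truth["rho"] +
                                 2 * truth["phi2"] - t) / truth["phi2"]))
  scm <- fit_movement_models(data.frame(day = t, nsd = y))
  expect_equal(scm$best, "migrant")
  est <- scm$fits[["migrant"]]$par
  expect_equal(unname(est[names(truth)]), unname(truth), tolerance = 0.01)
  # the residence bound: an accepted migrant fit never has rho < 30
  expect_gte(est[["rho"]], 30)
  # series too short is refused
  expect_error(fit_movement_models(const[1:100, ]), "need")
})

test_that("reference-point choice is deterministic and favours the pre-migration range", {
  cfg <- sim_config(step_sd_km = 2, migration_distance_km = 40)
  tr <- thin_daily(simulate_track("migrant", cfg, seed = 5))
  s1 <- select_reference_point(tr)
  s2 <- select_reference_point(tr)
  expect_identical(s1$ref_index, s2$ref_index)
  expect_true(s1$scan$best %in% c("migrant", "mixed-migrant"))
  # a track starting mid-migration: a candidate later in the window wins
  tr2y <- thin_daily(simulate_track("migrant", sim_config(step_sd_km = 2,
    migration_distance_km = 40, n_years = 2), seed = 5))
  mid2 <- tr2y; mid2$fixes <- mid2$fixes[152:516, , drop = FALSE]
  sel_mid <- select_reference_point(mid2, candidate_step = 5)
  expect_gt(sel_mid$ref_index, 1)
  expect_equal(sel_mid$scan$best, "migrant")
})

test_that("animal classification maps models and flags switchers", {
  expect_equal(classify_animal(c(`2018` = "migrant", `2019` = "migrant"))$final,
               "migrant")
  cl <- classify_animal(c(`2018` = "migrant", `2019` = "resident"))
  expect_equal(cl$final, "switcher")
  expect_false(cl$included_in_association)
  expect_equal(classify_animal("resident")$final, "resident")
  # disperser/nomad years are excluded from the binary phenotype
  cl2 <- classify_animal(c(`2018` = "nomad", `2019` = "migrant"))
  expect_equal(cl2$final, "migrant")
  expect_true(is.na(cl2$yearly_class[1]))
  expect_equal(classify_animal(c(`2018` = "nomad"))$final, "unclassified")
})

test_that("migration parameters derive from delta, theta and range centroids", {
  fit <- structure(list(model = "migrant",
                        par = c(delta = 2500, theta = 100, phi = 5,
                                rho = 60, phi2 = 5)), class = "nsd_fit")
  p <- migration_params(fit, start_date = as.Date("2018-01-01"))
  expect_equal(p$distance_km, 50)
  expect_equal(p$timing_day, 100)
  # two years averaging
  fit2 <- fit; fit2$par["delta"] <- 3600
  avg <- average_migration_params(list(
    migration_params(fit, as.Date("2018-01-01")),
    migration_params(fit2, as.Date("2019-01-01"))))
  expect_equal(avg$distance_km, 55)
  # latitudinal shift of a 50 km due-north separation ~ +0.45 degrees
  mkrange <- function(cy) {
    structure(list(centroid = c(x = 0, y = cy), area = 1), class = "range_polygon")
  }
  p2 <- migration_params(fit, as.Date("2018-01-01"),
                         ranges = list(summer = mkrange(50), winter = mkrange(0)))
  expect_equal(p2$centroid_distance_km, 50)
  expect_equal(p2$lat_shift_deg, 50 / (6371.0088 * pi / 180), tolerance = 1e-6)
  expect_equal(p2$lat_shift_deg, 0.45, tolerance = 0.01)
  resid_fit <- structure(list(model = "resident", par = c(gamma = 1)),
                         class = "nsd_fit")
  expect_error(migration_params(resid_fit, Sys.Date()), "contract")
})
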