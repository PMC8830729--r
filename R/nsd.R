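#' Net squared displacement series for a track
#'
#' NSD_t is the squared Euclidean distance (km^2) from a reference fix to the
#' fix on day t. Day indices count from the first fix (day 1).
#'
#' @param track a thinned `telemetry_track`
#' @param ref_index index of the reference fix within the track (default 1)
#' @return data.frame with `day` (numeric, from 1), `nsd` (km^2), `date`;
#'   attributes `ref_index` and `start_date`
#' @export
compute_nsd <- function(track, ref_index = 1L) {
  f <- track$fixes
  if (ref_index < 1L || ref_index > nrow(f))
    stopf("input error: reference index %d outside the track", ref_index)
  x0 <- f$x[ref_index]; y0 <- f$y[ref_index]
  day <- as.numeric(difftime(f$timestamp, f$timestamp[1], units = "days")) + 1
  out <- data.frame(day = day, nsd = (f$x - x0)^2 + (f$y - y0)^2,
                    date = as.Date(f$timestamp, tz = "UTC"))
  attr(out, "ref_index") <- ref_index
  attr(out, "start_date") <- as.Date(f$timestamp[1], tz = "UTC")
  out
}

# -- NSD movement-model mean functions ---------------------------------------
# The classification names the classic movement-model family: the migrant
# model is a bell curve (out to the second range and back, with at least
# rho = 30 days of residence there), the mixed-migrant returns to a
# different displacement level, the disperser reaches an asymptote, the
# nomad grows linearly, and the resident fluctuates about a constant.

nsd_mean_fun <- list(
  migrant = function(t, delta, theta, phi, rho, phi2)
    delta / (1 + exp((theta - t) / phi)) -
      delta / (1 + exp((theta + 2 * phi + rho + 2 * phi2 - t) / phi2)),
  `mixed-migrant` = function(t, delta, theta, phi, rho, phi2, delta2)
    delta / (1 + exp((theta - t) / phi)) -
      delta2 / (1 + exp((theta + 2 * phi + rho + 2 * phi2 - t) / phi2)),
  disperser = function(t, delta, theta, phi)
    delta / (1 + exp((theta - t) / phi)),
  nomad = function(t, D) 4 * D * t,
  resident = function(t, gamma) rep(gamma, length(t))
)

nsd_n_par <- c(migrant = 5L, `mixed-migrant` = 6L, disperser = 3L,
               nomad = 1L, resident = 1L)

# Gaussian-RSS AIC with a sigma parameter counted for every model, so AICs
# are comparable across the family: AIC = n log(RSS/n) + 2(k+1).
rss_aic <- function(rss, n, k) n * log(rss / n) + 2 * (k + 1)

nsd_initials <- function(day, nsd) {
  dmax <- max(nsd)
  q95 <- quantile(nsd, 0.95, names = FALSE)
  # day of steepest smoothed rise
  sm <- stats::filter(nsd, rep(1 / 7, 7), sides = 2)
  sm[is.na(sm)] <- nsd[is.na(sm)]
  dif <- diff(sm)
  theta0 <- day[which.max(dif)]
  list(delta = max(q95, 1e-3), theta = max(theta0, min(day) + 5),
       phi = 7, rho = 60, phi2 = 7)
}

fit_one_nsd_model <- function(model, day, nsd) {
  n <- length(nsd)
  ini <- nsd_initials(day, nsd)
  res <- switch(model,
    resident = {
      g <- mean(nsd)
      list(par = c(gamma = g), rss = sum((nsd - g)^2))
    },
    nomad = {
      # least squares through the origin for slope 4D
      s <- sum(day * nsd) / sum(day * day)
      list(par = c(D = s / 4), rss = sum((nsd - s * day)^2))
    },
    {
      # nonlinear models via bounded Levenberg-Marquardt, multi-start
      starts <- switch(model,
        migrant = list(
          with(ini, list(delta = delta, theta = theta, phi = phi, rho = rho, phi2 = phi2)),
          with(ini, list(delta = delta, theta = max(min(day) + 5, theta - 30),
                         phi = 10, rho = 90, phi2 = 10))),
        `mixed-migrant` = list(
          with(ini, list(delta = delta, theta = theta, phi = phi, rho = rho,
                         phi2 = phi2, delta2 = 0.8 * delta)),
          with(ini, list(delta = delta, theta = max(min(day) + 5, theta - 30),
                         phi = 10, rho = 90, phi2 = 10, delta2 = 0.5 * delta))),
        disperser = list(
          with(ini, list(delta = delta, theta = theta, phi = phi)),
          with(ini, list(delta = delta, theta = mean(day), phi = 20))))
      lower <- switch(model,
        migrant = c(delta = 0, theta = min(day), phi = 0.5, rho = 30, phi2 = 0.5),
        `mixed-migrant` = c(delta = 0, theta = min(day), phi = 0.5, rho = 30,
                            phi2 = 0.5, delta2 = 0),
        disperser = c(delta = 0, theta = min(day), phi = 0.5))
      upper <- switch(model,
        migrant = c(delta = Inf, theta = max(day), phi = 100, rho = 365, phi2 = 100),
        `mixed-migrant` = c(delta = Inf, theta = max(day), phi = 100, rho = 365,
                            phi2 = 100, delta2 = Inf),
        disperser = c(delta = Inf, theta = max(day), phi = 200))
      fn <- nsd_mean_fun[[model]]
      resid_fun <- function(p) nsd - do.call(fn, c(list(t = day), as.list(p)))
      best <- NULL
      for (st in starts) {
        fit <- tryCatch(
          minpack.lm::nls.lm(par = unlist(st), lower = lower, upper = upper,
                             fn = resid_fun,
                             control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (is.null(fit) || !is.finite(fit$deviance)) next
        if (is.null(best) || fit$deviance < best$rss)
          best <- list(par = setNames(fit$par, names(st)), rss = fit$deviance)
      }
      best
    })
  if (is.null(res) || !is.finite(res$rss)) return(NULL)
  k <- nsd_n_par[[model]]
  structure(list(model = model, par = res$par, rss = res$rss, n = n,
                 aic = rss_aic(max(res$rss, 1e-12), n, k)),
            class = "nsd_fit")
}

#' @export
print.nsd_fit <- function(x, ...) {
  cat(sprintf("nsd_fit [%s]: AIC %.1f, n = %d\n", x$model, x$aic, x$n))
  print(round(x$par, 3))
  invisible(x)
}

#' @export
coef.nsd_fit <- function(object, ...) object$par

#' Fit the five movement models to an NSD series
#'
#' Nonlinear least squares with Gaussian errors for the migrant,
#' mixed-migrant and disperser shapes (residence time rho bounded at >= 30
#' days for the round-trip models), closed-form least squares for the nomad
#' and resident shapes. AIC = n log(RSS/n) + 2(k+1) is comparable across the
#' family. Models whose optimizer fails are excluded with a warning, never
#' silently classified.
#'
#' @param nsd_series data.frame from [compute_nsd()]
#' @param models subset of model names to fit
#' @param min_days minimum series length (default 360)
#' @return object of class `nsd_scan`: list of `nsd_fit`s, the best model
#'   name, and the AIC table
#' @export
fit_movement_models <- function(nsd_series,
                                models = names(nsd_mean_fun),
                                min_days = 360L) {
  if (nrow(nsd_series) < min_days)
    stopf("input error: NSD series has %d days, need >= %d",
          nrow(nsd_series), min_days)
  fits <- list()
  for (m in models) {
    f <- fit_one_nsd_model(m, nsd_series$day, nsd_series$nsd)
    if (is.null(f)) warnf("model %s failed to converge; excluded", m)
    else fits[[m]] <- f
  }
  if (!length(fits)) stopf("all movement models failed for this series")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  structure(list(fits = fits, best = names(which.min(aics)), aic = aics,
                 ref_index = attr(nsd_series, "ref_index"),
                 start_date = attr(nsd_series, "start_date")),
            class = "nsd_scan")
}

#' @export
print.nsd_scan <- function(x, ...) {
  cat("nsd_scan -- best model:", x$best, "\n")
  print(round(sort(x$aic), 1))
  invisible(x)
}

#' Plot an NSD series with the fitted movement curves
#' @param x an `nsd_scan`
#' @param nsd_series the series it was fitted to
#' @param ... passed to `plot`
#' @export
plot.nsd_scan <- function(x, nsd_series, ...) {
  plot(nsd_series$day, nsd_series$nsd, pch = 16, cex = 0.4, col = "grey40",
       xlab = "day of tracking", ylab = expression(NSD ~ (km^2)), ...)
  cols <- setNames(seq_along(x$fits) + 1, names(x$fits))
  for (m in names(x$fits)) {
    f <- x$fits[[m]]
    yy <- do.call(nsd_mean_fun[[m]], c(list(t = nsd_series$day), as.list(f$par)))
    graphics::lines(nsd_series$day, yy, col = cols[m],
                    lwd = if (m == x$best) 2.5 else 1)
  }
  graphics::legend("topleft", legend = names(x$fits), col = cols, lwd = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Choose the rNSD reference point for one animal-year
#'
#' Candidates are the daily fixes within the first `n_candidate_days` days of
#' the series, stepped by `candidate_step` (step 1 = the exhaustive search).
#' For each candidate all models are fitted and the candidate whose best
#' model attains the lowest AIC wins (ties go to the earliest day).
#'
#' @param track a thinned `telemetry_track`
#' @param n_candidate_days candidate window length in days (default 60)
#' @param candidate_step step through the candidate days (default 5)
#' @param models models to fit
#' @return list: `ref_index`, `scan` (the winning `nsd_scan`), `nsd`
#' @export
select_reference_point <- function(track, n_candidate_days = 60L,
                                   candidate_step = 5L,
                                   models = names(nsd_mean_fun)) {
  f <- track$fixes
  day <- as.numeric(difftime(f$timestamp, f$timestamp[1], units = "days")) + 1
  cand <- which(day <= n_candidate_days)
  cand <- cand[seq(1, length(cand), by = candidate_step)]
  best <- NULL
  for (ci in cand) {
    nsd <- compute_nsd(track, ref_index = ci)
    scan <- tryCatch(suppressWarnings(fit_movement_models(nsd, models = models)),
                     error = function(e) NULL)
    if (is.null(scan)) next
    a <- min(scan$aic)
    if (is.null(best) || a < best$aic - 1e-9) # strict: ties keep earliest
      best <- list(ref_index = ci, scan = scan, nsd = nsd, aic = a)
  }
  if (is.null(best)) stopf("animal-year unclassifiable: all candidates failed")
  best[c("ref_index", "scan", "nsd")]
}

#' Classify an animal from its per-year best movement models
#'
#' Each year's minimum-AIC model is mapped to the binary phenotype
#' (round-trip migrant shapes count as migrant; the resident shape as
#' resident; disperser and nomad years are flagged and excluded from the
#' binary phenotype). Animals whose classified years disagree are switchers
#' and are excluded from association input.
#'
#' @param yearly_best named character vector (or list) of per-year best model
#'   names for one animal
#' @param migrant_models model names mapped to migrant
#' @param resident_models model names mapped to resident
#' @return object of class `migration_classification`: per-year class, final
#'   class (migrant/resident/switcher/unclassified), and an
#'   `included_in_association` flag
#' @export
classify_animal <- function(yearly_best,
                            migrant_models = c("migrant", "mixed-migrant"),
                            resident_models = "resident") {
  yearly_best <- unlist(yearly_best)
  cls <- ifelse(yearly_best %in% migrant_models, "migrant",
                ifelse(yearly_best %in% resident_models, "resident", NA))
  usable <- cls[!is.na(cls)]
  final <- if (!length(usable)) "unclassified"
    else if (all(usable == "migrant")) "migrant"
    else if (all(usable == "resident")) "resident"
    else "switcher"
  structure(list(yearly_model = yearly_best, yearly_class = cls,
                 final = final,
                 included_in_association = final %in% c("migrant", "resident")),
            class = "migration_classification")
}

#' @export
print.migration_classification <- function(x, ...) {
  cat(sprintf("migration_classification: %s (%s association)\n", x$final,
              if (x$included_in_association) "included in" else "excluded from"))
  print(x$yearly_model)
  invisible(x)
}

#' Migration parameters for a migrant animal-year
#'
#' Distance is sqrt(delta) km (delta being the asymptotic NSD); timing is
#' theta converted to a numeric day of year (1 Jan = day 1) using the series
#' start date. The centroid distance between the seasonal 95% isopleths and
#' the latitudinal shift (summer minus winter centroid latitude, by inverse
#' projection) are reported alongside when ranges are supplied. Multi-year
#' values are averaged by [average_migration_params()].
#'
#' @param fit an accepted migrant/mixed-migrant `nsd_fit`
#' @param start_date Date of day 1 of the fitted series
#' @param ranges optional list from [seasonal_overlap()]
#' @param proj_center optional c(lon0, lat0) to unproject centroids
#' @return data.frame: distance_km, timing_day, centroid_distance_km,
#'   lat_shift_deg
#' @export
migration_params <- function(fit, start_date, ranges = NULL,
                             proj_center = NULL) {
  if (!fit$model %in% c("migrant", "mixed-migrant"))
    stopf("contract error: migration_params called on a %s fit", fit$model)
  dist <- sqrt(fit$par[["delta"]])
  timing <- date_to_numeric(as.Date(start_date) + round(fit$par[["theta"]]) - 1)
  cdist <- lat_shift <- NA_real_
  if (!is.null(ranges)) {
    cs <- ranges$summer$centroid; cw <- ranges$winter$centroid
    cdist <- sqrt(sum((cs - cw)^2))
    if (!is.null(proj_center)) {
      lls <- unproject_laea(cs[1], cs[2], proj_center)
      llw <- unproject_laea(cw[1], cw[2], proj_center)
      lat_shift <- lls$lat - llw$lat
    } else {
      # synthetic plane: convert the northing shift to degrees latitude
      lat_shift <- (cs[2] - cw[2]) / (EARTH_RADIUS_KM * pi / 180)
    }
  }
  data.frame(distance_km = dist, timing_day = timing,
             centroid_distance_km = cdist, lat_shift_deg = lat_shift)
}

#' Average migration parameters across years
#' @param params_by_year data.frames from [migration_params()]
#' @return one-row data.frame of arithmetic means
#' @export
average_migration_params <- function(params_by_year) {
  d <- do.call(rbind, params_by_year)
  as.data.frame(t(colMeans(d, na.rm = TRUE)))
}

#' Classify a cohort of tracks end to end
#'
#' For each animal and eligible year: choose the rNSD reference point, fit
#' the movement-model family, take the minimum-AIC model, then combine years
#' with [classify_animal()].
#'
#' @param tracks list of thinned `telemetry_track`s
#' @param max_gap_days NSD screening gap (default 1)
#' @param n_candidate_days,candidate_step reference-point search controls
#' @return data.frame: animal_id, final class, distance_km, timing_day (NA
#'   for non-migrants), plus a list-column-free summary; per-animal details in
#'   attribute `"details"`
#' @export
classify_cohort <- function(tracks, max_gap_days = 1L,
                            n_candidate_days = 60L, candidate_step = 5L) {
  screen <- screen_for_nsd(tracks, max_gap_days = max_gap_days)
  details <- list()
  rows <- list()
  for (tr in tracks) {
    el <- screen[screen$animal_id == tr$animal_id & screen$eligible, ]
    if (!nrow(el)) {
      rows[[tr$animal_id]] <- data.frame(animal_id = tr$animal_id,
                                         class = "ineligible",
                                         distance_km = NA, timing_day = NA)
      next
    }
    yr_best <- character(); params <- list()
    for (y in el$year) {
      days <- as.POSIXlt(as.Date(tr$fixes$timestamp, tz = "UTC"))$year + 1900L
      sub <- tr; sub$fixes <- tr$fixes[days == y, , drop = FALSE]
      sel <- tryCatch(select_reference_point(sub, n_candidate_days,
                                             candidate_step),
                      error = function(e) NULL)
      if (is.null(sel)) next
      yr_best[as.character(y)] <- sel$scan$best
      if (sel$scan$best %in% c("migrant", "mixed-migrant"))
        params[[as.character(y)]] <-
          migration_params(sel$scan$fits[[sel$scan$best]],
                           attr(sel$nsd, "start_date"))
      details[[tr$animal_id]][[as.character(y)]] <- sel$scan
    }
    cl <- classify_animal(yr_best)
    pm <- if (cl$final == "migrant" && length(params))
      average_migration_params(params)
      else data.frame(distance_km = NA, timing_day = NA,
                      centroid_distance_km = NA, lat_shift_deg = NA)
    rows[[tr$animal_id]] <- data.frame(animal_id = tr$animal_id,
                                       class = cl$final,
                                       distance_km = pm$distance_km,
                                       timing_day = pm$timing_day)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}
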