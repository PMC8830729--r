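#' Construct a telemetry track
#'
#' One animal's timestamped positions on a projected plane in km. Fixes are
#' sorted by time; exact duplicate timestamps are collapsed (first kept).
#'
#' @param animal_id id string
#' @param fixes data.frame with columns `timestamp` (POSIXct), `x`, `y` (km)
#' @param crs projection label
#' @return a `telemetry_track`
#' @export
telemetry_track <- function(animal_id, fixes, crs = "synthetic-plane-km") {
  if (!all(c("timestamp", "x", "y") %in% names(fixes)))
    stopf("schema error: fixes need columns timestamp, x, y")
  if (any(!is.finite(fixes$x)) || any(!is.finite(fixes$y)))
    stopf("input error: non-finite coordinates for %s", animal_id)
  fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
  dup <- duplicated(fixes$timestamp)
  if (any(dup)) {
    warnf("%s: %d duplicate timestamp(s) collapsed (first kept)",
          animal_id, sum(dup))
    fixes <- fixes[!dup, , drop = FALSE]
  }
  rownames(fixes) <- NULL
  structure(list(animal_id = animal_id, fixes = fixes, crs = crs),
            class = "telemetry_track")
}

#' @export
print.telemetry_track <- function(x, ...) {
  cat(sprintf("telemetry_track %s: %d fixes, %s to %s [%s]\n", x$animal_id,
              nrow(x$fixes), format(min(x$fixes$timestamp)),
              format(max(x$fixes$timestamp)), x$crs))
  invisible(x)
}

# Spherical Lambert azimuthal equal-area projection, km. One plane centred on
# the dataset centroid keeps inter-animal distances comparable.
EARTH_RADIUS_KM <- 6371.0088

#' Project longitude/latitude to an azimuthal equal-area plane
#'
#' @param lon,lat coordinates in degrees (WGS84, treated spherically)
#' @param center c(lon0, lat0) of the projection; default the centroid
#' @return data.frame with `x`, `y` in km and the center as an attribute
#' @export
project_laea <- function(lon, lat, center = NULL) {
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- center[1] * pi / 180; phi0 <- center[2] * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  kp <- sqrt(2 / denom)
  out <- data.frame(x = EARTH_RADIUS_KM * kp * cos(phi) * sin(lam - lam0),
                    y = EARTH_RADIUS_KM * kp *
                      (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0)))
  attr(out, "center") <- center
  out
}

#' Inverse of [project_laea()]
#' @param x,y projected coordinates in km
#' @param center c(lon0, lat0) used for the forward projection
#' @return data.frame with `lon`, `lat` in degrees
#' @export
unproject_laea <- function(x, y, center) {
  R <- EARTH_RADIUS_KM
  lam0 <- center[1] * pi / 180; phi0 <- center[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  cc <- 2 * asin(pmin(1, rho / (2 * R)))
  phi <- ifelse(rho == 0, phi0,
                asin(cos(cc) * sin(phi0) + y * sin(cc) * cos(phi0) / rho))
  lam <- lam0 + atan2(x * sin(cc),
                      rho * cos(phi0) * cos(cc) - y * sin(phi0) * sin(cc))
  data.frame(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Read a telemetry CSV into per-animal tracks
#'
#' Accepts either projected input (columns `x_km`, `y_km`, `crs`) or
#' geographic input (`longitude`, `latitude`), which is projected onto a
#' single azimuthal equal-area plane centred on the dataset centroid.
#'
#' @param path CSV with columns animal_id, timestamp, and coordinates
#' @return named list of `telemetry_track` objects; geographic input carries
#'   the projection center as attribute `"center"`
#' @export
read_telemetry <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("schema error: missing column(s) %s",
                          paste(miss, collapse = ", "))
  ts <- as.POSIXct(d$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  if (any(is.na(ts)))
    stopf("row-level error: unparseable timestamp at line(s) %s",
          paste(head(which(is.na(ts)) + 1L, 5), collapse = ", "))
  center <- NULL
  if (all(c("x_km", "y_km") %in% names(d))) {
    d$x <- d$x_km; d$y <- d$y_km
    crs <- if ("crs" %in% names(d)) d$crs[1] else "projected-km"
  } else if (all(c("longitude", "latitude") %in% names(d))) {
    pr <- project_laea(d$longitude, d$latitude)
    center <- attr(pr, "center")
    d$x <- pr$x; d$y <- pr$y
    crs <- sprintf("laea-km-center-%.4f-%.4f", center[1], center[2])
  } else {
    stopf("schema error: need x_km/y_km or longitude/latitude columns")
  }
  d$timestamp <- ts
  tracks <- lapply(split(d, d$animal_id), function(dd) {
    telemetry_track(dd$animal_id[1],
                    dd[, c("timestamp", "x", "y")], crs = crs)
  })
  if (!is.null(center)) attr(tracks, "center") <- center
  tracks
}

#' Thin a track to at most one fix per calendar day
#'
#' Keeps the fix nearest 12:00 (track time zone); ties go to the earlier fix.
#' Idempotent, and kept fixes retain their exact coordinates.
#'
#' @param track a `telemetry_track`
#' @return the thinned `telemetry_track`
#' @export
thin_daily <- function(track) {
  f <- track$fixes
  if (!nrow(f)) return(track)
  day <- as.Date(f$timestamp, tz = "UTC")
  lt <- as.POSIXlt(f$timestamp, tz = "UTC")
  secs <- lt$hour * 3600 + lt$min * 60 + lt$sec
  off <- abs(secs - 12 * 3600)
  keep <- unlist(lapply(split(seq_len(nrow(f)), day), function(ii) {
    ii[which.min(off[ii])]        # which.min takes the first = earlier fix
  }), use.names = FALSE)
  track$fixes <- f[sort(keep), , drop = FALSE]
  rownames(track$fixes) <- NULL
  track
}

#' Season windows for seasonal range definition
#'
#' Summer is 1 July--15 September; winter is 1 December--30 April and spans
#' the year boundary (December fixes are keyed to the season-year of the
#' following January--April block so each winter is contiguous under one key).
#'
#' @param fix_dates Date vector
#' @return data.frame with `season` (summer/winter/none) and `season_year`
#' @export
assign_seasons <- function(fix_dates) {
  d <- as.Date(fix_dates)
  lt <- as.POSIXlt(d)
  mo <- lt$mon + 1L; mday <- lt$mday; yr <- lt$year + 1900L
  season <- rep("none", length(d))
  season[(mo == 7) | (mo == 8) | (mo == 9 & mday <= 15)] <- "summer"
  winter <- (mo == 12) | (mo <= 4)
  season[winter] <- "winter"
  season_year <- yr
  season_year[season == "winter" & mo == 12] <- yr[season == "winter" & mo == 12] + 1L
  season_year[season == "none"] <- NA_integer_
  data.frame(season = season, season_year = season_year)
}

#' Screen animal-season-years for overlap (IO) analysis
#'
#' Keeps animal season-years with at least `min_locations` thinned fixes in
#' both summer and winter; animals monitored for less than one year are
#' dropped entirely. Exclusions are reported with reasons.
#'
#' @param tracks list of thinned `telemetry_track`s
#' @param min_locations minimum fixes per season (default 30)
#' @return data.frame: animal_id, season_year, n_summer, n_winter, eligible,
#'   reason
#' @export
screen_for_io <- function(tracks, min_locations = 30L) {
  out <- lapply(tracks, function(tr) {
    f <- tr$fixes
    span_days <- as.numeric(difftime(max(f$timestamp), min(f$timestamp),
                                     units = "days")) + 1
    se <- assign_seasons(as.Date(f$timestamp, tz = "UTC"))
    if (span_days < 365)
      return(data.frame(animal_id = tr$animal_id, season_year = NA_integer_,
                        n_summer = 0L, n_winter = 0L, eligible = FALSE,
                        reason = "monitoring shorter than one year"))
    yrs <- sort(unique(na.omit(se$season_year)))
    do.call(rbind, lapply(yrs, function(y) {
      ns <- sum(se$season == "summer" & se$season_year == y, na.rm = TRUE)
      nw <- sum(se$season == "winter" & se$season_year == y, na.rm = TRUE)
      ok <- ns >= min_locations && nw >= min_locations
      data.frame(animal_id = tr$animal_id, season_year = y,
                 n_summer = ns, n_winter = nw, eligible = ok,
                 reason = if (ok) "" else
                   sprintf("fewer than %d locations in %s", min_locations,
                           paste(c("summer", "winter")[c(ns, nw) < min_locations],
                                 collapse = " and ")))
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screen animal-years for NSD model fitting
#'
#' An animal-year is eligible when its fixes span at least 365 days and no
#' interval between consecutive fixes exceeds `max_gap_days` (default 1:
#' literal daily coverage).
#'
#' @param tracks list of thinned `telemetry_track`s
#' @param max_gap_days maximum allowed day gap between consecutive fixes
#' @return data.frame: animal_id, year, n_fixes, span_days, max_gap, eligible,
#'   reason
#' @export
screen_for_nsd <- function(tracks, max_gap_days = 1L) {
  out <- lapply(tracks, function(tr) {
    days <- as.Date(tr$fixes$timestamp, tz = "UTC")
    yr <- as.POSIXlt(days)$year + 1900L
    do.call(rbind, lapply(sort(unique(yr)), function(y) {
      dd <- sort(days[yr == y])
      span <- as.integer(max(dd) - min(dd)) + 1L
      gap <- if (length(dd) > 1) max(as.integer(diff(dd))) else 0L
      ok <- span >= 365L && gap <= max_gap_days
      data.frame(animal_id = tr$animal_id, year = y, n_fixes = length(dd),
                 span_days = span, max_gap = gap, eligible = ok,
                 reason = if (ok) "" else if (span < 365L)
                   "less than a full year of data" else
                     sprintf("gap of %d days exceeds %d", gap, max_gap_days))
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
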