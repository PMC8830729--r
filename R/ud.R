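#' Estimate a kernel utilization distribution
#'
#' Bivariate Gaussian product-kernel density on a regular grid, with the
#' reference bandwidth h = 0.5 * (sd_x + sd_y) * n^(-1/6) and a cell size of
#' at most h/4. Mass is normalised to 1 over the grid.
#'
#' @param xy data.frame or matrix with columns x, y (km)
#' @param h bandwidth override (km); default the reference bandwidth
#' @param grid optional list(x, y) of cell-center coordinates to evaluate on
#'   (used to put two seasonal UDs on one shared grid)
#' @param pad grid padding in bandwidths beyond the data range
#' @param cell cell size override (km)
#' @return object of class `ud`: grid vectors `x`, `y`, density matrix `z`
#'   (rows = x), bandwidth `h`, cell size `cell`
#' @export
estimate_ud <- function(xy, h = NULL, grid = NULL, pad = 3.5, cell = NULL) {
  xy <- as.data.frame(xy)
  x <- xy[[1]]; y <- xy[[2]]
  n <- length(x)
  if (sd(x) == 0 && sd(y) == 0)
    stopf("degenerate input: all points identical")
  if (is.null(h)) h <- reference_bandwidth(x, y)
  if (is.null(grid)) {
    if (is.null(cell)) cell <- h / 4
    gx <- seq(min(x) - pad * h, max(x) + pad * h, by = cell)
    gy <- seq(min(y) - pad * h, max(y) + pad * h, by = cell)
  } else {
    gx <- grid$x; gy <- grid$y
    cell <- gx[2] - gx[1]
  }
  # f(gx, gy) = (1/n) sum_i K((gx-xi)/h) K((gy-yi)/h) / h^2
  Dx <- dnorm(outer(gx, x, "-") / h) / h
  Dy <- dnorm(outer(gy, y, "-") / h) / h
  z <- (Dx %*% t(Dy)) / n
  mass <- sum(z) * cell^2
  z <- z / mass
  structure(list(x = gx, y = gy, z = z, h = h, cell = cell, n = n),
            class = "ud")
}

#' Reference bandwidth for a bivariate kernel UD
#' @param x,y coordinates
#' @return h = 0.5 * (sd(x) + sd(y)) * n^(-1/6), in the coordinate units
#' @export
reference_bandwidth <- function(x, y) {
  0.5 * (sd(x) + sd(y)) * length(x)^(-1 / 6)
}

#' @export
print.ud <- function(x, ...) {
  cat(sprintf("ud: %d x %d grid, cell %.3f km, h_ref %.3f km, n = %d\n",
              length(x$x), length(x$y), x$cell, x$h, x$n))
  invisible(x)
}

#' Extract an isopleth (home-range contour) from a UD
#'
#' The smallest-density-threshold region whose enclosed probability mass is
#' at least `level`, represented as the set of grid cells above the
#' threshold. Area is the summed cell area (km^2); the centroid is the
#' density-weighted mean of cell centers within the region.
#'
#' @param ud a `ud`
#' @param level probability mass, in (0,1); default 0.95
#' @param season optional label carried through to reports
#' @return object of class `range_polygon`: logical `mask` on the UD grid,
#'   `area` (km^2), `centroid` (km), `threshold`, `polygons`
#'   (grDevices::contourLines output for export/plotting)
#' @export
isopleth <- function(ud, level = 0.95, season = NA_character_) {
  if (!is.finite(level) || level <= 0 || level >= 1)
    stopf("input error: level must lie in (0,1)")
  cellarea <- ud$cell^2
  ord <- order(ud$z, decreasing = TRUE)
  cum <- cumsum(ud$z[ord]) * cellarea
  k <- which(cum >= level)[1]
  thr <- ud$z[ord][k]
  mask <- ud$z >= thr
  area <- sum(mask) * cellarea
  wz <- ud$z * mask
  wsum <- sum(wz)
  centroid <- c(x = sum(outer(ud$x, rep(1, length(ud$y))) * wz) / wsum,
                y = sum(outer(rep(1, length(ud$x)), ud$y) * wz) / wsum)
  polys <- grDevices::contourLines(ud$x, ud$y, ud$z, levels = thr)
  structure(list(season = season, mask = mask, x = ud$x, y = ud$y,
                 cell = ud$cell, area = area, centroid = centroid,
                 threshold = thr, level = level, polygons = polys),
            class = "range_polygon")
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("range_polygon (%s, %.0f%% isopleth): area %.2f km^2, %d part(s)\n",
              x$season, 100 * x$level, x$area, length(x$polygons)))
  invisible(x)
}

#' Index of overlap between two seasonal ranges
#'
#' IO = 2 * A12 / (A1 + A2), where A1 and A2 are the seasonal 95%-isopleth
#' areas and A12 their intersection area. 0 means fully separated ranges
#' (migrant-like); 1 means identical ranges (resident-like). The two ranges
#' must live on the same grid (see [seasonal_overlap()]).
#'
#' @param summer,winter `range_polygon` objects on a shared grid
#' @return IO in [0, 1]
#' @export
compute_io <- function(summer, winter) {
  if (!identical(dim(summer$mask), dim(winter$mask)) ||
      !isTRUE(all.equal(summer$x, winter$x)))
    stopf("input error: ranges must be computed on a shared grid")
  a1 <- summer$area; a2 <- winter$area
  if (a1 + a2 <= 0) stopf("undefined IO: zero total area")
  a12 <- sum(summer$mask & winter$mask) * summer$cell^2
  io_index(a1, a2, a12)
}

#' IO from areas
#' @param a1,a2 seasonal range areas (km^2)
#' @param a12 intersection area (km^2)
#' @return 2*a12/(a1+a2), clipped to [0,1]
#' @export
io_index <- function(a1, a2, a12) {
  if (a1 + a2 <= 0) stopf("undefined IO: zero total area")
  min(1, max(0, 2 * a12 / (a1 + a2)))
}

#' Seasonal ranges and IO for one animal-season-year
#'
#' Estimates summer and winter UDs on one shared grid (covering both point
#' sets, cell size tied to the smaller bandwidth) and returns the two 95%
#' isopleths and their overlap index.
#'
#' @param summer_xy,winter_xy seasonal fix coordinates (data.frame x, y)
#' @param level isopleth level
#' @return list: `summer`, `winter` (`range_polygon`s), `io`
#' @export
seasonal_overlap <- function(summer_xy, winter_xy, level = 0.95) {
  summer_xy <- as.data.frame(summer_xy); winter_xy <- as.data.frame(winter_xy)
  hs <- reference_bandwidth(summer_xy[[1]], summer_xy[[2]])
  hw <- reference_bandwidth(winter_xy[[1]], winter_xy[[2]])
  cell <- min(hs, hw) / 4
  allx <- c(summer_xy[[1]], winter_xy[[1]])
  ally <- c(summer_xy[[2]], winter_xy[[2]])
  pad <- 3.5 * max(hs, hw)
  grid <- list(x = seq(min(allx) - pad, max(allx) + pad, by = cell),
               y = seq(min(ally) - pad, max(ally) + pad, by = cell))
  uds <- estimate_ud(summer_xy, h = hs, grid = grid)
  udw <- estimate_ud(winter_xy, h = hw, grid = grid)
  s <- isopleth(uds, level, season = "summer")
  w <- isopleth(udw, level, season = "winter")
  list(summer = s, winter = w, io = compute_io(s, w))
}
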