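#' Normalize point heights against a digital elevation model
#'
#' Subtracts the bilinearly interpolated DEM elevation from each return's
#' `h` (here raw elevation z). Interpolation is between the four surrounding
#' cell centers, clamped at the DEM border; points outside the DEM extent are
#' dropped and their count reported in a message.
#'
#' @param points `lidar_points` with raw elevations in `h`.
#' @param dem a [raster_grid()] of ground elevations.
#' @return `lidar_points` with normalized heights.
#' @export
normalize_heights <- function(points, dem) {
  stopifnot(inherits(dem, "raster_grid"))
  nx <- ncol(dem$values); ny <- nrow(dem$values); cs <- dem$cellsize
  inside <- points$x >= dem$xll & points$x <= dem$xll + nx * cs &
    points$y >= dem$yll & points$y <= dem$yll + ny * cs
  if (!any(inside)) stop("point extent is disjoint from the DEM extent")
  n_drop <- sum(!inside)
  if (n_drop > 0)
    message(n_drop, " points outside the DEM extent dropped")
  pts <- points[inside, , drop = FALSE]
  gx <- (pts$x - dem$xll) / cs - 0.5
  gy <- (pts$y - dem$yll) / cs - 0.5
  i0 <- pmin(pmax(floor(gx), 0), max(nx - 2, 0))
  j0 <- pmin(pmax(floor(gy), 0), max(ny - 2, 0))
  tx <- pmin(pmax(gx - i0, 0), 1)
  ty <- pmin(pmax(gy - j0, 0), 1)
  v <- dem$values
  idx <- function(j, i) v[cbind(j + 1L, i + 1L)]
  ground <- (1 - tx) * (1 - ty) * idx(j0, i0) +
    tx * (1 - ty) * idx(j0, pmin(i0 + 1, nx - 1)) +
    (1 - tx) * ty * idx(pmin(j0 + 1, ny - 1), i0) +
    tx * ty * idx(pmin(j0 + 1, ny - 1), pmin(i0 + 1, nx - 1))
  pts$h <- pts$h - ground
  lidar_points(as.data.frame(pts), h_tol = Inf)
}

#' Compute the understory-density raster
#'
#' Per cell, the understory density is `100 * n_mid / n_all`, where `n_mid`
#' counts returns with height in the half-open stratum `[low, high)` and
#' `n_all` all returns in the cell. Cells with zero returns carry no value
#' (they are no-data, not 0 percent, and are flagged separately), non-forest
#' cells are masked, and forest cells intersecting a disqualifying management
#' event (clear-cut strictly before LiDAR acquisition, or thinning at any
#' recorded date) are assigned the management no-data flag.
#'
#' @param points `lidar_points` with normalized heights.
#' @param template a [raster_grid()] defining the output grid (12.5 m cells
#'   by default pipeline configuration).
#' @param low,high stratum bounds (m), `low < high`.
#' @param forest_mask logical matrix congruent with the grid (`NULL` = all
#'   forest).
#' @param management_events data frame with columns `xmin`, `xmax`, `ymin`,
#'   `ymax`, `type` (`"clearcut"`/`"thinning"`), `date` (`Date`); may be
#'   empty.
#' @param acquisition_date `Date` of the LiDAR acquisition (needed to judge
#'   clear-cut events).
#' @return An object of class `density_raster`: list with `ud`
#'   ([raster_grid()], `NA` on masked/no-data cells), `forest`, `nodata`
#'   (management-affected), `zero_return` (logical matrices) and `provenance`.
#' @export
understory_density_raster <- function(points, template, low = 0.5, high = 5,
                                      forest_mask = NULL,
                                      management_events = NULL,
                                      acquisition_date = as.Date("2010-09-29")) {
  stopifnot(inherits(template, "raster_grid"), low < high)
  if (nrow(points) == 0L) stop("point set contains no returns")
  ny <- nrow(template$values); nx <- ncol(template$values)
  cs <- template$cellsize
  if (is.null(forest_mask)) forest_mask <- matrix(TRUE, ny, nx)
  stopifnot(all(dim(forest_mask) == c(ny, nx)))

  ix <- floor((points$x - template$xll) / cs) + 1L
  iy <- floor((points$y - template$yll) / cs) + 1L
  ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  cell <- iy[ok] + (ix[ok] - 1L) * ny
  h <- points$h[ok]
  n_all <- tabulate(cell, nbins = ny * nx)
  n_mid <- tabulate(cell[h >= low & h < high], nbins = ny * nx)
  ud <- matrix(ifelse(n_all > 0, 100 * n_mid / pmax(n_all, 1), NA_real_),
               ny, nx)
  zero_return <- matrix(n_all == 0L, ny, nx)

  nodata <- matrix(FALSE, ny, nx)
  if (!is.null(management_events) && nrow(management_events) > 0L) {
    disq <- (management_events$type == "thinning") |
      (management_events$type == "clearcut" &
         as.Date(management_events$date) < as.Date(acquisition_date))
    ev <- management_events[disq, , drop = FALSE]
    xs <- raster_xcoords(template); ys <- raster_ycoords(template)
    for (k in seq_len(nrow(ev))) {
      # a cell intersects the event rectangle if its footprint overlaps it
      ci <- which(xs + cs / 2 > ev$xmin[k] & xs - cs / 2 < ev$xmax[k])
      cj <- which(ys + cs / 2 > ev$ymin[k] & ys - cs / 2 < ev$ymax[k])
      nodata[cj, ci] <- TRUE
    }
  }
  nodata <- nodata & forest_mask
  ud[!forest_mask | nodata] <- NA

  structure(list(
    ud = raster_grid(ud, template$xll, template$yll, cs),
    forest = forest_mask,
    nodata = nodata,
    zero_return = zero_return,
    provenance = list(low = low, high = high,
                      acquisition_date = acquisition_date)
  ), class = "density_raster")
}

#' @export
print.density_raster <- function(x, ...) {
  cat(sprintf("<density_raster> stratum [%g, %g) m; %d forest cells, %d management no-data, %d zero-return\n",
              x$provenance$low, x$provenance$high, sum(x$forest),
              sum(x$nodata), sum(x$zero_return)))
  print(x$ud)
  invisible(x)
}

#' Wrap a density field as a density raster
#'
#' Treats an existing percentage field (e.g. a synthetic scene's true
#' understory field) as a `density_raster` with no management no-data and no
#' zero-return cells, so profile extraction and the scale analysis can run on
#' noise-free ground truth.
#'
#' @param field a [raster_grid()] of densities (percent).
#' @param forest_mask logical matrix congruent with the grid (`NULL` = all
#'   forest).
#' @return A `density_raster`.
#' @export
density_from_field <- function(field, forest_mask = NULL) {
  stopifnot(inherits(field, "raster_grid"))
  ny <- nrow(field$values); nx <- ncol(field$values)
  if (is.null(forest_mask)) forest_mask <- matrix(TRUE, ny, nx)
  stopifnot(all(dim(forest_mask) == c(ny, nx)))
  v <- field$values
  v[!forest_mask] <- NA
  structure(list(
    ud = raster_grid(v, field$xll, field$yll, field$cellsize),
    forest = forest_mask,
    nodata = matrix(FALSE, ny, nx),
    zero_return = matrix(FALSE, ny, nx),
    provenance = list(low = NA_real_, high = NA_real_,
                      acquisition_date = NA)
  ), class = "density_raster")
}

#' Radial summary of understory density around a point
#'
#' Summarizes the density raster over the cells whose centers lie within
#' `radius` of `center`. The mean is taken over valid forest cells (excluding
#' management no-data and zero-return cells); the no-data fraction is the
#' share of management-affected cells among forest member cells, and the
#' summary is invalid when it exceeds `nodata_max`. Forest cover is the share
#' of forest cells among all member cells.
#'
#' @param dr a `density_raster`.
#' @param center `c(x, y)` in metres.
#' @param radius radius in metres (at least one cell size).
#' @param nodata_max maximum tolerated no-data fraction (default 0.05).
#' @return List with `mean_ud`, `forest_cover`, `nodata_fraction`, `valid`,
#'   `n_cells`, and `reason` when degenerate.
#' @export
radial_summary <- function(dr, center, radius, nodata_max = 0.05) {
  stopifnot(inherits(dr, "density_raster"), radius >= dr$ud$cellsize)
  xs <- raster_xcoords(dr$ud); ys <- raster_ycoords(dr$ud)
  ci <- which(abs(xs - center[1]) <= radius)
  cj <- which(abs(ys - center[2]) <= radius)
  if (!length(ci) || !length(cj))
    return(list(mean_ud = NA_real_, forest_cover = NA_real_,
                nodata_fraction = NA_real_, valid = FALSE, n_cells = 0L,
                reason = "no member cells"))
  d2 <- outer((ys[cj] - center[2])^2, (xs[ci] - center[1])^2, "+")
  member <- d2 <= radius^2
  n_member <- sum(member)
  if (n_member == 0L)
    return(list(mean_ud = NA_real_, forest_cover = NA_real_,
                nodata_fraction = NA_real_, valid = FALSE, n_cells = 0L,
                reason = "no member cells"))
  forest <- dr$forest[cj, ci, drop = FALSE][member]
  nodata <- dr$nodata[cj, ci, drop = FALSE][member]
  vals <- dr$ud$values[cj, ci, drop = FALSE][member]
  n_forest <- sum(forest)
  nodata_fraction <- if (n_forest > 0) sum(nodata & forest) / n_forest else NA_real_
  valid <- !is.na(nodata_fraction) && nodata_fraction <= nodata_max
  mean_ud <- if (any(!is.na(vals))) mean(vals, na.rm = TRUE) else NA_real_
  list(mean_ud = mean_ud,
       forest_cover = n_forest / n_member,
       nodata_fraction = nodata_fraction,
       valid = valid && !is.na(mean_ud),
       n_cells = n_member,
       reason = if (n_forest == 0L) "no forest member cells" else NULL)
}

#' Radius schedule for the scale analysis
#'
#' The nest radius plus 100 radii up to the territory border. With
#' `"equal_area"` spacing (default) the territory radii are
#' `territory_radius * sqrt(k / 100)`, `k = 1..100`, so consecutive discs add
#' equal area; with `"linear"` the 101 radii are evenly spaced from the nest
#' radius to the border.
#'
#' @param config a [run_config()].
#' @return Strictly increasing numeric vector of radii (m).
#' @export
default_radii <- function(config) {
  if (config$radius_spacing == "linear") {
    seq(config$nest_radius, config$territory_radius, length.out = 101)
  } else {
    sort(unique(c(config$nest_radius,
                  config$territory_radius * sqrt((1:100) / 100))))
  }
}

#' Multi-radius density profile at a nest
#'
#' Runs [radial_summary()] at every radius of the schedule (by default the
#' nest radius plus 100 radii to the territory border).
#'
#' @param dr a `density_raster`.
#' @param center `c(x, y)`.
#' @param config a [run_config()].
#' @param radii optional explicit radius schedule (overrides the config).
#' @return Data frame (class `scale_profile`) with one row per radius:
#'   `radius`, `mean_ud`, `forest_cover`, `nodata_fraction`, `valid`.
#' @export
radius_series <- function(dr, center, config = run_config(), radii = NULL) {
  if (is.null(radii)) radii <- default_radii(config)
  stopifnot(all(diff(radii) > 0))
  m <- radius_series_core(dr, center, radii, config$nodata_fraction_max)
  res <- as.data.frame(m)
  res$valid <- as.logical(res$valid)
  class(res) <- c("scale_profile", "data.frame")
  res
}

# numeric-matrix core shared with extract_profiles: sorts cells by distance
# once and reads every radius off cumulative sums
radius_series_core <- function(dr, center, radii, nodata_max) {
  nr <- length(radii)
  out <- matrix(NA_real_, nr, 5,
                dimnames = list(NULL, c("radius", "mean_ud", "forest_cover",
                                        "nodata_fraction", "valid")))
  out[, "radius"] <- radii
  out[, "valid"] <- 0
  rmax <- max(radii)
  xs <- raster_xcoords(dr$ud); ys <- raster_ycoords(dr$ud)
  ci <- which(abs(xs - center[1]) <= rmax)
  cj <- which(abs(ys - center[2]) <= rmax)
  if (!length(ci) || !length(cj)) return(out)
  d2 <- outer((ys[cj] - center[2])^2, (xs[ci] - center[1])^2, "+")
  ord <- order(d2)
  d_sorted <- sqrt(d2[ord])
  f <- as.numeric(dr$forest[cj, ci, drop = FALSE][ord])
  nd <- as.numeric((dr$nodata[cj, ci, drop = FALSE] &
                      dr$forest[cj, ci, drop = FALSE])[ord])
  v <- dr$ud$values[cj, ci, drop = FALSE][ord]
  v_ok <- !is.na(v)
  cs_n <- seq_along(d_sorted)
  cs_f <- cumsum(f)
  cs_nd <- cumsum(nd)
  cs_v <- cumsum(ifelse(v_ok, v, 0))
  cs_vn <- cumsum(v_ok)
  pos <- findInterval(radii, d_sorted)       # cells with distance <= radius
  nz <- pos > 0L
  n_member <- pos[nz]
  n_forest <- cs_f[n_member]
  n_nodata <- cs_nd[n_member]
  n_val <- cs_vn[n_member]
  out[nz, "forest_cover"] <- n_forest / n_member
  out[nz, "nodata_fraction"] <- ifelse(n_forest > 0, n_nodata / n_forest,
                                       NA_real_)
  out[nz, "mean_ud"] <- ifelse(n_val > 0, cs_v[n_member] / pmax(n_val, 1),
                               NA_real_)
  out[, "valid"] <- as.numeric(!is.na(out[, "nodata_fraction"]) &
                                 out[, "nodata_fraction"] <= nodata_max &
                                 !is.na(out[, "mean_ud"]))
  out
}

#' Extract density profiles for a nest table
#'
#' @param dr a `density_raster`.
#' @param nests nest data frame with `id`, `x`, `y`.
#' @param config a [run_config()].
#' @param radii optional explicit radius schedule.
#' @return Long data frame: one row per nest x radius.
#' @export
extract_profiles <- function(dr, nests, config = run_config(), radii = NULL) {
  if (is.null(radii)) radii <- default_radii(config)
  stopifnot(all(diff(radii) > 0))
  n <- nrow(nests)
  mats <- vector("list", n)
  for (i in seq_len(n))
    mats[[i]] <- radius_series_core(dr, c(nests$x[i], nests$y[i]), radii,
                                    config$nodata_fraction_max)
  m <- do.call(rbind, mats)
  data.frame(id = rep(nests$id, each = length(radii)),
             radius = m[, "radius"], mean_ud = m[, "mean_ud"],
             forest_cover = m[, "forest_cover"],
             nodata_fraction = m[, "nodata_fraction"],
             valid = as.logical(m[, "valid"]),
             stringsAsFactors = FALSE)
}
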