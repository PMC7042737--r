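#' Pipeline run configuration
#'
#' Bundles the fixed constants of the analysis: grid resolution, the
#' understory height stratum, the territory and nest radii, the no-data
#' tolerance for radial summaries, the breakpoint candidate grid and the
#' default close/far threshold.
#'
#' @param grid_cell_size raster cell edge (m); 12.5 m is the Swedish forestry
#'   map standard.
#' @param understory_low,understory_high height stratum bounds (m) defining
#'   understory returns; the stratum is half-open `[low, high)`.
#' @param territory_radius radius (m) of the largest nest-centred summary
#'   (territory border).
#' @param nest_radius radius (m) of the nest-level summary (GPS uncertainty).
#' @param nodata_fraction_max maximum tolerated fraction of management no-data
#'   cells within a radius before the summary is invalidated.
#' @param breakpoint_grid numeric `c(min, max, step)` (m) of candidate
#'   close/far breakpoints.
#' @param close_threshold default close/far threshold (m) when no scan is run.
#' @param radius_spacing `"equal_area"` (default) spaces the 100 territory
#'   radii so consecutive discs add equal area; `"linear"` spaces them evenly
#'   between the nest radius and the territory border.
#' @param log_floor percentage floor applied to understory density before
#'   taking logs (zero densities are floored, not dropped).
#' @param seed integer seed recorded with the run.
#' @return An object of class `run_config` (named list).
#' @export
run_config <- function(grid_cell_size = 12.5,
                       understory_low = 0.5,
                       understory_high = 5,
                       territory_radius = 460,
                       nest_radius = 15,
                       nodata_fraction_max = 0.05,
                       breakpoint_grid = c(500, 3500, 50),
                       close_threshold = 1500,
                       radius_spacing = c("equal_area", "linear"),
                       log_floor = 0.1,
                       seed = 1L) {
  radius_spacing <- match.arg(radius_spacing)
  lengths <- c(grid_cell_size, understory_high, territory_radius, nest_radius,
               close_threshold)
  stopifnot(all(is.finite(lengths)), all(lengths > 0),
            understory_low < understory_high, understory_low >= 0,
            nodata_fraction_max >= 0, nodata_fraction_max <= 1,
            length(breakpoint_grid) == 3L, breakpoint_grid[1] > 0,
            breakpoint_grid[2] >= breakpoint_grid[1], breakpoint_grid[3] > 0,
            log_floor > 0)
  structure(list(grid_cell_size = grid_cell_size,
                 understory_low = understory_low,
                 understory_high = understory_high,
                 territory_radius = territory_radius,
                 nest_radius = nest_radius,
                 nodata_fraction_max = nodata_fraction_max,
                 breakpoint_grid = breakpoint_grid,
                 close_threshold = close_threshold,
                 radius_spacing = radius_spacing,
                 log_floor = log_floor,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm,
                                   paste(x[[nm]], collapse = " ")))
  invisible(x)
}

#' Read a point cloud
#'
#' Reads height-normalized LiDAR returns from whitespace-separated XYZ text
#' (columns x, y, h; extra columns ignored; `#` comment lines skipped).
#' Binary LAS/LAZ is not supported by this package; convert to XYZ text first
#' (e.g. with `las2txt` or PDAL).
#'
#' @param path input file.
#' @param format `"xyz"` (whitespace text). `"las"` raises an error.
#' @return A data frame of class `lidar_points` with columns `x`, `y`, `h`.
#' @export
read_point_cloud <- function(path, format = c("xyz", "las")) {
  format <- match.arg(format)
  if (format == "las")
    stop("LAS/LAZ input is not supported; convert the tile to XYZ text ",
         "(x y h columns) and use format = \"xyz\"")
  if (!file.exists(path)) stop("point cloud file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    warning("empty point cloud file: ", path)
    return(lidar_points(data.frame(x = numeric(), y = numeric(),
                                   h = numeric())))
  }
  toks <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(toks)
  if (any(ncols < 3L))
    stop("row ", line_no[which(ncols < 3L)[1]],
         ": fewer than 3 columns (need x y h)")
  xyz <- vapply(toks, function(tk) suppressWarnings(as.numeric(tk[1:3])),
                numeric(3))
  bad <- which(colSums(is.na(xyz)) > 0L)
  if (length(bad))
    stop("row ", line_no[bad[1]], ": non-numeric coordinate ‘",
         paste(toks[[bad[1]]][1:3], collapse = " "), "’")
  lidar_points(data.frame(x = xyz[1, ], y = xyz[2, ], h = xyz[3, ]))
}

lidar_points <- function(df, h_tol = 0.2) {
  stopifnot(all(c("x", "y", "h") %in% names(df)))
  if (nrow(df) && any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$h)))
    stop("non-finite coordinates in point set")
  n_neg <- sum(df$h < -h_tol)
  if (n_neg > 0)
    warning(n_neg, " returns with normalized height below -", h_tol,
            " m (beyond DEM-noise tolerance)")
  class(df) <- c("lidar_points", "data.frame")
  df
}

#' @rdname read_point_cloud
#' @param points a `lidar_points` data frame.
#' @export
write_point_cloud <- function(points, path) {
  stopifnot(all(c("x", "y", "h") %in% names(points)))
  lines <- sprintf("%s %s %s",
                   formatC(points$x, digits = 17, format = "g"),
                   formatC(points$y, digits = 17, format = "g"),
                   formatC(points$h, digits = 17, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

nest_required_cols <- c("id", "x", "y", "year", "breeder_f", "breeder_m",
                        "success", "renest_flag", "treated_flag", "area")

#' Read a nest/breeding-event table
#'
#' One row per breeding event. Required columns: `id`, `x`, `y`, `year`,
#' `breeder_f`, `breeder_m`, `success` (strictly 0/1), `renest_flag`,
#' `treated_flag`, `area` (`managed`/`unmanaged`). Flags may be 0/1 or
#' logical; missing flag values are treated as `FALSE`.
#'
#' @param path CSV file.
#' @return A data frame with one record per row.
#' @export
read_nest_table <- function(path) {
  if (!file.exists(path)) stop("nest table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(nest_required_cols, names(df))
  if (length(miss))
    stop("nest table is missing required columns: ",
         paste(miss, collapse = ", "))
  if (!all(df$success %in% c(0, 1)))
    stop("column 'success' must be coded 0/1 (found: ",
         paste(utils::head(unique(df$success[!df$success %in% c(0, 1)]), 3),
               collapse = ", "), ")")
  df$success <- as.integer(df$success)
  for (fl in c("renest_flag", "treated_flag")) {
    v <- df[[fl]]
    if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "1")
    v <- as.logical(v)
    v[is.na(v)] <- FALSE
    df[[fl]] <- v
  }
  df
}

#' @rdname read_nest_table
#' @param nests nest data frame.
#' @export
write_nest_table <- function(nests, path) {
  utils::write.csv(nests, path, row.names = FALSE)
  invisible(path)
}

#' Read settlement points
#'
#' Accepts either a CSV with `x`, `y` columns or a GeoJSON
#' FeatureCollection/GeometryCollection of Point geometries.
#'
#' @param path `.csv` or `.geojson`/`.json` file.
#' @return Data frame with columns `x`, `y`.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("points file not found: ", path)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    coords <- NULL
    if (identical(gj$type, "FeatureCollection")) {
      coords <- lapply(gj$features, function(f) f$geometry$coordinates)
    } else if (identical(gj$type, "GeometryCollection")) {
      coords <- lapply(gj$geometries, function(g) g$coordinates)
    } else stop("unsupported GeoJSON type: ", gj$type)
    xy <- do.call(rbind, lapply(coords, function(co)
      c(as.numeric(co[[1]]), as.numeric(co[[2]]))))
    return(data.frame(x = xy[, 1], y = xy[, 2]))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("points CSV needs 'x' and 'y' columns")
  df[, c("x", "y")]
}

#' @rdname read_points
#' @param points data frame with `x`, `y`.
#' @export
write_points_geojson <- function(points, path) {
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
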