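#' Regular grid raster
#'
#' A minimal single-band raster on a regular square grid in a projected metric
#' coordinate system. Values are stored as a matrix with `nrow(values)` rows
#' (y, bottom row first) and `ncol(values)` columns (x); `NA` marks no-data
#' cells. The grid origin is the lower-left corner and cells are half-open
#' `[x0, x0 + cell)` x `[y0, y0 + cell)`, addressed by their centers.
#'
#' @param values numeric matrix, row 1 = southernmost row.
#' @param xll,yll coordinates (m) of the lower-left corner of the grid.
#' @param cellsize cell edge length in metres; must be positive.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L, cellsize > 0,
            is.finite(xll), is.finite(yll))
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cellsize, x$xll, x$yll))
  cat(sprintf("  values: [%s, %s], %d no-data cells\n",
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE))),
              sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell-center coordinates of a raster
#'
#' @param r a [raster_grid()].
#' @return For `raster_xcoords`/`raster_ycoords`, the vector of column/row
#'   center coordinates. For `raster_cell_centers`, a two-column matrix with
#'   one row per cell in column-major (matrix) order.
#' @export
raster_xcoords <- function(r) r$xll + (seq_len(ncol(r$values)) - 0.5) * r$cellsize

#' @rdname raster_xcoords
#' @export
raster_ycoords <- function(r) r$yll + (seq_len(nrow(r$values)) - 0.5) * r$cellsize

#' @rdname raster_xcoords
#' @export
raster_cell_centers <- function(r) {
  xs <- raster_xcoords(r); ys <- raster_ycoords(r)
  cbind(x = rep(xs, each = length(ys)), y = rep(ys, times = length(xs)))
}

same_grid <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    a$cellsize == b$cellsize && a$xll == b$xll && a$yll == b$yll
}

#' Read an ESRI ASCII grid
#'
#' Reads a single-band raster in ESRI ASCII grid format (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `nodata_value` header
#' followed by rows of values, northernmost row first). Coordinates must be in
#' a projected metric system; a cell size below 0.01 is taken as evidence of
#' geographic (degree) coordinates and rejected.
#'
#' @param path path to the `.asc` file.
#' @return A [raster_grid()]; no-data cells are `NA`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("malformed ASCII grid header; missing: ",
                         paste(miss, collapse = ", "))
  if (hdr$cellsize < 0.01)
    stop("cell size ", hdr$cellsize, " suggests geographic (degree) ",
         "coordinates; reproject to a projected metric CRS first")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop("expected ", nc * nr, " values, found ", length(vals))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  # file rows run north -> south; flip to bottom-row-first storage
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  raster_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the doubles bit-exactly.
#'
#' @param r a [raster_grid()].
#' @param path output path.
#' @param nodata_value sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path, nodata_value = -9999) {
  stopifnot(inherits(r, "raster_grid"))
  v <- r$values
  if (any(!is.na(v) & v == nodata_value))
    stop("a data value equals nodata_value (", nodata_value, ")")
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", formatC(r$xll, digits = 17, format = "g")),
    paste("yllcorner", formatC(r$yll, digits = 17, format = "g")),
    paste("cellsize", formatC(r$cellsize, digits = 17, format = "g")),
    paste("nodata_value", formatC(nodata_value, digits = 17, format = "g"))
  )
  flipped <- v[nr:1, , drop = FALSE]
  flipped[is.na(flipped)] <- nodata_value
  body <- apply(flipped, 1L, function(row)
    paste(formatC(row, digits = 17, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Min-max normalization of a raster
#'
#' Rescales values to `[0, 1]` via `z = (x - min) / (max - min)`, computed
#' over valid (non-`NA`) cells; `NA` cells are preserved.
#'
#' @param r a [raster_grid()].
#' @return A [raster_grid()] with values in `[0, 1]`.
#' @export
minmax_normalize <- function(r) {
  stopifnot(inherits(r, "raster_grid"))
  v <- r$values
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1])) stop("raster has no valid cells")
  if (rng[1] == rng[2])
    stop("constant raster: min-max normalization is undefined")
  raster_grid((v - rng[1]) / (rng[2] - rng[1]),
              xll = r$xll, yll = r$yll, cellsize = r$cellsize)
}

#' Aggregate a fine raster to a coarse grid
#'
#' Each coarse cell takes the mean of the fine cells whose centers fall inside
#' it. `NA` fine cells are omitted from the mean; a coarse cell is `NA` only
#' when every contributing fine cell is `NA` (or none falls inside).
#'
#' @param fine a fine-resolution [raster_grid()].
#' @param coarse_cellsize coarse cell edge (m); need not divide the extent.
#' @return A coarse [raster_grid()] anchored at the same lower-left corner.
#' @export
aggregate_to_coarse <- function(fine, coarse_cellsize) {
  stopifnot(inherits(fine, "raster_grid"), coarse_cellsize >= fine$cellsize)
  cc <- raster_cell_centers(fine)
  ci <- floor((cc[, "x"] - fine$xll) / coarse_cellsize)
  cj <- floor((cc[, "y"] - fine$yll) / coarse_cellsize)
  nxc <- max(ci) + 1L; nyc <- max(cj) + 1L
  idx <- cj + ci * nyc + 1L
  v <- as.vector(fine$values)
  ok <- !is.na(v)
  sums <- numeric(nxc * nyc); cnts <- numeric(nxc * nyc)
  sums[] <- rowsum_safe(v[ok], idx[ok], nxc * nyc)
  cnts[] <- rowsum_safe(rep(1, sum(ok)), idx[ok], nxc * nyc)
  out <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  raster_grid(matrix(out, nrow = nyc, ncol = nxc),
              xll = fine$xll, yll = fine$yll, cellsize = coarse_cellsize)
}

# sum x by integer group index into a vector of length n
rowsum_safe <- function(x, g, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, g)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Distance-to-nearest-settlement raster
#'
#' Euclidean distance (m) from every cell center to the nearest settlement
#' point.
#'
#' @param settlements data frame with numeric `x`, `y` columns.
#' @param template a [raster_grid()] defining the output grid.
#' @return A [raster_grid()] of distances.
#' @export
distance_raster <- function(settlements, template) {
  stopifnot(inherits(template, "raster_grid"))
  if (is.null(settlements) || nrow(settlements) == 0L)
    stop("settlement set is empty")
  cc <- raster_cell_centers(template)
  d2 <- rep(Inf, nrow(cc))
  for (k in seq_len(nrow(settlements))) {
    dk <- (cc[, "x"] - settlements$x[k])^2 + (cc[, "y"] - settlements$y[k])^2
    d2 <- pmin(d2, dk)
  }
  raster_grid(matrix(sqrt(d2), nrow = nrow(template$values)),
              xll = template$xll, yll = template$yll,
              cellsize = template$cellsize)
}

#' Neighborhood mean of a raster
#'
#' Focal mean over the cells whose centers lie within `radius` of each target
#' cell center (the target cell always belongs). `NA` neighbours are omitted;
#' the result is `NA` where no valid neighbour exists.
#'
#' @param r a [raster_grid()].
#' @param radius neighbourhood radius in metres.
#' @return A [raster_grid()] of local means.
#' @export
neighborhood_mean <- function(r, radius) {
  stopifnot(inherits(r, "raster_grid"), radius >= 0)
  cs <- r$cellsize
  k <- floor(radius / cs)
  offs <- expand.grid(di = -k:k, dj = -k:k)
  offs <- offs[sqrt((offs$di * cs)^2 + (offs$dj * cs)^2) <= radius, ,
               drop = FALSE]
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  sums <- matrix(0, nr, nc); cnts <- matrix(0, nr, nc)
  for (o in seq_len(nrow(offs))) {
    di <- offs$dj[o]; dj <- offs$di[o]  # dj along columns (x), di along rows (y)
    src_r <- seq_len(nr) + di; src_c <- seq_len(nc) + dj
    ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
    shifted <- matrix(NA_real_, nr, nc)
    shifted[ok_r, ok_c] <- v[src_r[ok_r], src_c[ok_c]]
    good <- !is.na(shifted)
    sums[good] <- sums[good] + shifted[good]
    cnts <- cnts + good
  }
  out <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  raster_grid(out, xll = r$xll, yll = r$yll, cellsize = cs)
}
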