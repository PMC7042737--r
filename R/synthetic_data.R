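#' Default generating truth for synthetic scenes
#'
#' Fixed-effect coefficients of the breeding-success model (intercept,
#' unmanaged-area contrast, close-to-settlement contrast, log understory
#' density slope, close x log-density interaction), variance components of the
#' crossed random intercepts (year, female breeder, male breeder), the
#' occurrence-vs-distance logistic coefficients of the nest predator proxy,
#' and the true close/far breakpoint (m).
#'
#' @param beta named numeric length 5.
#' @param sigma2 named numeric length 3 (all `>= 0`).
#' @param jay_alpha intercept and per-metre slope of the predator occurrence
#'   logistic.
#' @param breakpoint true settlement-distance breakpoint (m).
#' @return A list of class `scene_truth`.
#' @export
scene_truth <- function(beta = c(intercept = 0.24, area = -0.52,
                                 close = 1.04, logud = 0.40,
                                 interaction = -1.57),
                        sigma2 = c(year = 0.5, breeder_f = 0.5,
                                   breeder_m = 0.5),
                        jay_alpha = c(3.948, -0.003),
                        breakpoint = 1450) {
  stopifnot(length(beta) == 5L, length(sigma2) == 3L, all(sigma2 >= 0),
            length(jay_alpha) == 2L, breakpoint > 0)
  names(beta) <- c("intercept", "area", "close", "logud", "interaction")
  names(sigma2) <- c("year", "breeder_f", "breeder_m")
  structure(list(beta = beta, sigma2 = sigma2, jay_alpha = jay_alpha,
                 breakpoint = breakpoint), class = "scene_truth")
}

# independent per-stage RNG streams: deterministic small hash of (seed, stage)
stream_seed <- function(seed, stage) {
  cp <- utf8ToInt(stage)
  h <- sum(cp * seq_along(cp)) %% 100003L
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483629)
}

# separable gaussian smoothing with circular boundary (keeps the field
# stationary so edge cells have the same marginal variance)
smooth_field <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  kernel_for <- function(n) {
    half <- min(max(1L, ceiling(3 * sigma_cells)), floor((n - 1) / 2))
    k <- stats::dnorm(-half:half, sd = sigma_cells)
    k / sum(k)
  }
  conv_cols <- function(mat, k) {
    out <- apply(mat, 2, function(col)
      as.numeric(stats::filter(col, k, circular = TRUE)))
    matrix(out, nrow = nrow(mat))
  }
  sm <- conv_cols(m, kernel_for(nrow(m)))
  t(conv_cols(t(sm), kernel_for(ncol(m))))
}

#' Generate a synthetic landscape scene
#'
#' Builds a spatially autocorrelated understory-density field (smoothed
#' Gaussian noise rescaled to a target mean/SD, clipped to 0-100 percent), a
#' forest mask from a second smoothed field, settlements from a homogeneous
#' Poisson process, a managed/unmanaged split line, and optionally a set of
#' rectangular management events in the managed area.
#'
#' @param extent `c(width, height)` in metres (>= 1 km2).
#' @param config a [run_config()].
#' @param seed integer; all stages derive independent streams from it.
#' @param corr_range smoothing range of the understory field (m).
#' @param mean_ud,sd_ud target mean and SD of the density field (percent).
#' @param settlement_intensity settlements per km2.
#' @param forest_fraction approximate fraction of forest cells.
#' @param managed_fraction fraction of the x-extent assigned to the managed
#'   area (west side).
#' @param n_events number of rectangular management (thinning) events drawn in
#'   the managed area.
#' @param truth a [scene_truth()].
#' @return A list of class `scene` with elements `ud` ([raster_grid()],
#'   percent), `forest` (logical matrix), `settlements` (data frame),
#'   `management_events` (data frame), `split_x`, `extent`, `truth`, `config`.
#' @export
generate_landscape <- function(extent = c(5000, 5000), config = run_config(),
                               seed = config$seed, corr_range = 100,
                               mean_ud = 13, sd_ud = 6,
                               settlement_intensity = 0.05,
                               forest_fraction = 0.85,
                               managed_fraction = 53 / 83,
                               n_events = 0,
                               truth = scene_truth()) {
  stopifnot(length(extent) == 2L, all(extent > 0))
  if (prod(extent) < 1e6) stop("extent must cover at least 1 km^2")
  cs <- config$grid_cell_size
  nx <- ceiling(extent[1] / cs); ny <- ceiling(extent[2] / cs)

  set.seed(stream_seed(seed, "landscape_field"))
  z <- smooth_field(matrix(stats::rnorm(ny * nx), ny, nx), corr_range / cs)
  z <- (z - mean(z)) / stats::sd(z)
  ud <- mean_ud + sd_ud * z
  ud[ud < 0] <- 0
  ud[ud > 100] <- 100

  set.seed(stream_seed(seed, "landscape_forest"))
  zf <- smooth_field(matrix(stats::rnorm(ny * nx), ny, nx), 2 * corr_range / cs)
  forest <- zf <= stats::quantile(zf, forest_fraction)

  set.seed(stream_seed(seed, "landscape_settlements"))
  area_km2 <- prod(extent) / 1e6
  n_set <- stats::rpois(1, settlement_intensity * area_km2)
  settlements <- data.frame(x = stats::runif(n_set, 0, extent[1]),
                            y = stats::runif(n_set, 0, extent[2]))

  split_x <- managed_fraction * extent[1]

  set.seed(stream_seed(seed, "landscape_events"))
  events <- if (n_events > 0) {
    w <- stats::runif(n_events, 50, 200)
    h <- stats::runif(n_events, 50, 200)
    x0 <- stats::runif(n_events, 0, max(split_x - w, 1))
    y0 <- stats::runif(n_events, 0, extent[2] - h)
    data.frame(xmin = x0, xmax = x0 + w, ymin = y0, ymax = y0 + h,
               type = sample(c("thinning", "clearcut"), n_events, TRUE),
               date = as.Date("2005-01-01") +
                 sample.int(4000, n_events, TRUE))
  } else {
    data.frame(xmin = numeric(), xmax = numeric(), ymin = numeric(),
               ymax = numeric(), type = character(), date = as.Date(character()))
  }

  structure(list(
    ud = raster_grid(ud, 0, 0, cs),
    forest = forest,
    settlements = settlements,
    management_events = events,
    split_x = split_x,
    extent = extent,
    truth = truth,
    config = config
  ), class = "scene")
}

#' Simulate a LiDAR point cloud over a scene
#'
#' Per cell, the total number of returns is Poisson with mean
#' `pulse_density * cellsize^2`; each return is an understory return
#' (height uniform on the understory stratum) with probability `field / 100`,
#' otherwise a ground return (below the stratum) with probability
#' `ground_fraction` or a canopy return (above it). Return positions are
#' uniform within the cell.
#'
#' @param scene a `scene` from [generate_landscape()].
#' @param pulse_density returns per m2 (0.1-10).
#' @param ground_fraction fraction of non-understory returns below the
#'   stratum.
#' @param seed integer.
#' @return A `lidar_points` data frame.
#' @export
generate_point_cloud <- function(scene, pulse_density = 0.75,
                                 ground_fraction = 0.2,
                                 seed = scene$config$seed) {
  stopifnot(pulse_density >= 0.1, pulse_density <= 10,
            ground_fraction >= 0, ground_fraction <= 1)
  r <- scene$ud
  if (!all(dim(r$values) == dim(scene$forest)))
    stop("understory field and forest mask grids do not match")
  cs <- r$cellsize
  cfg <- scene$config
  set.seed(stream_seed(seed, "point_cloud"))
  ncell <- length(r$values)
  n_tot <- stats::rpois(ncell, pulse_density * cs^2)
  total <- sum(n_tot)
  cell <- rep.int(seq_len(ncell), n_tot)
  p_und <- as.vector(r$values)[cell] / 100
  is_und <- stats::runif(total) < p_und
  is_gnd <- !is_und & (stats::runif(total) < ground_fraction)
  h <- numeric(total)
  h[is_und] <- stats::runif(sum(is_und), cfg$understory_low,
                            cfg$understory_high)
  h[is_gnd] <- stats::runif(sum(is_gnd), 0, cfg$understory_low)
  can <- !is_und & !is_gnd
  h[can] <- stats::runif(sum(can), cfg$understory_high, 20)
  ny <- nrow(r$values)
  iy <- (cell - 1L) %% ny; ix <- (cell - 1L) %/% ny
  x <- r$xll + (ix + stats::runif(total)) * cs
  y <- r$yll + (iy + stats::runif(total)) * cs
  lidar_points(data.frame(x = x, y = y, h = h))
}

#' Simulate breeding events on a scene
#'
#' Territories are fixed forest locations observed over `n_years` breeding
#' seasons; each breeder identity persists to the next year with probability
#' `pair_persistence`, inducing the crossed repeated-measures structure. The
#' linear predictor follows the generating truth: intercept + unmanaged-area
#' contrast + close contrast + log-density slope + close x log-density
#' interaction, plus year and both-breeder random intercepts; success is
#' Bernoulli through the logit link. The density covariate is the scene's
#' true field averaged over the nest-radius neighbourhood.
#'
#' @param scene a `scene`.
#' @param n_nests total breeding events to return.
#' @param n_years number of breeding seasons.
#' @param pair_persistence yearly persistence probability of each breeder.
#' @param seed integer.
#' @param n_renest,n_treated number of rows flagged as renesting attempts /
#'   experimentally treated breeders (for exercising the cohort filters).
#' @return A nest data frame (one row per breeding event) with the generating
#'   covariates, including the realized `dist_settlement` and true `ud_nest`.
#' @export
generate_nests <- function(scene, n_nests = 235, n_years = 10,
                           pair_persistence = 0.7,
                           seed = scene$config$seed,
                           n_renest = 0, n_treated = 0) {
  stopifnot(n_nests >= 1, n_years >= 1)
  truth <- scene$truth
  cfg <- scene$config
  forest_idx <- which(scene$forest)
  if (!length(forest_idx)) stop("scene has no forest cells to place nests on")
  set.seed(stream_seed(seed, "nests"))
  n_terr <- ceiling(n_nests / n_years)
  cells <- sample(forest_idx, n_terr, replace = n_terr > length(forest_idx))
  ny <- nrow(scene$ud$values)
  tx <- scene$ud$xll + ((cells - 1L) %/% ny + stats::runif(n_terr)) *
    cfg$grid_cell_size
  ty <- scene$ud$yll + ((cells - 1L) %% ny + stats::runif(n_terr)) *
    cfg$grid_cell_size

  # breeder identities: geometric persistence, independent per sex
  id_counter <- 0L
  make_ids <- function() {
    ids <- matrix(NA_integer_, n_terr, n_years)
    for (tt in seq_len(n_terr)) {
      for (yy in seq_len(n_years)) {
        if (yy == 1L || stats::runif(1) > pair_persistence) {
          id_counter <<- id_counter + 1L
          ids[tt, yy] <- id_counter
        } else ids[tt, yy] <- ids[tt, yy - 1L]
      }
    }
    ids
  }
  idf <- make_ids(); idm <- make_ids()

  grid <- expand.grid(terr = seq_len(n_terr), year = seq_len(n_years))
  grid <- grid[sample.int(nrow(grid), n_nests), , drop = FALSE]

  nests <- data.frame(
    id = sprintf("nest_%04d", seq_len(n_nests)),
    x = tx[grid$terr], y = ty[grid$terr],
    year = 1997L + grid$year,
    breeder_f = sprintf("F%04d", idf[cbind(grid$terr, grid$year)]),
    breeder_m = sprintf("M%04d", idm[cbind(grid$terr, grid$year)]),
    area = ifelse(tx[grid$terr] < scene$split_x, "managed", "unmanaged"),
    stringsAsFactors = FALSE
  )
  # same membership rule as the density-profile extraction: mean of the true
  # field over cells whose centers lie within the nest radius of the nest
  nests$ud_nest <- radial_mean_field(scene$ud, nests$x, nests$y,
                                     cfg$nest_radius)
  nests <- distance_to_settlements(nests, scene$settlements)

  u_year <- stats::rnorm(n_years, 0, sqrt(truth$sigma2["year"]))
  u_f <- stats::rnorm(id_counter, 0, sqrt(truth$sigma2["breeder_f"]))
  u_m <- stats::rnorm(id_counter, 0, sqrt(truth$sigma2["breeder_m"]))
  b <- truth$beta
  close <- as.numeric(nests$dist_settlement < truth$breakpoint)
  lud <- log(pmax(nests$ud_nest, cfg$log_floor))
  eta <- b["intercept"] + b["area"] * (nests$area == "unmanaged") +
    b["close"] * close + b["logud"] * lud +
    b["interaction"] * close * lud +
    u_year[grid$year] +
    u_f[idf[cbind(grid$terr, grid$year)]] +
    u_m[idm[cbind(grid$terr, grid$year)]]
  nests$success <- stats::rbinom(n_nests, 1, stats::plogis(eta))

  nests$renest_flag <- FALSE
  nests$treated_flag <- FALSE
  flag <- sample.int(n_nests, min(n_nests, n_renest + n_treated))
  if (n_renest > 0) nests$renest_flag[flag[seq_len(n_renest)]] <- TRUE
  if (n_treated > 0)
    nests$treated_flag[flag[n_renest + seq_len(min(n_treated,
                                            length(flag) - n_renest))]] <- TRUE
  nests
}

# mean of a raster over cells whose centers fall within `radius` of (x, y)
radial_mean_field <- function(r, x, y, radius) {
  xs <- raster_xcoords(r); ys <- raster_ycoords(r)
  vapply(seq_along(x), function(i) {
    ci <- which(abs(xs - x[i]) <= radius)
    cj <- which(abs(ys - y[i]) <= radius)
    if (!length(ci) || !length(cj)) return(NA_real_)
    d2 <- outer((ys[cj] - y[i])^2, (xs[ci] - x[i])^2, "+")
    v <- r$values[cj, ci, drop = FALSE][d2 <= radius^2]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

# raster value at arbitrary coordinates (cell membership, half-open cells)
raster_value_at <- function(r, x, y) {
  ix <- floor((x - r$xll) / r$cellsize) + 1L
  iy <- floor((y - r$yll) / r$cellsize) + 1L
  ok <- ix >= 1L & ix <= ncol(r$values) & iy >= 1L & iy <= nrow(r$values)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(iy[ok], ix[ok])]
  out
}

#' Simulate nest-predator occurrence observations
#'
#' Presence/absence of the predator near nests as a Bernoulli draw from a
#' logistic curve in the distance to the nearest settlement; distances are
#' resampled from the scene's nest-to-settlement distances.
#'
#' @param scene a `scene`.
#' @param nests a nest table with `dist_settlement` (default: a fresh draw).
#' @param n_obs number of observation bouts.
#' @param seed integer.
#' @return Data frame with columns `distance` (m) and `presence` (0/1).
#' @export
generate_jay_observations <- function(scene, nests = NULL, n_obs = 200,
                                      seed = scene$config$seed) {
  if (n_obs < 10) warning("n_obs < 10: occurrence fit will be unstable")
  if (is.null(nests))
    nests <- generate_nests(scene, n_nests = max(n_obs, 50), seed = seed)
  set.seed(stream_seed(seed, "jay_obs"))
  d <- sample(nests$dist_settlement, n_obs, replace = TRUE) *
    stats::runif(n_obs, 0.95, 1.05)
  a <- scene$truth$jay_alpha
  presence <- stats::rbinom(n_obs, 1, stats::plogis(a[1] + a[2] * d))
  data.frame(distance = d, presence = presence)
}

#' True breeding-success suitability raster of a scene
#'
#' Per-cell success probability from the generating fixed effects (random
#' effects at zero), with non-forest cells set to zero — the landscape-level
#' quantity the fitted model is later asked to reproduce.
#'
#' @param scene a `scene`.
#' @return A [raster_grid()] of probabilities.
#' @export
true_suitability <- function(scene) {
  cfg <- scene$config
  truth <- scene$truth
  ud <- neighborhood_mean(scene$ud, cfg$nest_radius)
  dist <- distance_raster(scene$settlements, scene$ud)
  b <- truth$beta
  close <- dist$values < truth$breakpoint
  lud <- log(pmax(ud$values, cfg$log_floor))
  xs <- raster_xcoords(scene$ud)
  unman <- matrix(rep(xs >= scene$split_x, each = nrow(scene$ud$values)),
                  nrow(scene$ud$values))
  eta <- b["intercept"] + b["area"] * unman + b["close"] * close +
    b["logud"] * lud + b["interaction"] * close * lud
  p <- stats::plogis(eta)
  p[!scene$forest] <- 0
  raster_grid(p, scene$ud$xll, scene$ud$yll, cfg$grid_cell_size)
}

#' Per-cell management-status mask of a scene
#'
#' Logical matrix (congruent with the scene grid) marking cells east of the
#' managed/unmanaged split line as unmanaged.
#'
#' @param scene a `scene`.
#' @return Logical matrix, `TRUE` for unmanaged cells.
#' @export
scene_unmanaged_mask <- function(scene) {
  xs <- raster_xcoords(scene$ud)
  matrix(rep(xs >= scene$split_x, each = nrow(scene$ud$values)),
         nrow(scene$ud$values))
}

#' Simulate a coarse occurrence-probability raster
#'
#' Emulates an independent occurrence map for validation: block means of a
#' fine suitability raster on a coarse grid, plus Gaussian noise and an
#' optional additive bias field, clipped to `[0, 1]`.
#'
#' @param scene a `scene` (provides the RNG stream).
#' @param suitability fine [raster_grid()] of probabilities (e.g.
#'   [true_suitability()]).
#' @param coarse_cell coarse cell size (m).
#' @param noise_sd SD of the additive Gaussian noise.
#' @param bias_field optional coarse [raster_grid()] (or matrix congruent with
#'   the coarse grid) added before clipping.
#' @param seed integer.
#' @return A coarse [raster_grid()] with values in `[0, 1]`.
#' @export
generate_occurrence_raster <- function(scene, suitability, coarse_cell = 2000,
                                       noise_sd = 0.05, bias_field = NULL,
                                       seed = scene$config$seed) {
  coarse <- aggregate_to_coarse(suitability, coarse_cell)
  set.seed(stream_seed(seed, "occurrence"))
  v <- coarse$values + stats::rnorm(length(coarse$values), 0, noise_sd)
  if (!is.null(bias_field)) {
    bm <- if (inherits(bias_field, "raster_grid")) bias_field$values
          else bias_field
    if (!all(dim(bm) == dim(coarse$values)))
      stop("bias_field grid is not congruent with the coarse grid")
    v <- v + bm
  }
  v <- pmin(1, pmax(0, v))
  v[is.na(coarse$values)] <- NA
  raster_grid(matrix(v, nrow(coarse$values)), coarse$xll, coarse$yll,
              coarse$cellsize)
}
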