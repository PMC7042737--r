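# Fixture builders shared across the test files. Everything is generated in
# code under fixed seeds; no data files are read from disk.

# direct simulator of breeding records from the generating model, without a
# spatial scene: fast path for the mixed-model contracts
sim_glmm_data <- function(n, truth = scene_truth(), n_years = 16,
                          persistence = 0.7, seed = 1,
                          dist_range = c(300, 2800)) {
  set.seed(seed)
  n_terr <- max(2L, ceiling(n / n_years))
  terr <- sample.int(n_terr, n, TRUE)
  yr <- sample.int(n_years, n, TRUE)
  dist <- stats::runif(n_terr, dist_range[1], dist_range[2])[terr]
  ud <- pmin(60, pmax(0.5, stats::rlnorm(n, log(12), 0.5)))
  make_ids <- function() {
    m <- matrix(0L, n_terr, n_years); id <- 0L
    for (tt in seq_len(n_terr)) {
      for (yy in seq_len(n_years)) {
        if (yy == 1L || stats::runif(1) > persistence) {
          id <- id + 1L; m[tt, yy] <- id
        } else m[tt, yy] <- m[tt, yy - 1L]
      }
    }
    m
  }
  mf <- make_ids(); mm <- make_ids()
  b <- truth$beta; s2 <- truth$sigma2
  uy <- stats::rnorm(n_years, 0, sqrt(s2["year"]))
  uf <- stats::rnorm(max(mf), 0, sqrt(s2["breeder_f"]))
  um <- stats::rnorm(max(mm), 0, sqrt(s2["breeder_m"]))
  unman <- stats::rbinom(n_terr, 1, 0.35)[terr]
  close <- as.numeric(dist < truth$breakpoint)
  lud <- log(pmax(ud, 0.1))
  eta <- b["intercept"] + b["area"] * unman + b["close"] * close +
    b["logud"] * lud + b["interaction"] * close * lud +
    uy[yr] + uf[mf[cbind(terr, yr)]] + um[mm[cbind(terr, yr)]]
  data.frame(id = sprintf("n%05d", seq_len(n)),
             success = stats::rbinom(n, 1, stats::plogis(eta)),
             area = ifelse(unman == 1, "unmanaged", "managed"),
             dist_settlement = dist, ud_nest = ud, year = 1997L + yr,
             breeder_f = sprintf("F%d", mf[cbind(terr, yr)]),
             breeder_m = sprintf("M%d", mm[cbind(terr, yr)]),
             stringsAsFactors = FALSE)
}

# small scene with enough settlements for close/far contrasts
tiny_scene <- function(seed = 1, extent = c(2000, 2000), ...) {
  generate_landscape(extent = extent, config = run_config(),
                     seed = seed, settlement_intensity = 1, ...)
}

# density_raster taken directly from a scene's true field (no LiDAR sampling
# noise); forest mask from the scene, no management events
density_from_scene <- function(scene) {
  density_from_field(scene$ud, scene$forest)
}

# brute-force understory density: per-cell double loop over all returns
brute_force_density <- function(points, template, low = 0.5, high = 5) {
  ny <- nrow(template$values); nx <- ncol(template$values)
  cs <- template$cellsize
  out <- matrix(NA_real_, ny, nx)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      x0 <- template$xll + (i - 1) * cs; y0 <- template$yll + (j - 1) * cs
      inc <- points$x >= x0 & points$x < x0 + cs &
        points$y >= y0 & points$y < y0 + cs
      n_all <- sum(inc)
      if (n_all > 0)
        out[j, i] <- 100 * sum(inc & points$h >= low & points$h < high) / n_all
    }
  }
  out
}

random_cloud <- function(seed, n = 400, extent = 100) {
  set.seed(seed)
  data.frame(x = runif(n, 0, extent), y = runif(n, 0, extent),
             h = runif(n, 0, 12))
}

quiet_fit <- function(...) suppressWarnings(suppressMessages(fit_glmm(...)))
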