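test_that("height normalization matches an independent bilinear interpolation", {
  dem_flat <- raster_grid(matrix(100, 5, 5), cellsize = 10)
  pts <- data.frame(x = 25, y = 25, h = 103)
  expect_equal(normalize_heights(pts, dem_flat)$h, 3)

  set.seed(3)
  dem <- raster_grid(matrix(rnorm(20 * 20, 100, 5), 20, 20), cellsize = 10)
  # point exactly on a DEM node (cell center) takes the node value
  expect_equal(normalize_heights(data.frame(x = 35, y = 55, h = 0), dem)$h,
               -dem$values[6, 4])

  pts <- data.frame(x = runif(1000, 5, 195), y = runif(1000, 5, 195),
                    h = runif(1000, 90, 130))
  got <- normalize_heights(pts, dem)$h
  # second implementation: scalar loop over the four surrounding centers
  want <- vapply(seq_len(1000), function(i) {
    gx <- pts$x[i] / 10 - 0.5; gy <- pts$y[i] / 10 - 0.5
    i0 <- min(max(floor(gx), 0), 18); j0 <- min(max(floor(gy), 0), 18)
    tx <- gx - i0; ty <- gy - j0
    v <- dem$values
    g <- (1 - tx) * (1 - ty) * v[j0 + 1, i0 + 1] +
      tx * (1 - ty) * v[j0 + 1, i0 + 2] +
      (1 - tx) * ty * v[j0 + 2, i0 + 1] + tx * ty * v[j0 + 2, i0 + 2]
    pts$h[i] - g
  }, numeric(1))
  expect_lt(max(abs(got - want)), 1e-9)

  expect_error(normalize_heights(data.frame(x = 1e6, y = 1e6, h = 0), dem),
               "disjoint")
  expect_message(normalize_heights(rbind(pts[1:3, ],
                                         data.frame(x = -50, y = 0, h = 0)),
                                   dem), "1 points outside")
})

test_that("understory density follows its counting definition", {
  tpl <- raster_grid(matrix(0, 1, 1), cellsize = 10)
  pts <- data.frame(x = rep(5, 4), y = rep(5, 4), h = c(0.2, 0.7, 3.0, 6.0))
  expect_equal(understory_density_raster(pts, tpl)$ud$values[1, 1], 50)
  high <- data.frame(x = rep(5, 3), y = rep(5, 3), h = c(5, 7, 19))
  expect_equal(understory_density_raster(high, tpl)$ud$values[1, 1], 0)
  # stratum is half-open: h = 5 is canopy, h = 0.5 is understory
  edge <- data.frame(x = rep(5, 2), y = rep(5, 2), h = c(0.5, 5))
  expect_equal(understory_density_raster(edge, tpl)$ud$values[1, 1], 50)
  expect_error(understory_density_raster(pts[0, ], tpl), "no returns")
})

test_that("density raster equals brute-force counting and is order-invariant", {
  tpl <- raster_grid(matrix(0, 8, 8), cellsize = 12.5)
  pts <- random_cloud(19, n = 600)
  dr <- understory_density_raster(pts, tpl)
  expect_identical(dr$ud$values, brute_force_density(pts, tpl))
  shuffled <- pts[sample.int(nrow(pts)), ]
  expect_identical(understory_density_raster(shuffled, tpl)$ud$values,
                   dr$ud$values)
  doubled <- rbind(pts, pts)
  expect_identical(understory_density_raster(doubled, tpl)$ud$values,
                   dr$ud$values)
})

test_that("stratum fractions sum to 100 percent per cell", {
  tpl <- raster_grid(matrix(0, 6, 6), cellsize = 20)
  pts <- random_cloud(23, n = 2000, extent = 120)
  mid <- understory_density_raster(pts, tpl, low = 0.5, high = 5)$ud$values
  below <- understory_density_raster(pts, tpl, low = -1, high = 0.5)$ud$values
  above <- understory_density_raster(pts, tpl, low = 5, high = 1e6)$ud$values
  expect_equal(mid + below + above,
               matrix(100, 6, 6), tolerance = 1e-9)
})

test_that("masking rules: zero-return, non-forest and management no-data", {
  tpl <- raster_grid(matrix(0, 4, 4), cellsize = 10)
  pts <- data.frame(x = c(5, 15), y = c(5, 5), h = c(1, 1))
  forest <- matrix(TRUE, 4, 4); forest[4, 4] <- FALSE
  ev <- data.frame(xmin = 20, xmax = 30, ymin = 0, ymax = 10,
                   type = c("thinning"), date = as.Date("2012-05-01"))
  dr <- understory_density_raster(pts, tpl, forest_mask = forest,
                                  management_events = ev,
                                  acquisition_date = as.Date("2010-09-29"))
  expect_true(dr$zero_return[2, 2])          # no returns: no-data, not 0
  expect_true(is.na(dr$ud$values[2, 2]))
  expect_true(dr$nodata[1, 3])               # thinning at any date disqualifies
  expect_true(is.na(dr$ud$values[4, 4]))     # non-forest masked
  # clear-cut after acquisition does NOT disqualify
  ev2 <- data.frame(xmin = 0, xmax = 10, ymin = 0, ymax = 10,
                    type = "clearcut", date = as.Date("2012-01-01"))
  dr2 <- understory_density_raster(pts, tpl, management_events = ev2,
                                   acquisition_date = as.Date("2010-09-29"))
  expect_false(dr2$nodata[1, 1])
  expect_equal(dr2$ud$values[1, 1], 100)
  ev3 <- ev2; ev3$date <- as.Date("2009-01-01")
  dr3 <- understory_density_raster(pts, tpl, management_events = ev3,
                                   acquisition_date = as.Date("2010-09-29"))
  expect_true(dr3$nodata[1, 1])
})

test_that("radial summaries honour the 5 percent no-data rule", {
  sc <- tiny_scene(seed = 3)
  dr <- density_from_scene(sc)
  dr$ud$values[] <- 20; dr$forest[] <- TRUE
  rs <- radial_summary(dr, c(1000, 1000), 100)
  expect_equal(rs$mean_ud, 20)
  expect_equal(rs$forest_cover, 1)
  expect_true(rs$valid)

  # 2 management no-data cells among ~30 member forest cells: >5 percent
  xs <- raster_xcoords(dr$ud); ys <- raster_ycoords(dr$ud)
  d2 <- outer((ys - 1000)^2, (xs - 1000)^2, "+")
  members <- which(d2 <= 38^2)
  rs30 <- radial_summary(dr, c(1000, 1000), 38)
  expect_equal(rs30$n_cells, length(members))
  dr2 <- dr
  dr2$nodata[members[1:2]] <- TRUE
  dr2$ud$values[members[1:2]] <- NA
  rs2 <- radial_summary(dr2, c(1000, 1000), 38)
  expect_gt(rs2$nodata_fraction, 0.05)
  expect_false(rs2$valid)
  # exactly one of 29 (3.4%) stays valid
  dr3 <- dr
  dr3$nodata[members[1]] <- TRUE; dr3$ud$values[members[1]] <- NA
  expect_true(radial_summary(dr3, c(1000, 1000), 38)$valid)
})

test_that("radial mean matches a brute-force loop over all cells", {
  sc <- tiny_scene(seed = 29)
  dr <- density_from_scene(sc)
  center <- c(987, 1103); radius <- 80
  rs <- radial_summary(dr, center, radius)
  xs <- raster_xcoords(dr$ud); ys <- raster_ycoords(dr$ud)
  acc <- c(); nf <- 0L; nm <- 0L
  for (i in seq_along(xs)) for (j in seq_along(ys)) {
    if ((xs[i] - center[1])^2 + (ys[j] - center[2])^2 <= radius^2) {
      nm <- nm + 1L
      if (dr$forest[j, i]) { nf <- nf + 1L; acc <- c(acc, dr$ud$values[j, i]) }
    }
  }
  expect_equal(rs$mean_ud, mean(acc, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(rs$forest_cover, nf / nm, tolerance = 1e-12)
})

test_that("the radius schedule spans nest radius to territory border", {
  cfg <- run_config()
  radii <- default_radii(cfg)
  expect_equal(length(radii), 101L)
  expect_equal(radii[1], 15)
  expect_equal(max(radii), 460)
  expect_true(all(diff(radii) > 0))
  lin <- default_radii(run_config(radius_spacing = "linear"))
  expect_equal(length(lin), 101L)
  expect_equal(range(lin), c(15, 460))

  sc <- tiny_scene(seed = 43)
  dr <- density_from_scene(sc)
  dr$ud$values[] <- 20; dr$forest[] <- TRUE
  prof <- radius_series(dr, c(1000, 1000), cfg)
  expect_s3_class(prof, "scale_profile")
  expect_equal(nrow(prof), 101L)
  expect_equal(unique(prof$mean_ud), 20)  # uniform raster: constant profile

  # field increasing with distance from the center: mean increases in radius
  xs <- raster_xcoords(dr$ud); ys <- raster_ycoords(dr$ud)
  dr$ud$values <- sqrt(outer((ys - 1000)^2, (xs - 1000)^2, "+"))
  mono <- radius_series(dr, c(1000, 1000), cfg)
  expect_true(all(diff(mono$mean_ud) > 0))
})
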