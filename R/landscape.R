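#' Observed nesting ranges of understory density
#'
#' Per proximity class, the range of understory densities observed at actual
#' nests. Landscape predictions outside the class-specific range are masked
#' to zero (sites never chosen for nesting cannot yield a success).
#'
#' @param records nest data frame with `proximity` and the density covariate.
#' @param ud_col density column name.
#' @return List with `close = c(min, max)` and `far = c(min, max)` (percent).
#' @export
nesting_ranges <- function(records, ud_col = "ud_nest") {
  stopifnot(!is.null(records$proximity), ud_col %in% names(records))
  ud <- records[[ud_col]]
  list(close = range(ud[records$proximity == "close"], na.rm = TRUE),
       far = range(ud[records$proximity == "far"], na.rm = TRUE))
}

#' Predict breeding-success suitability over a landscape
#'
#' Evaluates the fitted model's fixed effects (random effects at zero,
#' population-level prediction; study-area term at a configurable reference
#' level) for every grid cell, from the neighbourhood-mean understory density
#' and the distance to the nearest settlement. Predictions are set to zero
#' for non-forest cells and for cells whose density lies outside the
#' proximity-specific nesting range; cells with no density value stay
#' no-data.
#'
#' @param fit a `glmm_fit` (log, linear or quadratic transform).
#' @param ud_raster [raster_grid()] of neighbourhood-mean density (percent).
#' @param dist_raster [raster_grid()] of distance to nearest settlement (m),
#'   congruent with `ud_raster`.
#' @param forest_mask logical matrix congruent with the grids.
#' @param ranges nesting ranges from [nesting_ranges()].
#' @param breakpoint close/far threshold (m); defaults to the fit's.
#' @param area_level reference study-area level applied to every cell when no
#'   per-cell assignment is given.
#' @param unmanaged_mask optional logical matrix (congruent with the grids)
#'   marking unmanaged cells; overrides `area_level` cell by cell.
#' @return A [raster_grid()] of predicted success probabilities.
#' @export
predict_suitability <- function(fit, ud_raster, dist_raster, forest_mask,
                                ranges, breakpoint = fit$breakpoint,
                                area_level = c("managed", "unmanaged"),
                                unmanaged_mask = NULL) {
  stopifnot(inherits(fit, "glmm_fit"), inherits(ud_raster, "raster_grid"),
            same_grid(ud_raster, dist_raster),
            all(dim(forest_mask) == dim(ud_raster$values)))
  if (!fit$converged) stop("refusing to predict from a non-converged fit")
  if (length(fit$convergence_messages))
    warning("fit carries convergence diagnostics: ",
            paste(fit$convergence_messages, collapse = "; "))
  if (is.null(breakpoint)) stop("no breakpoint available for prediction")
  area_level <- match.arg(area_level)

  ud <- as.vector(ud_raster$values)
  dist <- as.vector(dist_raster$values)
  ok <- !is.na(ud)
  area_cell <- if (is.null(unmanaged_mask)) {
    rep(area_level, sum(ok))
  } else {
    stopifnot(all(dim(unmanaged_mask) == dim(ud_raster$values)))
    ifelse(as.vector(unmanaged_mask)[ok], "unmanaged", "managed")
  }
  newdata <- data.frame(
    area = factor(area_cell, levels = c("managed", "unmanaged")),
    proximity = factor(ifelse(dist[ok] < breakpoint, "close", "far"),
                       levels = c("far", "close")),
    ud = ud[ok]
  )
  newdata$lud <- log(pmax(newdata$ud, fit$log_floor))
  if (fit$include_forest_cover) newdata$forest_cover <- 1
  tt <- stats::delete.response(stats::terms(lme4::nobars(
    stats::formula(fit$model))))
  X <- stats::model.matrix(tt, newdata)
  eta <- as.vector(X %*% lme4::fixef(fit$model))
  p <- rep(NA_real_, length(ud))
  p[ok] <- stats::plogis(eta)

  in_range <- rep(FALSE, length(ud))
  close <- !is.na(dist) & dist < breakpoint
  in_range[ok & close] <- ud[ok & close] >= ranges$close[1] &
    ud[ok & close] <= ranges$close[2]
  in_range[ok & !close] <- ud[ok & !close] >= ranges$far[1] &
    ud[ok & !close] <= ranges$far[2]
  p[ok & !in_range] <- 0
  p[as.vector(!forest_mask)] <- 0

  raster_grid(matrix(p, nrow(ud_raster$values)), ud_raster$xll,
              ud_raster$yll, ud_raster$cellsize)
}

#' Compare predicted and observed occurrence rasters
#'
#' Both coarse rasters are min-max normalized to `[0, 1]` and subtracted,
#' `diff = occurrence - prediction` (negative values mean breeding success is
#' overestimated relative to occurrence). The Pearson product-moment
#' correlation is computed on the non-normalized values over jointly valid
#' cells. Optional region labels yield per-region summaries of the
#' difference.
#'
#' @param pred coarse predicted-suitability [raster_grid()].
#' @param occ coarse occurrence [raster_grid()], congruent with `pred`.
#' @param regions optional matrix (character/integer) of region labels,
#'   congruent with the coarse grids.
#' @return List with `diff` ([raster_grid()]), `ppmc`, `n_valid`,
#'   `region_summaries` (per-region mean and quantiles of the difference),
#'   and `note` when the correlation is undefined.
#' @export
compare_maps <- function(pred, occ, regions = NULL) {
  stopifnot(inherits(pred, "raster_grid"), inherits(occ, "raster_grid"))
  if (!same_grid(pred, occ)) stop("coarse grids are not congruent")
  valid <- !is.na(pred$values) & !is.na(occ$values)
  if (sum(valid) < 3L) stop("fewer than 3 jointly valid coarse cells")
  note <- NULL
  pv <- pred$values[valid]; ov <- occ$values[valid]
  if (stats::sd(pv) == 0 || stats::sd(ov) == 0) {
    ppmc <- NA_real_
    note <- "zero variance in a raster: correlation undefined"
  } else {
    ppmc <- stats::cor(pv, ov)
  }
  mask <- function(r) {
    v <- r$values; v[!valid] <- NA
    raster_grid(v, r$xll, r$yll, r$cellsize)
  }
  dv <- if (is.na(ppmc) && !is.null(note)) {
    # a constant raster cannot be min-max normalized: difference undefined
    matrix(NA_real_, nrow(pred$values), ncol(pred$values))
  } else {
    minmax_normalize(mask(occ))$values - minmax_normalize(mask(pred))$values
  }
  diff <- raster_grid(dv, pred$xll, pred$yll, pred$cellsize)

  region_summaries <- NULL
  if (!is.null(regions)) {
    stopifnot(all(dim(regions) == dim(pred$values)))
    labs <- unique(stats::na.omit(as.vector(regions[valid])))
    region_summaries <- do.call(rbind, lapply(labs, function(lb) {
      dd <- dv[valid & regions == lb]
      qs <- stats::quantile(dd, c(0.05, 0.25, 0.5, 0.75, 0.95), na.rm = TRUE)
      data.frame(region = lb, n = sum(!is.na(dd)), mean = mean(dd, na.rm = TRUE),
                 q05 = qs[1], q25 = qs[2], median = qs[3], q75 = qs[4],
                 q95 = qs[5], row.names = NULL)
    }))
  }
  list(diff = diff, ppmc = ppmc, n_valid = sum(valid),
       region_summaries = region_summaries, note = note)
}
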