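#' Scale-of-effect profile of the breeding-success model
#'
#' Refits the breeding-success GLMM once per radius, replacing the nest-level
#' density covariate by the mean understory density within that radius and
#' adding the forest cover within the radius as a fixed effect (at every
#' radius, including the nest radius, for comparability). Only nests with a
#' valid summary at every radius enter (complete-profile subset), so `n` is
#' constant across radii. The settlement-proximity term is identical across
#' radii. Alongside the marginal R2, the Pearson correlation between the
#' radius-level and nest-level densities is recorded, to separate a genuine
#' scale of effect from mere spatial autocorrelation of the metric.
#'
#' @param nests nest data frame with `success`, `area`, `dist_settlement`,
#'   `year`, `breeder_f`, `breeder_m`.
#' @param profiles long profile table from [extract_profiles()] (`id`,
#'   `radius`, `mean_ud`, `forest_cover`, `valid`).
#' @param breakpoint close/far threshold (m).
#' @param method passed to [fit_glmm()]; defaults to the fast screening
#'   approximation.
#' @param ... passed to [fit_glmm()].
#' @return An object of class `scale_result`: data frame with one row per
#'   radius (`radius`, `r2_marginal`, `cor_nest`, `aicc`, `n`), plus
#'   attributes `n_complete` and `n_dropped`.
#' @export
scale_profile <- function(nests, profiles, breakpoint, method = "pirls",
                          ...) {
  radii <- sort(unique(profiles$radius))
  ok_ids <- tapply(profiles$valid, profiles$id, all)
  complete <- names(ok_ids)[ok_ids]
  n_dropped <- sum(!ok_ids)
  if (n_dropped > 0)
    message(n_dropped, " nests without a valid summary at every radius dropped")
  if (length(complete) < 50)
    warning("fewer than 50 complete-profile nests: R2 profile will be unstable")
  nests <- nests[nests$id %in% complete, , drop = FALSE]
  prof <- profiles[profiles$id %in% complete, , drop = FALSE]

  nest_r <- min(radii)
  ud_nest <- prof$mean_ud[prof$radius == nest_r][
    match(nests$id, prof$id[prof$radius == nest_r])]

  rows <- lapply(radii, function(r) {
    sub <- prof[prof$radius == r, , drop = FALSE]
    m <- match(nests$id, sub$id)
    dat <- nests
    dat$ud_r <- sub$mean_ud[m]
    dat$forest_cover <- sub$forest_cover[m]
    fit <- fit_glmm(dat, breakpoint = breakpoint, ud_col = "ud_r",
                    include_forest_cover = TRUE, method = method, ...)
    data.frame(radius = r, r2_marginal = fit$r2_marginal,
               cor_nest = stats::cor(dat$ud_r, ud_nest),
               aicc = fit$aicc, n = fit$n)
  })
  res <- do.call(rbind, rows)
  attr(res, "n_complete") <- length(complete)
  attr(res, "n_dropped") <- n_dropped
  class(res) <- c("scale_result", "data.frame")
  res
}

#' Effective radius band of the understory effect
#'
#' Operationalizes the visual judgement of the scale-of-effect profile: the
#' largest contiguous radius band, starting at the nest radius, within which
#' the marginal R2 stays at or above `retention` times its maximum over the
#' profile. Radii whose density correlates less than `cor_min` with the
#' nest-level density are excluded from the band regardless of R2 (they can
#' no longer be attributed to the nest-scale effect).
#'
#' @param result a `scale_result` from [scale_profile()].
#' @param retention fraction of the maximum marginal R2 to retain (default
#'   0.9; always reported with the band).
#' @param cor_min minimum correlation with the nest-level density.
#' @return List with `band = c(min, max)` radii (m), `retention`, `cor_min`,
#'   and the `threshold` R2 used.
#' @export
effective_band <- function(result, retention = 0.9, cor_min = 0.5) {
  stopifnot(inherits(result, "scale_result"), retention > 0, retention <= 1)
  res <- result[order(result$radius), ]
  thr <- retention * max(res$r2_marginal)
  # an undefined correlation (constant density) cannot trigger the bound
  ok <- res$r2_marginal >= thr &
    (is.na(res$cor_nest) | res$cor_nest >= cor_min)
  if (!ok[1])
    return(list(band = c(res$radius[1], res$radius[1]), retention = retention,
                cor_min = cor_min, threshold = thr))
  last <- if (all(ok)) length(ok) else which(!ok)[1] - 1L
  list(band = c(res$radius[1], res$radius[last]), retention = retention,
       cor_min = cor_min, threshold = thr)
}
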