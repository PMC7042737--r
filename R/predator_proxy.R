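#' Fit the predator occurrence-vs-distance logistic
#'
#' Maximum-likelihood logistic regression of predator presence near nests on
#' the distance to the nearest human settlement, with Wald standard errors.
#' Complete separation is detected (fitted probabilities all within 1e-8 of
#' 0/1) and flagged; the fit is still returned so a switch distance can be
#' derived from the separating threshold.
#'
#' @param observations data frame with numeric `distance` (m) and `presence`
#'   (0/1).
#' @return An object of class `occurrence_fit`: coefficients `alpha0`,
#'   `alpha1` with SEs, slope p-value, covariance matrix, log-likelihoods,
#'   `separation` flag and the underlying `glm` object.
#' @export
fit_occurrence <- function(observations) {
  stopifnot(all(c("distance", "presence") %in% names(observations)),
            all(observations$presence %in% c(0, 1)))
  if (length(unique(observations$distance)) < 2L)
    stop("need at least 2 distinct distances")
  if (length(unique(observations$presence)) < 2L)
    stop("both outcome classes must be present")
  fit <- suppressWarnings(
    stats::glm(presence ~ distance, family = stats::binomial(),
               data = observations))
  p_hat <- stats::fitted(fit)
  separation <- all(p_hat < 1e-8 | p_hat > 1 - 1e-8)
  if (separation)
    warning("complete separation: slope diverges, SEs are unreliable")
  sm <- summary(fit)$coefficients
  structure(list(
    alpha0 = unname(sm[1, 1]), alpha0_se = unname(sm[1, 2]),
    alpha1 = unname(sm[2, 1]), alpha1_se = unname(sm[2, 2]),
    p_value = unname(sm[2, 4]),
    vcov = stats::vcov(fit),
    loglik = as.numeric(stats::logLik(fit)),
    loglik_null = as.numeric(stats::logLik(
      stats::glm(presence ~ 1, family = stats::binomial(),
                 data = observations))),
    n_obs = nrow(observations),
    separation = separation,
    model = fit
  ), class = "occurrence_fit")
}

#' @export
print.occurrence_fit <- function(x, ...) {
  cat(sprintf("<occurrence_fit> n = %d\n  alpha0 = %.4g (SE %.3g)\n  alpha1 = %.4g (SE %.3g), p = %.3g\n",
              x$n_obs, x$alpha0, x$alpha0_se, x$alpha1, x$alpha1_se,
              x$p_value))
  if (x$separation) cat("  ! complete separation flagged\n")
  invisible(x)
}

#' Occurrence switch distance
#'
#' The distance at which the fitted occurrence probability crosses 0.5:
#' `d* = -alpha0 / alpha1`. The standard error follows from the delta method
#' with gradient `(-1/alpha1, alpha0/alpha1^2)` applied to the coefficient
#' covariance.
#'
#' @param fit an `occurrence_fit`.
#' @return List with `distance` (m) and `se` (m).
#' @export
switch_distance <- function(fit) {
  stopifnot(inherits(fit, "occurrence_fit"))
  if (fit$alpha1 == 0) stop("slope is exactly zero: no switch distance")
  if (abs(fit$alpha1) < 2 * fit$alpha1_se && !fit$separation)
    warning("slope is within 2 SE of zero; switch distance is ill-determined")
  d <- -fit$alpha0 / fit$alpha1
  g <- c(-1 / fit$alpha1, fit$alpha0 / fit$alpha1^2)
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  if (fit$separation) se <- Inf
  list(distance = d, se = se)
}

#' Variance explained by the occurrence fit
#'
#' The default metric is the squared Pearson correlation between the fitted
#' probabilities and the 0/1 outcomes; McFadden's and Tjur's pseudo-R2 are
#' reported alongside, none treated as canonical. A constant fitted
#' probability yields 0 with a note.
#'
#' @param fit an `occurrence_fit`.
#' @param observations the data the fit was computed from.
#' @return List with `pearson_r2`, `mcfadden`, `tjur`, and `note` when
#'   degenerate.
#' @export
variance_explained <- function(fit, observations) {
  y <- observations$presence
  p <- stats::predict(fit$model, newdata = observations, type = "response")
  note <- NULL
  if (stats::sd(p) == 0) {
    pearson <- 0
    note <- "constant fitted probability: correlation undefined, reported as 0"
  } else {
    pearson <- stats::cor(p, y)^2
  }
  mcfadden <- 1 - fit$loglik / fit$loglik_null
  tjur <- mean(p[y == 1]) - mean(p[y == 0])
  list(pearson_r2 = pearson, mcfadden = mcfadden, tjur = tjur, note = note)
}
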