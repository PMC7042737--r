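#' Small-sample corrected AIC
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`, with `k` counting all
#' estimated parameters (fixed effects plus variance components).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(is.finite(loglik), k >= 1, n > k + 1)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Marginal and conditional R2 for a binomial mixed model
#'
#' The variance-partitioning R2 for GLMMs on the logit scale: with
#' `s2f` the variance of the fixed-effect linear predictor across
#' observations and `s2r` the summed random-intercept variances,
#' `R2m = s2f / (s2f + s2r + pi^2/3)` and
#' `R2c = (s2f + s2r) / (s2f + s2r + pi^2/3)` (the logit
#' distribution-specific variance is `pi^2/3`).
#'
#' @param sigma2_fixed variance of the fixed-effect linear predictor.
#' @param sigma2_random summed random-effect variances.
#' @return List with `marginal` and `conditional`.
#' @export
r2_glmm_parts <- function(sigma2_fixed, sigma2_random) {
  stopifnot(sigma2_fixed >= 0, sigma2_random >= 0)
  denom <- sigma2_fixed + sigma2_random + pi^2 / 3
  list(marginal = sigma2_fixed / denom,
       conditional = (sigma2_fixed + sigma2_random) / denom)
}

#' @rdname r2_glmm_parts
#' @param fit a `glmm_fit` from [fit_glmm()].
#' @export
r2_glmm <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  X <- lme4::getME(fit$model, "X")
  eta_f <- as.vector(X %*% lme4::fixef(fit$model))
  r2_glmm_parts(stats::var(eta_f), sum(fit$sigma2))
}

#' Variance inflation factors of a design matrix
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the ordinary
#' least-squares regression of column `j` on the remaining columns (intercept
#' included). Exactly collinear columns yield `Inf`.
#'
#' @param X numeric design matrix; an intercept column (constant) is detected
#'   and skipped.
#' @return Named numeric vector, one value per non-intercept column.
#' @export
vif_design <- function(X) {
  X <- as.matrix(X)
  is_const <- apply(X, 2, function(col) stats::sd(col) == 0)
  cols <- which(!is_const)
  if (length(cols) < 2L) stop("need at least 2 non-intercept columns")
  out <- vapply(cols, function(j) {
    others <- cbind(1, X[, setdiff(cols, j), drop = FALSE])
    yj <- X[, j]
    fit <- stats::lm.fit(others, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)[cols]
  out
}

# model frame shared by fit_glmm and the scans
prepare_model_frame <- function(records, ud_col, breakpoint, log_floor) {
  df <- as.data.frame(records)
  if (!is.null(breakpoint)) df <- classify_proximity(df, breakpoint)
  stopifnot(!is.null(df$proximity), !is.null(df$success),
            ud_col %in% names(df))
  df$proximity <- factor(df$proximity, levels = c("far", "close"))
  df$area <- factor(df$area, levels = c("managed", "unmanaged"))
  df$ud <- df[[ud_col]]
  if (any(is.na(df$ud))) stop("missing understory density covariate")
  df$lud <- log(pmax(df$ud, log_floor))
  for (rf in c("year", "breeder_f", "breeder_m"))
    df[[rf]] <- factor(df[[rf]])
  df
}

glmm_formula <- function(ud_transform, include_forest_cover, random_terms,
                         include_area = TRUE) {
  ud_part <- switch(ud_transform,
                    log = "proximity * lud",
                    linear = "proximity * ud",
                    quadratic = "proximity * (ud + I(ud^2))")
  fixed <- if (include_area) paste("success ~ area +", ud_part)
           else paste("success ~", ud_part)
  if (include_forest_cover) fixed <- paste(fixed, "+ forest_cover")
  stats::as.formula(paste(fixed, "+", paste(random_terms, collapse = " + ")))
}

#' Fit the breeding-success binomial GLMM
#'
#' Binomial (logit link) mixed model of breeding success with crossed random
#' intercepts for year and both breeder identities, the study area as a fixed
#' effect, and an interaction between settlement proximity (close/far) and
#' the understory-density term. The marginal likelihood is maximized under
#' the Laplace approximation (via `lme4::glmer`); `method = "pirls"` selects
#' the faster penalized-least-squares approximation used for large model
#' scans.
#'
#' @param records nest data frame with `success`, `area`, `year`,
#'   `breeder_f`, `breeder_m`, the density covariate, and either `proximity`
#'   or `dist_settlement` (+ `breakpoint`).
#' @param ud_transform `"log"` (natural log of the density percentage,
#'   floored at `log_floor`), `"linear"`, or `"quadratic"`.
#' @param breakpoint close/far threshold (m) used to derive `proximity` when
#'   absent.
#' @param ud_col name of the density covariate column.
#' @param include_forest_cover add `forest_cover` as a fixed effect.
#' @param log_floor percentage floor before the log transform.
#' @param method `"laplace"` or `"pirls"`.
#' @return An object of class `glmm_fit`: fixed-effect table (`beta`),
#'   variance components (`sigma2`), `loglik`, `n`, `k`, `aicc`, marginal and
#'   conditional R2, VIFs, convergence flag and the underlying `merMod`.
#' @export
fit_glmm <- function(records, ud_transform = c("log", "linear", "quadratic"),
                     breakpoint = NULL, ud_col = "ud_nest",
                     include_forest_cover = FALSE, log_floor = 0.1,
                     method = c("laplace", "pirls")) {
  ud_transform <- match.arg(ud_transform)
  method <- match.arg(method)
  df <- prepare_model_frame(records, ud_col, breakpoint, log_floor)

  random <- c("year", "breeder_f", "breeder_m")
  levels_ok <- vapply(random, function(rf) nlevels(df[[rf]]) >= 2L,
                      logical(1))
  if (!all(levels_ok)) {
    warning("random factor(s) dropped (fewer than 2 levels): ",
            paste(random[!levels_ok], collapse = ", "))
    random <- random[levels_ok]
  }
  if (!length(random))
    stop("no usable random factor; fit a plain logistic model instead")
  if (nlevels(droplevels(df$proximity)) < 2L)
    stop("all nests fall in one proximity class at this breakpoint; ",
         "the close/far contrast cannot be estimated")
  include_area <- nlevels(droplevels(df$area)) >= 2L
  if (!include_area)
    warning("study-area term dropped: only one area level present")
  form <- glmm_formula(ud_transform, include_forest_cover,
                       sprintf("(1 | %s)", random), include_area)
  nagq <- if (method == "laplace") 1L else 0L
  model <- suppressMessages(
    lme4::glmer(form, data = df, family = stats::binomial(), nAGQ = nagq))

  sm <- summary(model)$coefficients
  beta <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                     z = sm[, 3], p = sm[, 4], row.names = NULL)
  vc <- lme4::VarCorr(model)
  sigma2 <- vapply(vc, function(v) as.numeric(v[1]), numeric(1))
  loglik <- as.numeric(stats::logLik(model))
  n <- stats::nobs(model)
  k <- nrow(beta) + length(sigma2)
  # optimizer exit status decides convergence; lme4's post-hoc gradient
  # checks are kept as messages (they flag benign cases often)
  conv <- model@optinfo$conv$opt == 0L
  conv_messages <- unlist(model@optinfo$conv$lme4$messages)
  X <- lme4::getME(model, "X")
  vifs <- if (ncol(X) >= 3L) vif_design(X) else NULL
  eta_f <- as.vector(X %*% lme4::fixef(model))
  r2 <- r2_glmm_parts(stats::var(eta_f), sum(sigma2))

  structure(list(
    beta = beta, sigma2 = sigma2, loglik = loglik, n = n, k = k,
    aicc = aicc(loglik, k, n),
    r2_marginal = r2$marginal, r2_conditional = r2$conditional,
    vif = vifs, converged = conv,
    convergence_messages = conv_messages, method = method,
    ud_transform = ud_transform, log_floor = log_floor,
    include_forest_cover = include_forest_cover,
    breakpoint = if (!is.null(breakpoint)) breakpoint
                 else attr(records, "breakpoint"),
    model = model
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> binomial(logit), %s, n = %d, k = %d\n",
              x$method, x$n, x$k))
  print(x$beta, digits = 3)
  cat("variance components:",
      paste(sprintf("%s = %.3f", names(x$sigma2), x$sigma2), collapse = ", "),
      "\n")
  cat(sprintf("logLik = %.2f, AICc = %.2f, R2m = %.3f, R2c = %.3f%s\n",
              x$loglik, x$aicc, x$r2_marginal, x$r2_conditional,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Compare understory-density transforms by AICc
#'
#' Fits the breeding-success model with log-transformed, linear and quadratic
#' density terms (identical random structure and data) and ranks them by
#' AICc.
#'
#' @inheritParams fit_glmm
#' @param ... passed to [fit_glmm()].
#' @return List with `table` (transform, k, loglik, aicc, delta_aicc; sorted)
#'   and the three `fits`.
#' @export
transform_selection <- function(records, breakpoint = NULL, ...) {
  transforms <- c("log", "linear", "quadratic")
  fits <- lapply(transforms, function(tr)
    fit_glmm(records, ud_transform = tr, breakpoint = breakpoint, ...))
  names(fits) <- transforms
  tab <- data.frame(
    transform = transforms,
    k = vapply(fits, function(f) f$k, numeric(1)),
    n = vapply(fits, function(f) f$n, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1))
  )
  tab <- tab[order(tab$aicc), ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Scan candidate settlement-distance breakpoints by AICc
#'
#' Refits the full breeding-success model with `proximity = I(dist < D)` for
#' every candidate `D` on the configured grid, clipped to the 10th-90th
#' percentile of the nest distances (rounded to the grid step). Candidates
#' leaving fewer than `min_class` nests in either class are skipped. The best
#' breakpoint minimizes AICc; ties break toward the smaller distance.
#'
#' @param records nest data frame with `dist_settlement`.
#' @param config a [run_config()] providing `breakpoint_grid`.
#' @param min_class minimum nests per proximity class.
#' @param method passed to [fit_glmm()]; defaults to the fast `"pirls"`
#'   approximation for screening.
#' @param ... passed to [fit_glmm()].
#' @return List with `best_breakpoint`, `table` (one row per candidate:
#'   breakpoint, n_close, n_far, loglik, aicc, skipped), and `method`.
#' @export
breakpoint_scan <- function(records, config = run_config(), min_class = 10,
                            method = "pirls", ...) {
  d <- records$dist_settlement
  stopifnot(!is.null(d))
  bg <- config$breakpoint_grid
  step <- bg[3]
  q <- stats::quantile(d, c(0.1, 0.9), names = FALSE)
  lo <- max(bg[1], ceiling(q[1] / step) * step)
  hi <- min(bg[2], floor(q[2] / step) * step)
  grid <- seq(bg[1], bg[2], by = step)
  grid <- grid[grid >= lo & grid <= hi]
  if (!length(grid)) stop("no breakpoint candidates inside the distance range")
  rows <- lapply(grid, function(D) {
    n_close <- sum(d < D); n_far <- sum(d >= D)
    if (min(n_close, n_far) < min_class)
      return(data.frame(breakpoint = D, n_close = n_close, n_far = n_far,
                        loglik = NA_real_, aicc = NA_real_, skipped = TRUE))
    fit <- fit_glmm(records, breakpoint = D, method = method, ...)
    data.frame(breakpoint = D, n_close = n_close, n_far = n_far,
               loglik = fit$loglik, aicc = fit$aicc, skipped = FALSE)
  })
  tab <- do.call(rbind, rows)
  usable <- which(!tab$skipped)
  if (!length(usable)) stop("every breakpoint candidate was skipped")
  best <- tab$breakpoint[usable[which.min(tab$aicc[usable])]]
  list(best_breakpoint = best, table = tab, method = method)
}

#' Sensitivity of the interaction to the breakpoint choice
#'
#' Refits the model across a range of breakpoints and reports the
#' proximity x density interaction estimate with its SE, flagging breakpoints
#' where `estimate +- SE` crosses zero (loss of the qualitative result).
#'
#' @param records nest data frame with `dist_settlement`.
#' @param range `c(min, max)` breakpoints (m).
#' @param step grid step (m).
#' @param method passed to [fit_glmm()].
#' @param ... passed to [fit_glmm()].
#' @return Data frame: one row per candidate with `breakpoint`, `term`,
#'   `estimate`, `se`, `crosses_zero`.
#' @export
breakpoint_sensitivity <- function(records, range = c(1350, 1800), step = 50,
                                   method = "pirls", ...) {
  grid <- seq(range[1], range[2], by = step)
  rows <- lapply(grid, function(D) {
    fit <- fit_glmm(records, breakpoint = D, method = method, ...)
    ia <- fit$beta[grepl(":", fit$beta$term), , drop = FALSE][1, ]
    data.frame(breakpoint = D, term = ia$term, estimate = ia$estimate,
               se = ia$se,
               crosses_zero = (ia$estimate - ia$se) <= 0 &
                 (ia$estimate + ia$se) >= 0)
  })
  do.call(rbind, rows)
}
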