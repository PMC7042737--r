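test_that("AICc follows its closed form", {
  expect_equal(aicc(-100, 5, 235), 210 + 60 / 229, tolerance = 1e-12)
  # converges to AIC as n grows
  expect_equal(aicc(-100, 5, 1e9), 210, tolerance = 1e-6)
  expect_error(aicc(-100, 5, 6))
  set.seed(2)
  for (i in 1:20) {
    ll <- runif(1, -500, -10); k <- sample(2:10, 1); n <- k + 1 + sample(5:500, 1)
    expect_equal(aicc(ll, k, n), -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1),
                 tolerance = 1e-12)
  }
})

test_that("variance-partitioning R2 follows its closed form", {
  r2 <- r2_glmm_parts(1, 1)
  expect_equal(r2$marginal, 1 / (2 + pi^2 / 3), tolerance = 1e-12)
  expect_equal(r2$conditional, 2 / (2 + pi^2 / 3), tolerance = 1e-12)
  expect_equal(r2_glmm_parts(0, 2)$marginal, 0)
  set.seed(4)
  for (i in 1:10) {
    f <- runif(1, 0, 3); r <- runif(1, 0, 3)
    expect_equal(r2_glmm_parts(f, r)$conditional,
                 (f + r) / (f + r + pi^2 / 3), tolerance = 1e-12)
  }
})

test_that("VIF matches ordinary-least-squares computation", {
  set.seed(6)
  # columns orthogonal to each other and to the intercept
  ortho <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), 100))))[, 2:4]
  expect_equal(unname(vif_design(cbind(1, ortho))), rep(1, 3),
               tolerance = 1e-9)
  dup <- cbind(1, rnorm(50), rnorm(50))
  dup <- cbind(dup, dup[, 2])
  expect_true(any(is.infinite(vif_design(dup))))
  X <- cbind(1, matrix(rnorm(200 * 3), 200))
  X[, 3] <- X[, 3] + 0.8 * X[, 2]
  got <- vif_design(X)
  want <- vapply(2:4, function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, setdiff(2:4, j)]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-10)
})

test_that("VIF agrees with the standard automotive-package implementation", {
  skip_if_not_installed("car")
  set.seed(8)
  d <- data.frame(y = rnorm(120), a = rnorm(120), b = rnorm(120))
  d$c <- 0.6 * d$a + rnorm(120)
  m <- stats::lm(y ~ a + b + c, data = d)
  expect_equal(unname(vif_design(stats::model.matrix(m))),
               unname(car::vif(m)), tolerance = 1e-9)
})

test_that("with zero random variance the GLMM collapses to plain logistic", {
  truth0 <- scene_truth(sigma2 = c(year = 0, breeder_f = 0, breeder_m = 0))
  d <- sim_glmm_data(1500, truth = truth0, seed = 51)
  fit <- quiet_fit(d, breakpoint = 1450)
  ref <- stats::glm(success ~ area + proximity * log(pmax(ud_nest, 0.1)),
                    family = stats::binomial(),
                    data = classify_proximity(d, 1450))
  expect_lt(max(abs(fit$beta$estimate - unname(stats::coef(ref)))),
            2 * max(fit$beta$se))
  # under a zero-variance truth the estimated total random variance stays
  # near the boundary (data generated with sigma^2 = 0.5 each yields ~1.5)
  sum_s2 <- median(vapply(201:203, function(s)
    sum(quiet_fit(sim_glmm_data(3000, truth = truth0, seed = s),
                  breakpoint = 1450, method = "pirls")$sigma2), numeric(1)))
  expect_lt(sum_s2, 0.2)
})

test_that("Laplace log-likelihood matches an adaptive-quadrature oracle", {
  set.seed(7)
  g <- factor(rep(1:3, each = 10))
  u <- rnorm(3, 0, 0.8)
  x <- rnorm(30)
  y <- rbinom(30, 1, plogis(0.3 + 0.7 * x + u[g]))
  m <- lme4::glmer(y ~ x + (1 | g), family = stats::binomial())
  beta <- lme4::fixef(m)
  s2 <- as.numeric(lme4::VarCorr(m)$g)
  ll_oracle <- sum(vapply(split(seq_len(30), g), function(idx) {
    f <- function(uu) vapply(uu, function(u1) {
      p <- plogis(beta[1] + beta[2] * x[idx] + u1)
      prod(p^y[idx] * (1 - p)^(1 - y[idx])) * dnorm(u1, 0, sqrt(s2))
    }, numeric(1))
    log(stats::integrate(f, -Inf, Inf)$value)
  }, numeric(1)))
  expect_lt(abs(as.numeric(stats::logLik(m)) - ll_oracle), 0.05)
})

test_that("fit_glmm bookkeeping: k, AICc, R2 and purity", {
  d <- sim_glmm_data(400, seed = 61)
  fit <- quiet_fit(d, breakpoint = 1450)
  expect_equal(fit$k, nrow(fit$beta) + length(fit$sigma2))
  expect_equal(fit$aicc, aicc(fit$loglik, fit$k, fit$n), tolerance = 1e-12)
  r2 <- r2_glmm(fit)
  expect_equal(r2$marginal, fit$r2_marginal, tolerance = 1e-12)
  expect_true(all(fit$sigma2 >= 0))
  expect_true(all(fit$beta$p > 0 & fit$beta$p <= 1))
  fit2 <- quiet_fit(d, breakpoint = 1450)
  expect_identical(fit$beta$estimate, fit2$beta$estimate)
})

test_that("adding a truly active predictor does not lower the likelihood", {
  d <- sim_glmm_data(800, seed = 71)
  full <- quiet_fit(d, breakpoint = 1450)
  d0 <- d; d0$ud_flat <- 1
  reduced <- quiet_fit(d0, breakpoint = 1450, ud_col = "ud_flat")
  expect_gte(full$loglik, reduced$loglik)
})

test_that("transform selection shares data and random structure across fits", {
  d <- sim_glmm_data(500, seed = 81)
  ts <- suppressWarnings(suppressMessages(
    transform_selection(d, breakpoint = 1450, method = "pirls")))
  expect_setequal(ts$table$transform, c("log", "linear", "quadratic"))
  expect_equal(length(unique(ts$table$n)), 1L)
  expect_equal(ts$table$delta_aicc[1], 0)
  expect_true(all(diff(ts$table$aicc) >= 0))
  ks <- vapply(ts$fits, function(f) length(f$sigma2), numeric(1))
  expect_equal(length(unique(ks)), 1L)
})

test_that("log transform wins the AICc comparison on log-generated data", {
  wins <- 0L
  for (r in 1:10) {
    d <- sim_glmm_data(3000, seed = 900 + r)
    ts <- suppressWarnings(suppressMessages(
      transform_selection(d, breakpoint = 1450, method = "pirls")))
    if (ts$table$transform[1] == "log") wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("breakpoint scan grid respects spacing, clipping and class sizes", {
  d <- sim_glmm_data(300, seed = 91)
  sc <- suppressWarnings(suppressMessages(breakpoint_scan(d, run_config())))
  tab <- sc$table
  expect_true(all(diff(tab$breakpoint) == 50))
  expect_true(all(tab$breakpoint %% 50 == 0))
  q <- quantile(d$dist_settlement, c(0.1, 0.9))
  expect_gte(min(tab$breakpoint), q[1] - 50)
  expect_lte(max(tab$breakpoint), q[2] + 50)
  expect_true(all(tab$n_close + tab$n_far == nrow(d)))
  expect_true(all(pmin(tab$n_close, tab$n_far)[!tab$skipped] >= 10))
  expect_true(sc$best_breakpoint %in% tab$breakpoint)
})

test_that("no distance effect leaves the AICc profile flat", {
  truth_flat <- scene_truth(beta = c(intercept = 0.2, area = -0.3, close = 0,
                                     logud = 0.4, interaction = 0))
  flats <- 0L
  for (r in 1:5) {
    d <- sim_glmm_data(1000, truth = truth_flat, seed = 700 + r)
    sc <- suppressWarnings(suppressMessages(breakpoint_scan(d, run_config())))
    rng <- diff(range(sc$table$aicc, na.rm = TRUE))
    if (rng < 6) flats <- flats + 1L
  }
  expect_gte(flats, 4L)
})

test_that("interaction sign is stable near the true breakpoint and unstable under a null", {
  d <- sim_glmm_data(2000, seed = 95)
  sens <- suppressWarnings(suppressMessages(
    breakpoint_sensitivity(d, range = c(1250, 1650), step = 100)))
  expect_equal(nrow(sens), 5L)
  expect_true(all(!sens$crosses_zero))
  expect_true(all(sens$estimate < 0))

  # under a null interaction the +-1 SE interval covers 0 about 68% of the
  # time; refits on one dataset are correlated, so aggregate over datasets
  truth0 <- scene_truth(beta = c(intercept = 0.2, area = 0, close = 0,
                                 logud = 0, interaction = 0))
  crossings <- vapply(1:6, function(s) {
    d0 <- sim_glmm_data(500, truth = truth0, seed = 960 + s)
    sens0 <- suppressWarnings(suppressMessages(
      breakpoint_sensitivity(d0, range = c(1350, 1550), step = 100,
                             method = "pirls")))
    mean(sens0$crosses_zero)
  }, numeric(1))
  expect_gte(mean(crossings), 1 / 3)
})

test_that("random factors with a single level are dropped with a warning", {
  d <- sim_glmm_data(300, seed = 97)
  d$breeder_f <- "F1"
  expect_warning(fit_glmm(d, breakpoint = 1450, method = "pirls"),
                 "breeder_f")
})
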