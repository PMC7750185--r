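test_that("the intercept-only fit on balanced data returns the grand mean", {
  set.seed(1)
  d <- data.frame(farm_id = rep(letters[1:4], each = 5), y = rnorm(20, 3))
  fit <- lmm_ml(y ~ 1, d)
  expect_equal(unname(coef(fit)[1]), mean(d$y), tolerance = 1e-7)
})

test_that("the profiled likelihood matches a dense-covariance oracle", {
  for (seed in 1:8) {
    d <- random_lmm_instance(seed)
    fit <- lmm_ml(y ~ x1 + x2, d)
    ll <- dense_loglik(fit$X, fit$y, as.character(fit$g), coef(fit),
                       fit$theta_U, fit$theta_eps)
    expect_equal(fit$loglik, ll, tolerance = 1e-6)
    expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$k_params)
    expect_identical(fit$k_params, length(coef(fit)) + 2L)
  }
})

test_that("forcing a zero variance ratio reproduces ordinary least squares", {
  for (seed in c(3, 9)) {
    d <- random_lmm_instance(seed)
    fit <- lmm_ml(y ~ x1 + x2, d, lambda = 0)
    ols <- lm(y ~ x1 + x2, d)
    expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
    expect_equal(fit$theta_U, 0)
    expect_true(fit$boundary)
    # ML residual variance uses the 1/n denominator
    expect_equal(fit$theta_eps, sum(residuals(ols)^2) / nobs(ols),
                 tolerance = 1e-8)
  }
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- simulate_colostrum(n_farms = 25, seed = 17)
  fit <- lmm_ml(log_tbc ~ milking_system + feeding_hot_water + calving_pen_days,
                standardize_dataset(d))
  m <- lme4::lmer(
    log_tbc ~ milking_system + feeding_hot_water + scale(calving_pen_days) +
      (1 | farm_id), d, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-5)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(m)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$theta_U, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$theta_eps, vc$vcov[2], tolerance = 1e-4)
})

test_that("fits are invariant to record order and farm relabelling", {
  d <- random_lmm_instance(5)
  fit <- lmm_ml(y ~ x1 + x2, d)
  perm <- sample.int(nrow(d))
  fit2 <- lmm_ml(y ~ x1 + x2, d[perm, ])
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
  relab <- d
  relab$farm_id <- paste0("zz_", rev(as.character(relab$farm_id)))
  fit3 <- lmm_ml(y ~ x1 + x2, relab)
  expect_equal(fit3$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("rank-deficient designs error by default and drop when allowed", {
  d <- random_lmm_instance(2)
  d$x1_copy <- d$x1
  expect_error(lmm_ml(y ~ x1 + x1_copy, d), "x1_copy")
  fit <- lmm_ml(y ~ x1 + x1_copy, d, drop_aliased = TRUE)
  expect_identical(fit$dropped_columns, "x1_copy")
  ref <- lmm_ml(y ~ x1, d)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-8)
  expect_error(lmm_ml(y ~ x1, transform(d, farm_id = "one")), "2 distinct")
})

test_that("predictions honour the farm effect modes and unseen levels error", {
  d <- random_lmm_instance(7)
  fit <- lmm_ml(y ~ x1 + x2, d)
  pf <- predict(fit, mode = "fixed_only")
  pw <- predict(fit)
  # BLUP shrinkage: per-farm mean conditional residual is the shrunken
  # remainder, and marginal-residual farm means shrink toward it by
  # n_j * lambda / (1 + n_j * lambda)
  rm <- tapply(d$y - pf, as.character(fit$g), mean)
  nj <- table(as.character(fit$g))[names(rm)]
  shrink <- as.numeric(nj) * fit$lambda / (1 + as.numeric(nj) * fit$lambda)
  expect_equal(unname(fit$u[names(rm)]), as.numeric(rm) * shrink,
               tolerance = 1e-8)
  expect_equal(pw, pf + unname(fit$u[as.character(fit$g)]))
  # unseen farm predicts from fixed effects alone
  nd <- d[1:2, ]
  nd$farm_id <- "brand_new_farm"
  expect_equal(predict(fit, nd), predict(fit, nd, mode = "fixed_only"))
  # zero farm variance makes the modes identical
  fit0 <- lmm_ml(y ~ x1, d, lambda = 0)
  expect_equal(predict(fit0), predict(fit0, mode = "fixed_only"))
  # unseen factor level errors
  nd2 <- d[1:2, ]
  nd2$x2 <- factor(c("zzz", "a"))
  expect_error(predict(fit, nd2), "unseen level")
})

test_that("aic_of returns the penalised likelihood and guards convergence", {
  d <- random_lmm_instance(4)
  fit <- lmm_ml(y ~ x1, d)
  expect_equal(aic_of(fit), -2 * fit$loglik + 2 * fit$k_params)
  broken <- fit
  broken$converged <- FALSE
  expect_error(aic_of(broken), "converge")
  # nested models: the larger model's likelihood is at least as high
  small <- lmm_ml(y ~ x1, d)
  large <- lmm_ml(y ~ x1 + x2, d)
  expect_gte(large$loglik, small$loglik - 1e-8)
})

test_that("residual normality diagnostics flag skew and small samples", {
  set.seed(10)
  d <- data.frame(farm_id = rep(sprintf("f%d", 1:30), each = 8))
  d$y <- rnorm(240) + rnorm(30)[rep(1:30, each = 8)]
  fit <- lmm_ml(y ~ 1, d)
  rn <- residual_normality(fit)
  expect_lt(abs(rn$skewness), 0.5)
  expect_false(rn$unreliable)
  # exponential noise is right-skewed
  d$y <- rexp(240)
  fit2 <- lmm_ml(y ~ 1, d)
  expect_gt(residual_normality(fit2)$skewness, 0.5)
  small <- lmm_ml(y ~ 1, d[c(1:3, 9:11), ])
  expect_true(residual_normality(small)$unreliable)
})

test_that("simulate draws from the fitted generative model", {
  d <- random_lmm_instance(6)
  fit <- lmm_ml(y ~ x1, d)
  s1 <- simulate(fit, nsim = 2, seed = 1)
  s2 <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(s1, s2)
  expect_identical(dim(s1), c(nrow(d), 2L))
  big <- simulate(fit, nsim = 200, seed = 3)
  expect_lt(abs(mean(as.matrix(big)) - mean(fit$fitted_fixed)), 0.5)
})
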