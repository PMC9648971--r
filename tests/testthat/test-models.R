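test_that("intercept-only model predicts the training mean everywhere", {
  d <- recovery_dataset(c(10, 20), c(50, 60))
  fit <- fit_intercept_only(d)
  expect_equal(fit$parameters$mu, 55)
  expect_equal(predict(fit, 0), predict(fit, 66))
  expect_equal(predict(fit, c(0, 33, 66)), rep(55, 3))
})

test_that("censored-normal fit recovers the recovery constant", {
  # no censoring: closed form c = mean(delta)
  d <- recovery_dataset(c(10, 20, 30, 40), c(25, 32, 41, 52))
  fit <- fit_constant_ceiling(d)
  expect_equal(fit$parameters$c, mean(d$y - d$x), tolerance = 1e-12)
  expect_equal(fit$n_censored, 0L)

  # noise-free data against the ceiling: exact recovery of c = 40
  x <- seq(2, 60, by = 2)
  d0 <- recovery_dataset(x, pmin(x + 40, 66))
  fit0 <- fit_constant_ceiling(d0)
  expect_equal(fit0$parameters$c, 40, tolerance = 1e-9)
  expect_equal(predict(fit0, x), pmin(x + 40, 66), tolerance = 1e-9)

  # all observations censored: not identifiable
  expect_error(
    fit_constant_ceiling(recovery_dataset(c(40, 50, 60), c(66, 66, 66))),
    class = "prr_degenerate_error"
  )
})

test_that("censored-normal MLE matches the survreg oracle", {
  skip_if_not_installed("survival")
  d <- ceiling_cohort(150, shift = 30, noise_sd = 5, seed = 91)
  expect_gt(sum(d$y == 66), 5)  # censoring actually present
  fit <- fit_constant_ceiling(d)
  oracle <- survival::survreg(
    survival::Surv(y, y < 66 - 1e-9, type = "right") ~ 1 + offset(x),
    data = as.data.frame(d), dist = "gaussian"
  )
  expect_equal(fit$parameters$c, unname(coef(oracle)), tolerance = 1e-5)
  expect_equal(fit$parameters$sigma, oracle$scale, tolerance = 1e-4)
})

test_that("exponential fit recovers generating parameters exactly", {
  x <- seq(1, 64, by = 3)
  d <- recovery_dataset(x, 66 - 30 * exp(-0.05 * x))
  fit <- fit_exponential(d)
  expect_true(fit$converged)
  expect_equal(fit$parameters$A, 30, tolerance = 1e-6)
  expect_equal(fit$parameters$r, 0.05, tolerance = 1e-6)

  # r -> 0: the model collapses to a constant mean 66 - A
  set.seed(92)
  flat <- recovery_dataset(runif(50, 5, 60),
                           pmin(pmax(rnorm(50, 40, 2), 0), 66))
  ffit <- fit_exponential(flat)
  preds <- predict(ffit, c(10, 30, 50))
  expect_lt(max(preds) - min(preds), 1.5)
  expect_equal(mean(preds), 40, tolerance = 0.1)
})

test_that("penalized spline tracks simple mean structures", {
  # near-linear truth: the smooth stays within 1 scale unit of the line
  set.seed(93)
  x <- runif(100, 5, 60)
  y <- pmin(pmax(10 + 0.8 * x + rnorm(100, 0, 1), 0), 66)
  fit <- fit_smooth_additive(recovery_dataset(x, y))
  grid <- seq(10, 55, by = 5)
  expect_lt(max(abs(predict(fit, grid) - (10 + 0.8 * grid))), 1)

  # constant-mean data: penalization typically collapses the smooth to
  # ~1 effective df (GCV occasionally latches onto noise, so assert on
  # the median over replicate datasets; total edf includes the
  # intercept)
  edfs <- vapply(1:10, function(i) {
    set.seed(600 + i)
    xx <- runif(100, 5, 60)
    yc <- pmin(pmax(rnorm(100, 35, 2), 0), 66)
    fit_smooth_additive(recovery_dataset(xx, yc))$parameters$edf
  }, numeric(1))
  expect_lt(median(edfs), 2.5)
})

test_that("PRR slope solves the no-intercept normal equation", {
  x1 <- c(26, 46, 56)
  d1 <- recovery_dataset(x1, x1 + c(28, 14, 7))
  fit1 <- fit_prr(d1)
  expect_equal(fit1$parameters$beta, 0.7, tolerance = 1e-12)
  expect_equal(predict(fit1, x1), c(54, 60, 63), tolerance = 1e-12)

  # closed-form oracle: beta = sum(delta * I) / sum(I^2) with
  # I = (60, 40, 20): (30*60 + 30*40 + 10*20) / (60^2 + 40^2 + 20^2)
  x2 <- c(6, 26, 46)
  delta2 <- c(30, 30, 10)
  d2 <- recovery_dataset(x2, x2 + delta2)
  expect_equal(fit_prr(d2)$parameters$beta, 3200 / 5600,
               tolerance = 1e-12)

  expect_error(fit_prr(recovery_dataset(c(66, 66), c(66, 66))),
               class = "prr_degenerate_error")
})

test_that("all families share the fit/predict contract and clip to scale", {
  d <- prr_cohort(80, seed = 94)
  xnew <- c(-5, 0, 15, 40, 66, 80)  # deliberately outside the scale too
  for (fam in recovery_families()) {
    fit <- fit_recovery_model(fam, d)
    expect_s3_class(fit, "recovery_model")
    expect_identical(fit$family, fam)
    expect_equal(fit$n_train, 80L)
    p <- predict(fit, xnew)
    expect_true(all(is.finite(p)), info = fam)
    expect_true(all(p >= 0 & p <= 66), info = fam)
  }
  expect_error(fit_recovery_model("tobit", d), class = "prr_config_error")
})

test_that("training error nests but CV protects against the overfit", {
  # on intercept-only truth the spline's training MSE can only improve,
  # while its held-out MAPE should not beat the true model systematically
  set.seed(95)
  wins <- 0L
  for (i in 1:10) {
    x <- runif(60, 5, 60)
    y <- pmin(pmax(rnorm(60, 40, 4), 0), 66)
    d <- recovery_dataset(x, y)
    ifit <- fit_recovery_model("intercept_only", d)
    gfit <- fit_recovery_model("smooth_additive", d)
    mse <- function(f) mean((predict(f, d$x) - d$y)^2)
    expect_lte(mse(gfit), mse(ifit) + 1e-8)
    cv <- cv_compare(d, c("intercept_only", "smooth_additive"),
                     n_splits = 40, seed = 100 + i)
    m <- colMeans(cv$mape, na.rm = TRUE)
    if (m["smooth_additive"] < m["intercept_only"]) wins <- wins + 1L
  }
  expect_lte(wins, 7L)  # the flexible model must not dominate
})
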