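test_that("coupling surface matches closed form and Monte-Carlo oracle", {
  # canonical coupling anchor: independent, equal-variance scores
  expect_equal(cor_x_delta_surface(0, 1), -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(round(cor_x_delta_surface(0, 1), 2), -0.71)
  # exact algebra at the illustrative-dataset parameter values
  expect_equal(cor_x_delta_surface(0, 0.16), -1 / sqrt(1.16),
               tolerance = 1e-12)
  expect_equal(cor_x_delta_surface(0.9, 0.16), -0.64 / sqrt(0.44),
               tolerance = 1e-12)

  # independent Monte-Carlo oracle: empirical cor(x, y - x) on 1e6
  # bivariate-normal draws with the stated moments
  mc_cor_xdelta <- function(rho, k, n = 1e6) {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    x <- z1
    y <- sqrt(k) * (rho * z1 + sqrt(1 - rho^2) * z2)
    cor(x, y - x)
  }
  set.seed(401)
  expect_equal(mc_cor_xdelta(0, 0.16), cor_x_delta_surface(0, 0.16),
               tolerance = 2e-3)
  expect_equal(mc_cor_xdelta(0.9, 0.16), cor_x_delta_surface(0.9, 0.16),
               tolerance = 2e-3)

  # baseline noise negligible relative to follow-up: surface -> cor_xy
  expect_equal(cor_x_delta_surface(0.42, 1e8), 0.42, tolerance = 1e-3)

  expect_error(cor_x_delta_surface(0, 0), class = "prr_domain_error")
  expect_error(cor_x_delta_surface(0, -1), class = "prr_domain_error")
  expect_error(cor_x_delta_surface(1, 1), class = "prr_degenerate_error")
  expect_error(cor_x_delta_surface(1.2, 1), class = "prr_domain_error")
})

test_that("surface is monotone in cor_xy exactly where algebra says", {
  # d/dr [(s r - 1)/sqrt(s^2 + 1 - 2 s r)] has the sign of (s - r),
  # s = sqrt(k): increasing while cor_xy < s, decreasing beyond. For
  # k >= 1 the surface is therefore increasing on the whole range; for
  # k < 1 it turns at cor_xy = sqrt(k) and falls towards -1.
  for (k in c(0.05, 0.16, 0.5, 1, 2, 4)) {
    s <- sqrt(k)
    r <- seq(-0.99, 0.99, length.out = 199)
    vals <- cor_x_delta_surface(r, k)
    rising <- r[-1] < s
    expect_true(all(diff(vals)[rising] > 0), info = paste("k =", k))
    falling <- r[-length(r)] > s
    expect_true(all(diff(vals)[falling] < 0), info = paste("k =", k))
    expect_true(all(vals >= -1 & vals <= 1))
  }
  # spot check of the turn for k < 1
  expect_lt(cor_x_delta_surface(0.9, 0.16), cor_x_delta_surface(0.5, 0.16))
  expect_gt(cor_x_delta_surface(0.3, 0.16), cor_x_delta_surface(0, 0.16))
})

test_that("no-recovery null values sit on the k = 1 contour", {
  expect_equal(null_cor_x_delta(0), -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(null_cor_x_delta(0.5), -0.5, tolerance = 1e-12)
  r <- seq(-0.99, 0.99, by = 0.02)
  expect_equal(null_cor_x_delta(r), cor_x_delta_surface(r, 1),
               tolerance = 1e-12)
  # limit: as cor_xy -> 1 the null value approaches 0
  expect_lt(abs(null_cor_x_delta(1 - 1e-9)), 1e-4)
  expect_error(null_cor_x_delta(1), class = "prr_degenerate_error")
})

test_that("summary statistics agree with direct computation", {
  x <- c(10, 22, 34, 46, 58)
  s <- summarize_recovery(recovery_dataset(x, x / 2))
  expect_equal(s$k, 0.25)
  expect_equal(s$cor_xy, 1)
  expect_equal(s$n, 5L)
  expect_equal(s$mean_y, mean(x) / 2)

  # constant change: cor(x, delta) is degenerate, not an error
  s2 <- summarize_recovery(recovery_dataset(x, x + 5))
  expect_equal(s2$k, 1)
  expect_equal(s2$cor_xy, 1)
  expect_true(is.na(s2$cor_xdelta))
  expect_true("constant change" %in% s2$degenerate)

  expect_error(summarize_recovery(recovery_dataset(c(1, 2), c(3, 4))),
               class = "prr_insufficient_data_error")
  err <- expect_error(
    summarize_recovery(recovery_dataset(c(5, 5, 5), c(1, 2, 3))),
    class = "prr_degenerate_error"
  )
  expect_match(conditionMessage(err), "x")
})

test_that("direct cor(x, delta) equals the surface at the sample moments", {
  set.seed(402)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    x <- runif(n, 1, 60)
    y <- pmin(pmax(runif(1, -0.5, 1.2) * x + rnorm(n, 20, 8), 0), 66)
    if (sd(y) < 1e-8 || sd(y - x) < 1e-8) next
    s <- summarize_recovery(recovery_dataset(x, y))
    expect_equal(s$cor_xdelta, cor_x_delta_surface(s$cor_xy, s$k),
                 tolerance = 1e-10)
  }
})

test_that("Oldham correlation tracks the variance ratio", {
  x <- c(5, 17, 29, 41, 53)
  # equal variances (y is a permutation of x): Oldham correlation is
  # exactly 0 whatever the correlation between x and y
  expect_equal(
    oldham_correlation(recovery_dataset(x, c(17, 5, 41, 53, 29))), 0,
    tolerance = 1e-10
  )
  # y = c - x also has sd_y = sd_x, but makes x + y constant, so the
  # correlation is undefined rather than 0
  expect_error(oldham_correlation(recovery_dataset(x, 60 - x)),
               class = "prr_degenerate_error")
  # sd_y < sd_x: positive; sign(cor) = sign(1 - k)
  set.seed(403)
  d_small_k <- biv_cohort(100, k = 0.25, rho = 0.3, seed = 11)
  expect_gt(oldham_correlation(d_small_k), 0)
  d_big_k <- biv_cohort(100, k = 3, rho = 0.3, mean_y = 40, sd_x = 4,
                        seed = 12)
  expect_lt(oldham_correlation(d_big_k), 0)

  # invariance to adding a common constant to both x and y
  d <- grid_cohort()
  shifted <- recovery_dataset(d$x + 7, d$y + 7, scale_max = 80)
  expect_equal(oldham_correlation(d), oldham_correlation(shifted),
               tolerance = 1e-12)

  # Monte-Carlo: k = 1 bivariate normal has Oldham correlation ~ 0
  set.seed(404)
  n <- 1e6
  z1 <- rnorm(n); z2 <- rnorm(n)
  x_mc <- z1
  y_mc <- 0.5 * z1 + sqrt(0.75) * z2
  expect_lt(abs(cor(x_mc + y_mc, x_mc - y_mc)), 0.005)

  expect_error(oldham_correlation(recovery_dataset(x, x + 5)),
               class = "prr_degenerate_error")
})

test_that("summary matches Oldham sign rule on random cohorts", {
  set.seed(405)
  for (i in 1:20) {
    d <- biv_cohort(50, k = runif(1, 0.1, 3), rho = runif(1, -0.3, 0.9),
                    mean_y = 40, sd_x = 5, seed = 500 + i)
    s <- summarize_recovery(d)
    if (abs(1 - s$k) > 1e-8) {
      expect_equal(sign(s$cor_oldham), sign(1 - s$k))
    }
  }
})

test_that("PRR variance explained is 1 for noise-free proportional data", {
  x <- c(5, 15, 25, 35, 45, 55)
  y <- x + 0.7 * (66 - x)
  d <- recovery_dataset(x, y)
  expect_equal(prr_variance_explained(d), 1, tolerance = 1e-12)

  # unbounded below: an intercept-free fit can do worse than the mean
  d_bad <- recovery_dataset(c(2, 5, 60, 63), c(60, 63, 62, 65))
  expect_lt(prr_variance_explained(d_bad), 1)

  expect_error(
    prr_variance_explained(recovery_dataset(x, rep(30, 6)),
                           fit_prr(recovery_dataset(x, y))),
    class = "prr_degenerate_error"
  )
})
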