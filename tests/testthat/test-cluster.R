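# Two groups with the geometry this method is used on: "recoverers"
# along the proportional-recovery line, "non-recoverers" changing
# little regardless of baseline.
two_group_cohort <- function(n_rec = 50, n_non = 25, seed = 1) {
  set.seed(seed)
  xr <- runif(n_rec, 5, 55)
  yr <- pmin(xr + 0.75 * (66 - xr) + rnorm(n_rec, 0, 2.5), 66)
  xn <- runif(n_non, 2, 30)
  yn <- pmin(pmax(xn + rnorm(n_non, 1, 2), 0), 66)
  list(
    dataset = recovery_dataset(c(xr, xn), c(yr, yn)),
    truth = rep(1:2, c(n_rec, n_non))
  )
}

test_that("well-separated recovery groups are recovered exactly", {
  for (seed in c(111, 112, 113)) {
    tg <- two_group_cohort(seed = seed)
    cl <- mahalanobis_hclust(tg$dataset, k = 2)
    agree <- max(mean(cl$labels == tg$truth),
                 mean(cl$labels == 3 - tg$truth))
    expect_equal(agree, 1)
    expect_length(cl$labels, 75)
    expect_equal(sort(unique(cl$labels)), 1:2)
  }
})

test_that("labels are invariant to affine transforms of the features", {
  d <- prr_cohort(50, seed = 112)
  cl1 <- mahalanobis_hclust(d, k = 2)
  # (x, y) -> (66 - x, y - x): an affine map, so Mahalanobis distances
  # (full-sample covariance) are unchanged
  Z2 <- cbind(66 - d$x, d$y - d$x)
  lab2 <- prrtools:::cluster_features(Z2, k = 2)
  agree <- max(mean(cl1$labels == lab2), mean(cl1$labels == 3 - lab2))
  expect_equal(agree, 1)

  # collinear features: singular covariance error
  expect_error(
    mahalanobis_hclust(recovery_dataset(c(1, 2, 3, 4), c(2, 4, 6, 8) / 2)),
    class = "prr_degenerate_error"
  )
})

test_that("within-cluster dispersion matches brute-force computation", {
  # hand-computed case: two clusters split by x, each with variance
  # only in y: W = 4 * (1^2) = 4
  Z <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  expect_equal(within_dispersion(Z, c(1, 1, 2, 2)), 4)
  # every point its own cluster / one cluster
  expect_equal(within_dispersion(Z, 1:4), 0)
  expect_equal(within_dispersion(Z, rep(1, 4)),
               sum(sweep(Z, 2, colMeans(Z))^2))

  # brute-force pairwise oracle on random instances:
  # W = sum_r (1 / (2 n_r)) sum_{i,j in C_r} ||z_i - z_j||^2
  set.seed(113)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    Zr <- matrix(runif(2 * n, 0, 66), ncol = 2)
    labels <- sample(1:3, n, replace = TRUE)
    brute <- 0
    for (g in unique(labels)) {
      idx <- which(labels == g)
      acc <- 0
      for (i in idx) for (j in idx) {
        acc <- acc + sum((Zr[i, ] - Zr[j, ])^2)
      }
      brute <- brute + acc / (2 * length(idx))
    }
    expect_equal(within_dispersion(Zr, labels), brute, tolerance = 1e-10)
  }

  expect_error(within_dispersion(Z, c(1, 2)), class = "prr_validation_error")
})

test_that("dispersion is non-increasing under nested refinement", {
  set.seed(114)
  Z <- matrix(runif(60, 0, 66), ncol = 2)
  coarse <- sample(1:2, 30, replace = TRUE)
  fine <- coarse * 10 + sample(1:2, 30, replace = TRUE)  # refines coarse
  expect_lte(within_dispersion(Z, fine), within_dispersion(Z, coarse))
})

test_that("gap statistic separates structure from uniform noise", {
  # data themselves uniform on a rectangle: gap near 0
  set.seed(115)
  unif <- recovery_dataset(runif(200, 0, 60), runif(200, 0, 66))
  g_unif <- gap_statistic(unif, B_ref = 50, seed = 5)
  expect_lt(abs(g_unif), 0.25)

  # genuinely grouped cohort: strictly positive and larger than
  # the uniform data's gap
  tg <- two_group_cohort(seed = 114)
  g_groups <- gap_statistic(tg$dataset, B_ref = 50, seed = 5)
  expect_gt(g_groups, 0)
  expect_gt(g_groups, g_unif)

  # determinism
  expect_identical(gap_statistic(unif, B_ref = 20, seed = 6),
                   gap_statistic(unif, B_ref = 20, seed = 6))
})

test_that("random-recovery gap test rejects structure, accepts its null", {
  # clearly clustered cohort: small p
  set.seed(116)
  x <- c(runif(40, 5, 55), runif(40, 2, 30))
  y <- c(pmin(x[1:40] + 0.75 * (66 - x[1:40]), 66),
         pmin(pmax(x[41:80] + rnorm(40, 1, 1.5), 0), 66))
  d <- recovery_dataset(x, y)
  res <- random_recovery_gap_test(d, R_null = 99, B_ref = 25, seed = 7)
  expect_lt(res$p_value, 0.05)
  expect_length(res$gap_null, 99)

  # data generated under random recovery: typically non-significant
  rr <- generate_random_recovery(runif(50, 0, 60), n = 50, seed = 117)
  res_rr <- random_recovery_gap_test(rr, R_null = 99, B_ref = 25, seed = 8)
  expect_gt(res_rr$p_value, 0.05)

  # add-one correction bounds
  res1 <- random_recovery_gap_test(rr, R_null = 1, B_ref = 10, seed = 9)
  expect_true(res1$p_value %in% c(0.5, 1))
  expect_gt(res_rr$p_value, 0)
  expect_lte(res_rr$p_value, 1)
})

test_that("gap-test p-value is invariant to consistent affine rescaling", {
  d <- prr_cohort(40, seed = 118)
  a <- 0.5
  b <- 10
  d2 <- recovery_dataset(a * d$x + b, a * d$y + b,
                         scale_max = a * 66 + b, scale_min = a * 0 + b)
  r1 <- random_recovery_gap_test(d, R_null = 60, B_ref = 15, seed = 10)
  r2 <- random_recovery_gap_test(d2, R_null = 60, B_ref = 15, seed = 10)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$gap_observed, r2$gap_observed, tolerance = 1e-8)
})
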