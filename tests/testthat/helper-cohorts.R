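# Cohort builders used across test files. All fixtures are generated in
# code; seeds are fixed so every run sees identical data.

# Bivariate-normal cohort with means/SDs chosen so that truncation by
# the [0, 66] scale is negligible (4+ SDs from both bounds).
biv_cohort <- function(n, k = 0.5, rho = 0.6, mean_x = 30, sd_x = 7,
                       mean_y = 45, seed = NULL) {
  spec <- cohort_spec(n = n, mean_x = mean_x, sd_x = sd_x,
                      mean_y = mean_y, k = k, cor = rho)
  generate_bivariate(spec, seed = seed)
}

# Deterministic in-bounds cohort for algebraic checks.
grid_cohort <- function(x = c(5, 12, 20, 33, 41, 55), y = NULL) {
  if (is.null(y)) y <- 66 - 0.4 * (66 - x)
  recovery_dataset(x, y)
}

# A cohort drawn under the proportional recovery rule with Gaussian
# noise on the change score.
prr_cohort <- function(n = 200, beta = 0.7, noise_sd = 4, seed = 1) {
  set.seed(seed)
  x <- runif(n, 5, 60)
  d <- beta * (66 - x) + rnorm(n, 0, noise_sd)
  y <- pmin(pmax(x + d, 0), 66)
  recovery_dataset(x, y)
}

# Constant recovery + ceiling cohort (the censored-regression truth).
ceiling_cohort <- function(n = 200, shift = 40, noise_sd = 5, seed = 1) {
  set.seed(seed)
  x <- runif(n, 0, 60)
  y <- pmin(pmax(x + shift + rnorm(n, 0, noise_sd), 0), 66)
  recovery_dataset(x, y)
}

# Labelled cohort: recoverers follow the PRR, non-recoverers change
# little regardless of baseline.
labelled_cohort <- function(n_rec = 60, n_non = 20, seed = 5) {
  set.seed(seed)
  xr <- runif(n_rec, 10, 55)
  yr <- pmin(xr + 0.7 * (66 - xr) + rnorm(n_rec, 0, 3), 66)
  xn <- runif(n_non, 2, 25)
  yn <- pmin(pmax(xn + rnorm(n_non, 1, 2), 0), 66)
  recovery_dataset(
    x = c(xr, xn), y = c(yr, yn),
    group = rep(c("recoverer", "non-recoverer"), c(n_rec, n_non))
  )
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}
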