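#' Specify a truncated bivariate-normal cohort
#'
#' A cohort specification for [generate_bivariate()]: latent baseline
#' and follow-up scores are bivariate normal with the given moments, and
#' subjects with any coordinate outside `bounds` are redrawn until the
#' whole cohort lies inside the scale.
#'
#' @param n Number of subjects (at least 2).
#' @param mean_x,sd_x Latent baseline mean and SD, scale units.
#' @param mean_y Latent follow-up mean, scale units.
#' @param k Target variance ratio \eqn{var(y)/var(x)} (the latent
#'   follow-up SD is `sd_x * sqrt(k)`).
#' @param cor Target latent correlation between baseline and follow-up.
#' @param bounds Length-2 scale bounds, default `c(0, 66)`.
#' @param seed Optional default seed used by [generate_bivariate()].
#' @return An object of class `cohort_spec`.
#' @seealso [dataset_preset()] for the named illustrative cohorts.
#' @export
cohort_spec <- function(n, mean_x, sd_x, mean_y, k, cor,
                        bounds = c(0, 66), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2L) {
    domain_error("`n` must be a single count >= 2")
  }
  if (sd_x <= 0) domain_error("`sd_x` must be positive")
  if (k <= 0) domain_error("the variance ratio `k` must be positive")
  if (cor < -1 || cor > 1) domain_error("`cor` must lie in [-1, 1]")
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    domain_error("`bounds` must be an ordered pair")
  }
  structure(
    list(
      n = as.integer(n), mean_x = mean_x, sd_x = sd_x, mean_y = mean_y,
      k = k, cor = cor, bounds = bounds, seed = seed
    ),
    class = "cohort_spec"
  )
}

# Parameters of the illustrative cohorts: x ~ Normal(30, 14), 30 (or
# 200) subjects, follow-up mean 30 or 53, variance ratio 1 or 0.16,
# latent correlation 0 or 0.9; all values kept inside [0, 66].
preset_table <- function() {
  list(
    A    = list(n = 30L,  mean_y = 30, k = 1,    cor = 0),
    B    = list(n = 30L,  mean_y = 30, k = 1,    cor = 0.9),
    C    = list(n = 30L,  mean_y = 53, k = 0.16, cor = 0),
    D    = list(n = 30L,  mean_y = 53, k = 0.16, cor = 0.9),
    C200 = list(n = 200L, mean_y = 53, k = 0.16, cor = 0),
    D200 = list(n = 200L, mean_y = 53, k = 0.16, cor = 0.9)
  )
}

#' Named preset cohorts
#'
#' Returns the generator settings for the illustrative datasets used
#' throughout the package: `A`--`D` (30 subjects) and `C200` / `D200`
#' (200 subjects) are truncated bivariate-normal cohorts differing in
#' the variance ratio and baseline-follow-up correlation; `E200` is
#' constant recovery with noise pushed against a hard ceiling; and
#' `random-recovery` draws follow-up uniformly between baseline and the
#' scale maximum.
#'
#' @param name One of `"A"`, `"B"`, `"C"`, `"D"`, `"C200"`, `"D200"`,
#'   `"E200"`, `"random-recovery"`.
#' @param seed Optional seed stored in the returned spec.
#' @return For the bivariate presets, a [cohort_spec()]; for `E200` and
#'   `random-recovery`, a named parameter list with a `generator` field.
#' @examples
#' generate_preset("D", seed = 1)
#' @export
dataset_preset <- function(name, seed = NULL) {
  tab <- preset_table()
  if (name %in% names(tab)) {
    p <- tab[[name]]
    return(cohort_spec(
      n = p$n, mean_x = 30, sd_x = 14, mean_y = p$mean_y,
      k = p$k, cor = p$cor, bounds = c(0, 66), seed = seed
    ))
  }
  if (name == "E200") {
    return(list(
      generator = "constant_ceiling", n = 200L, mean_x = 30, sd_x = 14,
      constant_shift = 40, noise_sd = constant_ceiling_noise_sd(14),
      scale_max = 66, scale_min = 0, seed = seed
    ))
  }
  if (name == "random-recovery") {
    return(list(
      generator = "random_recovery", n = 200L, x_min = 0, x_max = 60,
      scale_max = 66, scale_min = 0, seed = seed
    ))
  }
  config_error(sprintf(
    "unknown preset \"%s\"; choose from %s", name,
    paste(c(names(tab), "E200", "random-recovery"), collapse = ", ")
  ))
}

#' @rdname dataset_preset
#' @export
generate_preset <- function(name, seed = NULL) {
  spec <- dataset_preset(name, seed = seed)
  if (inherits(spec, "cohort_spec")) {
    return(generate_bivariate(spec, seed = seed))
  }
  if (spec$generator == "constant_ceiling") {
    return(generate_constant_ceiling(
      n = spec$n, mean_x = spec$mean_x, sd_x = spec$sd_x,
      constant_shift = spec$constant_shift, noise_sd = spec$noise_sd,
      scale_max = spec$scale_max, scale_min = spec$scale_min, seed = seed
    ))
  }
  with_seed(seed, {
    pool <- stats::runif(spec$n, spec$x_min, spec$x_max)
    generate_random_recovery(pool, n = spec$n, scale_max = spec$scale_max,
                             scale_min = spec$scale_min, seed = NULL)
  })
}

# Redraw cap: a subject is abandoned after ~1e5 rejected draws, which
# flags specs whose acceptance region has vanishing probability.
MAX_REDRAWS <- 1e5

#' Generate a bounded bivariate-normal cohort
#'
#' Draws `(x, y)` pairs from a bivariate normal with the moments in
#' `spec`; any subject with a coordinate outside `spec$bounds` is
#' redrawn (per-subject rejection), so the emitted cohort respects the
#' scale exactly while preserving `n` and approximately preserving the
#' joint shape. Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return A [recovery_dataset()].
#' @export
generate_bivariate <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "cohort_spec")) {
    validation_error("`spec` must be a cohort_spec")
  }
  with_seed(seed, {
    n <- spec$n
    sd_y <- spec$sd_x * sqrt(spec$k)
    rho <- spec$cor
    lo <- spec$bounds[1]
    hi <- spec$bounds[2]
    x <- numeric(n)
    y <- numeric(n)
    need <- rep(TRUE, n)
    tries <- 0L
    while (any(need)) {
      m <- sum(need)
      z1 <- stats::rnorm(m)
      z2 <- stats::rnorm(m)
      xi <- spec$mean_x + spec$sd_x * z1
      yi <- spec$mean_y + sd_y * (rho * z1 + sqrt(1 - rho^2) * z2)
      ok <- xi >= lo & xi <= hi & yi >= lo & yi <= hi
      idx <- which(need)[ok]
      x[idx] <- xi[ok]
      y[idx] <- yi[ok]
      need[idx] <- FALSE
      tries <- tries + 1L
      if (tries > MAX_REDRAWS) {
        generation_error(sprintf(
          "gave up after %d redraw rounds: the spec's acceptance region has vanishing probability",
          tries
        ))
      }
    }
    recovery_dataset(x, y, scale_max = hi, scale_min = lo)
  })
}

# Noise SD giving latent cor(x, x + c + noise) = 0.9 for additive
# independent noise: sd_x * sqrt(1/0.81 - 1).
constant_ceiling_noise_sd <- function(sd_x, target_cor = 0.9) {
  sd_x * sqrt(1 / target_cor^2 - 1)
}

#' Generate constant recovery with noise against a hard ceiling
#'
#' Latent follow-up is `y* = x + constant_shift + noise` with Gaussian
#' noise; the emitted follow-up is `min(y*, scale_max)` (and is floored
#' at `scale_min` so the cohort respects the scale). Baselines are drawn
#' from a normal and rejected into the scale range. With the defaults
#' (`mean_x = 30`, `constant_shift = 40`) the latent follow-up mean is
#' 70, above the 66 ceiling, so a sizeable fraction of follow-up scores
#' sit exactly at the maximum. The default `noise_sd` makes the latent
#' `cor(x, y*)` equal 0.9.
#'
#' @param n Number of subjects.
#' @param mean_x,sd_x Baseline mean and SD.
#' @param constant_shift The constant recovery c, scale units.
#' @param noise_sd SD of the additive Gaussian noise (non-negative).
#' @param scale_max,scale_min Scale bounds (default 66 and 0).
#' @param seed Optional seed.
#' @return A [recovery_dataset()].
#' @examples
#' d <- generate_constant_ceiling(200, seed = 1)
#' mean(d$y == 66)  # fraction at ceiling
#' @export
generate_constant_ceiling <- function(n, mean_x = 30, sd_x = 14,
                                      constant_shift = 40,
                                      noise_sd = constant_ceiling_noise_sd(sd_x),
                                      scale_max = 66, scale_min = 0,
                                      seed = NULL) {
  if (noise_sd < 0) domain_error("`noise_sd` must be non-negative")
  if (sd_x <= 0) domain_error("`sd_x` must be positive")
  with_seed(seed, {
    x <- numeric(n)
    need <- rep(TRUE, n)
    tries <- 0L
    while (any(need)) {
      m <- sum(need)
      xi <- stats::rnorm(m, mean_x, sd_x)
      ok <- xi >= scale_min & xi <= scale_max
      idx <- which(need)[ok]
      x[idx] <- xi[ok]
      need[idx] <- FALSE
      tries <- tries + 1L
      if (tries > MAX_REDRAWS) {
        generation_error("baseline acceptance region has vanishing probability")
      }
    }
    ystar <- x + constant_shift +
      (if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
    y <- pmax(pmin(ystar, scale_max), scale_min)
    recovery_dataset(x, y, scale_max = scale_max, scale_min = scale_min)
  })
}

#' Generate a cohort under "random recovery"
#'
#' The random-recovery null mechanism: baselines are sampled with
#' replacement from `x_pool`, and each follow-up is drawn uniformly
#' between the subject's baseline and the scale maximum,
#' \eqn{y_i \sim U(x_i, M)}. Under this mechanism
#' \eqn{E[\delta \mid x] = (M - x)/2}, so forced two-group clustering
#' tends to manufacture an apparent "recoverer" cluster.
#'
#' @param x_pool Baseline scores to resample from; all values must lie
#'   in `[scale_min, scale_max]`.
#' @param n Cohort size, default `length(x_pool)`.
#' @param scale_max,scale_min Scale bounds.
#' @param seed Optional seed.
#' @return A [recovery_dataset()].
#' @export
generate_random_recovery <- function(x_pool, n = length(x_pool),
                                     scale_max = 66, scale_min = 0,
                                     seed = NULL) {
  if (length(x_pool) == 0L) {
    domain_error("`x_pool` must be non-empty")
  }
  if (any(!is.finite(x_pool)) || any(x_pool > scale_max) ||
      any(x_pool < scale_min)) {
    domain_error(sprintf(
      "all pool values must lie in [%g, %g]", scale_min, scale_max
    ))
  }
  with_seed(seed, {
    x <- x_pool[sample.int(length(x_pool), n, replace = TRUE)]
    y <- stats::runif(n, x, scale_max)
    recovery_dataset(x, y, scale_max = scale_max, scale_min = scale_min)
  })
}
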