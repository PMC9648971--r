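#' Bootstrap inference for the variance ratio and the
#' baseline-follow-up correlation
#'
#' Resamples subjects (paired `x`, `y` values) with replacement,
#' recomputes \eqn{k = s_y^2 / s_x^2} and \eqn{cor(x, y)} on each
#' bootstrap sample, and returns percentile confidence intervals.
#' Resamples with zero variance in `x` or `y` are redrawn (and counted)
#' rather than propagated.
#'
#' @param dataset A [recovery_dataset()].
#' @param n_boot Number of bootstrap samples (default 1000).
#' @param conf_level Confidence level for the percentile intervals.
#' @param seed Optional seed; with a seed the result is fully
#'   reproducible.
#' @param group Optional group filter applied before resampling (the
#'   usual workflow bootstraps the recoverer subsample).
#' @return An object of class `prr_bootstrap` with fields `k_hat`,
#'   `cor_hat` (full-sample point estimates), `k_samples`,
#'   `cor_samples` (length `n_boot`), `k_ci`, `cor_ci` (percentile
#'   intervals), `conf_level`, `n`, `n_boot`, `n_degenerate`, `seed`.
#' @examples
#' d <- generate_preset("D", seed = 3)
#' bootstrap_k_cor(d, n_boot = 200, seed = 7)
#' @seealso [test_against_null()] to compare the intervals to null
#'   values; [confint.prr_bootstrap()] for intervals at other levels.
#' @export
bootstrap_k_cor <- function(dataset, n_boot = 1000, conf_level = 0.95,
                            seed = NULL, group = NULL) {
  assert_dataset(dataset)
  if (!is.null(group)) {
    dataset <- filter_group(dataset, group)
  }
  x <- dataset$x
  y <- dataset$y
  n <- length(x)
  if (n < 3L) {
    insufficient_data_error("bootstrap needs at least 3 subjects")
  }
  if (stats::sd(x) <= 0) degenerate_error("baseline x has zero variance")
  if (stats::sd(y) <= 0) degenerate_error("follow-up y has zero variance")
  if (n < 10L) {
    warning("fewer than 10 subjects; bootstrap intervals may be unreliable",
            call. = FALSE)
  }
  if (conf_level <= 0 || conf_level >= 1) {
    domain_error("`conf_level` must be in (0, 1)")
  }

  with_seed(seed, {
    draw <- boot_stats(x, y, n_boot)
    ks <- draw$k
    cs <- draw$cor
    n_degenerate <- 0L
    pass <- 0L
    bad <- which(!is.finite(ks) | !is.finite(cs))
    while (length(bad) > 0L) {
      n_degenerate <- n_degenerate + length(bad)
      redraw <- boot_stats(x, y, length(bad))
      ks[bad] <- redraw$k
      cs[bad] <- redraw$cor
      bad <- bad[!is.finite(ks[bad]) | !is.finite(cs[bad])]
      pass <- pass + 1L
      if (pass > 1000L) {
        inference_error("could not obtain non-degenerate bootstrap resamples")
      }
    }
    alpha <- (1 - conf_level) / 2
    structure(
      list(
        k_hat = stats::var(y) / stats::var(x),
        cor_hat = stats::cor(x, y),
        k_samples = ks,
        cor_samples = cs,
        k_ci = unname(stats::quantile(ks, c(alpha, 1 - alpha))),
        cor_ci = unname(stats::quantile(cs, c(alpha, 1 - alpha))),
        conf_level = conf_level,
        n = n,
        n_boot = as.integer(n_boot),
        n_degenerate = n_degenerate,
        seed = seed
      ),
      class = "prr_bootstrap"
    )
  })
}

# Vectorized k and cor(x, y) over B index resamples. Degenerate
# resamples surface as NaN/Inf and are redrawn by the caller.
boot_stats <- function(x, y, B) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  X <- matrix(x[idx], n, B)
  Y <- matrix(y[idx], n, B)
  sx <- colSums(X)
  sy <- colSums(Y)
  vx <- (colSums(X^2) - sx^2 / n) / (n - 1)
  vy <- (colSums(Y^2) - sy^2 / n) / (n - 1)
  cxy <- (colSums(X * Y) - sx * sy / n) / (n - 1)
  k <- ifelse(vx > 0, vy / vx, NaN)
  r <- ifelse(vx > 0 & vy > 0, cxy / sqrt(vx * vy), NaN)
  # exact resamples (e.g. y = x) can step just outside [-1, 1] in
  # floating point
  r <- pmin(pmax(r, -1), 1)
  list(k = k, cor = r)
}

#' @export
print.prr_bootstrap <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<prr_bootstrap> n = %d subjects, %d resamples (%d degenerate redrawn)\n",
    x$n, x$n_boot, x$n_degenerate
  ))
  cat(sprintf(
    "  k        = %.*f, %.0f%% CI [%.*f, %.*f]\n",
    digits, x$k_hat, 100 * x$conf_level,
    digits, x$k_ci[1], digits, x$k_ci[2]
  ))
  cat(sprintf(
    "  cor(x,y) = %.*f, %.0f%% CI [%.*f, %.*f]\n",
    digits, x$cor_hat, 100 * x$conf_level,
    digits, x$cor_ci[1], digits, x$cor_ci[2]
  ))
  invisible(x)
}

#' Percentile intervals from a bootstrap result at any level
#'
#' @param object A [bootstrap_k_cor()] result.
#' @param parm `"k"`, `"cor"`, or both.
#' @param level Confidence level.
#' @param ... Unused.
#' @return A matrix with one row per parameter and lower/upper columns.
#' @export
confint.prr_bootstrap <- function(object, parm = c("k", "cor"),
                                  level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  alpha <- (1 - level) / 2
  out <- t(vapply(parm, function(p) {
    s <- if (p == "k") object$k_samples else object$cor_samples
    unname(stats::quantile(s, c(alpha, 1 - alpha)))
  }, numeric(2)))
  colnames(out) <- sprintf("%g %%", 100 * c(alpha, 1 - alpha))
  out
}

#' Empirical null values of k and cor(x, y) under a generative mechanism
#'
#' For nulls stated as data-generating mechanisms (such as random
#' recovery) rather than parameter values, the corresponding null values
#' of the variance ratio and correlation are obtained by generating one
#' large dataset under the mechanism and computing both directly.
#'
#' @param null_generator A function taking a single cohort size `n` and
#'   returning a [recovery_dataset()].
#' @param n_large Size of the generated dataset (default `1e6`).
#' @param seed Optional seed.
#' @return A list with `k_null`, `cor_null`, and `n`.
#' @examples
#' nulls <- empirical_null_values(
#'   function(n) generate_random_recovery(runif(n, 0, 60), n = n),
#'   n_large = 1e5, seed = 1
#' )
#' @export
empirical_null_values <- function(null_generator, n_large = 1e6,
                                  seed = NULL) {
  if (!is.function(null_generator)) {
    config_error("`null_generator` must be a function of the cohort size")
  }
  with_seed(seed, {
    d <- null_generator(as.integer(n_large))
    assert_dataset(d)
    if (stats::sd(d$x) <= 0 || stats::sd(d$y) <= 0) {
      degenerate_error(
        "the null mechanism produced zero variance in x or y"
      )
    }
    list(
      k_null = stats::var(d$y) / stats::var(d$x),
      cor_null = stats::cor(d$x, d$y),
      n = length(d$x)
    )
  })
}

#' Compare bootstrap intervals to null values
#'
#' Rejects a null value when the percentile interval excludes it; an
#' interval endpoint exactly equal to the null counts as non-rejection
#' (closed-interval convention). The suggested null values are k = 1
#' ("no recovery": change unrelated to baseline beyond coupling) and
#' cor(x, y) = 0 (follow-up unrelated to baseline), but nulls derived
#' from other mechanisms -- e.g. [empirical_null_values()] under random
#' recovery -- can be supplied. No p-value is produced; the decision is
#' read directly from the interval.
#'
#' @param result A [bootstrap_k_cor()] result.
#' @param k_null,cor_null Null values (defaults 1 and 0).
#' @return An object of class `prr_null_test`: per parameter, the null
#'   value, interval, rejection decision, and direction (`"below"` /
#'   `"above"` the null when rejecting).
#' @export
test_against_null <- function(result, k_null = 1, cor_null = 0) {
  if (!inherits(result, "prr_bootstrap")) {
    validation_error("`result` must come from bootstrap_k_cor()")
  }
  one <- function(ci, null) {
    reject <- ci[1] > null || ci[2] < null
    direction <- if (!reject) NA_character_
                 else if (ci[2] < null) "below" else "above"
    list(null = null, ci = ci, reject = reject, direction = direction)
  }
  structure(
    list(
      k = one(result$k_ci, k_null),
      cor = one(result$cor_ci, cor_null),
      conf_level = result$conf_level
    ),
    class = "prr_null_test"
  )
}

#' @export
print.prr_null_test <- function(x, digits = 3, ...) {
  cat(sprintf("<prr_null_test> at %.0f%% confidence\n", 100 * x$conf_level))
  for (p in c("k", "cor")) {
    r <- x[[p]]
    cat(sprintf(
      "  %-3s null %.*f, CI [%.*f, %.*f]: %s\n",
      p, digits, r$null, digits, r$ci[1], digits, r$ci[2],
      if (r$reject) paste("reject,", r$direction, "null") else "fail to reject"
    ))
  }
  invisible(x)
}
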