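#' Closed-form surface for the baseline-change correlation
#'
#' For paired scores with baseline x and follow-up y, the correlation
#' between baseline and change \eqn{\delta = y - x} is fully determined
#' by the baseline-follow-up correlation \eqn{r = cor(x, y)} and the
#' variance ratio \eqn{k = \sigma_y^2 / \sigma_x^2}:
#' \deqn{cor(x, \delta) = \frac{s r - 1}{\sqrt{s^2 + 1 - 2 s r}},
#'   \quad s = \sqrt{k}.}
#' At \eqn{r = 0, k = 1} (independent, equal-variance scores -- the
#' canonical mathematical-coupling case) the surface equals
#' \eqn{-1/\sqrt{2} \approx -0.71}, which is why a null value of zero is
#' inappropriate for tests of \eqn{cor(x, \delta)}.
#'
#' @param cor_xy Correlation(s) between baseline and follow-up, in
#'   `[-1, 1]`.
#' @param k Variance ratio(s) \eqn{var(y)/var(x)}, strictly positive.
#'   Recycled against `cor_xy`.
#' @return Numeric vector of implied values of \eqn{cor(x, \delta)},
#'   each in `[-1, 1]`.
#' @examples
#' cor_x_delta_surface(0, 1)      # -0.7071, the coupling anchor
#' cor_x_delta_surface(0.9, 0.16) # strong follow-up compression
#' @seealso [null_cor_x_delta()] for the k = 1 ("no recovery") contour.
#' @export
cor_x_delta_surface <- function(cor_xy, k) {
  if (!is.numeric(cor_xy) || !is.numeric(k)) {
    domain_error("`cor_xy` and `k` must be numeric")
  }
  if (any(!is.finite(cor_xy)) || any(cor_xy < -1 | cor_xy > 1)) {
    domain_error("`cor_xy` must lie in [-1, 1]")
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    domain_error("the variance ratio `k` must be strictly positive")
  }
  m <- max(length(cor_xy), length(k))
  cor_xy <- rep_len(cor_xy, m)
  k <- rep_len(k, m)
  s <- sqrt(k)
  denom_sq <- s^2 + 1 - 2 * s * cor_xy
  if (any(denom_sq <= .Machine$double.eps)) {
    degenerate_error(
      "cor_xy = 1 with k = 1 implies a change score with zero variance"
    )
  }
  out <- (s * cor_xy - 1) / sqrt(denom_sq)
  pmin(pmax(out, -1), 1)
}

#' Null value for the baseline-change correlation under "no recovery"
#'
#' The "no recovery" null keeps the variance ratio at k = 1, so the
#' appropriate null value for a test of \eqn{cor(x, \delta)} is the k = 1
#' contour of the coupling surface,
#' \deqn{-\sqrt{(1 - cor(x, y)) / 2},}
#' not zero. At \eqn{cor(x, y) = 0} this equals \eqn{-0.71}.
#'
#' @param cor_xy Correlation(s) between baseline and follow-up, in
#'   `[-1, 1)`.
#' @return The null value(s) of \eqn{cor(x, \delta)}.
#' @examples
#' null_cor_x_delta(0)   # -0.7071
#' null_cor_x_delta(0.5) # -0.5
#' @export
null_cor_x_delta <- function(cor_xy) {
  if (!is.numeric(cor_xy) || any(!is.finite(cor_xy)) ||
      any(cor_xy < -1 | cor_xy > 1)) {
    domain_error("`cor_xy` must lie in [-1, 1)")
  }
  if (any(cor_xy == 1)) {
    degenerate_error(
      "cor_xy = 1 with k = 1 implies a change score with zero variance"
    )
  }
  -sqrt((1 - cor_xy) / 2)
}

#' Oldham's correlation
#'
#' Oldham's method replaces \eqn{cor(x, \delta)} with
#' \eqn{cor(x + y, x - y)}, which equals zero exactly when
#' \eqn{var(x) = var(y)} regardless of \eqn{cor(x, y)}, and therefore
#' sidesteps mathematical coupling: its sign matches the sign of
#' \eqn{1 - k}.
#'
#' @param dataset A [recovery_dataset()].
#' @return The Pearson correlation of `x + y` with `x - y`.
#' @export
oldham_correlation <- function(dataset) {
  assert_dataset(dataset)
  if (length(dataset$x) < 3L) {
    insufficient_data_error("Oldham's correlation needs at least 3 subjects")
  }
  s <- dataset$x + dataset$y
  d <- dataset$x - dataset$y
  if (stats::var(s) <= 0) {
    degenerate_error("x + y has zero variance; Oldham's correlation undefined")
  }
  if (stats::var(d) <= 0) {
    degenerate_error("x - y has zero variance; Oldham's correlation undefined")
  }
  stats::cor(s, d)
}

#' Descriptive summary of a recovery cohort
#'
#' Computes sample moments, the variance ratio
#' \eqn{k = s_y^2 / s_x^2}, and the three correlations central to
#' baseline-change analyses: \eqn{cor(x, y)}, \eqn{cor(x, \delta)}
#' (computed directly from the paired data), and Oldham's
#' \eqn{cor(x + y, x - y)}. All variances use n - 1 denominators. The
#' directly computed \eqn{cor(x, \delta)} always agrees with
#' [cor_x_delta_surface()] evaluated at the sample \eqn{cor(x, y)} and k
#' (an algebraic identity).
#'
#' @param dataset A [recovery_dataset()].
#' @param group Optional group filter (`"recoverer"`,
#'   `"non-recoverer"`, `"unknown"`) applied before summarizing.
#' @return An object of class `recovery_summary`: a list with fields
#'   `n`, `mean_x`, `mean_y`, `sd_x`, `sd_y`, `k`, `cor_xy`,
#'   `cor_xdelta`, `cor_oldham`, and `degenerate` (character notes, e.g.
#'   `"constant change"` when \eqn{sd(\delta) = 0} makes
#'   \eqn{cor(x, \delta)} undefined).
#' @examples
#' d <- recovery_dataset(x = c(10, 20, 40, 55), y = c(45, 50, 58, 63))
#' summarize_recovery(d)
#' @export
summarize_recovery <- function(dataset, group = NULL) {
  assert_dataset(dataset)
  if (!is.null(group)) {
    dataset <- filter_group(dataset, group)
  }
  x <- dataset$x
  y <- dataset$y
  n <- length(x)
  if (n < 3L) {
    insufficient_data_error(sprintf(
      "summary needs at least 3 subjects (have %d)", n
    ))
  }
  sd_x <- stats::sd(x)
  sd_y <- stats::sd(y)
  if (sd_x <= 0) {
    degenerate_error("baseline x has zero variance")
  }
  if (sd_y <= 0) {
    degenerate_error("follow-up y has zero variance")
  }
  d <- y - x
  degenerate <- character(0)
  if (stats::sd(d) <= 0) {
    cor_xdelta <- NA_real_
    degenerate <- c(degenerate, "constant change")
  } else {
    cor_xdelta <- stats::cor(x, d)
  }
  if (stats::var(x + y) <= 0 || stats::var(x - y) <= 0) {
    cor_oldham <- NA_real_
    degenerate <- c(degenerate, "degenerate Oldham sums")
  } else {
    cor_oldham <- stats::cor(x + y, x - y)
  }
  structure(
    list(
      n = n,
      mean_x = mean(x), mean_y = mean(y),
      sd_x = sd_x, sd_y = sd_y,
      k = sd_y^2 / sd_x^2,
      cor_xy = stats::cor(x, y),
      cor_xdelta = cor_xdelta,
      cor_oldham = cor_oldham,
      degenerate = degenerate
    ),
    class = "recovery_summary"
  )
}

#' @export
print.recovery_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<recovery_summary> n = %d\n", x$n))
  cat(sprintf(
    "  mean x = %.*f (sd %.*f), mean y = %.*f (sd %.*f)\n",
    digits, x$mean_x, digits, x$sd_x, digits, x$mean_y, digits, x$sd_y
  ))
  cat(sprintf(
    "  k = var(y)/var(x) = %.*f\n  cor(x, y) = %.*f\n",
    digits, x$k, digits, x$cor_xy
  ))
  cat(sprintf(
    "  cor(x, delta) = %s\n  Oldham cor(x+y, x-y) = %s\n",
    format_or_na(x$cor_xdelta, digits), format_or_na(x$cor_oldham, digits)
  ))
  if (length(x$degenerate) > 0L) {
    cat("  notes:", paste(x$degenerate, collapse = "; "), "\n")
  }
  invisible(x)
}

format_or_na <- function(v, digits) {
  if (is.na(v)) "undefined (degenerate)" else sprintf("%.*f", digits, v)
}

#' Proportion of follow-up variation explained by the proportional
#' recovery rule
#'
#' Fitted follow-up values are formed by adding the PRR-predicted change
#' to the observed baseline, \eqn{\hat y_i = x_i + \hat\beta (M - x_i)},
#' and the statistic is
#' \deqn{1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2.}
#' Because the PRR is fitted to the change score without an intercept,
#' the value is not an ordinary regression R-squared: it can be
#' negative, and is bounded above by 1.
#'
#' @param dataset A [recovery_dataset()] (use [filter_group()] first to
#'   restrict to recoverers, as in the usual workflow).
#' @param prr_fit A fitted PRR model from [fit_prr()]. Defaults to a PRR
#'   fit on `dataset` itself.
#' @return A single number, at most 1 and unbounded below.
#' @export
prr_variance_explained <- function(dataset, prr_fit = fit_prr(dataset)) {
  assert_dataset(dataset)
  if (!inherits(prr_fit, "prr_model_prr")) {
    validation_error("`prr_fit` must be a fitted PRR model (see fit_prr())")
  }
  n <- length(dataset$x)
  if (n < 3L) {
    insufficient_data_error("needs at least 3 subjects")
  }
  y <- dataset$y
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) {
    degenerate_error("follow-up y has zero variance")
  }
  yhat <- predict(prr_fit, dataset$x)
  1 - sum((y - yhat)^2) / sst
}
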