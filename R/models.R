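#' Candidate recovery models
#'
#' Five models for follow-up as a function of baseline share a uniform
#' fit/predict contract:
#'
#' * `intercept_only` -- follow-up varies around a common mean,
#'   independent of baseline.
#' * `constant_ceiling` -- constant recovery pushed against the scale
#'   ceiling, `y = min(x + c + noise, M)`, fitted as censored-normal
#'   (Tobit) regression with offset x and unit slope.
#' * `exponential` -- `E[y | x] = M - A exp(-r x)`: recovery approaches
#'   the ceiling as baseline grows, and collapses to a constant mean
#'   `M - A` as `r -> 0`.
#' * `smooth_additive` -- a penalized cubic regression spline of y on x
#'   (a generalized additive model), smoothing parameter chosen by GCV.
#' * `prr` -- the proportional recovery rule: change is a fixed
#'   proportion of initial impairment, \eqn{\delta = \beta (M - x)},
#'   fitted through the origin (no intercept).
#'
#' Predictions from every family are clipped to the scale range
#' `[scale_min, scale_max]`.
#'
#' @param family One of [recovery_families()].
#' @param train A [recovery_dataset()] used for fitting.
#' @param ... Passed to the family's fit function.
#' @return An object of classes `prr_model_<family>` and
#'   `recovery_model`, with fields `family`, `parameters`, `n_train`,
#'   `converged`, `scale_max`, `scale_min`.
#' @examples
#' d <- generate_preset("D200", seed = 2)
#' fit <- fit_recovery_model("prr", d)
#' predict(fit, c(10, 30, 50))
#' @export
fit_recovery_model <- function(family, train, ...) {
  registry <- model_registry()
  if (!family %in% names(registry)) {
    config_error(sprintf(
      "unknown model family \"%s\"; choose from %s",
      family, paste(names(registry), collapse = ", ")
    ))
  }
  registry[[family]](train, ...)
}

#' @rdname fit_recovery_model
#' @export
recovery_families <- function() {
  names(model_registry())
}

model_registry <- function() {
  list(
    intercept_only = fit_intercept_only,
    constant_ceiling = fit_constant_ceiling,
    exponential = fit_exponential,
    smooth_additive = fit_smooth_additive,
    prr = fit_prr
  )
}

new_recovery_model <- function(family, parameters, train, converged = TRUE,
                               extra = list()) {
  structure(
    c(
      list(
        family = family,
        parameters = parameters,
        n_train = length(train$x),
        converged = converged,
        scale_max = train$scale_max,
        scale_min = train$scale_min
      ),
      extra
    ),
    class = c(paste0("prr_model_", family), "recovery_model")
  )
}

#' @rdname fit_recovery_model
#' @export
fit_intercept_only <- function(train, ...) {
  assert_dataset(train)
  if (length(train$x) < 2L) {
    insufficient_data_error("intercept-only fit needs at least 2 subjects")
  }
  new_recovery_model("intercept_only", list(mu = mean(train$y)), train)
}

#' @rdname fit_recovery_model
#' @param scale_max Ceiling M used for censoring / the model form;
#'   defaults to the dataset's scale maximum.
#' @export
fit_constant_ceiling <- function(train, scale_max = train$scale_max, ...) {
  assert_dataset(train)
  x <- train$x
  y <- train$y
  if (length(x) < 3L) {
    insufficient_data_error("Tobit fit needs at least 3 subjects")
  }
  M <- scale_max
  cens <- y >= M - 1e-9
  if (all(cens)) {
    degenerate_error(
      "all observations are at the ceiling; the constant is not identifiable"
    )
  }
  d <- y - x
  if (!any(cens)) {
    # no censoring: the censored-normal MLE reduces to the normal MLE
    fit <- list(c = mean(d), sigma = stats::sd(d))
    return(new_recovery_model("constant_ceiling",
                              list(c = fit$c, sigma = fit$sigma), train,
                              extra = list(n_censored = 0L)))
  }
  c0 <- mean(d[!cens])
  resid_sd <- stats::sd(d[!cens])
  if (!is.finite(resid_sd) || resid_sd < 1e-8) {
    # (near) noise-free data: the uncensored rows pin down c exactly
    return(new_recovery_model("constant_ceiling",
                              list(c = c0, sigma = max(resid_sd, 1e-8, na.rm = TRUE)),
                              train, extra = list(n_censored = sum(cens))))
  }
  yu <- y[!cens] - x[!cens]
  xc <- x[cens]
  nll <- function(p) {
    cc <- p[1]
    s <- exp(p[2])
    -(sum(stats::dnorm(yu - cc, 0, s, log = TRUE)) +
        sum(stats::pnorm(M - xc - cc, 0, s,
                         lower.tail = FALSE, log.p = TRUE)))
  }
  opt <- stats::optim(c(c0, log(resid_sd)), nll, method = "BFGS",
                      control = list(maxit = 500))
  new_recovery_model(
    "constant_ceiling",
    list(c = opt$par[1], sigma = exp(opt$par[2])),
    train,
    converged = opt$convergence == 0L,
    extra = list(n_censored = sum(cens), optim_message = opt$message)
  )
}

#' @rdname fit_recovery_model
#' @export
fit_exponential <- function(train, scale_max = train$scale_max, ...) {
  assert_dataset(train)
  if (length(train$x) < 3L) {
    insufficient_data_error("exponential fit needs at least 3 subjects")
  }
  M <- scale_max
  df <- data.frame(x = train$x, y = train$y)
  start <- exp_start_values(df, M)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ M - A * exp(-r * x),
      data = df,
      start = start,
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # fallback: constant mean (the r -> 0 limit), flagged unconverged
    return(new_recovery_model(
      "exponential",
      list(A = max(M - mean(df$y), 0), r = 0),
      train, converged = FALSE,
      extra = list(start = start)
    ))
  }
  co <- stats::coef(fit)
  new_recovery_model(
    "exponential",
    list(A = unname(co["A"]), r = unname(co["r"])),
    train,
    extra = list(start = start)
  )
}

# Start values from a linearization: M - y ~ A exp(-r x), so
# log(M - y) is linear in x. Falls back to the constant-mean limit.
exp_start_values <- function(df, M) {
  st <- tryCatch({
    lf <- stats::lm(log(pmax(M - df$y, 0.5)) ~ df$x)
    list(
      A = max(unname(exp(stats::coef(lf)[1])), 1e-3),
      r = max(unname(-stats::coef(lf)[2]), 1e-4)
    )
  }, error = function(e) NULL)
  if (is.null(st) || !all(vapply(st, is.finite, TRUE))) {
    st <- list(A = max(M - mean(df$y), 1e-3), r = 0.01)
  }
  st
}

#' @rdname fit_recovery_model
#' @export
fit_smooth_additive <- function(train, ...) {
  assert_dataset(train)
  n <- length(train$x)
  if (n < 4L) {
    insufficient_data_error("additive fit needs at least 4 subjects")
  }
  if (n < 10L) {
    warning("fewer than 10 subjects; the smooth fit may be unstable",
            call. = FALSE)
  }
  df <- data.frame(x = train$x, y = train$y)
  kb <- max(3L, min(10L, n - 2L))
  fit <- NULL
  while (is.null(fit) && kb >= 3L) {
    fit <- tryCatch(
      mgcv::gam(y ~ s(x, k = kb, bs = "cr"), data = df,
                method = "GCV.Cp"),
      error = function(e) NULL
    )
    if (is.null(fit)) kb <- kb - 1L
  }
  if (is.null(fit)) {
    degenerate_error("could not fit a penalized spline (singular basis)")
  }
  new_recovery_model(
    "smooth_additive",
    list(
      sp = unname(fit$sp),
      edf = sum(fit$edf),
      basis_dim = kb,
      coefficients = unname(stats::coef(fit))
    ),
    train,
    extra = list(engine = fit)
  )
}

#' @rdname fit_recovery_model
#' @export
fit_prr <- function(train, scale_max = train$scale_max, ...) {
  assert_dataset(train)
  if (length(train$x) < 2L) {
    insufficient_data_error("PRR fit needs at least 2 subjects")
  }
  M <- scale_max
  impair <- M - train$x
  if (all(impair <= 0)) {
    degenerate_error(
      "all baselines are at the ceiling; the recovery proportion is undefined"
    )
  }
  d <- train$y - train$x
  beta <- sum(d * impair) / sum(impair^2)
  new_recovery_model("prr", list(beta = beta), train)
}

#' Predict follow-up scores from a fitted recovery model
#'
#' @param object A fitted model from [fit_recovery_model()].
#' @param newdata Baseline scores: a numeric vector, a
#'   [recovery_dataset()], or a data frame with an `x` column.
#' @param ... Unused.
#' @return Predicted follow-up scores, clipped to the scale range.
#' @export
predict.recovery_model <- function(object, newdata, ...) {
  x <- extract_x(newdata)
  p <- predict_raw(object, x)
  pmin(pmax(p, object$scale_min), object$scale_max)
}

extract_x <- function(newdata) {
  if (inherits(newdata, "recovery_dataset")) {
    return(newdata$x)
  }
  if (is.data.frame(newdata)) {
    if (!"x" %in% names(newdata)) {
      validation_error("`newdata` data frame must have an `x` column")
    }
    return(newdata$x)
  }
  if (is.numeric(newdata)) {
    return(as.numeric(newdata))
  }
  validation_error("`newdata` must be numeric, a data frame, or a dataset")
}

predict_raw <- function(object, x) UseMethod("predict_raw")

#' @export
predict_raw.prr_model_intercept_only <- function(object, x) {
  rep(object$parameters$mu, length(x))
}

#' @export
predict_raw.prr_model_constant_ceiling <- function(object, x) {
  pmin(x + object$parameters$c, object$scale_max)
}

#' @export
predict_raw.prr_model_exponential <- function(object, x) {
  object$scale_max - object$parameters$A * exp(-object$parameters$r * x)
}

#' @export
predict_raw.prr_model_smooth_additive <- function(object, x) {
  as.numeric(stats::predict(object$engine, newdata = data.frame(x = x)))
}

#' @export
predict_raw.prr_model_prr <- function(object, x) {
  x + object$parameters$beta * (object$scale_max - x)
}

#' @export
print.recovery_model <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<recovery_model: %s> fitted to %d subjects%s\n",
    x$family, x$n_train,
    if (isTRUE(x$converged)) "" else " (NOT converged)"
  ))
  p <- x$parameters
  scalars <- p[vapply(p, function(v) length(v) == 1L, TRUE)]
  cat("  ", paste(sprintf("%s = %s", names(scalars),
                          vapply(scalars, function(v) format(v, digits = digits), "")),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Serializable view of a fitted model: scalar parameters + metadata,
# without fit engines.
model_to_list <- function(fit) {
  p <- fit$parameters
  p <- p[vapply(p, function(v) length(v) <= 25L, TRUE)]
  list(
    family = fit$family,
    parameters = p,
    n_train = fit$n_train,
    converged = fit$converged,
    scale_max = fit$scale_max,
    scale_min = fit$scale_min
  )
}
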