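#' Cross-validated comparison of recovery models
#'
#' Repeated random-split cross-validation: each split assigns
#' `round(train_frac * n)` subjects to training (round-half-up) and the
#' remainder to testing; every family is fitted on the same training
#' subjects and scored by the median absolute prediction error (MAPE)
#' of its follow-up predictions on the held-out subjects. The split
#' stream depends only on the dataset size and seed, never on the
#' family list, so adding a family leaves all other columns unchanged.
#' A family that fails to fit (or does not converge) on a split yields a
#' missing MAPE for that cell, counted in `n_failed`, rather than being
#' imputed or re-split.
#'
#' @param dataset A [recovery_dataset()].
#' @param families Character vector of model families (default: all of
#'   [recovery_families()]).
#' @param n_splits Number of random splits (default 1000).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Optional seed.
#' @param group Optional group filter applied first.
#' @return An object of class `prr_cv`: `mape` is an
#'   `n_splits x length(families)` matrix of per-split MAPEs (scale
#'   units), plus `families`, `n_splits`, `train_frac`, `n_failed`,
#'   `seed`.
#' @examples
#' d <- generate_preset("D200", seed = 5)
#' cv <- cv_compare(d, n_splits = 50, seed = 9)
#' summarize_cv(cv)
#' @export
cv_compare <- function(dataset, families = recovery_families(),
                       n_splits = 1000, train_frac = 0.8, seed = NULL,
                       group = NULL) {
  assert_dataset(dataset)
  if (!is.null(group)) {
    dataset <- filter_group(dataset, group)
  }
  known <- recovery_families()
  bad <- setdiff(families, known)
  if (length(bad) > 0L) {
    config_error(sprintf(
      "unknown model famil%s: %s",
      if (length(bad) > 1L) "ies" else "y", paste(bad, collapse = ", ")
    ))
  }
  if (anyDuplicated(families)) {
    config_error("`families` must not contain duplicates")
  }
  n <- length(dataset$x)
  if (n < 10L) {
    insufficient_data_error("cross-validation needs at least 10 subjects")
  }
  if (train_frac <= 0 || train_frac >= 1) {
    domain_error("`train_frac` must be in (0, 1)")
  }
  n_train <- floor(train_frac * n + 0.5)  # round half up
  n_test <- n - n_train
  if (n_test < 2L) {
    insufficient_data_error("test split must contain at least 2 subjects")
  }

  with_seed(seed, {
    # all split indices are drawn before any fitting, so the split
    # stream is independent of the family list
    splits <- lapply(seq_len(n_splits), function(s) {
      sample.int(n, n_train)
    })
    mape <- matrix(NA_real_, nrow = n_splits, ncol = length(families),
                   dimnames = list(NULL, families))
    n_failed <- integer(length(families))
    names(n_failed) <- families
    for (s in seq_len(n_splits)) {
      tr_idx <- splits[[s]]
      train <- dataset_subset(dataset, tr_idx)
      test <- dataset_subset(dataset, -tr_idx)
      for (f in families) {
        val <- tryCatch({
          fit <- fit_recovery_model(f, train)
          if (!isTRUE(fit$converged)) {
            NA_real_
          } else {
            stats::median(abs(predict(fit, test$x) - test$y))
          }
        }, error = function(e) NA_real_)
        if (is.na(val)) {
          n_failed[f] <- n_failed[f] + 1L
        }
        mape[s, f] <- val
      }
    }
    structure(
      list(
        mape = mape,
        families = families,
        n_splits = as.integer(n_splits),
        train_frac = train_frac,
        n_train = n_train,
        n_failed = n_failed,
        seed = seed
      ),
      class = "prr_cv"
    )
  })
}

#' Summarize and rank a cross-validation run
#'
#' Per-family mean and median MAPE over non-missing splits, the matrix
#' of pairwise mean differences, and a rank order by mean MAPE (lower
#' is better). Exact ties are ranked lexicographically by family name
#' and flagged.
#'
#' @param result A [cv_compare()] result.
#' @return An object of class `prr_cv_summary` with a `table` data
#'   frame (family, n_ok, mean_mape, median_mape, rank, tied) and a
#'   `pairwise` matrix of differences in mean MAPE (row minus column).
#' @export
summarize_cv <- function(result) {
  if (!inherits(result, "prr_cv")) {
    validation_error("`result` must come from cv_compare()")
  }
  fams <- result$families
  mean_mape <- apply(result$mape, 2, mean, na.rm = TRUE)
  median_mape <- apply(result$mape, 2, stats::median, na.rm = TRUE)
  n_ok <- colSums(!is.na(result$mape))
  ord <- order(mean_mape, fams)
  rank <- integer(length(fams))
  rank[ord] <- seq_along(fams)
  tied <- vapply(seq_along(fams), function(i) {
    sum(mean_mape == mean_mape[i], na.rm = TRUE) > 1L
  }, TRUE)
  pairwise <- outer(mean_mape, mean_mape, "-")
  dimnames(pairwise) <- list(fams, fams)
  structure(
    list(
      table = data.frame(
        family = fams,
        n_ok = as.integer(n_ok),
        mean_mape = unname(mean_mape),
        median_mape = unname(median_mape),
        rank = rank,
        tied = tied,
        stringsAsFactors = FALSE
      ),
      pairwise = pairwise,
      n_splits = result$n_splits
    ),
    class = "prr_cv_summary"
  )
}

#' @export
print.prr_cv_summary <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<prr_cv_summary> %d splits; MAPE in scale units (lower is better)\n",
    x$n_splits
  ))
  tab <- x$table[order(x$table$rank), ]
  tab$mean_mape <- round(tab$mean_mape, digits)
  tab$median_mape <- round(tab$median_mape, digits)
  print(tab, row.names = FALSE)
  if (any(x$table$tied)) {
    cat("  note: exact ties broken lexicographically by family name\n")
  }
  invisible(x)
}

#' @export
print.prr_cv <- function(x, ...) {
  cat(sprintf(
    "<prr_cv> %d splits x %d families (train fraction %.2f, n_train %d)\n",
    x$n_splits, length(x$families), x$train_frac, x$n_train
  ))
  if (any(x$n_failed > 0L)) {
    f <- x$n_failed[x$n_failed > 0L]
    cat("  failed fits:",
        paste(sprintf("%s = %d", names(f), f), collapse = ", "), "\n")
  }
  print(summarize_cv(x))
  invisible(x)
}
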