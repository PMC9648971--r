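#' Construct a recovery dataset
#'
#' A recovery dataset holds paired baseline (`x`) and follow-up (`y`)
#' impairment scores on a bounded scale, with an optional recoverer /
#' non-recoverer label per subject. The change score \eqn{\delta = y - x}
#' and the initial impairment \eqn{M - x} are always derived from `x`
#' and `y` (see [delta()] and [initial_impairment()]), never stored.
#'
#' @param x,y Numeric vectors of equal length: baseline and follow-up
#'   scores in scale units. All values must lie in
#'   `[scale_min, scale_max]`.
#' @param subject_id Optional identifiers, one per subject. Defaults to
#'   the row index.
#' @param group Optional character vector of group labels, matched
#'   case-insensitively to `"recoverer"` / `"non-recoverer"`
#'   (`"non_recoverer"` and `"nonrecoverer"` are also accepted). Other
#'   labels are mapped to `"unknown"` with a warning.
#' @param scale_max Scale maximum M (default 66, the FMA-UE ceiling).
#' @param scale_min Scale minimum (default 0).
#'
#' @return An object of class `recovery_dataset`: a list with elements
#'   `x`, `y`, `subject_id`, `group`, `scale_max`, `scale_min`.
#' @examples
#' d <- recovery_dataset(x = c(10, 30, 50), y = c(40, 55, 62))
#' delta(d)
#' initial_impairment(d)
#' @export
recovery_dataset <- function(x, y, subject_id = NULL, group = NULL,
                             scale_max = 66, scale_min = 0) {
  if (!is.numeric(x) || !is.numeric(y)) {
    validation_error("`x` and `y` must be numeric")
  }
  if (length(x) != length(y)) {
    validation_error(sprintf(
      "`x` (n = %d) and `y` (n = %d) must have equal length",
      length(x), length(y)
    ))
  }
  n <- length(x)
  if (n < 1L) {
    insufficient_data_error("a recovery dataset needs at least one subject")
  }
  if (!is.numeric(scale_max) || length(scale_max) != 1L ||
      !is.numeric(scale_min) || length(scale_min) != 1L ||
      !is.finite(scale_max) || !is.finite(scale_min) ||
      scale_max <= scale_min) {
    validation_error("`scale_min` must be finite and below `scale_max`")
  }
  if (anyNA(x) || anyNA(y)) {
    bad <- which(is.na(x) | is.na(y))
    validation_error(sprintf(
      "missing x or y for subject(s): %s", paste(bad, collapse = ", ")
    ))
  }
  out_of_range <- which(
    x < scale_min | x > scale_max | y < scale_min | y > scale_max
  )
  if (length(out_of_range) > 0L) {
    validation_error(sprintf(
      "scores outside [%g, %g] in row(s): %s",
      scale_min, scale_max,
      paste(utils::head(out_of_range, 10L), collapse = ", ")
    ))
  }
  if (is.null(subject_id)) {
    subject_id <- as.character(seq_len(n))
  } else {
    subject_id <- as.character(subject_id)
    if (length(subject_id) != n) {
      validation_error("`subject_id` must have one entry per subject")
    }
  }
  group <- normalize_group(group, n)
  structure(
    list(
      x = as.numeric(x), y = as.numeric(y),
      subject_id = subject_id, group = group,
      scale_max = scale_max, scale_min = scale_min
    ),
    class = "recovery_dataset"
  )
}

normalize_group <- function(group, n) {
  if (is.null(group)) {
    return(rep("unknown", n))
  }
  group <- as.character(group)
  if (length(group) != n) {
    validation_error("`group` must have one entry per subject")
  }
  canon <- tolower(trimws(group))
  canon <- gsub("[ _]", "-", canon)
  canon[canon %in% c("nonrecoverer", "non-recoverer")] <- "non-recoverer"
  canon[is.na(group) | canon == ""] <- "unknown"
  unknown <- !(canon %in% c("recoverer", "non-recoverer", "unknown"))
  if (any(unknown)) {
    warning(sprintf(
      "unrecognized group label(s) %s mapped to \"unknown\"",
      paste(unique(group[unknown]), collapse = ", ")
    ), call. = FALSE)
    canon[unknown] <- "unknown"
  }
  canon
}

#' Change score and initial impairment
#'
#' `delta()` returns the change score \eqn{\delta = y - x};
#' `initial_impairment()` returns \eqn{M - x}, the maximal potential
#' recovery from baseline.
#'
#' @param dataset A [recovery_dataset()].
#' @return A numeric vector, one value per subject.
#' @export
delta <- function(dataset) {
  assert_dataset(dataset)
  dataset$y - dataset$x
}

#' @rdname delta
#' @export
initial_impairment <- function(dataset) {
  assert_dataset(dataset)
  dataset$scale_max - dataset$x
}

#' Filter a dataset by group label
#'
#' @param dataset A [recovery_dataset()].
#' @param group `"recoverer"`, `"non-recoverer"`, or `"unknown"`.
#' @return A [recovery_dataset()] restricted to the matching subjects.
#' @export
filter_group <- function(dataset, group) {
  assert_dataset(dataset)
  group <- match.arg(group, c("recoverer", "non-recoverer", "unknown"))
  keep <- which(dataset$group == group)
  if (length(keep) == 0L) {
    insufficient_data_error(sprintf("no subjects with group \"%s\"", group))
  }
  dataset_subset(dataset, keep)
}

dataset_subset <- function(dataset, idx) {
  structure(
    list(
      x = dataset$x[idx], y = dataset$y[idx],
      subject_id = dataset$subject_id[idx], group = dataset$group[idx],
      scale_max = dataset$scale_max, scale_min = dataset$scale_min
    ),
    class = "recovery_dataset"
  )
}

assert_dataset <- function(dataset) {
  if (!inherits(dataset, "recovery_dataset")) {
    validation_error("expected a `recovery_dataset` object")
  }
  invisible(dataset)
}

#' @export
length.recovery_dataset <- function(x) length(x$x)

#' @export
as.data.frame.recovery_dataset <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id, x = x$x, y = x$y, group = x$group,
    stringsAsFactors = FALSE
  )
}

#' @export
print.recovery_dataset <- function(x, ...) {
  cat(sprintf(
    "<recovery_dataset> n = %d, scale [%g, %g]\n",
    length(x$x), x$scale_min, x$scale_max
  ))
  tab <- table(x$group)
  cat("  groups:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf(
    "  mean x = %.1f, mean y = %.1f, mean delta = %.1f\n",
    mean(x$x), mean(x$y), mean(x$y - x$x)
  ))
  invisible(x)
}
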