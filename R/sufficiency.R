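#' Coefficient of variation (percent)
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector with at least 2 values and nonzero mean.
#' @return CV in percent (>= 0 for non-negative-mean data).
#' @examples
#' coefficient_of_variation(c(8, 12)) # 28.28427
#' @export
coefficient_of_variation <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    abort("`values` must be numeric with at least 2 elements.")
  }
  if (any(!is.finite(values))) abort("`values` must be finite.")
  m <- mean(values)
  if (m == 0) abort("CV is undefined for data with mean 0.")
  100 * sd(values) / m
}

#' Construct a CV curve from precomputed values
#'
#' Builds the object returned by [subset_cv_curve()] from already-known CV
#' values, e.g. when re-assessing a curve loaded from a report file.
#'
#' @param sizes Strictly increasing group sizes.
#' @param cv_pct CV values (%) per size.
#' @param metric Metric name the CVs refer to.
#' @param threshold_pct Sufficiency threshold (default 10).
#' @param n_subsets Subsets per size used to compute the CVs (default 4).
#' @return A `cv_curve`.
#' @export
cv_curve <- function(sizes, cv_pct, metric = "pct_colonized_area",
                     threshold_pct = 10, n_subsets = 4) {
  if (length(sizes) != length(cv_pct)) {
    abort("`sizes` and `cv_pct` must have equal length.")
  }
  if (is.unsorted(sizes, strictly = TRUE)) {
    abort("`sizes` must be strictly increasing.")
  }
  if (any(cv_pct < 0)) abort("CV values must be >= 0.")
  out <- tibble::tibble(size = as.integer(sizes), cv_pct = as.numeric(cv_pct))
  class(out) <- c("cv_curve", class(out))
  attr(out, "metric") <- metric
  attr(out, "threshold_pct") <- threshold_pct
  attr(out, "n_subsets") <- as.integer(n_subsets)
  out
}

#' CV convergence curve over random image subsets
#'
#' Assesses whether enough tiles were analyzed to estimate a colonization
#' metric reliably. For each group size `g`, `n_subsets` random subsets of
#' `g` tiles are drawn (without replacement within a subset; subsets are
#' independent and may overlap each other), the subset mean of the metric is
#' computed, and the CV across the subset means is recorded. For i.i.d.
#' tiles the curve decreases roughly as `1/sqrt(g)`; sampling is deemed
#' sufficient when the CV at the largest group size falls below the
#' threshold (default 10%).
#'
#' @param metrics Data frame of per-tile metrics (e.g. from
#'   [quantify_tiles()]), or a numeric vector of per-tile values.
#' @param metric Column analyzed when `metrics` is a data frame (default
#'   `"pct_colonized_area"`).
#' @param group_sizes Increasing group sizes (default `c(1, 2, 9, 18, 36, 72)`).
#' @param n_subsets Subsets per group size (default 4).
#' @param threshold_pct Sufficiency threshold in percent (default 10).
#' @param seed Seed for subset draws; fixed seed gives an identical curve.
#' @return A `cv_curve`: tibble with columns `size` and `cv_pct`, and
#'   attributes `metric`, `threshold_pct`, `n_subsets`, `n_tiles`, `seed`.
#' @export
subset_cv_curve <- function(metrics, metric = "pct_colonized_area",
                            group_sizes = c(1, 2, 9, 18, 36, 72),
                            n_subsets = 4, threshold_pct = 10, seed = NULL) {
  values <- if (is.data.frame(metrics)) {
    if (!metric %in% names(metrics)) {
      abort(sprintf("metric column `%s` not found.", metric))
    }
    metrics[[metric]]
  } else {
    metric <- "value"
    as.numeric(metrics)
  }
  if (!is.numeric(group_sizes) || any(group_sizes < 1) ||
      is.unsorted(group_sizes, strictly = TRUE)) {
    abort("`group_sizes` must be strictly increasing and >= 1.")
  }
  check_number(n_subsets, "n_subsets", lower = 2, integerish = TRUE)
  check_number(threshold_pct, "threshold_pct", lower = 0, strict_lower = TRUE)
  n <- length(values)
  if (max(group_sizes) > n) {
    abort(sprintf(
      "largest group size (%d) exceeds available tiles (%d); feasible sizes: %s.",
      max(group_sizes), n,
      paste(group_sizes[group_sizes <= n], collapse = ", ")
    ))
  }
  cv <- with_seed(seed, {
    vapply(group_sizes, function(g) {
      means <- vapply(seq_len(n_subsets), function(s) {
        mean(values[sample.int(n, g)])
      }, numeric(1))
      coefficient_of_variation(means)
    }, numeric(1))
  })
  out <- tibble::tibble(size = as.integer(group_sizes), cv_pct = cv)
  class(out) <- c("cv_curve", class(out))
  attr(out, "metric") <- metric
  attr(out, "threshold_pct") <- threshold_pct
  attr(out, "n_subsets") <- as.integer(n_subsets)
  attr(out, "n_tiles") <- n
  attr(out, "seed") <- seed
  out
}

#' Sampling-sufficiency verdict from a CV curve
#'
#' Sampling is sufficient when the CV at the largest evaluated group size is
#' below the threshold. The report also gives the first group size from
#' which the curve has stabilized, i.e. from which all subsequent CVs stay
#' below the threshold.
#'
#' @param curve A [subset_cv_curve()] result.
#' @param threshold_pct Threshold in percent; defaults to the curve's own.
#' @return A `sufficiency_report`: list with `sufficient` (logical),
#'   `first_stable_size` (NA when never stabilized), `threshold_pct`,
#'   `metric` and `curve`.
#' @export
sufficiency_check <- function(curve, threshold_pct = NULL) {
  stopifnot(inherits(curve, "cv_curve"))
  threshold_pct <- threshold_pct %||% attr(curve, "threshold_pct")
  below <- curve$cv_pct < threshold_pct
  k <- length(below)
  sufficient <- below[k]
  first_stable <- NA_integer_
  if (sufficient) {
    # last index before which some CV is still above threshold
    runs <- rev(cumprod(rev(below))) # 1 where all later (incl. this) below
    first_stable <- curve$size[match(1, runs)]
  }
  structure(
    list(sufficient = sufficient, first_stable_size = first_stable,
         threshold_pct = threshold_pct,
         metric = attr(curve, "metric"), curve = curve),
    class = "sufficiency_report"
  )
}

#' @export
print.sufficiency_report <- function(x, ...) {
  cat(sprintf("<sufficiency_report> metric %s: %s (threshold %.1f%%)\n",
              x$metric,
              if (x$sufficient) "sufficient" else "NOT sufficient",
              x$threshold_pct))
  if (!is.na(x$first_stable_size)) {
    cat(sprintf("  stabilized below threshold from group size %d\n",
                x$first_stable_size))
  }
  print(tibble::as_tibble(x$curve))
  invisible(x)
}

#' Plot a CV convergence curve
#'
#' @param object A `cv_curve`.
#' @param ... Unused.
#' @return A ggplot: CV (%) against group size (log axis) with the
#'   sufficiency threshold as a dashed line.
#' @export
autoplot.cv_curve <- function(object, ...) {
  thr <- attr(object, "threshold_pct")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$size, y = .data$cv_pct)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::scale_x_log10(breaks = object$size) +
    ggplot2::labs(
      x = "tiles per subset", y = "CV of subset means (%)",
      title = sprintf("Sampling sufficiency (%s)", attr(object, "metric")),
      subtitle = sprintf("%d subsets per size; threshold %.0f%%",
                         attr(object, "n_subsets"), thr)
    ) +
    ggplot2::theme_minimal()
}
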