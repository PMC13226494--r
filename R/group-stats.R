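as_value_group <- function(data, value, group, call_value, call_group) {
  if (is.list(data) && !is.data.frame(data)) {
    # list of per-group numeric vectors
    groups <- names(data) %||% paste0("group", seq_along(data))
    if (any(groups == "")) {
      groups[groups == ""] <- paste0("group", which(groups == ""))
    }
    values <- unlist(data, use.names = FALSE)
    g <- rep(groups, lengths(data))
    return(tibble::tibble(value = as.numeric(values), group = g))
  }
  stopifnot(is.data.frame(data))
  tibble::tibble(
    value = as.numeric(rlang::eval_tidy(call_value, data)),
    group = as.character(rlang::eval_tidy(call_group, data))
  )
}

validate_kw_data <- function(df) {
  if (any(!is.finite(df$value))) abort("values must be finite.")
  if (dplyr::n_distinct(df$group) < 2) abort("need at least 2 groups.")
  if (any(table(df$group) < 1)) abort("every group needs at least 1 value.")
  if (dplyr::n_distinct(df$value) < 2) {
    abort("degenerate data: all values identical, rank statistic undefined.")
  }
  df
}

#' Kruskal-Wallis rank-sum comparison of conditions
#'
#' Nonparametric k-group omnibus test on mid-ranks with tie correction, the
#' appropriate comparison for colonization metrics whose distributions are
#' far from Gaussian. The statistic H is referred to a chi-square
#' distribution with `k - 1` degrees of freedom.
#'
#' @param data A data frame, or a (optionally named) list of numeric vectors,
#'   one per group.
#' @param value,group When `data` is a data frame: unquoted columns holding
#'   the metric values and the group labels.
#' @return A `kw_test` object with elements `statistic` (H, tie-corrected),
#'   `df`, `p_value`, `n`, `groups`, and the `data` used. [tidy()] returns a
#'   one-row tibble; [glance()] adds group counts.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
kruskal_wallis <- function(data, value, group) {
  df <- validate_kw_data(as_value_group(data, value, group,
                                        rlang::enquo(value),
                                        rlang::enquo(group)))
  kt <- stats::kruskal.test(df$value, factor(df$group))
  structure(
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = unname(kt$p.value), n = nrow(df),
         groups = sort(unique(df$group)), data = df,
         method = "Kruskal-Wallis rank sum test (tie-corrected)"),
    class = "kw_test"
  )
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("<kw_test> H = %.4f, df = %d, p = %.4g (n = %d, %d groups)\n",
              x$statistic, x$df, x$p_value, x$n, length(x$groups)))
  invisible(x)
}

#' @rdname kruskal_wallis
#' @param x A `kw_test`.
#' @param ... Unused.
#' @export
tidy.kw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 method = x$method)
}

#' @rdname kruskal_wallis
#' @export
glance.kw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 n = x$n, n_groups = length(x$groups))
}

#' Significance stars
#'
#' GraphPad-style mapping: `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 5e-2 ~ "*",
    TRUE ~ "ns"
  )
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Rank-based pairwise z-tests following a Kruskal-Wallis omnibus test:
#' `z = (mean rank A - mean rank B) / SE` with the tie-corrected standard
#' error `sqrt((N(N+1)/12 - T/(12(N-1))) (1/nA + 1/nB))`, where
#' `T = sum(t^3 - t)` over tie groups. Two-sided p-values from the normal
#' distribution, adjusted for multiplicity (Holm by default). Mirroring
#' standard practice, the pairwise table is only computed when the omnibus
#' test is significant, unless `only_if_significant = FALSE`.
#'
#' @param x A `kw_test` object, a data frame, or a list of numeric vectors.
#' @param ... When `x` is a data frame: unquoted `value` and `group` columns.
#' @param adjust Multiplicity adjustment: `"holm"` (default), `"bonferroni"`,
#'   `"sidak"` or `"none"`.
#' @param only_if_significant Skip the pairwise table when the omnibus p is
#'   at or above `alpha` (default `TRUE`).
#' @param alpha Omnibus significance level gate (default 0.05).
#' @return A tibble with columns `group1`, `group2`, `z`, `p.value`,
#'   `p.adjusted`, `stars`, and attribute `"omnibus"` (the `kw_test`). When
#'   gated out, a zero-row tibble with the same columns.
#' @export
dunn_posthoc <- function(x, ..., adjust = c("holm", "bonferroni", "sidak",
                                            "none"),
                         only_if_significant = TRUE, alpha = 0.05) {
  adjust <- match.arg(adjust)
  kw <- if (inherits(x, "kw_test")) x else kruskal_wallis(x, ...)
  df <- kw$data
  empty <- tibble::tibble(group1 = character(0), group2 = character(0),
                          z = numeric(0), p.value = numeric(0),
                          p.adjusted = numeric(0), stars = character(0))
  if (only_if_significant && kw$p_value >= alpha) {
    attr(empty, "omnibus") <- kw
    return(empty)
  }
  r <- rank(df$value) # mid-ranks
  N <- length(r)
  mean_rank <- tapply(r, df$group, mean)
  n_g <- tapply(r, df$group, length)
  ties <- table(df$value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  groups <- sort(names(mean_rank))
  pairs <- utils::combn(groups, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    se <- sqrt(var_base * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    tibble::tibble(group1 = a, group2 = b, z = z,
                   p.value = 2 * pnorm(-abs(z)))
  })
  m <- nrow(res)
  res$p.adjusted <- switch(adjust,
    holm = p.adjust(res$p.value, "holm"),
    bonferroni = p.adjust(res$p.value, "bonferroni"),
    sidak = pmin(1, 1 - (1 - res$p.value)^m),
    none = res$p.value
  )
  res$stars <- significance_stars(res$p.adjusted)
  attr(res, "omnibus") <- kw
  res
}

#' Compare conditions over the experiment hierarchy
#'
#' Runs the Kruskal-Wallis omnibus test and Dunn's post hoc on a per-tile
#' metrics table. By default tests are run on tile-level values (the unit
#' counted in the sampling design); because tiles within a replicate are not
#' independent, a conservative alternative tests replicate medians
#' (`level = "replicate"`).
#'
#' @param metrics Data frame of per-tile metrics with design coordinates.
#' @param metric Metric column (default `"colony_density_mm2"`).
#' @param by Grouping column (default `"condition"`).
#' @param level `"tile"` (default) or `"replicate"` (replicate medians).
#' @param adjust Dunn adjustment method (see [dunn_posthoc()]).
#' @param alpha Omnibus gate for the post hoc (default 0.05).
#' @return A `condition_comparison`: list with `omnibus` (`kw_test`),
#'   `pairwise` (tibble), `metric`, `level`. [tidy()] returns the pairwise
#'   tibble; [glance()] the omnibus summary.
#' @export
compare_conditions <- function(metrics, metric = "colony_density_mm2",
                               by = "condition", level = c("tile", "replicate"),
                               adjust = "holm", alpha = 0.05) {
  level <- match.arg(level)
  stopifnot(is.data.frame(metrics))
  for (col in c(metric, by)) {
    if (!col %in% names(metrics)) {
      abort(sprintf("column `%s` not found in metrics.", col))
    }
  }
  df <- if (level == "replicate") {
    if (!"replicate" %in% names(metrics)) {
      abort("replicate-level testing needs a `replicate` column.")
    }
    metrics |>
      dplyr::group_by(dplyr::across(dplyr::any_of(
        c(by, "replicate", "technical")))) |>
      dplyr::summarise(value = median(.data[[metric]]), .groups = "drop") |>
      dplyr::transmute(value = .data$value, group = .data[[by]])
  } else {
    tibble::tibble(value = metrics[[metric]], group = metrics[[by]])
  }
  kw <- kruskal_wallis(df, value, group)
  pw <- dunn_posthoc(kw, adjust = adjust, alpha = alpha)
  structure(
    list(omnibus = kw, pairwise = pw, metric = metric, level = level),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> metric %s at %s level\n", x$metric,
              x$level))
  print(x$omnibus)
  if (nrow(x$pairwise) > 0) print(x$pairwise) else
    cat("  omnibus not significant; post hoc not run\n")
  invisible(x)
}

#' @rdname compare_conditions
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @export
tidy.condition_comparison <- function(x, ...) x$pairwise

#' @rdname compare_conditions
#' @export
glance.condition_comparison <- function(x, ...) glance(x$omnibus)

#' Distribution summaries per condition
#'
#' Median, interquartile range and n of a metric per condition, with the
#' observational unit chosen by `level`: raw tiles, per-pearl means, or
#' per-replicate means.
#'
#' @param metrics Data frame of per-tile metrics with design coordinates.
#' @param metric Metric column (default `"colony_density_mm2"`).
#' @param level `"tile"` (default), `"pearl"` or `"replicate"`.
#' @return A tibble with `condition`, `n`, `median`, `q25`, `q75`, `iqr`.
#' @export
summarize_conditions <- function(metrics, metric = "colony_density_mm2",
                                 level = c("tile", "pearl", "replicate")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(metrics))
  if (nrow(metrics) == 0) {
    return(tibble::tibble(condition = character(0), n = integer(0),
                          median = numeric(0), q25 = numeric(0),
                          q75 = numeric(0), iqr = numeric(0)))
  }
  needed <- switch(level,
    tile = c("condition", metric),
    pearl = c("condition", "replicate", "pearl", metric),
    replicate = c("condition", "replicate", metric)
  )
  missing_cols <- setdiff(needed, names(metrics))
  if (length(missing_cols) > 0) {
    abort(paste0("metrics lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  units <- switch(level,
    tile = dplyr::mutate(metrics, .value = .data[[metric]]),
    pearl = metrics |>
      dplyr::group_by(dplyr::across(dplyr::any_of(
        c("condition", "replicate", "technical", "pearl")))) |>
      dplyr::summarise(.value = mean(.data[[metric]]), .groups = "drop"),
    replicate = metrics |>
      dplyr::group_by(dplyr::across(dplyr::any_of(
        c("condition", "replicate", "technical")))) |>
      dplyr::summarise(.value = mean(.data[[metric]]), .groups = "drop")
  )
  units |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.value),
      q25 = quantile(.value, 0.25, names = FALSE),
      q75 = quantile(.value, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(iqr = .data$q75 - .data$q25)
}

#' Condition-level metric plot
#'
#' Box-and-jitter plot of a per-tile metric by condition, the standard
#' presentation of colonization results.
#'
#' @param metrics Data frame of per-tile metrics.
#' @param metric Metric column (default `"colony_density_mm2"`).
#' @return A ggplot.
#' @export
plot_condition_summary <- function(metrics, metric = "colony_density_mm2") {
  stopifnot(is.data.frame(metrics), metric %in% names(metrics))
  lab <- c(colony_density_mm2 = "colony density (colonies/mm²)",
           pct_colonized_area = "colonized area (%)")[metric]
  if (is.na(lab)) lab <- metric
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$condition,
                                        y = .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.25, size = 0.6,
                         color = "steelblue") +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA, linewidth = 0.6) +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}
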