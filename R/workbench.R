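#' Pipeline configuration
#'
#' One object holding every tunable of an end-to-end run: the synthetic
#' generator (or ingestion) parameters, the experiment design, per-condition
#' effects, the image-processing chain, the CV sufficiency settings and the
#' statistics settings. All defaults are explicit, and the object
#' round-trips losslessly through YAML ([write_config()] / [read_config()]).
#'
#' @param design An [experiment_design()].
#' @param base_spec A [tile_spec()].
#' @param condition_effects Named list of `c(density =, coverage =)`
#'   multipliers, one per condition (default: all 1).
#' @param quant A [quant_config()].
#' @param cv_group_sizes,cv_n_subsets,cv_threshold_pct CV procedure settings
#'   (defaults `c(1, 2, 9, 18, 36, 72)`, 4 subsets, 10%).
#' @param cv_metrics Metric columns the CV procedure certifies (default both
#'   colony density and percent area).
#' @param stats_metric,stats_adjust,stats_alpha Comparison settings.
#' @param seed Master seed for generation and CV subset draws.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(design = experiment_design(),
                            base_spec = tile_spec(),
                            condition_effects = NULL,
                            quant = quant_config(),
                            cv_group_sizes = c(1, 2, 9, 18, 36, 72),
                            cv_n_subsets = 4, cv_threshold_pct = 10,
                            cv_metrics = c("colony_density_mm2",
                                           "pct_colonized_area"),
                            stats_metric = "colony_density_mm2",
                            stats_adjust = "holm", stats_alpha = 0.05,
                            seed = 1) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(base_spec, "tile_spec"),
            inherits(quant, "quant_config"))
  if (is.null(condition_effects)) {
    condition_effects <- setNames(
      rep(list(c(density = 1, coverage = 1)), length(design$conditions)),
      design$conditions
    )
  }
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(design = design, base_spec = base_spec,
         condition_effects = condition_effects, quant = quant,
         cv_group_sizes = cv_group_sizes,
         cv_n_subsets = as.integer(cv_n_subsets),
         cv_threshold_pct = cv_threshold_pct, cv_metrics = cv_metrics,
         stats_metric = stats_metric, stats_adjust = stats_adjust,
         stats_alpha = stats_alpha, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Stable hash of a pipeline configuration
#'
#' Recorded in every output manifest so results can be traced to the exact
#' configuration that produced them.
#'
#' @param config A [pipeline_config()].
#' @return A 32-character hexadecimal string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  digest::digest(rapply(unclass(config), unclass, how = "replace"),
                 algo = "md5")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$design <- unclass(x$design)
  x$base_spec <- unclass(x$base_spec)
  x$quant <- unclass(x$quant)
  x$condition_effects <- lapply(x$condition_effects, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    design = do.call(experiment_design, x$design),
    base_spec = do.call(tile_spec, x$base_spec),
    condition_effects = lapply(x$condition_effects, function(e) {
      unlist(e)[c("density", "coverage")]
    }),
    quant = do.call(quant_config, x$quant),
    cv_group_sizes = x$cv_group_sizes,
    cv_n_subsets = x$cv_n_subsets,
    cv_threshold_pct = x$cv_threshold_pct,
    cv_metrics = x$cv_metrics,
    stats_metric = x$stats_metric,
    stats_adjust = x$stats_adjust,
    stats_alpha = x$stats_alpha,
    seed = x$seed
  )
}

#' Run a synthetic colonization experiment end-to-end
#'
#' Generates the dataset prescribed by the configuration, quantifies every
#' tile, runs the CV sampling-sufficiency procedure per biological
#' replicate, compares conditions (Kruskal-Wallis + Dunn), and writes an
#' artifact bundle: `metrics.csv`, `cv_report.csv`, `cv_verdicts.json`,
#' `stats.json`, `pairwise.csv`, figures (when requested) and a
#' `run_manifest.json` recording the package version, seed and configuration
#' hash. Per-tile processing failures are logged, excluded and counted.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for the bundle.
#' @param write_images Write per-tile TIFFs and quantify from disk (`TRUE`,
#'   the full I/O path) or keep tiles in memory (`FALSE`, faster).
#' @param write_figures Also save summary figures as PNG (default `FALSE`).
#' @return (Invisibly) a list with `metrics`, `cv` (per replicate/metric
#'   [sufficiency_check()] reports), `comparison`, `truth` and `manifest`.
#' @export
run_experiment <- function(config, out_dir, write_images = FALSE,
                           write_figures = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (write_images) {
    img_dir <- file.path(out_dir, "tiles")
    truth <- generate_experiment(config$design, config$base_spec,
                                 config$condition_effects,
                                 seed = config$seed, out_dir = img_dir)
    metrics <- quantify_dir(img_dir, config$quant,
                            pixel_scale = config$base_spec$pixel_scale)
    n_failed <- attr(metrics, "n_failed") %||% 0L
  } else {
    grid <- enumerate_design(config$design)
    rows <- vector("list", nrow(grid))
    truth_rows <- vector("list", nrow(grid))
    n_failed <- 0L
    for (k in seq_len(nrow(grid))) {
      g <- grid[k, ]
      fx <- config$condition_effects[[g$condition]]
      sp <- config$base_spec
      sp$colony_density_per_mm2 <- sp$colony_density_per_mm2 * fx[["density"]]
      rad_mult <- sqrt(fx[["coverage"]] / fx[["density"]])
      sp$colony_radius_mean_um <- sp$colony_radius_mean_um * rad_mult
      sp$colony_radius_sd_um <- sp$colony_radius_sd_um * rad_mult
      sp$seed <- stable_hash(config$seed, g$condition, g$replicate,
                             g$technical, g$pearl, g$mosaic, g$tile)
      res <- tryCatch({
        st <- generate_tile(sp, coords = as.list(g))
        list(metrics = process_tile(st$image, config$quant),
             truth = tibble::tibble(
               condition = g$condition, replicate = g$replicate,
               technical = g$technical, pearl = g$pearl, mosaic = g$mosaic,
               tile = g$tile, colony_count = st$truth$colony_count,
               true_pct_area = st$truth$true_pct_area))
      }, error = function(e) {
        warning(sprintf("tile %d failed: %s", k, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
      if (is.null(res)) {
        n_failed <- n_failed + 1L
      } else {
        rows[[k]] <- res$metrics
        truth_rows[[k]] <- res$truth
      }
    }
    metrics <- dplyr::bind_rows(rows)
    truth <- dplyr::bind_rows(truth_rows)
  }
  readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))

  # CV sufficiency per condition x biological replicate x metric
  sizes <- config$cv_group_sizes
  cv_reports <- list()
  cv_rows <- list()
  for (cond in unique(metrics$condition)) {
    for (rep_i in unique(metrics$replicate[metrics$condition == cond])) {
      sub <- dplyr::filter(metrics, .data$condition == cond,
                           .data$replicate == rep_i)
      feasible <- sizes[sizes <= nrow(sub)]
      if (length(feasible) < 2) next
      for (m in config$cv_metrics) {
        curve <- subset_cv_curve(
          sub, metric = m, group_sizes = feasible,
          n_subsets = config$cv_n_subsets,
          threshold_pct = config$cv_threshold_pct,
          seed = stable_hash(config$seed, "cv", cond, rep_i, m)
        )
        rep_id <- sprintf("%s/rep%d/%s", cond, rep_i, m)
        cv_reports[[rep_id]] <- sufficiency_check(curve)
        cv_rows[[rep_id]] <- tibble::tibble(
          condition = cond, replicate = rep_i, metric = m,
          size = curve$size, cv_pct = curve$cv_pct
        )
      }
    }
  }
  cv_tbl <- dplyr::bind_rows(cv_rows)
  readr::write_csv(cv_tbl, file.path(out_dir, "cv_report.csv"))
  jsonlite::write_json(
    lapply(cv_reports, function(r) {
      list(sufficient = r$sufficient,
           first_stable_size = r$first_stable_size,
           threshold_pct = r$threshold_pct, metric = r$metric)
    }),
    file.path(out_dir, "cv_verdicts.json"), auto_unbox = TRUE, pretty = TRUE
  )

  # condition comparison (omnibus + post hoc) when >= 2 conditions
  comparison <- NULL
  if (dplyr::n_distinct(metrics$condition) >= 2) {
    comparison <- compare_conditions(metrics, metric = config$stats_metric,
                                     adjust = config$stats_adjust,
                                     alpha = config$stats_alpha)
    jsonlite::write_json(
      list(omnibus = glance(comparison$omnibus),
           pairwise = comparison$pairwise),
      file.path(out_dir, "stats.json"), dataframe = "rows",
      auto_unbox = TRUE, pretty = TRUE
    )
    readr::write_csv(comparison$pairwise, file.path(out_dir, "pairwise.csv"))
  }

  if (write_figures) {
    for (m in config$cv_metrics) {
      p <- plot_condition_summary(metrics, m)
      ggplot2::ggsave(file.path(out_dir, paste0(m, ".png")), p,
                      width = 6, height = 4, dpi = 150)
    }
  }

  manifest <- list(
    package = "biofilmq",
    version = as.character(utils::packageVersion("biofilmq")),
    seed = config$seed,
    config_hash = config_hash(config),
    n_tiles = nrow(metrics),
    n_failed = n_failed,
    conditions = unique(metrics$condition)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(metrics = metrics, cv = cv_reports, comparison = comparison,
                 truth = truth, manifest = manifest))
}
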