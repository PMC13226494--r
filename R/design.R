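#' Hierarchical experiment design
#'
#' The sampling hierarchy of a colonization experiment: each condition is
#' observed in biological replicates (optionally with technical replicates);
#' within each replicate several sulfur pearls are examined; on each pearl
#' several tiled mosaics are acquired; each mosaic contributes
#' `tile_rows * tile_cols` fields (tiles), the unit on which metrics are
#' computed. The reference design (3 replicates x 4 pearls x 4 mosaics x 16
#' tiles) yields 64 tiles per pearl, 256 per replicate and 768 per condition;
#' a control run with 2 biological x 3 technical replicates yields 1,536.
#'
#' @param conditions Character vector of condition labels.
#' @param replicates Biological replicates per condition.
#' @param technical_replicates Technical replicates nested in each biological
#'   replicate (default 1).
#' @param pearls Sulfur pearls examined per replicate.
#' @param mosaics Tiled mosaics acquired per pearl.
#' @param tile_rows,tile_cols Tile grid per mosaic (default 4 x 4 = 16 fields).
#' @return An `experiment_design` object.
#' @examples
#' d <- experiment_design("control", replicates = 3)
#' design_counts(d)
#' @export
experiment_design <- function(conditions = "control", replicates = 3,
                              technical_replicates = 1, pearls = 4,
                              mosaics = 4, tile_rows = 4, tile_cols = 4) {
  stopifnot(is.character(conditions), length(conditions) >= 1,
            !anyDuplicated(conditions))
  for (nm in c("replicates", "technical_replicates", "pearls", "mosaics",
               "tile_rows", "tile_cols")) {
    check_number(get(nm), nm, lower = 1, integerish = TRUE)
  }
  structure(
    list(conditions = conditions, replicates = as.integer(replicates),
         technical_replicates = as.integer(technical_replicates),
         pearls = as.integer(pearls), mosaics = as.integer(mosaics),
         tile_rows = as.integer(tile_rows), tile_cols = as.integer(tile_cols)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat(sprintf("  %d replicate(s) x %d technical x %d pearls x %d mosaics x %d tiles\n",
              x$replicates, x$technical_replicates, x$pearls, x$mosaics,
              x$tile_rows * x$tile_cols))
  print(design_counts(x))
  invisible(x)
}

#' Enumerate all tile coordinates of a design
#'
#' @param design An [experiment_design()].
#' @return A tibble with one row per tile: `condition`, `replicate`,
#'   `technical`, `pearl`, `mosaic`, `tile`, `tile_row`, `tile_col`, plus the
#'   per-level counts of [design_counts()] as attribute `"counts"`.
#' @export
enumerate_design <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  tpm <- design$tile_rows * design$tile_cols
  grid <- tidyr::expand_grid(
    condition = design$conditions,
    replicate = seq_len(design$replicates),
    technical = seq_len(design$technical_replicates),
    pearl = seq_len(design$pearls),
    mosaic = seq_len(design$mosaics),
    tile = seq_len(tpm)
  )
  grid$tile_row <- (grid$tile - 1L) %/% design$tile_cols + 1L
  grid$tile_col <- (grid$tile - 1L) %% design$tile_cols + 1L
  attr(grid, "counts") <- design_counts(design)
  grid
}

#' Per-level tile counts of a design
#'
#' @param design An [experiment_design()].
#' @return A tibble with columns `level` and `n_tiles`: tiles per mosaic, per
#'   pearl, per replicate (one biological x technical cell), per condition,
#'   and in total.
#' @export
design_counts <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  tpm <- design$tile_rows * design$tile_cols
  per_pearl <- design$mosaics * tpm
  per_rep <- design$pearls * per_pearl
  per_cond <- design$replicates * design$technical_replicates * per_rep
  tibble::tibble(
    level = c("mosaic", "pearl", "replicate", "condition", "total"),
    n_tiles = c(tpm, per_pearl, per_rep, per_cond,
                per_cond * length(design$conditions))
  )
}
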