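#' Image-processing configuration
#'
#' Parameters of the per-tile quantification chain
#' ([process_tile()]): percentile contrast stretch, unsharp masking,
#' rolling-ball background subtraction, thresholding and small-object
#' removal.
#'
#' @param low_pct,high_pct Percentiles mapped onto the full dynamic range by
#'   [enhance_contrast()] (defaults 0.05 and 99.95, a robust "best fit"
#'   stretch).
#' @param sharpen_amount,sharpen_radius_px Unsharp-mask strength and Gaussian
#'   radius for [sharpen()].
#' @param ball_radius_px Rolling-ball radius in pixels (default 25 px, about
#'   4.6 um at the default scale — larger than a microcolony so colonies are
#'   not absorbed into the background).
#' @param ball_height_scale Intensity units of ball height per pixel of
#'   geometric height (default 1).
#' @param threshold_method `"otsu"` (default), `"fixed"` or `"percentile"`.
#' @param threshold_value Threshold intensity for `"fixed"`, or percentile in
#'   `[0, 100]` for `"percentile"`.
#' @param min_separability Otsu bimodality guard passed to [binarize()]
#'   (default 0.75).
#' @param min_area_px Minimum component area kept by [label_colonies()]
#'   (default 5 px; a 1-um coccus covers about 23 px^2 at the default scale).
#' @param connectivity 4 or 8 (default 8).
#' @return A `quant_config` object (a validated list).
#' @export
quant_config <- function(low_pct = 0.05, high_pct = 99.95,
                         sharpen_amount = 1, sharpen_radius_px = 2,
                         ball_radius_px = 25, ball_height_scale = 1,
                         threshold_method = c("otsu", "fixed", "percentile"),
                         threshold_value = NULL, min_separability = 0.75,
                         min_area_px = 5, connectivity = 8) {
  threshold_method <- match.arg(threshold_method)
  check_number(low_pct, "low_pct", lower = 0, upper = 100)
  check_number(high_pct, "high_pct", lower = 0, upper = 100)
  if (low_pct >= high_pct) abort("`low_pct` must be < `high_pct`.")
  check_number(sharpen_amount, "sharpen_amount", lower = 0)
  check_number(sharpen_radius_px, "sharpen_radius_px", lower = 0,
               strict_lower = TRUE)
  check_number(ball_radius_px, "ball_radius_px", lower = 1)
  check_number(ball_height_scale, "ball_height_scale", lower = 0)
  check_number(min_area_px, "min_area_px", lower = 0)
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  if (threshold_method != "otsu" && is.null(threshold_value)) {
    abort("`threshold_value` is required for fixed/percentile thresholding.")
  }
  structure(
    list(low_pct = low_pct, high_pct = high_pct,
         sharpen_amount = sharpen_amount,
         sharpen_radius_px = sharpen_radius_px,
         ball_radius_px = ball_radius_px,
         ball_height_scale = ball_height_scale,
         threshold_method = threshold_method,
         threshold_value = threshold_value,
         min_separability = min_separability,
         min_area_px = min_area_px, connectivity = as.integer(connectivity)),
    class = "quant_config"
  )
}

#' Percentile contrast stretch
#'
#' Linearly rescales the `[P_low, P_high]` intensity percentiles onto the
#' full dynamic range `[0, max_intensity]`, clipping outside it. The mapping
#' is monotone non-decreasing; a constant image is returned unchanged.
#'
#' @param img A [tile_image()].
#' @param low_pct,high_pct Percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @return A [tile_image()].
#' @export
enhance_contrast <- function(img, low_pct = 0.05, high_pct = 99.95) {
  stopifnot(inherits(img, "tile_image"))
  check_number(low_pct, "low_pct", lower = 0, upper = 100)
  check_number(high_pct, "high_pct", lower = 0, upper = 100)
  if (low_pct >= high_pct) abort("`low_pct` must be < `high_pct`.")
  x <- img$pixels
  p <- quantile(x, c(low_pct, high_pct) / 100, names = FALSE)
  if (p[2] <= p[1]) return(img)
  out <- clip((x - p[1]) / (p[2] - p[1]) * img$max_intensity,
              0, img$max_intensity)
  tile_image(out, img$pixel_scale, img$coords, img$max_intensity)
}

# Separable Gaussian blur with replicate boundary (kernel support 3 sigma).
gaussian_blur <- function(x, sigma) {
  .gauss_blur_cpp(x, sigma)
}

#' Unsharp-mask sharpening
#'
#' `out = in + amount * (in - blur(in))` with a Gaussian blur of the given
#' radius, clipped to the valid intensity range. `amount = 0` is the
#' identity.
#'
#' @param img A [tile_image()].
#' @param amount Strength (>= 0).
#' @param radius_px Gaussian sigma in pixels (> 0).
#' @return A [tile_image()].
#' @export
sharpen <- function(img, amount = 1, radius_px = 2) {
  stopifnot(inherits(img, "tile_image"))
  check_number(amount, "amount", lower = 0)
  check_number(radius_px, "radius_px", lower = 0, strict_lower = TRUE)
  if (amount == 0) return(img)
  x <- img$pixels
  out <- clip(x + amount * (x - gaussian_blur(x, radius_px)),
              0, img$max_intensity)
  tile_image(out, img$pixel_scale, img$coords, img$max_intensity)
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence field as the grayscale
#' opening of the intensity surface by a ball (spherical) structuring
#' element — the surface traced by rolling a ball of the given radius beneath
#' the intensity landscape — and subtracts it. Objects narrower than the ball
#' (microcolonies) survive in the corrected image; broad illumination
#' structure is absorbed into the background. The background never exceeds
#' the image, so the corrected image is non-negative, and the opening is
#' idempotent: applied to its own background it returns that background.
#'
#' @param img A [tile_image()].
#' @param ball_radius_px Ball radius in pixels (>= 1, smaller than the image).
#' @param height_scale Intensity units per pixel of ball height (default 1).
#' @return A list with `background` (numeric matrix) and `corrected`
#'   (a [tile_image()]).
#' @export
rolling_ball_background <- function(img, ball_radius_px = 25,
                                    height_scale = 1) {
  stopifnot(inherits(img, "tile_image"))
  check_number(ball_radius_px, "ball_radius_px", lower = 1)
  check_number(height_scale, "height_scale", lower = 0)
  d <- dim(img$pixels)
  if (ball_radius_px >= min(d)) {
    abort(sprintf("ball radius %s px does not fit a %d x %d px image.",
                  format(ball_radius_px), d[1], d[2]))
  }
  eroded <- .ball_erode_cpp(img$pixels, ball_radius_px, height_scale)
  background <- .ball_dilate_cpp(eroded, ball_radius_px, height_scale)
  # the opening is anti-extensive analytically; clamp float rounding dust
  background <- pmin(background, img$pixels)
  corrected <- img$pixels - background
  list(
    background = background,
    corrected = tile_image(corrected, img$pixel_scale, img$coords,
                           img$max_intensity)
  )
}

#' Threshold a background-corrected tile into a binary mask
#'
#' @param corrected A background-corrected [tile_image()] (or numeric
#'   matrix).
#' @param method `"otsu"` (default; Otsu's threshold on the corrected
#'   histogram), `"fixed"` (absolute intensity) or `"percentile"`.
#' @param value Threshold intensity (`"fixed"`) or percentile in `[0, 100]`
#'   (`"percentile"`); ignored for `"otsu"`.
#' @param min_separability Guard for foreground-free fields under `"otsu"`:
#'   Otsu's separability measure eta (between-class variance over total
#'   variance at the chosen threshold) is close to 1 for genuinely bimodal
#'   colony/background images but drops when the histogram is a single noise
#'   mode, in which case Otsu would split the noise in half. Below this value
#'   (default 0.75) the tile is declared colony-free. Set to 0 to disable.
#' @return A logical matrix, `TRUE` where intensity exceeds the threshold. A
#'   constant (e.g. all-zero) image yields an all-`FALSE` mask.
#' @export
binarize <- function(corrected, method = c("otsu", "fixed", "percentile"),
                     value = NULL, min_separability = 0.75) {
  method <- match.arg(method)
  x <- if (inherits(corrected, "tile_image")) corrected$pixels else corrected
  stopifnot(is.matrix(x), is.numeric(x))
  check_number(min_separability, "min_separability", lower = 0, upper = 1)
  rng <- range(x)
  if (rng[1] == rng[2]) return(matrix(FALSE, nrow(x), ncol(x)))
  thr <- switch(method,
    otsu = {
      # Otsu on the normalized corrected histogram (256 levels)
      span <- rng[2] - rng[1]
      t01 <- EBImage::otsu((x - rng[1]) / span, range = c(0, 1), levels = 256)
      t <- rng[1] + t01 * span
      if (otsu_separability(x, t) < min_separability) {
        return(matrix(FALSE, nrow(x), ncol(x)))
      }
      t
    },
    fixed = {
      check_number(value, "value")
      value
    },
    percentile = {
      check_number(value, "value", lower = 0, upper = 100)
      quantile(x, value / 100, names = FALSE)
    }
  )
  x > thr
}

# Otsu's effectiveness measure: between-class variance / total variance.
otsu_separability <- function(x, thr) {
  lo <- x <= thr
  w1 <- mean(lo)
  if (w1 == 0 || w1 == 1) return(0)
  w1 * (1 - w1) * (mean(x[!lo]) - mean(x[lo]))^2 / var(as.vector(x))
}

#' Label microcolonies in a binary mask
#'
#' Connected-component labeling under 4- or 8-connectivity, removal of
#' components smaller than `min_area_px`, and boundary tracing of each
#' surviving microcolony.
#'
#' @param mask Logical matrix (colonized pixels `TRUE`).
#' @param min_area_px Minimum component area in pixels; smaller components
#'   are removed from both mask and labels.
#' @param connectivity 4 or 8 (default 8).
#' @return A `colony_labeling`: list with `mask` (filtered logical matrix),
#'   `labels` (integer matrix, 0 = background, 1..n colonies), `outlines`
#'   (per-colony ordered boundary coordinates, 0-based `(row, col)`),
#'   `areas_px` (integer vector), `n` and `connectivity`.
#' @export
label_colonies <- function(mask, min_area_px = 5, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  check_number(min_area_px, "min_area_px", lower = 0)
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  labels <- .cc_label_cpp(mask, as.integer(connectivity))
  n0 <- max(labels)
  if (n0 > 0) {
    areas <- tabulate(labels[labels > 0], nbins = n0)
    keep <- which(areas >= min_area_px)
    remap <- integer(n0)
    remap[keep] <- seq_along(keep)
    relabeled <- matrix(0L, nrow(mask), ncol(mask))
    pos <- labels > 0
    relabeled[pos] <- remap[labels[pos]]
    labels <- relabeled
    areas <- areas[keep]
  } else {
    areas <- integer(0)
  }
  mask_out <- labels > 0L
  n <- length(areas)
  outlines <- if (n > 0) EBImage::ocontour(labels) else list()
  structure(
    list(mask = mask_out, labels = labels, outlines = outlines,
         areas_px = as.integer(areas), n = n,
         connectivity = as.integer(connectivity)),
    class = "colony_labeling"
  )
}

#' @export
print.colony_labeling <- function(x, ...) {
  cat(sprintf("<colony_labeling> %d colonies (%d-connectivity), %.2f%% of pixels\n",
              x$n, x$connectivity, 100 * mean(x$mask)))
  invisible(x)
}

#' Per-tile colonization metrics
#'
#' Colony density (colonies per mm^2) and percent colonized area for one
#' tile: `density = colony_count / tile_area_mm2` and
#' `pct = 100 * colonized pixels / total pixels`.
#'
#' @param labeling A [label_colonies()] result derived from `img`.
#' @param img The [tile_image()] the labeling came from (provides pixel
#'   calibration and design coordinates).
#' @return A one-row tibble: design coordinates (when present), `colony_count`,
#'   `colony_density_mm2`, `pct_colonized_area`, `tile_area_mm2`.
#' @export
compute_tile_metrics <- function(labeling, img) {
  stopifnot(inherits(labeling, "colony_labeling"), inherits(img, "tile_image"))
  if (!identical(dim(labeling$mask), dim(img$pixels))) {
    abort("labeling and image dimensions differ.")
  }
  area <- tile_area_mm2(img)
  if (area <= 0) abort("tile area must be positive.")
  coords <- img$coords %||% list()
  out <- tibble::tibble(
    condition = coords$condition %||% NA_character_,
    replicate = coords$replicate %||% NA_integer_,
    technical = coords$technical %||% NA_integer_,
    pearl = coords$pearl %||% NA_integer_,
    mosaic = coords$mosaic %||% NA_integer_,
    tile = coords$tile %||% NA_integer_,
    colony_count = labeling$n,
    colony_density_mm2 = labeling$n / area,
    pct_colonized_area = 100 * mean(labeling$mask),
    tile_area_mm2 = area
  )
  out
}

#' Quantify one tile end-to-end
#'
#' The full per-tile processing chain: contrast stretch, unsharp masking,
#' rolling-ball background subtraction, thresholding, microcolony labeling
#' and metric computation. Deterministic: identical input and configuration
#' give identical metrics.
#'
#' @param img A [tile_image()].
#' @param config A [quant_config()].
#' @param keep_intermediates If `TRUE`, the returned tibble carries an
#'   `"intermediates"` attribute (list with `enhanced`, `sharpened`,
#'   `background`, `corrected`, `labeling`).
#' @return A one-row tibble of metrics (see [compute_tile_metrics()]).
#' @examples
#' st <- generate_tile(tile_spec(width_px = 128, height_px = 128, seed = 3))
#' process_tile(st$image, quant_config(ball_radius_px = 15))
#' @export
process_tile <- function(img, config = quant_config(),
                         keep_intermediates = FALSE) {
  stopifnot(inherits(img, "tile_image"), inherits(config, "quant_config"))
  enhanced <- enhance_contrast(img, config$low_pct, config$high_pct)
  sharpened <- sharpen(enhanced, config$sharpen_amount,
                       config$sharpen_radius_px)
  rb <- rolling_ball_background(sharpened, config$ball_radius_px,
                                config$ball_height_scale)
  mask <- binarize(rb$corrected, config$threshold_method,
                   config$threshold_value, config$min_separability)
  labeling <- label_colonies(mask, config$min_area_px, config$connectivity)
  metrics <- compute_tile_metrics(labeling, img)
  if (keep_intermediates) {
    attr(metrics, "intermediates") <- list(
      enhanced = enhanced, sharpened = sharpened, background = rb$background,
      corrected = rb$corrected, labeling = labeling
    )
  }
  metrics
}

#' Quantify a collection of tiles
#'
#' @param tiles A list of [tile_image()]s (or `synthetic_tile`s, whose images
#'   are extracted).
#' @param config A [quant_config()].
#' @return A tibble with one metrics row per tile.
#' @export
quantify_tiles <- function(tiles, config = quant_config()) {
  tiles <- lapply(tiles, function(t) {
    if (inherits(t, "synthetic_tile")) t$image else t
  })
  purrr::map_dfr(tiles, process_tile, config = config)
}

#' Quantify a tiled dataset on disk
#'
#' Reads every tile of a dataset written by [generate_experiment()] (or any
#' directory with a compatible `ground_truth.csv`/manifest mapping files to
#' design coordinates) and computes per-tile metrics. Tiles that fail to
#' process are skipped with a warning; the number skipped is reported in the
#' `"n_failed"` attribute.
#'
#' @param input_dir Dataset directory.
#' @param config A [quant_config()].
#' @param pixel_scale Micrometres per pixel of the stored tiles.
#' @param manifest Optional data frame with columns `file`, `condition`,
#'   `replicate`, `technical`, `pearl`, `mosaic`, `tile`; defaults to the
#'   dataset's `ground_truth.csv`.
#' @return A tibble of per-tile metrics.
#' @export
quantify_dir <- function(input_dir, config = quant_config(),
                         pixel_scale = 0.1845, manifest = NULL) {
  if (is.null(manifest)) {
    gt_path <- file.path(input_dir, "ground_truth.csv")
    if (!file.exists(gt_path)) {
      abort("no `manifest` given and no ground_truth.csv in `input_dir`.")
    }
    manifest <- readr::read_csv(gt_path, show_col_types = FALSE)
    if (!"tile" %in% names(manifest) && all(c("row", "col") %in% names(manifest))) {
      ncol_grid <- max(manifest$col)
      manifest$tile <- (manifest$row - 1L) * ncol_grid + manifest$col
    }
  }
  needed <- c("file", "condition", "replicate", "pearl", "mosaic", "tile")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"technical" %in% names(manifest)) manifest$technical <- 1L
  rows <- vector("list", nrow(manifest))
  n_failed <- 0L
  for (k in seq_len(nrow(manifest))) {
    m <- manifest[k, ]
    rows[[k]] <- tryCatch({
      img <- read_tile(file.path(input_dir, m$file),
                       pixel_scale = pixel_scale,
                       coords = list(condition = m$condition,
                                     replicate = m$replicate,
                                     technical = m$technical,
                                     pearl = m$pearl, mosaic = m$mosaic,
                                     tile = m$tile))
      process_tile(img, config)
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      warning(sprintf("tile %s failed: %s", m$file, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_failed") <- n_failed
  out
}
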