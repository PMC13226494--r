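#' Specification of a synthetic fluorescence tile
#'
#' Parameters of the synthetic epifluorescence tile generator. The generator
#' emulates DAPI-stained microcolonies on a sulfur-pearl surface: bright,
#' roughly circular blobs of variable size on an uneven illumination
#' background with additive sensor noise. Colony placement is a homogeneous
#' Poisson process (`clustering_factor = 1`) or a Thomas cluster process
#' (`clustering_factor > 1`: parent points with Gaussian offspring scatter),
#' reflecting the patchy colonization typical of mineral surfaces.
#'
#' Colony count on a tile is Poisson with mean
#' `colony_density_per_mm2 * tile area (mm^2)`. Colonies are rendered as
#' filled disks with a Gaussian-feathered edge (sigma = 1 px), mimicking
#' diffraction blur without modelling optics. Noise is additive Gaussian;
#' the final image is clipped to `[0, max_intensity]`.
#'
#' @param width_px,height_px Tile dimensions in pixels (default 512 x 512).
#' @param pixel_scale Micrometres per pixel (> 0; default 0.1845, the scale of
#'   a 5,135 px-wide mosaic imaging 947.5 micrometres).
#' @param colony_density_per_mm2 Expected microcolonies per mm^2 (>= 0).
#' @param colony_radius_mean_um,colony_radius_sd_um Mean and SD of colony
#'   radius in micrometres (Gaussian, truncated below at 0.2 um).
#' @param colony_intensity Peak colony fluorescence added above background,
#'   arbitrary units in `(0, max_intensity]`.
#' @param background_level Mean background intensity (>= 0).
#' @param illumination_gradient_amplitude Fractional amplitude in `[0, 1]` of
#'   the smooth illumination field; the background varies by `+/- amplitude/2`
#'   around `background_level` along the gradient.
#' @param gradient_type `"linear"` (diagonal plane) or `"radial"` (center
#'   bright vignetting).
#' @param noise_sd SD of additive zero-mean Gaussian sensor noise (>= 0).
#' @param clustering_factor >= 1; 1 places colonies uniformly, larger values
#'   concentrate the same expected count on ~`n/clustering_factor` parents.
#' @param cluster_sd_um Gaussian scatter of offspring around a parent, um.
#' @param max_intensity Full-scale intensity (default 65535, 16-bit).
#' @param seed Integer seed; fixed seed gives bit-identical tiles.
#' @return A `tile_spec` object.
#' @examples
#' st <- generate_tile(tile_spec(seed = 7))
#' st$truth$colony_count
#' @export
tile_spec <- function(width_px = 512, height_px = 512, pixel_scale = 0.1845,
                      colony_density_per_mm2 = 2500,
                      colony_radius_mean_um = 2, colony_radius_sd_um = 0.6,
                      colony_intensity = 20000, background_level = 2000,
                      illumination_gradient_amplitude = 0.1,
                      gradient_type = c("linear", "radial"),
                      noise_sd = 200, clustering_factor = 1,
                      cluster_sd_um = 15, max_intensity = 65535, seed = 1) {
  gradient_type <- match.arg(gradient_type)
  check_number(width_px, "width_px", lower = 1, integerish = TRUE)
  check_number(height_px, "height_px", lower = 1, integerish = TRUE)
  check_number(pixel_scale, "pixel_scale", lower = 0, strict_lower = TRUE)
  check_number(colony_density_per_mm2, "colony_density_per_mm2", lower = 0)
  check_number(colony_radius_mean_um, "colony_radius_mean_um", lower = 0)
  check_number(colony_radius_sd_um, "colony_radius_sd_um", lower = 0)
  check_number(max_intensity, "max_intensity", lower = 0, strict_lower = TRUE)
  check_number(colony_intensity, "colony_intensity", lower = 0,
               upper = max_intensity, strict_lower = TRUE)
  check_number(background_level, "background_level", lower = 0)
  check_number(illumination_gradient_amplitude,
               "illumination_gradient_amplitude", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(clustering_factor, "clustering_factor", lower = 1)
  check_number(cluster_sd_um, "cluster_sd_um", lower = 0, strict_lower = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_scale = pixel_scale,
         colony_density_per_mm2 = colony_density_per_mm2,
         colony_radius_mean_um = colony_radius_mean_um,
         colony_radius_sd_um = colony_radius_sd_um,
         colony_intensity = colony_intensity,
         background_level = background_level,
         illumination_gradient_amplitude = illumination_gradient_amplitude,
         gradient_type = gradient_type, noise_sd = noise_sd,
         clustering_factor = clustering_factor, cluster_sd_um = cluster_sd_um,
         max_intensity = max_intensity, seed = as.integer(seed)),
    class = "tile_spec"
  )
}

# Smooth illumination field in [-0.5, 0.5] scaled by the amplitude.
illumination_field <- function(nr, nc, amplitude, type) {
  if (amplitude == 0) return(matrix(0, nr, nc))
  if (type == "linear") {
    u <- if (nr > 1) (seq_len(nr) - 1) / (nr - 1) else rep(0.5, nr)
    v <- if (nc > 1) (seq_len(nc) - 1) / (nc - 1) else rep(0.5, nc)
    g <- (outer(u, v, `+`) / 2) - 0.5
  } else {
    ci <- (nr - 1) / 2
    cj <- (nc - 1) / 2
    d <- sqrt(outer((seq_len(nr) - 1 - ci)^2, (seq_len(nc) - 1 - cj)^2, `+`))
    g <- 0.5 - d / max(d, 1e-12)
  }
  amplitude * g
}

# Draw colony centers (0-based pixel coordinates) for a tile.
place_colonies <- function(n, nr, nc, clustering_factor, cluster_sd_px) {
  if (n == 0) return(list(cx = numeric(0), cy = numeric(0)))
  if (clustering_factor <= 1) {
    return(list(cx = runif(n, 0, nr - 1), cy = runif(n, 0, nc - 1)))
  }
  n_par <- max(1L, as.integer(round(n / clustering_factor)))
  px <- runif(n_par, 0, nr - 1)
  py <- runif(n_par, 0, nc - 1)
  assign_to <- sample.int(n_par, n, replace = TRUE)
  cx <- px[assign_to] + rnorm(n, 0, cluster_sd_px)
  cy <- py[assign_to] + rnorm(n, 0, cluster_sd_px)
  # resample offsets that fall outside the tile; clamp as a last resort
  for (it in 1:100) {
    bad <- cx < 0 | cx > nr - 1 | cy < 0 | cy > nc - 1
    if (!any(bad)) break
    cx[bad] <- px[assign_to[bad]] + rnorm(sum(bad), 0, cluster_sd_px)
    cy[bad] <- py[assign_to[bad]] + rnorm(sum(bad), 0, cluster_sd_px)
  }
  list(cx = clip(cx, 0, nr - 1), cy = clip(cy, 0, nc - 1))
}

#' Generate one synthetic tile with ground truth
#'
#' Renders a synthetic epifluorescence field from a [tile_spec()] and returns
#' both the image and the exact ground truth used to render it, so that every
#' downstream processing stage can be validated against known answers.
#'
#' @param spec A [tile_spec()].
#' @param coords Optional design coordinates attached to the image.
#' @return A `synthetic_tile`: list with `image` (a [tile_image()]) and
#'   `truth`, itself a list with `colony_count` (placed colonies),
#'   `merged_count` (connected components of the true mask, i.e. after
#'   overlap merging), `true_mask` (logical matrix), `true_pct_area`,
#'   and `colonies` (tibble of 0-based `row`, `col` centers and `radius_um`).
#' @export
generate_tile <- function(spec, coords = NULL) {
  stopifnot(inherits(spec, "tile_spec"))
  nr <- spec$width_px
  nc <- spec$height_px
  area_mm2 <- nr * nc * spec$pixel_scale^2 * 1e-6
  with_seed(spec$seed, {
    n <- rpois(1, spec$colony_density_per_mm2 * area_mm2)
    ctr <- place_colonies(n, nr, nc, spec$clustering_factor,
                          spec$cluster_sd_um / spec$pixel_scale)
    radii_um <- if (n > 0) {
      pmax(rnorm(n, spec$colony_radius_mean_um, spec$colony_radius_sd_um), 0.2)
    } else {
      numeric(0)
    }
    r_px <- radii_um / spec$pixel_scale
    bg <- spec$background_level *
      (1 + illumination_field(nr, nc, spec$illumination_gradient_amplitude,
                              spec$gradient_type))
    img <- .render_disks_cpp(bg, ctr$cx, ctr$cy, r_px, spec$colony_intensity,
                             1.0)
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    img <- clip(img, 0, spec$max_intensity)
    mask <- .disk_mask_cpp(nr, nc, ctr$cx, ctr$cy, r_px)
    merged <- if (n > 0) max(.cc_label_cpp(mask, 8L)) else 0L
    structure(
      list(
        image = tile_image(img, pixel_scale = spec$pixel_scale,
                           coords = coords,
                           max_intensity = spec$max_intensity),
        truth = list(
          colony_count = n,
          merged_count = as.integer(merged),
          true_mask = mask,
          true_pct_area = 100 * mean(mask),
          colonies = tibble::tibble(row = ctr$cx, col = ctr$cy,
                                    radius_um = radii_um)
        ),
        spec = spec
      ),
      class = "synthetic_tile"
    )
  })
}

#' @export
print.synthetic_tile <- function(x, ...) {
  cat(sprintf("<synthetic_tile> %d colonies (%d after merging), %.3f%% area\n",
              x$truth$colony_count, x$truth$merged_count,
              x$truth$true_pct_area))
  print(x$image)
  invisible(x)
}

#' Generate a full synthetic experiment on disk
#'
#' Writes one grayscale TIFF per tile of a hierarchical design, together with
#' a ground-truth CSV and a YAML manifest, emulating a tiled acquisition
#' campaign with known per-condition effects. Per-tile seeds are derived by
#' stable hashing of the design coordinates from the master seed, so any
#' subset of the dataset is reproducible independently.
#'
#' Condition effects are multiplicative: the density multiplier scales
#' `colony_density_per_mm2`; the coverage multiplier scales the expected
#' colonized area, implemented by scaling colony radii by
#' `sqrt(coverage / density)` so that density x mean colony area tracks the
#' coverage multiplier.
#'
#' @param design An [experiment_design()].
#' @param base_spec A [tile_spec()] used for all tiles before effects.
#' @param condition_effects Named list, one entry per design condition, each
#'   `c(density = , coverage = )` with positive multipliers.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param write_images If `FALSE`, skip the TIFFs and return metrics-ready
#'   ground truth only (used for fast simulation studies).
#' @return (Invisibly) a tibble with one row per tile: design coordinates,
#'   `tile_id`, `file` (relative TIFF path or `NA`), `seed`, `colony_count`,
#'   `merged_count`, `true_pct_area`, `true_density_mm2`.
#' @export
generate_experiment <- function(design, base_spec = tile_spec(),
                                condition_effects = NULL, seed = 1,
                                out_dir, write_images = TRUE) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(base_spec, "tile_spec"))
  check_number(seed, "seed", integerish = TRUE)
  if (is.null(condition_effects)) {
    condition_effects <- setNames(
      rep(list(c(density = 1, coverage = 1)), length(design$conditions)),
      design$conditions
    )
  }
  unknown <- setdiff(names(condition_effects), design$conditions)
  if (length(unknown) > 0) {
    abort(paste0("condition_effects for unknown condition(s): ",
                 paste(unknown, collapse = ", ")))
  }
  missing_fx <- setdiff(design$conditions, names(condition_effects))
  if (length(missing_fx) > 0) {
    abort(paste0("condition_effects missing for: ",
                 paste(missing_fx, collapse = ", ")))
  }
  for (fx in condition_effects) {
    if (any(fx <= 0)) abort("effect multipliers must be > 0.")
  }

  grid <- enumerate_design(design)
  if (write_images) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    fx <- condition_effects[[g$condition]]
    sp <- base_spec
    sp$colony_density_per_mm2 <- sp$colony_density_per_mm2 * fx[["density"]]
    rad_mult <- sqrt(fx[["coverage"]] / fx[["density"]])
    sp$colony_radius_mean_um <- sp$colony_radius_mean_um * rad_mult
    sp$colony_radius_sd_um <- sp$colony_radius_sd_um * rad_mult
    sp$seed <- stable_hash(seed, g$condition, g$replicate, g$technical,
                           g$pearl, g$mosaic, g$tile)
    st <- generate_tile(sp, coords = as.list(g))
    tile_id <- sprintf("%s_r%d_t%d_p%d_m%d_tile%02d", g$condition,
                       g$replicate, g$technical, g$pearl, g$mosaic, g$tile)
    rel <- NA_character_
    if (write_images) {
      rel <- file.path(g$condition, sprintf("rep%d_t%d", g$replicate,
                                            g$technical),
                       sprintf("pearl%d", g$pearl),
                       sprintf("mosaic%d", g$mosaic),
                       sprintf("tile%02d.tif", g$tile))
      dir.create(dirname(file.path(out_dir, rel)), recursive = TRUE,
                 showWarnings = FALSE)
      write_tile(st$image, file.path(out_dir, rel))
    }
    rows[[k]] <- tibble::tibble(
      tile_id = tile_id, condition = g$condition, replicate = g$replicate,
      technical = g$technical, pearl = g$pearl, mosaic = g$mosaic,
      row = g$tile_row, col = g$tile_col, tile = g$tile, file = rel,
      seed = sp$seed, colony_count = st$truth$colony_count,
      merged_count = st$truth$merged_count,
      true_pct_area = st$truth$true_pct_area,
      true_density_mm2 = st$truth$colony_count / tile_area_mm2(st$image)
    )
  }
  truth <- dplyr::bind_rows(rows)
  if (write_images) {
    readr::write_csv(
      truth[, c("tile_id", "condition", "replicate", "technical", "pearl",
                "mosaic", "row", "col", "file", "colony_count",
                "true_pct_area")],
      file.path(out_dir, "ground_truth.csv")
    )
    manifest <- list(
      design = unclass(design),
      base_spec = unclass(base_spec),
      condition_effects = lapply(condition_effects, as.list),
      seed = seed,
      n_tiles = nrow(truth)
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(truth)
}
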