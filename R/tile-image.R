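#' Calibrated fluorescence tile
#'
#' A `tile_image` wraps a 2D grayscale intensity matrix together with its
#' pixel calibration (micrometres per pixel) and, optionally, the design
#' coordinates that locate the tile inside a hierarchical experiment
#' (condition / biological replicate / sulfur pearl / mosaic / tile index).
#'
#' Pixels are row-major with origin at the top-left; all pixel arithmetic in
#' the package is 0-based with half-open tile intervals. Intensities are held
#' in double precision internally regardless of the on-disk bit depth.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param pixel_scale Calibration in micrometres per pixel (> 0). The default
#'   0.1845 corresponds to a 5,135 px mosaic width imaging 947.5 micrometres.
#' @param coords Optional named list of design coordinates
#'   (`condition`, `replicate`, `pearl`, `mosaic`, `tile`).
#' @param max_intensity Full-scale intensity of the acquisition (default
#'   65535, i.e. 16-bit).
#' @return A `tile_image` object.
#' @export
tile_image <- function(pixels, pixel_scale = 0.1845, coords = NULL,
                       max_intensity = 65535) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (any(!is.finite(pixels))) abort("`pixels` must be finite.")
  if (any(pixels < 0)) abort("`pixels` must be non-negative.")
  check_number(pixel_scale, "pixel_scale", lower = 0, strict_lower = TRUE)
  check_number(max_intensity, "max_intensity", lower = 0, strict_lower = TRUE)
  structure(
    list(pixels = pixels, pixel_scale = pixel_scale, coords = coords,
         max_intensity = max_intensity),
    class = "tile_image"
  )
}

#' @export
print.tile_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<tile_image> %d x %d px @ %.4f um/px (%.4f x %.4f um), range [%.1f, %.1f]\n",
    d[1], d[2], x$pixel_scale, d[1] * x$pixel_scale, d[2] * x$pixel_scale,
    min(x$pixels), max(x$pixels)
  ))
  if (!is.null(x$coords)) {
    cat("  coords:", paste(names(x$coords), unlist(x$coords), sep = "=",
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Tile area in square millimetres
#'
#' @param img A [tile_image()].
#' @return Area in mm^2: `nrow * ncol * pixel_scale^2 * 1e-6`.
#' @export
tile_area_mm2 <- function(img) {
  stopifnot(inherits(img, "tile_image"))
  d <- dim(img$pixels)
  d[1] * d[2] * img$pixel_scale^2 * 1e-6
}

#' Split a mosaic into its acquisition tiles
#'
#' Tiled acquisition images a rectangular grid of fields in one pass
#' (typically 4 x 4, i.e. 16 fields per mosaic). This splits the mosaic back
#' into non-overlapping tiles covering it exactly. When a dimension is not
#' divisible by the grid, the remainder pixels are absorbed by the last
#' row/column of tiles, so the union of the tiles is always the full mosaic.
#'
#' @param mosaic A [tile_image()].
#' @param rows,cols Grid dimensions (default 4 x 4).
#' @return A list of `rows * cols` `tile_image`s in row-major order; each
#'   carries the parent's coords plus `tile` (1-based row-major index),
#'   `tile_row` and `tile_col`.
#' @export
split_mosaic <- function(mosaic, rows = 4, cols = 4) {
  stopifnot(inherits(mosaic, "tile_image"))
  check_number(rows, "rows", lower = 1, integerish = TRUE)
  check_number(cols, "cols", lower = 1, integerish = TRUE)
  d <- dim(mosaic$pixels)
  if (d[1] < rows || d[2] < cols) {
    abort(sprintf("mosaic (%d x %d px) is smaller than the %d x %d grid.",
                  d[1], d[2], rows, cols))
  }
  base_r <- d[1] %/% rows
  base_c <- d[2] %/% cols
  # half-open 0-based breakpoints; last tile absorbs the remainder
  r_start <- (seq_len(rows) - 1) * base_r
  r_end <- c(r_start[-1], d[1])
  c_start <- (seq_len(cols) - 1) * base_c
  c_end <- c(c_start[-1], d[2])
  out <- vector("list", rows * cols)
  k <- 0
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      k <- k + 1
      coords <- mosaic$coords %||% list()
      coords$tile <- k
      coords$tile_row <- i
      coords$tile_col <- j
      out[[k]] <- tile_image(
        mosaic$pixels[(r_start[i] + 1):r_end[i], (c_start[j] + 1):c_end[j],
                      drop = FALSE],
        pixel_scale = mosaic$pixel_scale, coords = coords,
        max_intensity = mosaic$max_intensity
      )
    }
  }
  out
}

#' Read and write single-channel grayscale TIFF tiles
#'
#' Thin wrappers around the \pkg{tiff} package that map between on-disk 8/16
#' bit integer TIFFs and the package's double-precision `tile_image`
#' representation.
#'
#' @param path File path.
#' @param pixel_scale,coords,max_intensity Passed to [tile_image()] on read.
#' @return `read_tile()` returns a [tile_image()]; `write_tile()` returns the
#'   path invisibly.
#' @export
read_tile <- function(path, pixel_scale = 0.1845, coords = NULL,
                      max_intensity = 65535) {
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3) px <- px[, , 1]
  tile_image(px * max_intensity, pixel_scale = pixel_scale, coords = coords,
             max_intensity = max_intensity)
}

#' @param img A [tile_image()].
#' @param bits_per_sample 8 or 16 (default 16).
#' @rdname read_tile
#' @export
write_tile <- function(img, path, bits_per_sample = 16) {
  stopifnot(inherits(img, "tile_image"))
  scaled <- clip(img$pixels / img$max_intensity, 0, 1)
  tiff::writeTIFF(scaled, path, bits.per.sample = bits_per_sample,
                  compression = "none")
  invisible(path)
}
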