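test_that("split_mosaic partitions exactly, remainder going to the last row/col", {
  # 10x10 with a 4x4 grid: base tile 2x2, last row/col absorb the remainder
  m <- tile_image(matrix(seq_len(100), 10, 10), pixel_scale = 1)
  tiles <- split_mosaic(m, 4, 4)
  expect_length(tiles, 16)
  dims <- t(vapply(tiles, function(t) dim(t$pixels), integer(2)))
  expect_true(all(dims[, 1] %in% c(2L, 4L)))
  expect_equal(sum(dims[, 1] * dims[, 2]), 100)
  # every mosaic pixel appears exactly once across tiles
  expect_equal(sort(unlist(lapply(tiles, function(t) t$pixels))),
               sort(as.vector(m$pixels)))

  tiny <- split_mosaic(tile_image(matrix(1:16, 4, 4), 1), 4, 4)
  expect_true(all(vapply(tiny, function(t) all(dim(t$pixels) == c(1, 1)),
                         logical(1))))
  expect_error(split_mosaic(tile_image(matrix(1:6, 2, 3), 1), 4, 4),
               "smaller")
})

test_that("a full-size 16-field mosaic splits conservatively", {
  m <- tile_image(matrix(0, 5135, 3841), pixel_scale = 0.1845)
  tiles <- split_mosaic(m, 4, 4)
  expect_length(tiles, 16)
  expect_equal(sum(vapply(tiles, function(t) prod(dim(t$pixels)),
                          numeric(1))),
               5135 * 3841)
})

test_that("contrast stretch maps the percentile window onto the full range", {
  const <- tile_image(matrix(500, 8, 8), 1)
  expect_identical(enhance_contrast(const)$pixels, const$pixels)

  two <- tile_image(matrix(rep(c(100, 200), each = 32), 8, 8), 1)
  out <- enhance_contrast(two, 0, 100)
  expect_setequal(unique(as.vector(out$pixels)), c(0, 65535))

  set.seed(1)
  x <- tile_image(matrix(runif(256, 0, 1000), 16, 16), 1)
  y <- enhance_contrast(x, 5, 95)
  ord <- order(x$pixels)
  expect_true(all(diff(y$pixels[ord]) >= 0))
})

test_that("unsharp masking matches a direct convolution oracle", {
  expect_identical(sharpen(tile_image(matrix(1:64, 8, 8), 1), amount = 0),
                   tile_image(matrix(1:64, 8, 8), 1))
  const <- tile_image(matrix(300, 12, 12), 1)
  expect_equal(sharpen(const, 2, 1.5)$pixels, const$pixels, tolerance = 1e-9)

  # single bright pixel: center rises, 4-neighbours fall (to the clip floor)
  px <- matrix(0, 15, 15)
  px[8, 8] <- 1000
  sh <- sharpen(tile_image(px, 1), amount = 1, radius_px = 1)
  expect_gt(sh$pixels[8, 8], 1000)
  expect_lte(sh$pixels[7, 8], 0)

  set.seed(7)
  x <- matrix(runif(24 * 24, 0, 40000), 24, 24)
  amount <- 1.3
  sigma <- 2
  got <- sharpen(tile_image(x, 1), amount, sigma)$pixels
  want <- pmin(pmax(x + amount * (x - oracle_gaussian_blur(x, sigma)), 0),
               65535)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("rolling-ball background equals the brute-force morphology oracle", {
  const <- tile_image(matrix(1234, 20, 20), 1)
  rb <- rolling_ball_background(const, 5)
  expect_equal(rb$background, const$pixels)
  expect_true(all(rb$corrected$pixels == 0))

  # constant + single spike: the spike is isolated into the corrected image;
  # the spherical element lets the background bulge under the spike by at
  # most the height step between adjacent ball samples
  px <- matrix(100, 32, 32)
  px[16, 16] <- 5000
  rb <- rolling_ball_background(tile_image(px, 1), 5)
  expect_lt(max(abs(rb$background - 100)), 5 - sqrt(24) + 1e-9)
  expect_equal(rb$corrected$pixels[16, 16], 4900, tolerance = 1e-4)
  expect_equal(sum(rb$corrected$pixels > 0), 1)
  expect_equal(rb$background, oracle_ball_opening(px, 5),
               tolerance = 1e-12)

  set.seed(33)
  for (k in 1:3) {
    x <- matrix(runif(32 * 32, 0, 65535), 32, 32)
    rb <- rolling_ball_background(tile_image(x, 1), 5)
    expect_equal(rb$background, oracle_ball_opening(x, 5), tolerance = 0)
  }
  expect_error(rolling_ball_background(tile_image(matrix(0, 10, 10), 1), 12),
               "does not fit")
})

test_that("rolling-ball honours its contracts: bound, positivity, idempotence", {
  st <- generate_tile(test_spec(seed = 21))
  rb <- rolling_ball_background(st$image, 10)
  expect_true(all(rb$background <= st$image$pixels + 1e-9))
  expect_true(all(rb$corrected$pixels >= -1e-9))
  rb2 <- rolling_ball_background(
    tile_image(rb$background, st$image$pixel_scale), 10
  )
  expect_equal(rb2$background, rb$background, tolerance = 1e-9)
})

test_that("a broad hill is absorbed into the background", {
  n <- 64
  d2 <- outer((1:n - n / 2)^2, (1:n - n / 2)^2, `+`)
  hill <- 10000 * exp(-d2 / (2 * 20^2))
  rb <- rolling_ball_background(tile_image(hill, 1), 8)
  expect_lt(max(rb$corrected$pixels), 0.1 * 10000)
})

test_that("binarization handles degenerate and separable images", {
  expect_false(any(binarize(matrix(0, 16, 16))))
  two <- matrix(0, 16, 16)
  two[5:8, 5:8] <- 1000
  expect_equal(binarize(two), two > 0)
  expect_equal(binarize(two, "fixed", value = 500), two > 500)
  expect_equal(binarize(two, "percentile", value = 90),
               two > quantile(two, 0.9))
})

test_that("thresholding a low-noise synthetic tile recovers the true mask", {
  st <- generate_tile(tile_spec(width_px = 128, height_px = 128,
                                colony_density_per_mm2 = 4000,
                                noise_sd = 50, seed = 13))
  m <- process_tile(st$image, quant_config(ball_radius_px = 15),
                    keep_intermediates = TRUE)
  lab <- attr(m, "intermediates")$labeling
  expect_gte(jaccard(lab$mask, st$truth$true_mask), 0.8)
})

test_that("labeling matches a flood-fill oracle for both connectivities", {
  expect_equal(label_colonies(matrix(FALSE, 8, 8))$n, 0)

  mask <- matrix(FALSE, 12, 12)
  mask[2:4, 2:4] <- TRUE
  mask[8:10, 8:10] <- TRUE
  lab <- label_colonies(mask, min_area_px = 1)
  expect_equal(lab$n, 2)
  expect_equal(lab$areas_px, c(9L, 9L))

  set.seed(99)
  for (k in 1:6) {
    m <- matrix(runif(64 * 64) < 0.35, 64, 64)
    for (conn in c(4, 8)) {
      expect_equal(label_colonies(m, min_area_px = 1, connectivity = conn)$n,
                   oracle_flood_fill_count(m, conn))
    }
  }
})

test_that("min_area filtering removes small components from mask and labels", {
  mask <- matrix(FALSE, 10, 10)
  mask[2, 2] <- TRUE            # area 1: removed
  mask[5:7, 5:7] <- TRUE        # area 9: kept
  lab <- label_colonies(mask, min_area_px = 5)
  expect_equal(lab$n, 1)
  expect_false(lab$mask[2, 2])
  expect_equal(sort(unique(as.vector(lab$labels))), c(0L, 1L))
})

test_that("colony outlines lie on component boundaries", {
  mask <- matrix(FALSE, 16, 16)
  mask[4:9, 4:9] <- TRUE
  lab <- label_colonies(mask, min_area_px = 1)
  expect_length(lab$outlines, 1)
  oc <- lab$outlines[[1]] + 1 # 0-based tracing -> 1-based matrix indexing
  expect_true(all(mask[oc]))
  # every outline pixel has a background 4-neighbour or touches the border
  on_boundary <- apply(oc, 1, function(p) {
    i <- p[1]; j <- p[2]
    nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    any(nb[, 1] < 1 | nb[, 1] > 16 | nb[, 2] < 1 | nb[, 2] > 16) ||
      any(!mask[nb[nb[, 1] >= 1 & nb[, 1] <= 16 &
                     nb[, 2] >= 1 & nb[, 2] <= 16, , drop = FALSE]])
  })
  expect_true(all(on_boundary))
})

test_that("tile metrics follow the density and area definitions", {
  # 512 x 512 px at 0.1845 um/px: area 0.008923 mm^2; 3 colonies -> 336.2/mm^2
  mask <- matrix(FALSE, 512, 512)
  mask[10:12, 10:12] <- TRUE
  mask[100:102, 100:102] <- TRUE
  mask[300:302, 300:302] <- TRUE
  lab <- label_colonies(mask, min_area_px = 1)
  img <- tile_image(matrix(0, 512, 512), 0.1845)
  m <- compute_tile_metrics(lab, img)
  expect_equal(m$tile_area_mm2, (512 * 0.1845)^2 * 1e-6, tolerance = 1e-12)
  expect_equal(m$colony_count, 3)
  expect_equal(m$colony_density_mm2, 3 / 0.008923447, tolerance = 1e-4)
  expect_equal(m$colony_density_mm2, 336.2, tolerance = 1e-3)
  expect_equal(m$pct_colonized_area, 100 * 27 / 512^2)

  empty <- label_colonies(matrix(FALSE, 32, 32))
  me <- compute_tile_metrics(empty, tile_image(matrix(0, 32, 32), 0.5))
  expect_equal(me$colony_count, 0)
  expect_equal(me$colony_density_mm2, 0)
  expect_equal(me$pct_colonized_area, 0)

  full <- label_colonies(matrix(TRUE, 32, 32))
  mf <- compute_tile_metrics(full, tile_image(matrix(1, 32, 32), 0.5))
  expect_equal(mf$pct_colonized_area, 100)
  expect_equal(mf$colony_count, 1)
})

test_that("the full chain is deterministic and recovers known colony counts", {
  st <- generate_tile(tile_spec(seed = 7))
  cfg <- quant_config()
  m1 <- process_tile(st$image, cfg)
  m2 <- process_tile(st$image, cfg)
  expect_identical(m1, m2)
  # well-separated low-noise colonies: count within +/-5% of ground truth
  expect_gte(st$truth$merged_count, 20)
  expect_lte(abs(m1$colony_count - st$truth$merged_count),
             ceiling(0.05 * st$truth$merged_count))

  zero <- tile_image(matrix(0, 96, 96), 0.1845)
  mz <- process_tile(zero, quant_config(ball_radius_px = 10))
  expect_equal(mz$colony_count, 0)
  expect_equal(mz$pct_colonized_area, 0)
})

test_that("rolling-ball correction makes counts robust to illumination gradients", {
  flat <- generate_tile(tile_spec(illumination_gradient_amplitude = 0,
                                  seed = 17))
  grad <- generate_tile(tile_spec(illumination_gradient_amplitude = 0.3,
                                  seed = 17))
  cfg <- quant_config()
  n_flat <- process_tile(flat$image, cfg)$colony_count
  n_grad <- process_tile(grad$image, cfg)$colony_count
  expect_lte(abs(n_flat - n_grad), ceiling(0.1 * n_flat))
})

test_that("tile counts are conserved when processing a split mosaic", {
  st <- generate_tile(tile_spec(seed = 29, noise_sd = 100))
  whole <- process_tile(st$image, quant_config())$colony_count
  tiles <- split_mosaic(st$image, 4, 4)
  parts <- sum(quantify_tiles(tiles, quant_config(ball_radius_px = 15))$colony_count)
  # colonies straddling internal tile borders may be counted once per side
  ctr <- st$truth$colonies
  r_px <- ctr$radius_um / st$image$pixel_scale
  cuts <- c(128, 256, 384)
  straddles <- vapply(seq_len(nrow(ctr)), function(i) {
    any(abs(ctr$row[i] - cuts) < r_px[i]) || any(abs(ctr$col[i] - cuts) < r_px[i])
  }, logical(1))
  expect_lte(abs(parts - whole), max(sum(straddles), 1) + 1)
})

test_that("TIFF round trip preserves 16-bit tile content", {
  path <- withr::local_tempfile(fileext = ".tif")
  px <- matrix(sample(0:65535, 64 * 64, replace = TRUE), 64, 64)
  write_tile(tile_image(px, 0.1845), path)
  back <- read_tile(path, pixel_scale = 0.1845)
  expect_equal(back$pixels, px, tolerance = 1e-9)
})
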