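# Independent brute-force oracles used to validate the optimized
# implementations. Written as directly as possible; no shared code with R/.

# Grayscale opening by an explicit ball kernel: plain double loop over
# pixels and kernel offsets, erosion then dilation, offsets outside the
# image skipped.
oracle_ball_opening <- function(img, radius, height_scale = 1) {
  r <- floor(radius)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= radius^2, ]
  off$z <- height_scale * sqrt(radius^2 - off$di^2 - off$dj^2)
  nr <- nrow(img)
  nc <- ncol(img)
  eroded <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- i + off$di
      jj <- j + off$dj
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      eroded[i, j] <- min(img[cbind(ii[ok], jj[ok])] - off$z[ok])
    }
  }
  dilated <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- i + off$di
      jj <- j + off$dj
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      dilated[i, j] <- max(eroded[cbind(ii[ok], jj[ok])] + off$z[ok])
    }
  }
  # the opening never exceeds the image (anti-extensivity contract)
  pmin(dilated, img)
}

# Connected components by breadth-first flood fill.
oracle_flood_fill_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  seen <- matrix(FALSE, nr, nc)
  count <- 0
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      p <- queue[1]
      queue <- queue[-1]
      pi <- (p - 1) %% nr + 1
      pj <- (p - 1) %/% nr + 1
      for (k in seq_len(nrow(nb))) {
        ii <- pi + nb[k, 1]
        jj <- pj + nb[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue <- c(queue, ii + (jj - 1) * nr)
        }
      }
    }
  }
  count
}

# Direct 2D convolution with an outer-product Gaussian kernel and
# edge-clamped (replicate) boundary.
oracle_gaussian_blur <- function(img, sigma) {
  R <- ceiling(3 * sigma)
  k1 <- exp(-0.5 * (-R:R)^2 / sigma^2)
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  nr <- nrow(img)
  nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in -R:R) {
        for (b in -R:R) {
          ii <- min(max(i + a, 1), nr)
          jj <- min(max(j + b, 1), nc)
          acc <- acc + k2[a + R + 1, b + R + 1] * img[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Kruskal-Wallis H from the rank-sum formula with tie correction, and its
# exact permutation p-value by exhaustive enumeration of group assignments.
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  N <- length(r)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * (mean(x) - (N + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

oracle_kw_exact_p <- function(values, n1) {
  N <- length(values)
  groups_obs <- rep(c("a", "b"), c(n1, N - n1))
  h_obs <- oracle_kw_h(values, groups_obs)
  combos <- utils::combn(N, n1)
  hs <- apply(combos, 2, function(idx) {
    g <- rep("b", N)
    g[idx] <- "a"
    oracle_kw_h(values, g)
  })
  mean(hs >= h_obs - 1e-12)
}

# Mutual best hits by an O(n^2) scan over dense score matrices.
oracle_bbh <- function(score_ab, score_ba) {
  # score_ab: matrix A x B, score_ba: matrix B x A (dimnames = ids)
  pairs <- list()
  for (a in rownames(score_ab)) {
    sa <- score_ab[a, ]
    best_b <- names(sa)[sa == max(sa)]
    if (length(best_b) != 1) next
    sb <- score_ba[best_b, ]
    best_a <- names(sb)[sb == max(sb)]
    if (length(best_a) == 1 && best_a == a) {
      pairs[[length(pairs) + 1]] <- c(a, best_b)
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(seq_a = character(0), seq_b = character(0)))
  }
  out <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(out) <- c("seq_a", "seq_b")
  out[order(out$seq_a), , drop = FALSE]
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Small, fast default spec for unit tests.
test_spec <- function(...) {
  defaults <- list(width_px = 96, height_px = 96,
                   colony_density_per_mm2 = 6000, noise_sd = 100,
                   illumination_gradient_amplitude = 0.05, seed = 1)
  do.call(tile_spec, utils::modifyList(defaults, list(...)))
}

# Path to the packaged synthetic transporter-survey fixture.
fixture_path <- function(file) {
  system.file("extdata", "sulfobacillus", file, package = "biofilmq",
              mustWork = TRUE)
}
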