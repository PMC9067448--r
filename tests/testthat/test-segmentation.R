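fake_vness <- function(arr, spacing = c(1, 1, 1)) {
  structure(list(response = arr, scales_used = 1, tau = 0.5,
                 polarity = "bright", spacing = spacing,
                 origin = c(0, 0, 0), orientation = diag(3)),
            class = "vesselness_map")
}

test_that("thresholding matches its definition and a counting oracle", {
  arr <- array(0, c(4, 4, 4))
  arr[1, 1, 1] <- 0.2; arr[2, 2, 2] <- 0.6; arr[3, 3, 3] <- 0.9
  m <- threshold_segment(fake_vness(arr), 0.5)
  expect_identical(sum(m$data), 2L)
  expect_true(m$data[2, 2, 2] && m$data[3, 3, 3])
  expect_true(all(threshold_segment(fake_vness(array(0, c(3, 3, 3))), 0.5)$data == FALSE))
  set.seed(1)
  r <- array(runif(6^3), c(6, 6, 6))
  for (thr in c(0.2, 0.5, 0.8)) {
    expect_identical(sum(threshold_segment(fake_vness(r), thr)$data),
                     sum(r >= thr))
  }
  expect_error(threshold_segment(fake_vness(r), 0),
               class = "arterymap_argument_error")
  expect_error(threshold_segment(fake_vness(r), 1),
               class = "arterymap_argument_error")
})

test_that("raising the threshold never increases the foreground", {
  set.seed(2)
  v <- fake_vness(array(runif(5^3), c(5, 5, 5)))
  counts <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(t) sum(threshold_segment(v, t)$data), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the subcutaneous band of a ball is the analytic shell", {
  n <- 45; sp <- 1
  ctr <- 23
  x <- (seq_len(n) - ctr) * sp
  X <- array(rep(x, times = n * n), c(n, n, n))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  r <- sqrt(X^2 + Y^2 + Z^2)
  vol <- image_volume(100 * (r <= 20), spacing = rep(sp, 3))
  band <- subcutaneous_band_mask(vol, band_depth_mm = 5, closing_mm = 0)
  shell <- r <= 20 & r >= 15
  # agreement within one voxel of the shell boundaries
  mism <- which(band$data != shell)
  if (length(mism) > 0) {
    expect_true(all(abs(r[mism] - 15) <= sp | abs(r[mism] - 20) <= sp))
  }
  expect_gt(sum(band$data & shell) / sum(shell), 0.9)
  # saturation: a band deeper than the radius is the whole head
  full <- subcutaneous_band_mask(vol, band_depth_mm = 50, closing_mm = 0)
  expect_identical(sum(full$data), sum(r <= 20))
})

test_that("a skin margin removes exactly the outermost shell", {
  n <- 31
  ctr <- 16
  x <- seq_len(n) - ctr
  X <- array(rep(x, times = n * n), c(n, n, n))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  r <- sqrt(X^2 + Y^2 + Z^2)
  vol <- image_volume(100 * (r <= 12), spacing = c(1, 1, 1))
  b0 <- subcutaneous_band_mask(vol, 8, closing_mm = 0)
  b2 <- subcutaneous_band_mask(vol, 8, closing_mm = 0, skin_margin_mm = 2)
  expect_true(all(b2$data <= b0$data))
  expect_gt(sum(b0$data) - sum(b2$data), 0)
  inner <- r <= 9 & r >= 5
  expect_gt(sum(b2$data & inner) / sum(inner), 0.9)
})

test_that("an empty volume fails head segmentation", {
  vol <- image_volume(array(0, c(8, 8, 8)))
  expect_error(subcutaneous_band_mask(vol, 5),
               class = "arterymap_segmentation_failure")
})

test_that("separation intersects with the band and filters small components", {
  tube <- make_tube_mask(length_vox = 20, radius_vox = 1)
  d <- dim(tube$data)
  half <- binary_mask(array(rep(c(TRUE, FALSE), each = ceiling(d[1] / 2))[seq_len(d[1])],
                            d),
                      tube$spacing, tube$origin, tube$orientation)
  out <- separate_superficial(tube, half, min_component_voxels = 1L)
  expect_identical(out$data, tube$data & half$data)

  m <- array(FALSE, c(20, 10, 10))
  m[2:3, 2:3, 2] <- TRUE                     # small blob: < 50 voxels
  m[6:19, 3:8, 3:8] <- TRUE                  # big block: >= 500 voxels
  blk <- binary_mask(m)
  all_band <- binary_mask(array(TRUE, dim(m)))
  kept <- separate_superficial(blk, all_band, min_component_voxels = 50L)
  expect_identical(sum(kept$data), sum(m[6:19, 3:8, 3:8]))
  expect_true(all(!kept$data[2:3, 2:3, 2]))
})

test_that("separation equals a brute-force intersection + component filter", {
  set.seed(4)
  a <- array(runif(8^3) > 0.6, c(8, 8, 8))
  b <- array(runif(8^3) > 0.4, c(8, 8, 8))
  got <- separate_superficial(binary_mask(a), binary_mask(b),
                              min_component_voxels = 3L)
  inter <- a & b
  lab <- label_components(inter, 26L)
  keep <- which(tabulate(lab[lab > 0]) >= 3L)
  want <- array(lab %in% keep & inter, dim(a))
  expect_identical(got$data, want)
  # subset invariants
  expect_true(all(!got$data | a))
  expect_true(all(!got$data | b))
})

test_that("grids must match for separation", {
  a <- binary_mask(array(TRUE, c(4, 4, 4)))
  b <- binary_mask(array(TRUE, c(4, 4, 5)))
  expect_error(separate_superficial(a, b), class = "arterymap_geometry_error")
  b2 <- binary_mask(array(TRUE, c(4, 4, 4)), spacing = c(2, 1, 1))
  expect_error(separate_superficial(a, b2), class = "arterymap_geometry_error")
})

test_that("connected component labeling matches a reference flood fill", {
  set.seed(9)
  m <- array(runif(7^3) > 0.65, c(7, 7, 7))
  for (conn in c(6L, 26L)) {
    lab <- label_components(m, conn)
    expect_identical(lab > 0, m)
    # reference: flood fill in R
    ref <- array(0L, dim(m)); nxt <- 0L
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    if (conn == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
    for (i in seq_along(m)) {
      if (!m[i] || ref[i]) next
      nxt <- nxt + 1L
      queue <- i
      ref[i] <- nxt
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        cc <- arrayInd(cur, dim(m))
        for (r in seq_len(nrow(offs))) {
          nb <- cc + offs[r, ]
          if (any(nb < 1) || any(nb > dim(m))) next
          j <- nb[1] + (nb[2] - 1) * 7 + (nb[3] - 1) * 49
          if (m[j] && !ref[j]) { ref[j] <- nxt; queue <- c(queue, j) }
        }
      }
    }
    # same partition (labels may renumber)
    expect_identical(max(lab), max(ref))
    expect_true(all(tapply(ref[m], lab[m], function(v) length(unique(v))) == 1))
  }
})

test_that("the distance transform is exact against brute force", {
  set.seed(3)
  seed <- array(runif(6 * 5 * 7) > 0.8, c(6, 5, 7))
  if (!any(seed)) seed[2, 2, 2] <- TRUE
  sp <- c(0.7, 1.1, 0.9)
  d <- distance_transform(seed, sp)
  pts <- which(seed, arr.ind = TRUE)
  for (i in 1:6) for (j in 1:5) for (k in 1:7) {
    ref <- min(sqrt(((pts[, 1] - i) * sp[1])^2 +
                      ((pts[, 2] - j) * sp[2])^2 +
                      ((pts[, 3] - k) * sp[3])^2))
    expect_equal(d[i, j, k], ref, tolerance = 1e-12)
  }
})
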