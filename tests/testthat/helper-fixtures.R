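# Shared fixture builders. Everything is generated in code; nothing binary
# ships with the package.

round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

make_ball_mask <- function(radius_mm, spacing = 0.5, pad_vox = 4) {
  n <- as.integer(2 * radius_mm / spacing) + 2 * pad_vox
  ctr <- (n - 1) / 2
  x <- ((seq_len(n)) - 1 - ctr) * spacing
  X <- array(rep(x, times = n * n), c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  binary_mask((X^2 + Y^2 + Z^2) <= radius_mm^2,
              spacing = rep(spacing, 3),
              origin = rep(-ctr * spacing, 3))
}

# axis-aligned solid tube along the first array axis
make_tube_mask <- function(length_vox = 40, radius_vox = 2, pad = 4,
                           spacing = 1) {
  nx <- length_vox + 2 * pad
  nyz <- 2 * (radius_vox + pad) + 1
  ctr <- (nyz + 1) / 2
  m <- array(FALSE, c(nx, nyz, nyz))
  for (j in seq_len(nyz)) for (k in seq_len(nyz)) {
    if ((j - ctr)^2 + (k - ctr)^2 <= radius_vox^2) {
      m[(pad + 1):(pad + length_vox), j, k] <- TRUE
    }
  }
  binary_mask(m, spacing = rep(spacing, 3))
}

# bright Gaussian tube volume along the first axis, centred in y/z
make_tube_volume <- function(n = 41, spacing = 0.5, radius_mm = 1,
                             peak = 200, background = 100) {
  ctr <- (n + 1) / 2
  f <- array(0, c(n, n, n))
  sigma <- radius_mm / 2
  for (j in seq_len(n)) for (k in seq_len(n)) {
    d2 <- (((j - ctr) * spacing)^2 + ((k - ctr) * spacing)^2)
    f[, j, k] <- peak * exp(-d2 / (2 * sigma^2))
  }
  image_volume(f + background, spacing = rep(spacing, 3))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
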