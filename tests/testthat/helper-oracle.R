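# Independent dense oracle for the Hessian/vesselness chain: explicit 3-D
# kernel built from the sampled Gaussian-derivative formulas, convolution as
# a literal per-voxel sum with reflected indexing, eigenvalues from LAPACK
# (base eigen()) one voxel at a time. Shares no code path with the package's
# separable-matrix implementation.

oracle_kernels_1d <- function(sigma, h) {
  r <- max(1L, ceiling(4 * sigma / h))
  x <- (-r:r) * h
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g1 <- g1 / sum(-x * g1)
  g2 <- (x^2 / sigma^4 - 1 / sigma^2) * g
  g2 <- g2 - mean(g2)
  g2 <- g2 / (sum(x^2 * g2) / 2)
  list(g = g, g1 = g1, g2 = g2, r = r)
}

oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# full 3-D kernel convolution at every voxel (convolution orientation:
# out[p] = sum_o k[o] f[p - o])
oracle_conv3 <- function(f, kx, ky, kz) {
  d <- dim(f)
  rx <- (length(kx) - 1) / 2
  ry <- (length(ky) - 1) / 2
  rz <- (length(kz) - 1) / 2
  k3 <- outer(outer(kx, ky), kz)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (oi in -rx:rx) for (oj in -ry:ry) for (ok in -rz:rz) {
      acc <- acc + k3[oi + rx + 1, oj + ry + 1, ok + rz + 1] *
        f[oracle_reflect(i - oi, d[1]),
          oracle_reflect(j - oj, d[2]),
          oracle_reflect(k - ok, d[3])]
    }
    out[i, j, k] <- acc
  }
  out
}

oracle_hessian_eigs <- function(volume, scale_mm) {
  f <- volume$data
  sp <- volume$spacing
  ks <- lapply(sp, function(h) oracle_kernels_1d(scale_mm, h))
  comp <- function(o1, o2, o3) {
    pick <- function(kk, o) switch(o + 1L, kk$g, kk$g1, kk$g2)
    oracle_conv3(f, pick(ks[[1]], o1), pick(ks[[2]], o2), pick(ks[[3]], o3)) *
      scale_mm^2
  }
  h11 <- comp(2L, 0L, 0L); h22 <- comp(0L, 2L, 0L); h33 <- comp(0L, 0L, 2L)
  h12 <- comp(1L, 1L, 0L); h13 <- comp(1L, 0L, 1L); h23 <- comp(0L, 1L, 1L)
  d <- dim(f)
  l1 <- array(0, d); l2 <- array(0, d); l3 <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    H <- matrix(c(h11[i, j, k], h12[i, j, k], h13[i, j, k],
                  h12[i, j, k], h22[i, j, k], h23[i, j, k],
                  h13[i, j, k], h23[i, j, k], h33[i, j, k]), 3, 3)
    e <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    e <- e[order(abs(e))]
    l1[i, j, k] <- e[1]; l2[i, j, k] <- e[2]; l3[i, j, k] <- e[3]
  }
  list(lam1 = l1, lam2 = l2, lam3 = l3)
}

# scalar Jerman response evaluated directly from the formula
oracle_jerman <- function(l2f, l3f, tau) {
  m3 <- max(l3f)
  if (m3 <= 1e-12 * max(abs(l3f), 1)) return(array(0, dim(l2f)))
  cut <- tau * m3
  V <- array(0, dim(l2f))
  for (i in seq_along(l2f)) {
    l2 <- l2f[i]; l3 <- l3f[i]
    lr <- if (l3 > cut) l3 else if (l3 > 0) cut else 0
    V[i] <- if (l2 <= 0 || lr <= 0) 0
    else if (l2 >= lr / 2) 1
    else l2^2 * (lr - l2) * (3 / (l2 + lr))^3
  }
  V
}

oracle_vesselness <- function(volume, scales, tau) {
  out <- array(0, dim(volume$data))
  for (s in scales) {
    ev <- oracle_hessian_eigs(volume, s)
    out <- pmax(out, oracle_jerman(-ev$lam2, -ev$lam3, tau))
  }
  out
}
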