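#' Multiscale Jerman vessel enhancement
#'
#' @description
#' Hessian-eigenvalue vessel enhancement for bright tubular structures in
#' TOF-MRA-like volumes. The per-scale response uses the regularized largest
#' eigenvalue \eqn{\lambda_\rho} with cutoff fraction \eqn{\tau}:
#' \deqn{V = \lambda_2^2 (\lambda_\rho - \lambda_2)
#'           \left(\frac{3}{\lambda_2 + \lambda_\rho}\right)^3}
#' clamped to 1 where \eqn{\lambda_2 \ge \lambda_\rho / 2 > 0} and set to 0
#' where \eqn{\lambda_2 \le 0} or \eqn{\lambda_\rho \le 0}. The multiscale
#' response is the pointwise maximum over scales.
#'
#' @name vesselness
NULL

# 1-D sampled Gaussian and derivative kernels on a grid with step h (mm).
# The smoothing kernel is normalized to unit sum; the derivative kernels are
# moment-corrected so that first/second derivatives of linear/quadratic
# signals are reproduced exactly.
gaussian_kernels_1d <- function(sigma_mm, h_mm) {
  radius <- max(1L, ceiling(4 * sigma_mm / h_mm))
  x <- (-radius:radius) * h_mm
  g <- exp(-x^2 / (2 * sigma_mm^2))
  g <- g / sum(g)
  g1 <- -x / sigma_mm^2 * g
  g1 <- g1 / sum(-x * g1)
  g2 <- (x^2 / sigma_mm^4 - 1 / sigma_mm^2) * g
  g2 <- g2 - mean(g2)
  g2 <- g2 / (sum(x^2 * g2) / 2)
  list(g = g, g1 = g1, g2 = g2, radius = radius)
}

reflect_index <- function(p, n) {
  # half-sample symmetric boundary: ... 2 1 | 1 2 ... n | n n-1 ...
  while (any(p < 1L | p > n)) {
    p <- ifelse(p < 1L, 1L - p, p)
    p <- ifelse(p > n, 2L * n + 1L - p, p)
  }
  p
}

conv_matrix_1d <- function(kernel, n) {
  radius <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -radius:radius) {
    j <- reflect_index(seq_len(n) - o, n)
    idx <- cbind(seq_len(n), j)
    K[idx] <- K[idx] + kernel[o + radius + 1L]
  }
  K
}

# separable convolution of a 3-D array along one axis (reflect boundary)
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, perm)
  K <- conv_matrix_1d(kernel, d[axis])
  m <- K %*% matrix(ap, nrow = d[axis])
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

#' Scale-normalized Hessian eigenvalues
#'
#' Computes the Hessian of the volume from Gaussian second-derivative filters
#' with physical-space standard deviation `scale_mm` on every axis
#' (anisotropic spacing honoured), applies \eqn{\gamma = 2} scale
#' normalization (multiplication by `scale_mm^2`), and returns the per-voxel
#' eigenvalues sorted by absolute value.
#'
#' @param volume An [image_volume()].
#' @param scale_mm Gaussian scale in mm; must be at least half the largest
#'   voxel spacing.
#' @return A list of class `eigenvalue_field` with arrays `lam1`, `lam2`,
#'   `lam3` (|lam1| <= |lam2| <= |lam3| per voxel) and the `scale` used.
#' @export
hessian_eigenvalues <- function(volume, scale_mm) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.numeric(scale_mm) || length(scale_mm) != 1L || scale_mm <= 0) {
    am_stop("`scale_mm` must be a positive scalar", "arterymap_argument_error")
  }
  if (scale_mm < max(volume$spacing) / 2) {
    am_stop(sprintf("scale %.3f mm is below half the largest voxel spacing (%.3f mm)",
                    scale_mm, max(volume$spacing)),
            "arterymap_argument_error")
  }
  ks <- lapply(volume$spacing, function(h) gaussian_kernels_1d(scale_mm, h))
  f <- volume$data
  deriv <- function(orders) {
    out <- f
    for (ax in 1:3) {
      k <- switch(orders[ax] + 1L, ks[[ax]]$g, ks[[ax]]$g1, ks[[ax]]$g2)
      out <- conv_axis(out, k, ax)
    }
    out * scale_mm^2
  }
  h11 <- deriv(c(2L, 0L, 0L))
  h22 <- deriv(c(0L, 2L, 0L))
  h33 <- deriv(c(0L, 0L, 2L))
  h12 <- deriv(c(1L, 1L, 0L))
  h13 <- deriv(c(1L, 0L, 1L))
  h23 <- deriv(c(0L, 1L, 1L))
  ev <- eig3_sym(h11, h12, h13, h22, h23, h33)
  # eigenvalues smaller than this are floating-point residue of the filters,
  # not structure; the response formula is contrast-invariant, so without a
  # floor a constant volume would respond to pure rounding noise
  structure(list(lam1 = array(ev$lam1, dim(f)),
                 lam2 = array(ev$lam2, dim(f)),
                 lam3 = array(ev$lam3, dim(f)),
                 scale = scale_mm,
                 noise_floor = 1e-10 * max(abs(range(f)))),
            class = "eigenvalue_field")
}

#' Single-scale Jerman response from Hessian eigenvalues
#'
#' @param eigs An `eigenvalue_field` from [hessian_eigenvalues()].
#' @param tau Cutoff fraction \eqn{\tau} in (0, 1] for the regularized
#'   eigenvalue \eqn{\lambda_\rho}.
#' @param polarity `"bright"` (vessels brighter than background; eigenvalues
#'   are sign-flipped before evaluation) or `"dark"`.
#' @return Array of responses in `[0, 1]`.
#' @export
jerman_response <- function(eigs, tau = 0.5, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1) {
    am_stop("`tau` must lie in (0, 1]", "arterymap_argument_error")
  }
  sgn <- if (polarity == "bright") -1 else 1
  l2 <- sgn * eigs$lam2
  l3 <- sgn * eigs$lam3
  m3 <- max(l3)
  V <- array(0, dim(l2))
  if (m3 <= max(0, eigs$noise_floor %||% 0)) return(V)
  cut <- tau * m3
  lrho <- ifelse(l3 > cut, l3, ifelse(l3 > 0, cut, 0))
  active <- l2 > 0 & lrho > 0
  clamp <- active & (l2 >= lrho / 2)
  mid <- active & !clamp
  V[clamp] <- 1
  V[mid] <- l2[mid]^2 * (lrho[mid] - l2[mid]) * (3 / (l2[mid] + lrho[mid]))^3
  V
}

#' Multiscale vesselness map
#'
#' Applies [hessian_eigenvalues()] and [jerman_response()] at every scale and
#' takes the pointwise maximum. The \eqn{\lambda_\rho} regularization uses the
#' per-scale global maximum of \eqn{\lambda_3} over the whole volume.
#'
#' @inheritParams hessian_eigenvalues
#' @inheritParams jerman_response
#' @param scales_mm Ordered vector of Gaussian scales in mm.
#' @return A list of class `vesselness_map` with the `response` array in
#'   `[0, 1]`, `scales_used`, `tau`, and the source geometry (`spacing`,
#'   `origin`, `orientation`).
#' @export
multiscale_vesselness <- function(volume, scales_mm = c(0.5, 0.75, 1, 1.5, 2),
                                  tau = 0.5, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(volume, "image_volume"))
  if (length(scales_mm) == 0) {
    am_stop("`scales_mm` must be non-empty", "arterymap_argument_error")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1) {
    am_stop("`tau` must lie in (0, 1]", "arterymap_argument_error")
  }
  response <- array(0, dim(volume$data))
  for (s in scales_mm) {
    ev <- hessian_eigenvalues(volume, s)
    response <- pmax(response, jerman_response(ev, tau, polarity))
  }
  structure(list(response = response, scales_used = as.numeric(scales_mm),
                 tau = tau, polarity = polarity,
                 spacing = volume$spacing, origin = volume$origin,
                 orientation = volume$orientation),
            class = "vesselness_map")
}

#' @export
print.vesselness_map <- function(x, ...) {
  cat("<vesselness_map> ", paste(dim(x$response), collapse = " x "),
      " voxels, scales {", paste(x$scales_used, collapse = ", "),
      "} mm, tau ", x$tau, "\n", sep = "")
  cat("  response range: [", signif(min(x$response), 4), ", ",
      signif(max(x$response), 4), "]\n", sep = "")
  invisible(x)
}
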