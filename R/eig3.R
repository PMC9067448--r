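# Vectorized eigenvalues of symmetric 3x3 matrices.
#
# Closed-form trigonometric solution (Cardano on the shifted/scaled matrix)
# followed by one damped Newton polish per root on the characteristic
# polynomial, which restores near machine precision for well-separated roots.
# Inputs are arrays of the six unique components; output is the triple sorted
# by increasing absolute value at every element.

eig3_sym <- function(a11, a12, a13, a22, a23, a33) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  ok <- p > 0
  ps <- ifelse(ok, p, 1)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  # characteristic polynomial p(x) = x^3 - c2 x^2 + c1 x - c0
  c2 <- a11 + a22 + a33
  c1 <- a11 * a22 - a12^2 + a11 * a33 - a13^2 + a22 * a33 - a23^2
  c0 <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  scale <- pmax(abs(e1), abs(e3), .Machine$double.xmin)
  polish <- function(x) {
    for (i in 1:2) {
      fx <- ((x - c2) * x + c1) * x - c0
      dfx <- (3 * x - 2 * c2) * x + c1
      step <- fx / dfx
      step[!is.finite(step) | abs(step) > 0.1 * scale] <- 0
      x <- x - step
    }
    x
  }
  e1 <- polish(e1); e2 <- polish(e2); e3 <- polish(e3)
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  # sorting network on |.|
  sw <- abs(e1) > abs(e2)
  tmp <- e1[sw]; e1[sw] <- e2[sw]; e2[sw] <- tmp
  sw <- abs(e2) > abs(e3)
  tmp <- e2[sw]; e2[sw] <- e3[sw]; e3[sw] <- tmp
  sw <- abs(e1) > abs(e2)
  tmp <- e1[sw]; e1[sw] <- e2[sw]; e2[sw] <- tmp
  list(lam1 = e1, lam2 = e2, lam3 = e3)
}
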