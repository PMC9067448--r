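test_that("constant volumes give zero eigenvalues and zero response", {
  vol <- image_volume(array(7, c(12, 12, 12)))
  ev <- hessian_eigenvalues(vol, 1)
  expect_lt(max(abs(ev$lam3)), 1e-10)
  expect_true(all(jerman_response(ev, 0.5) == 0))
  expect_true(all(multiscale_vesselness(vol, c(1, 1.5))$response == 0))
})

test_that("a quadratic valley yields the analytic normalized eigenvalues", {
  n <- 21; s <- 1.5
  f <- array(0, c(n, n, n))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    f[, j, k] <- -((j - 11)^2 + (k - 11)^2)
  }
  ev <- hessian_eigenvalues(image_volume(f), s)
  ctr <- c(11, 11, 11)
  expect_equal(ev$lam1[11, 11, 11], 0, tolerance = 1e-8)
  expect_equal(ev$lam2[11, 11, 11], -2 * s^2, tolerance = 1e-4)
  expect_equal(ev$lam3[11, 11, 11], -2 * s^2, tolerance = 1e-4)
  expect_true(all(abs(ev$lam1) <= abs(ev$lam2) + 1e-12))
  expect_true(all(abs(ev$lam2) <= abs(ev$lam3) + 1e-12))
})

test_that("eigenvalues match a per-voxel LAPACK eigensolver on random data", {
  set.seed(11)
  vol <- image_volume(array(rnorm(9^3), c(9, 9, 9)))
  ev <- hessian_eigenvalues(vol, 1.2)
  oe <- oracle_hessian_eigs(vol, 1.2)
  expect_lt(max(abs(ev$lam1 - oe$lam1)), 1e-8)
  expect_lt(max(abs(ev$lam2 - oe$lam2)), 1e-8)
  expect_lt(max(abs(ev$lam3 - oe$lam3)), 1e-8)
})

test_that("response formula branches evaluate exactly", {
  fake <- structure(list(lam1 = array(0, c(1, 1, 3)),
                         lam2 = array(c(-0.5, -0.5, -1), c(1, 1, 3)),
                         lam3 = array(c(-2, -4, -2), c(1, 1, 3)),
                         scale = 1, noise_floor = 0),
                    class = "eigenvalue_field")
  # bright polarity flips: lam2 -> (0.5, 0.5, 1), lam3 -> (2, 4, 2); m3 = 4
  # voxel 1: lrho = tau*m3 = 2 -> V = 0.25 * 1.5 * (3/2.5)^3 = 0.648
  # voxel 2: lam3 = 4 > 2 -> lrho = 4, x = 1/8 branch
  # voxel 3: lam2 = 1 = lrho/2 -> clamp branch = 1
  V <- jerman_response(fake, tau = 0.5)
  expect_equal(V[1, 1, 1], 0.648, tolerance = 1e-12)
  expect_equal(V[1, 1, 2], 0.5^2 * (4 - 0.5) * (3 / 4.5)^3, tolerance = 1e-12)
  expect_equal(V[1, 1, 3], 1)
})

test_that("the response is continuous at the lam2 = lrho/2 clamp", {
  eps <- 1e-9
  mk <- function(l2) {
    structure(list(lam1 = array(0, c(1, 1, 1)),
                   lam2 = array(-l2, c(1, 1, 1)),
                   lam3 = array(-2, c(1, 1, 1)),
                   scale = 1, noise_floor = 0),
              class = "eigenvalue_field")
  }
  below <- jerman_response(mk(1 - eps), tau = 1)[1]
  at <- jerman_response(mk(1), tau = 1)[1]
  expect_equal(at, 1)
  expect_equal(below, 1, tolerance = 1e-7)
})

test_that("plate/background suppression: lam2 <= 0 gives zero response", {
  fake <- structure(list(lam1 = array(0, c(1, 1, 2)),
                         lam2 = array(c(0.3, 0), c(1, 1, 2)),
                         lam3 = array(c(-5, -5), c(1, 1, 2)),
                         scale = 1, noise_floor = 0),
                    class = "eigenvalue_field")
  V <- jerman_response(fake, tau = 0.5)  # flipped lam2 = (-0.3, 0) <= 0
  expect_true(all(V == 0))
})

test_that("argument contracts: tau range, scale floor, empty scale list", {
  vol <- image_volume(array(rnorm(6^3), c(6, 6, 6)))
  ev <- hessian_eigenvalues(vol, 1)
  expect_error(jerman_response(ev, 0), class = "arterymap_argument_error")
  expect_error(jerman_response(ev, 1.5), class = "arterymap_argument_error")
  expect_error(hessian_eigenvalues(vol, -1), class = "arterymap_argument_error")
  expect_error(hessian_eigenvalues(vol, 0.2),
               class = "arterymap_argument_error")  # below max spacing / 2
  expect_error(multiscale_vesselness(vol, numeric(0)),
               class = "arterymap_argument_error")
})

test_that("multiscale response is bounded, shift-invariant, single-scale consistent", {
  vol <- make_tube_volume(n = 25)
  vm <- multiscale_vesselness(vol, c(0.5, 1), tau = 0.5)
  expect_true(all(vm$response >= 0 & vm$response <= 1))
  shifted <- image_volume(vol$data + 37, vol$spacing, vol$origin)
  vs <- multiscale_vesselness(shifted, c(0.5, 1), tau = 0.5)
  expect_equal(vs$response, vm$response, tolerance = 1e-12)
  one <- multiscale_vesselness(vol, 1, tau = 0.5)
  ev <- hessian_eigenvalues(vol, 1)
  expect_identical(one$response, jerman_response(ev, 0.5))
})

test_that("axis-aligned 90-degree rotation permutes the response exactly", {
  vol <- make_tube_volume(n = 21)
  vm <- multiscale_vesselness(vol, c(0.75, 1), tau = 0.5)
  rot <- image_volume(aperm(vol$data, c(2, 1, 3)), vol$spacing, vol$origin)
  vr <- multiscale_vesselness(rot, c(0.75, 1), tau = 0.5)
  expect_equal(vr$response, aperm(vm$response, c(2, 1, 3)),
               tolerance = 1e-12)
})

test_that("tube response dominates plate and background responses", {
  n <- 33; sp <- 0.5
  f <- array(0, c(n, n, n))
  ctr <- 17
  # tube along x in the lower half
  for (j in seq_len(n)) for (k in seq_len(n)) {
    d2 <- ((j - 9) * sp)^2 + ((k - ctr) * sp)^2
    f[, j, k] <- f[, j, k] + 200 * exp(-d2 / (2 * 0.25))
  }
  # finite plate (thin slab) in the upper half
  f[9:25, 25, 9:25] <- f[9:25, 25, 9:25] + 200
  vol <- image_volume(f, spacing = rep(sp, 3))
  vm <- multiscale_vesselness(vol, c(0.5, 0.75, 1), tau = 0.5)
  tube_mean <- mean(vm$response[, 9, ctr])
  plate_mean <- mean(vm$response[12:22, 25, 12:22])
  bg_mean <- mean(vm$response[, 2, 2])
  expect_gt(tube_mean, plate_mean)
  expect_gte(plate_mean, bg_mean)
  expect_gt(tube_mean, 0.5)
})

test_that("full multiscale pipeline matches the dense oracle on a small volume", {
  set.seed(5)
  vol <- image_volume(array(rnorm(8^3), c(8, 8, 8)),
                      spacing = c(1, 1.2, 0.8))
  got <- multiscale_vesselness(vol, c(0.8, 1.1), tau = 0.6)$response
  want <- oracle_vesselness(vol, c(0.8, 1.1), tau = 0.6)
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("tube centerline response peaks on-axis at a scale near the radius", {
  vol <- make_tube_volume(n = 41, radius_mm = 1)
  scales <- c(0.5, 0.75, 1, 1.5, 2)
  per_scale <- sapply(scales, function(s) {
    ev <- hessian_eigenvalues(vol, s)
    jerman_response(ev, 0.5)[21, 21, 21]
  })
  vm <- multiscale_vesselness(vol, scales, tau = 0.5)
  expect_gt(vm$response[21, 21, 21], 0.5)
  off <- vm$response[, 21 + 6 / 0.5 * 1, ][, 21]  # 6 mm off axis (3+ radii)
  expect_true(all(vm$response[21, 21, 21] > off))
  best <- scales[which.max(per_scale)]
  expect_gte(best, 0.5)
  expect_lte(best, 2)
})
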