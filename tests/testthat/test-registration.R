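lm_matrix <- function() as.matrix(place_landmarks()[, c("x", "y", "z")])

test_that("identity and planted similarity transforms are recovered exactly", {
  X <- lm_matrix()
  id <- estimate_similarity(X, X)
  expect_equal(id$scale, 1, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(id$rms_mm, 1e-12)

  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Y <- 1.2 * X %*% t(R) + matrix(c(5, -3, 2), nrow(X), 3, byrow = TRUE)
  xf <- estimate_similarity(X, Y)
  expect_equal(xf$scale, 1.2, tolerance = 1e-9)
  expect_equal(xf$rotation, R, tolerance = 1e-9)
  expect_equal(xf$translation, c(5, -3, 2), tolerance = 1e-9)
  expect_lt(xf$rms_mm, 1e-9)
})

test_that("noisy targets give an rms near the noise level", {
  X <- lm_matrix()
  th <- 0.4
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  rms <- vapply(1:20, function(s) {
    set.seed(s)
    Y <- 0.9 * X %*% t(R) + matrix(c(1, 2, 3), nrow(X), 3, byrow = TRUE) +
      matrix(rnorm(length(X), 0, 0.5), ncol = 3)
    estimate_similarity(X, Y)$rms_mm
  }, numeric(1))
  expect_true(all(rms > 0.3 & rms < 0.7))
})

test_that("scale is recovered exactly across 100 seeded random transforms", {
  X <- lm_matrix()
  for (s in 1:100) {
    set.seed(s)
    sc <- exp(rnorm(1, 0, 0.3))
    R <- random_rotation()
    t <- rnorm(3, 0, 20)
    Y <- sc * X %*% t(R) + matrix(t, nrow(X), 3, byrow = TRUE)
    xf <- estimate_similarity(X, Y)
    expect_equal(xf$scale, sc, tolerance = 1e-9)
    expect_lt(max(abs(xf$rotation - R)), 1e-9)
    expect_lt(xf$rms_mm, 1e-9)
  }
})

test_that("the residual is invariant under a joint rigid pre-transform", {
  X <- lm_matrix()
  set.seed(77)
  Y <- X + matrix(rnorm(length(X), 0, 1), ncol = 3)
  base <- estimate_similarity(X, Y)$rms_mm
  Q <- random_rotation()
  t0 <- c(-3, 8, 12)
  Xp <- X %*% t(Q) + matrix(t0, nrow(X), 3, byrow = TRUE)
  Yp <- Y %*% t(Q) + matrix(t0, nrow(X), 3, byrow = TRUE)
  expect_equal(estimate_similarity(Xp, Yp)$rms_mm, base, tolerance = 1e-9)
})

test_that("degenerate sources are refused", {
  line <- cbind(1:68, 2 * (1:68), 3 * (1:68))
  expect_error(estimate_similarity(line, line),
               class = "arterymap_degeneracy_error")
  pt <- matrix(1, 68, 3)
  expect_error(estimate_similarity(pt, pt),
               class = "arterymap_degeneracy_error")
})

test_that("the similarity fit agrees with an independent procrustes solution", {
  X <- lm_matrix()
  set.seed(5)
  Y <- 1.1 * X %*% t(random_rotation()) +
    matrix(rnorm(length(X), 0, 0.8), ncol = 3) + 10
  xf <- estimate_similarity(X, Y)
  pr <- vegan::procrustes(Y, X, scale = TRUE, symmetric = FALSE)
  fitted_mine <- xf$scale * X %*% t(xf$rotation) +
    matrix(xf$translation, nrow(X), 3, byrow = TRUE)
  expect_equal(sum((fitted_mine - Y)^2), pr$ss, tolerance = 1e-9)
  expect_equal(xf$scale, pr$scale, tolerance = 1e-9)
})

test_that("apply_transform maps geometry consistently", {
  X <- lm_matrix()
  xf <- structure(list(scale = 1.5, rotation = random_rotation(),
                       translation = c(1, 2, 3)),
                  class = "similarity_transform")
  idxf <- structure(list(scale = 1, rotation = diag(3),
                         translation = c(0, 0, 0)),
                    class = "similarity_transform")
  expect_equal(apply_transform(X, idxf), X, ignore_attr = TRUE)
  # group inverse returns original points
  back <- apply_transform(apply_transform(X, xf), invert_similarity(xf))
  expect_equal(back, X, tolerance = 1e-9, ignore_attr = TRUE)
  # pairwise distances scale exactly by s
  Y <- apply_transform(X, xf)
  d0 <- as.matrix(dist(X)); d1 <- as.matrix(dist(Y))
  expect_equal(d1, 1.5 * d0, tolerance = 1e-9)
  # polyline and mesh methods preserve structure
  poly <- centerline_polyline(X[1:5, ], radius_mm = rep(1, 5), label = "Fa_left")
  tp <- apply_transform(poly, xf)
  expect_identical(tp$label, "Fa_left")
  expect_equal(tp$radius_mm, rep(1.5, 5))
})

test_that("pinhole projection follows the formulas and guards depth", {
  cam <- camera_model(1000, 1000, 500, 500)
  expect_equal(project_points(rbind(c(0, 0, 123)), cam)[1, ], c(500, 500))
  expect_equal(project_points(rbind(c(10, 0, 100)), cam)[1, 1], 600)
  cam2 <- camera_model(800, 1200, 320, 240)
  uv <- project_points(rbind(c(5, -2, 50)), cam2)
  expect_equal(uv[1, ], c(800 * 0.1 + 320, 1200 * -0.04 + 240))
  expect_error(project_points(rbind(c(0, 0, 0)), cam),
               class = "arterymap_projection_error")
  expect_error(project_points(rbind(c(0, 0, 5), c(0, 0, -1)), cam),
               class = "arterymap_projection_error")
  expect_error(camera_model(-1, 1, 0, 0), class = "arterymap_argument_error")
})

test_that("pose is recovered from noise-free synthetic views", {
  X <- lm_matrix()
  cam <- default_camera()
  uv <- project_points(X, cam)
  reg <- register_model_to_view(X, uv,
                                camera_model(cam$fx, cam$fy, cam$cx, cam$cy))
  expect_lt(reg$mean_reprojection_px, 1e-6)
  expect_equal(reg$camera$rotation, cam$rotation, tolerance = 1e-6)
  expect_equal(reg$camera$translation, cam$translation, tolerance = 1e-4)
})

test_that("1 px landmark noise yields a commensurate reprojection error", {
  X <- lm_matrix()
  cam <- default_camera()
  uv <- project_points(X, cam)
  errs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    reg <- register_model_to_view(
      X, uv + matrix(rnorm(length(uv), 0, 1), ncol = 2),
      camera_model(cam$fx, cam$fy, cam$cx, cam$cy))
    reg$mean_reprojection_px
  }, numeric(1))
  expect_true(all(errs > 0.5 & errs < 2))
})

test_that("projected model landmarks coincide with the view landmarks up to the residual", {
  X <- lm_matrix()
  cam <- default_camera()
  set.seed(31)
  uv <- project_points(X, cam) + matrix(rnorm(136, 0, 0.5), ncol = 2)
  reg <- register_model_to_view(X, uv,
                                camera_model(cam$fx, cam$fy, cam$cx, cam$cy))
  per_pt <- sqrt(rowSums((reg$landmarks2d - uv)^2))
  expect_lte(sqrt(mean(per_pt^2)), reg$mean_reprojection_px + 1e-9)
})

test_that("landmark files round-trip through CSV and JSON", {
  lm <- place_landmarks()
  for (ext in c(".csv", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_landmarks(lm, p)
    back <- read_landmarks(p)
    expect_equal(as.matrix(back[, c("x", "y", "z")]),
                 as.matrix(lm[, c("x", "y", "z")]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  cam <- default_camera()
  p <- withr::local_tempfile(fileext = ".json")
  write_camera(cam, p)
  cam2 <- read_camera(p)
  expect_equal(cam2$rotation, cam$rotation, tolerance = 1e-12)
  expect_equal(cam2$translation, cam$translation, tolerance = 1e-12)
})
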