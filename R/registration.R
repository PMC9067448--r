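#' Least-squares similarity transform between landmark sets
#'
#' Closed-form (Umeyama) fit of scale, proper rotation and translation
#' minimizing \eqn{\sum_i \| s R x_i + t - y_i \|^2}: centroid alignment,
#' SVD of the cross-covariance with a reflection guard (the smallest
#' singular axis is flipped if the raw solution is a reflection), scale from
#' the variance ratio.
#'
#' @param source,target Point sets (n x 3 matrices or tibbles with
#'   `x`,`y`,`z`), same row correspondence, n >= 3.
#' @return An object of class `similarity_transform`: `scale`, `rotation`
#'   (3 x 3, det +1), `translation` (mm) and `rms_mm`, the root-mean-square
#'   per-coordinate residual in mm (for isotropic Gaussian landmark noise of
#'   SD sigma this converges to sigma).
#' @export
estimate_similarity <- function(source, target) {
  X <- as_landmark_matrix(source)
  Y <- as_landmark_matrix(target)
  if (nrow(X) != nrow(Y) || nrow(X) < 3) {
    am_stop("source and target need the same number (>= 3) of points",
            "arterymap_argument_error")
  }
  n <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  var_x <- sum(Xc^2) / n
  sv_src <- svd(Xc)
  if (sv_src$d[2] < 1e-9 * max(sv_src$d[1], 1)) {
    am_stop("source points are collinear or coincident; similarity fit is degenerate",
            "arterymap_degeneracy_error")
  }
  C <- crossprod(Yc, Xc) / n
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  S <- diag(c(1, 1, d))
  R <- sv$u %*% S %*% t(sv$v)
  s <- sum(sv$d * c(1, 1, d)) / var_x
  t <- my - s * as.vector(R %*% mx)
  xf <- structure(list(scale = s, rotation = R, translation = t),
                  class = "similarity_transform")
  res <- transform_points(xf, X) - Y
  xf$rms_mm <- sqrt(mean(res^2))
  xf
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat("<similarity_transform> scale ", signif(x$scale, 6), ", translation (",
      paste(signif(x$translation, 5), collapse = ", "), ") mm",
      if (!is.null(x$rms_mm)) paste0(", rms ", signif(x$rms_mm, 4), " mm"),
      "\n", sep = "")
  invisible(x)
}

#' Invert a similarity transform
#' @param xf A `similarity_transform`.
#' @export
invert_similarity <- function(xf) {
  Ri <- t(xf$rotation)
  si <- 1 / xf$scale
  structure(list(scale = si, rotation = Ri,
                 translation = -si * as.vector(Ri %*% xf$translation)),
            class = "similarity_transform")
}

transform_points <- function(xf, p) {
  p <- matrix(as.numeric(p), ncol = 3)
  xf$scale * p %*% t(xf$rotation) +
    matrix(xf$translation, nrow(p), 3, byrow = TRUE)
}

#' Apply a similarity transform to geometry
#'
#' Maps every point by \eqn{s R x + t}; topology and attributes are
#' unchanged. Methods exist for point matrices, landmark tibbles,
#' [surface_mesh()] and [centerline_polyline()] (and lists thereof).
#'
#' @param geometry The object to transform.
#' @param xf A `similarity_transform` from [estimate_similarity()].
#' @return Object of the same type.
#' @export
apply_transform <- function(geometry, xf) UseMethod("apply_transform")

#' @export
apply_transform.matrix <- function(geometry, xf) transform_points(xf, geometry)

#' @export
apply_transform.data.frame <- function(geometry, xf) {
  p <- transform_points(xf, as.matrix(geometry[c("x", "y", "z")]))
  geometry$x <- p[, 1]; geometry$y <- p[, 2]; geometry$z <- p[, 3]
  geometry
}

#' @export
apply_transform.surface_mesh <- function(geometry, xf) {
  geometry$vertices <- transform_points(xf, geometry$vertices)
  geometry
}

#' @export
apply_transform.centerline_polyline <- function(geometry, xf) {
  geometry$points <- transform_points(xf, geometry$points)
  if (!is.null(geometry$radius_mm)) {
    geometry$radius_mm <- geometry$radius_mm * xf$scale
  }
  geometry
}

#' @export
apply_transform.list <- function(geometry, xf) {
  lapply(geometry, apply_transform, xf = xf)
}

#' Pinhole camera model
#'
#' Intrinsics in pixels plus the world-to-camera rigid pose
#' (`x_cam = R x_world + t`).
#'
#' @param fx,fy Focal lengths (px), > 0.
#' @param cx,cy Principal point (px).
#' @param rotation 3 x 3 world-to-camera rotation.
#' @param translation Length-3 world-to-camera translation (mm).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy, rotation = diag(3),
                         translation = c(0, 0, 0)) {
  if (fx <= 0 || fy <= 0) {
    am_stop("focal lengths must be positive", "arterymap_argument_error")
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 rotation = matrix(as.numeric(rotation), 3, 3),
                 translation = as.numeric(translation)),
            class = "camera_model")
}

#' Project 3-D points through a pinhole camera
#'
#' `u = fx X/Z + cx`, `v = fy Y/Z + cy` after the world-to-camera pose.
#' Every point must be strictly in front of the camera.
#'
#' @param points n x 3 matrix of world points (mm).
#' @param camera A [camera_model()].
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(points, camera) {
  stopifnot(inherits(camera, "camera_model"))
  p <- matrix(as.numeric(points), ncol = 3)
  pc <- p %*% t(camera$rotation) +
    matrix(camera$translation, nrow(p), 3, byrow = TRUE)
  bad <- which(pc[, 3] <= 0)
  if (length(bad) > 0) {
    am_stop(sprintf("points at or behind the camera plane: indices %s",
                    paste(utils::head(bad, 10), collapse = ", ")),
            "arterymap_projection_error")
  }
  cbind(camera$fx * pc[, 1] / pc[, 3] + camera$cx,
        camera$fy * pc[, 2] / pc[, 3] + camera$cy)
}

rotation_from_rvec <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew3(w))
  k <- w / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

skew3 <- function(w) {
  matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
}

#' Register the arterial model into a camera view
#'
#' Estimates the world-to-camera pose that minimizes the 2-D reprojection
#' error of the 68 landmarks (Gauss-Newton with a deterministic initial pose
#' from back-projecting the 2-D landmarks at a nominal depth and fitting a
#' similarity transform), then projects the arterial geometry into the view.
#'
#' @param model_landmarks3d 68 x 3 landmark matrix/tibble (mm, model space).
#' @param view_landmarks2d 68 x 2 matrix/tibble (px, camera view), same
#'   indexing scheme.
#' @param camera A [camera_model()]; its intrinsics are used, its pose is
#'   re-estimated.
#' @param arterial_geometry Optional list of [centerline_polyline()] (or a
#'   [surface_mesh()]) in model space to project.
#' @param init_depth_mm Nominal depth for the deterministic initialization.
#' @param max_iterations,step_tolerance Gauss-Newton controls.
#' @return An object of class `ar_registration`: the fitted `camera_model`,
#'   `mean_reprojection_px`, projected `landmarks2d`, and `overlay` -- a
#'   tibble (label, curve, u, v) of projected artery curves (empty when no
#'   geometry is given).
#' @export
register_model_to_view <- function(model_landmarks3d, view_landmarks2d,
                                   camera, arterial_geometry = NULL,
                                   init_depth_mm = 500,
                                   max_iterations = 100L,
                                   step_tolerance = 1e-10) {
  X <- check_landmark_count(as_landmark_matrix(model_landmarks3d))
  UV <- as_landmark_matrix(view_landmarks2d, d = 2L)
  if (nrow(UV) != 68L) {
    am_stop("expected 68 view landmarks", "arterymap_argument_error")
  }
  stopifnot(inherits(camera, "camera_model"))
  # deterministic init: back-project at nominal depth, similarity fit
  P0 <- cbind((UV[, 1] - camera$cx) / camera$fx * init_depth_mm,
              (UV[, 2] - camera$cy) / camera$fy * init_depth_mm,
              init_depth_mm)
  init <- estimate_similarity(X, P0)
  R <- init$rotation
  tr <- init$translation  # rigid init: keep R and t, drop the fitted scale
  cost <- function(R, tr) {
    pc <- X %*% t(R) + matrix(tr, 68, 3, byrow = TRUE)
    if (any(pc[, 3] <= 1e-9)) return(list(r = NULL, c = Inf))
    uv <- cbind(camera$fx * pc[, 1] / pc[, 3] + camera$cx,
                camera$fy * pc[, 2] / pc[, 3] + camera$cy)
    r <- as.vector(uv - UV)
    list(r = r, c = sum(r^2))
  }
  cur <- cost(R, tr)
  if (!is.finite(cur$c)) {
    # fall back: push the model in front of the camera along +z
    tr <- c(0, 0, init_depth_mm) - as.vector(R %*% colMeans(X))
    cur <- cost(R, tr)
  }
  lambda <- 0
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    # numeric Jacobian of residuals wrt (rotation increment, translation)
    J <- matrix(0, 136, 6)
    h <- 1e-6
    for (k in 1:6) {
      dp <- rep(0, 6); dp[k] <- h
      dm <- -dp
      Rp <- rotation_from_rvec(dp[1:3]) %*% R
      Rm <- rotation_from_rvec(dm[1:3]) %*% R
      cp <- cost(Rp, tr + dp[4:6])
      cm <- cost(Rm, tr + dm[4:6])
      if (is.null(cp$r) || is.null(cm$r)) next
      J[, k] <- (cp$r - cm$r) / (2 * h)
    }
    g <- crossprod(J, cur$r)
    H <- crossprod(J)
    step <- tryCatch(solve(H + lambda * diag(6), -g),
                     error = function(e) NULL)
    if (is.null(step)) { lambda <- max(lambda * 10, 1e-6); next }
    Rn <- rotation_from_rvec(step[1:3]) %*% R
    trn <- tr + step[4:6]
    nxt <- cost(Rn, trn)
    step_norm <- sqrt(sum(step^2))
    if (nxt$c <= cur$c) {
      R <- Rn; tr <- trn; cur <- nxt
      lambda <- lambda / 10
      if (step_norm < step_tolerance) { converged <- TRUE; break }
    } else {
      # a tiny proposal that cannot improve the fit means stationarity
      if (step_norm < step_tolerance) { converged <- TRUE; break }
      lambda <- max(lambda * 10, 1e-6)
      if (lambda > 1e12) break
    }
  }
  mean_err <- sqrt(mean(matrix(cur$r^2, ncol = 2) |> rowSums()))
  if (!converged) {
    am_stop(sprintf("pose estimation did not converge in %d iterations (last mean reprojection %.4g px)",
                    max_iterations, mean_err),
            "arterymap_convergence_error")
  }
  fitted_cam <- camera_model(camera$fx, camera$fy, camera$cx, camera$cy,
                             rotation = R, translation = tr)
  overlay <- tibble::tibble(label = character(), curve = integer(),
                            u = numeric(), v = numeric())
  if (!is.null(arterial_geometry)) {
    geoms <- if (inherits(arterial_geometry, "centerline_polyline") ||
                 inherits(arterial_geometry, "surface_mesh")) {
      list(arterial_geometry)
    } else arterial_geometry
    rowsl <- purrr::imap(geoms, function(gm, i) {
      pts <- if (inherits(gm, "surface_mesh")) gm$vertices else gm$points
      uv <- project_points(pts, fitted_cam)
      tibble::tibble(label = if (!is.null(gm$label)) gm$label else "unclassified",
                     curve = i, u = uv[, 1], v = uv[, 2])
    })
    overlay <- dplyr::bind_rows(rowsl)
  }
  structure(list(camera = fitted_cam,
                 mean_reprojection_px = mean_err,
                 landmarks2d = project_points(X, fitted_cam),
                 overlay = overlay,
                 iterations = it,
                 converged = converged || mean_err <= 1e-6),
            class = "ar_registration")
}

#' @export
print.ar_registration <- function(x, ...) {
  cat("<ar_registration> mean reprojection error ",
      signif(x$mean_reprojection_px, 4), " px over 68 landmarks; ",
      nrow(x$overlay), " projected curve points\n", sep = "")
  invisible(x)
}

#' Read landmarks from CSV or JSON
#'
#' CSV columns `index,x,y[,z]`; JSON as written by [write_landmarks()].
#'
#' @param path File path.
#' @return Tibble with `index`, `x`, `y` and optionally `z`, sorted by index.
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
  }
  if (!all(c("index", "x", "y") %in% names(df))) {
    am_stop(sprintf("%s: landmark file needs columns index,x,y[,z]", path),
            "arterymap_format_error")
  }
  dplyr::arrange(tibble::as_tibble(df), .data$index)
}

#' Write landmarks to CSV or JSON
#' @param landmarks Tibble with `index`, `x`, `y` and optionally `z`.
#' @param path Output path; format chosen by extension.
#' @export
write_landmarks <- function(landmarks, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(landmarks, path, digits = NA)
  } else {
    readr::write_csv(landmarks, path)
  }
  invisible(path)
}

#' Read / write a camera model as JSON
#' @param path JSON file with fields fx, fy, cx, cy, rotation (3x3),
#'   translation (length 3).
#' @export
read_camera <- function(path) {
  j <- jsonlite::fromJSON(path)
  rot <- if (is.matrix(j$rotation)) j$rotation else
    matrix(unlist(j$rotation), 3, 3, byrow = TRUE)
  camera_model(j$fx, j$fy, j$cx, j$cy, rotation = rot,
               translation = unlist(j$translation))
}

#' @rdname read_camera
#' @param camera A [camera_model()].
#' @export
write_camera <- function(camera, path) {
  jsonlite::write_json(
    list(fx = camera$fx, fy = camera$fy, cx = camera$cx, cy = camera$cy,
         rotation = apply(camera$rotation, 1, identity, simplify = FALSE),
         translation = camera$translation),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
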