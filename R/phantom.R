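#' Specification of a synthetic TOF-MRA head phantom
#'
#' Defines a head-shaped (ellipsoid) bright object on dark background with
#' planted tubular arteries of Gaussian cross-section (sigma = radius / 2,
#' emulating partial-volume blur of bright-blood contrast), plus seeded
#' noise. The defaults -- a 160^3 grid at 0.5 mm isotropic spacing,
#' background 100, vessel peak 200, Gaussian noise at 5% of peak -- are the
#' package's standing study conditions for synthetic experiments.
#'
#' @param shape Grid dimensions (3 integers).
#' @param spacing_mm Voxel spacing (mm).
#' @param head_semiaxes_mm Ellipsoid semi-axes (mm); the head is centred at
#'   the world origin.
#' @param vessels List of vessel specs: each a list with `label`
#'   (`"<artery>_<side>"` or other), `points` (control points, mm, n x 3),
#'   `radius_mm` (> 0) and optionally `peak` (intensity above background).
#' @param background Head tissue intensity.
#' @param peak Default vessel peak intensity (added to background).
#' @param noise_sigma Noise standard deviation (intensity units); 0 disables.
#' @param noise_model `"gaussian"` or `"rician"` (magnitude of complex
#'   Gaussian, the distribution of TOF magnitude data).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160, 160, 160),
                         spacing_mm = c(0.5, 0.5, 0.5),
                         head_semiaxes_mm = c(32, 36, 38),
                         vessels = list(),
                         background = 100,
                         peak = 200,
                         noise_sigma = 10,
                         noise_model = c("gaussian", "rician"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(head_semiaxes_mm) == 3L, all(head_semiaxes_mm > 0))
  for (vs in vessels) {
    if (is.null(vs$radius_mm) || vs$radius_mm <= 0) {
      am_stop("every vessel needs a positive radius", "arterymap_argument_error")
    }
  }
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 head_semiaxes_mm = as.numeric(head_semiaxes_mm),
                 vessels = vessels, background = background, peak = peak,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# cumulative-chord-length cubic-spline resampling of a control polygon
resample_path <- function(points, step_mm) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) == 1) return(points)
  tknot <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  tt <- seq(0, tknot[length(tknot)], by = step_mm)
  if (tail(tt, 1) < tknot[length(tknot)]) tt <- c(tt, tknot[length(tknot)])
  if (nrow(points) == 2) {
    f <- tt / tknot[2]
    return(cbind(points[1, 1] + f * diff(points[, 1]),
                 points[1, 2] + f * diff(points[, 2]),
                 points[1, 3] + f * diff(points[, 3])))
  }
  cbind(stats::spline(tknot, points[, 1], xout = tt)$y,
        stats::spline(tknot, points[, 2], xout = tt)$y,
        stats::spline(tknot, points[, 3], xout = tt)$y)
}

ellipsoid_norm <- function(p, semiaxes) {
  p <- matrix(as.numeric(p), ncol = 3)
  sqrt((p[, 1] / semiaxes[1])^2 + (p[, 2] / semiaxes[2])^2 +
         (p[, 3] / semiaxes[3])^2)
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Voxel intensity is `background * head + sum_v peak_v *
#' exp(-d^2 / (2 (r/2)^2))` with `d` the distance to the vessel centerline,
#' plus seeded noise. The returned truth carries the planted centerlines,
#' radii, the skin surface mesh, the 68 surface landmarks and the head
#' geometry, exactly as planted. Identical seeds give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (an [image_volume()]) and `truth` (list:
#'   `centerlines`, `landmarks3d`, `skin_mesh`, `head`, `spec`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$spacing_mm
  origin <- -(d - 1) / 2 * sp
  ax <- origin[1] + (seq_len(d[1]) - 1) * sp[1]
  ay <- origin[2] + (seq_len(d[2]) - 1) * sp[2]
  az <- origin[3] + (seq_len(d[3]) - 1) * sp[3]
  sa <- spec$head_semiaxes_mm
  ex2 <- (ax / sa[1])^2
  ey2 <- (ay / sa[2])^2
  ez2 <- (az / sa[3])^2
  head_ind <- outer(outer(ex2, ey2, `+`), ez2, `+`) <= 1
  vol <- spec$background * head_ind
  centerlines <- list()
  for (vs in spec$vessels) {
    dense <- resample_path(vs$points, min(sp) / 2)
    if (any(ellipsoid_norm(dense, sa) > 1)) {
      am_stop(sprintf("vessel '%s' leaves the head", vs$label %||% "unnamed"),
              "arterymap_geometry_error")
    }
    peak <- vs$peak %||% spec$peak
    sigma <- vs$radius_mm / 2
    reach <- 4 * sigma
    dist2 <- array(Inf, d)
    nseg <- nrow(dense) - 1
    for (si in seq_len(nseg)) {
      a <- dense[si, ]; b <- dense[si + 1, ]
      lo <- pmin(a, b) - reach; hi <- pmax(a, b) + reach
      i1 <- pmax(1L, ceiling((lo - origin) / sp) + 1L)
      i2 <- pmin(d, floor((hi - origin) / sp) + 1L)
      if (any(i1 > i2)) next
      xs <- ax[i1[1]:i2[1]]; ys <- ay[i1[2]:i2[2]]; zs <- az[i1[3]:i2[3]]
      nx <- length(xs); ny <- length(ys); nz <- length(zs)
      px <- array(xs, c(nx, ny, nz))
      py <- aperm(array(ys, c(ny, nx, nz)), c(2, 1, 3))
      pz <- aperm(array(zs, c(nz, ny, nx)), c(3, 2, 1))
      v <- b - a
      len2 <- sum(v^2)
      tpar <- ((px - a[1]) * v[1] + (py - a[2]) * v[2] + (pz - a[3]) * v[3]) /
        max(len2, .Machine$double.xmin)
      tpar <- pmin(pmax(tpar, 0), 1)
      dd <- (px - a[1] - tpar * v[1])^2 + (py - a[2] - tpar * v[2])^2 +
        (pz - a[3] - tpar * v[3])^2
      blk <- dist2[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]]
      dist2[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] <- pmin(blk, dd)
    }
    sel <- which(dist2 < reach^2)
    vol[sel] <- vol[sel] + peak * exp(-dist2[sel] / (2 * sigma^2))
    centerlines[[length(centerlines) + 1L]] <-
      centerline_polyline(dense,
                          radius_mm = rep(vs$radius_mm, nrow(dense)),
                          label = vs$label %||% "unclassified")
  }
  if (spec$noise_sigma > 0) {
    vol <- with_preserved_rng(spec$seed, {
      n <- length(vol)
      if (spec$noise_model == "gaussian") {
        vol + array(stats::rnorm(n, 0, spec$noise_sigma), d)
      } else {
        sqrt((vol + array(stats::rnorm(n, 0, spec$noise_sigma), d))^2 +
               array(stats::rnorm(n, 0, spec$noise_sigma), d)^2)
      }
    })
  }
  volume <- image_volume(vol, spacing = sp, origin = origin)
  landmarks3d <- place_landmarks(head_center = c(0, 0, 0), semiaxes = sa)
  truth <- list(centerlines = centerlines,
                landmarks3d = landmarks3d,
                skin_mesh = ellipsoid_mesh(c(0, 0, 0), sa),
                head = list(center = c(0, 0, 0), semiaxes = sa),
                spec = spec)
  list(volume = volume, truth = truth)
}

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# fixed parametric surface positions of the 68-point scheme:
# azimuth (deg, 0 = anterior midline, positive towards subject right) and
# elevation (deg); bilateral pairs mirror exactly in azimuth.
landmark_angles <- function() {
  jaw_a <- seq(80, -80, by = -10)
  jaw <- cbind(jaw_a, -20 - 35 * cos(jaw_a * pi / 180))
  brow_r <- cbind(c(45, 35, 25, 15, 8), 25)
  brow_l <- cbind(-c(8, 15, 25, 35, 45), 25)
  bridge <- cbind(0, c(20, 12, 4, -2))
  nose_low <- cbind(c(12, 6, 0, -6, -12), -8)
  eye_r <- cbind(c(33, 28.5, 21.5, 17, 21.5, 28.5), c(12, 15, 15, 12, 9, 9))
  eye_l <- cbind(-c(17, 21.5, 28.5, 33, 28.5, 21.5), c(12, 15, 15, 12, 9, 9))
  mouth_o <- cbind(c(14, 10, 5, 0, -5, -10, -14, -10, -5, 0, 5, 10),
                   c(-35, -31, -29.5, -29, -29.5, -31, -35, -39, -40.5, -41,
                     -40.5, -39))
  mouth_i <- cbind(c(10, 5, 0, -5, -10, -5, 0, 5),
                   c(-35, -33.5, -33, -33.5, -35, -36.5, -37, -36.5))
  rbind(jaw, brow_r, brow_l, bridge, nose_low, eye_r, eye_l, mouth_o, mouth_i)
}

#' Place the 68 landmarks on an ellipsoid head surface
#'
#' Landmarks sit at fixed parametric surface positions (azimuth/elevation
#' constants of the scheme); bilateral pairs mirror exactly across the
#' midsagittal plane, and scaling the head scales all pairwise distances by
#' the same factor.
#'
#' @param head_center World position of the head centre (mm).
#' @param semiaxes Ellipsoid semi-axes (mm).
#' @return Tibble (index, x, y, z) of 68 landmarks in mm.
#' @export
place_landmarks <- function(head_center = c(0, 0, 0),
                            semiaxes = c(32, 36, 38)) {
  ang <- landmark_angles() * pi / 180
  a <- ang[, 1]; e <- ang[, 2]
  dir <- cbind(cos(e) * sin(a), cos(e) * cos(a), sin(e))
  pts <- sweep(dir, 2, semiaxes, `*`) +
    matrix(head_center, nrow(dir), 3, byrow = TRUE)
  tibble::tibble(index = seq_len(68), x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

# closed UV triangulation of an ellipsoid (used as the phantom skin mesh)
ellipsoid_mesh <- function(center, semiaxes, n_lat = 24L, n_lon = 48L) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2)[2:(n_lat + 1)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  grid <- expand.grid(lat = lat, lon = lon)
  ring <- cbind(cos(grid$lat) * sin(grid$lon), cos(grid$lat) * cos(grid$lon),
                sin(grid$lat))
  poles <- rbind(c(0, 0, -1), c(0, 0, 1))
  verts <- sweep(rbind(ring, poles), 2, semiaxes, `*`) +
    matrix(center, nrow(ring) + 2, 3, byrow = TRUE)
  vid <- function(i, j) (((j - 1) %% n_lon)) * n_lat + i  # lat i, lon j
  faces <- NULL
  for (j in seq_len(n_lon)) {
    for (i in seq_len(n_lat - 1)) {
      faces <- rbind(faces,
                     c(vid(i, j), vid(i, j + 1), vid(i + 1, j)),
                     c(vid(i + 1, j), vid(i, j + 1), vid(i + 1, j + 1)))
    }
    s <- nrow(ring) + 1  # south pole
    n <- nrow(ring) + 2  # north pole
    faces <- rbind(faces,
                   c(s, vid(1, j + 1), vid(1, j)),
                   c(n, vid(n_lat, j), vid(n_lat, j + 1)))
  }
  surface_mesh(verts, faces)
}

#' Default arterial vessel set for the phantom
#'
#' Builds short vessel arcs centred on the landmark-anchored artery regions
#' of the phantom's own landmark set, sunk to a fixed depth fraction below
#' the skin so they lie inside the subcutaneous band and are labelable by
#' the region atlas.
#'
#' @param semiaxes Head semi-axes (mm).
#' @param arteries Character vector of arteries to plant (per side).
#' @param sides Sides to plant.
#' @param radius_mm Vessel radius (mm).
#' @param depth_fraction Radial position of the vessel (fraction of the
#'   ellipsoid surface; 0.93 is a few mm under the skin).
#' @return List of vessel specs for [phantom_spec()].
#' @export
default_phantom_vessels <- function(semiaxes = c(32, 36, 38),
                                    arteries = c("Fa", "Ang", "STr", "ST"),
                                    sides = c("left", "right"),
                                    radius_mm = 1,
                                    depth_fraction = 0.90) {
  lms <- place_landmarks(c(0, 0, 0), semiaxes)
  atlas <- build_region_atlas(lms)
  up <- c(0, 0, 1)
  vessels <- list()
  for (sd in sides) {
    for (art in arteries) {
      rg <- atlas[atlas$artery == art & atlas$side == sd, ]
      ctr <- c(rg$cx, rg$cy, rg$cz)
      span <- 0.6 * rg$radius_mm
      raw <- rbind(ctr - span * up, ctr, ctr + span * up)
      sunk <- raw / ellipsoid_norm(raw, semiaxes) * depth_fraction
      vessels[[length(vessels) + 1L]] <-
        list(label = paste(art, sd, sep = "_"), points = sunk,
             radius_mm = radius_mm)
    }
  }
  vessels
}

#' Spec of the single straight-tube phantom
#'
#' One axis-aligned tube of radius 1 mm on a 0.5 mm grid, running parallel
#' to the x axis at subcutaneous depth (8 mm below the lowest skin point, so
#' the whole tube lies inside the default subcutaneous band) -- the
#' canonical recovery benchmark for the
#' vesselness-segmentation-skeletonization chain.
#'
#' @param noise_sigma Noise SD (0 = noise-free).
#' @param shape,spacing_mm Grid geometry.
#' @param depth_mm Tube depth below the skin at its midpoint (mm).
#' @param half_length_mm Tube half-length (mm).
#' @param seed Seed for the noise.
#' @return A [phantom_spec()].
#' @export
single_tube_spec <- function(noise_sigma = 0, shape = c(160, 160, 160),
                             spacing_mm = c(0.5, 0.5, 0.5), depth_mm = 12,
                             half_length_mm = 15, seed = 1L) {
  semi <- (shape - 1) / 2 * spacing_mm * 0.9
  z0 <- -(semi[3] - depth_mm)
  phantom_spec(shape = shape, spacing_mm = spacing_mm,
               head_semiaxes_mm = semi,
               vessels = list(list(label = "tube",
                                   points = rbind(c(-half_length_mm, 0, z0),
                                                  c(half_length_mm, 0, z0)),
                                   radius_mm = 1)),
               noise_sigma = noise_sigma, seed = seed)
}

#' Render a camera view of the phantom truth
#'
#' Projects the 68 landmarks through the camera (with optional seeded
#' Gaussian pixel noise) and the planted artery centerlines noise-free, as
#' evaluation truth.
#'
#' @param truth Phantom truth from [generate_phantom()].
#' @param camera A [camera_model()].
#' @param landmark_noise_px Pixel noise SD on the landmarks.
#' @param seed Seed for the landmark noise.
#' @return List with `landmarks2d` (tibble index, u, v) and `curves2d`
#'   (tibble label, curve, u, v).
#' @export
render_view <- function(truth, camera, landmark_noise_px = 0, seed = 1L) {
  lm <- as_landmark_matrix(truth$landmarks3d)
  uv <- project_points(lm, camera)
  if (landmark_noise_px > 0) {
    uv <- with_preserved_rng(seed, {
      uv + matrix(stats::rnorm(length(uv), 0, landmark_noise_px), ncol = 2)
    })
  }
  curves <- purrr::imap_dfr(truth$centerlines, function(cl, i) {
    p <- project_points(cl$points, camera)
    tibble::tibble(label = cl$label, curve = i, u = p[, 1], v = p[, 2])
  })
  list(landmarks2d = tibble::tibble(index = seq_len(68), u = uv[, 1],
                                    v = uv[, 2]),
       curves2d = curves)
}

#' Default camera looking at the phantom face
#'
#' Positioned `distance_mm` anterior of the head centre, optical axis
#' through the centre, image x along world right.
#'
#' @param distance_mm Camera distance from the world origin (mm).
#' @param f Focal length (px).
#' @param width,height Image size (px).
#' @return A [camera_model()].
#' @export
default_camera <- function(distance_mm = 350, f = 1400,
                           width = 1024, height = 1024) {
  zc <- c(0, -1, 0)                 # viewing direction (towards the face)
  xc <- c(1, 0, 0)
  yc <- c(0, 0, 1)
  R <- rbind(xc, yc, zc)
  C <- c(0, distance_mm, 0)
  camera_model(f, f, width / 2, height / 2, rotation = R,
               translation = -as.vector(R %*% C))
}
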