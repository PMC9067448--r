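#' The 18 artery labels
#'
#' The nine named superficial facial arteries on each side of the face:
#' facial (Fa), inferior labial (IL), superior labial (SL), angular (Ang),
#' lateral nasal (LN), dorsal nasal (DN), supratrochlear (STr), supraorbital
#' (SO) and superficial temporal (ST).
#'
#' @return Tibble with columns `artery` and `side` (18 rows, fixed order).
#' @export
artery_labels <- function() {
  tidyr::expand_grid(side = c("left", "right"), artery = artery_order()) |>
    dplyr::arrange(match(.data$side, c("left", "right")),
                   match(.data$artery, artery_order())) |>
    dplyr::select("artery", "side")
}

artery_order <- function() c("Fa", "IL", "SL", "Ang", "LN", "DN", "STr", "SO", "ST")

#' 68-point facial landmark scheme
#'
#' Fixed index-to-anatomy convention: 1-17 jawline, 18-22 right eyebrow,
#' 23-27 left eyebrow, 28-31 nasal bridge, 32-36 lower nose, 37-42 right
#' eye, 43-48 left eye, 49-60 outer lip, 61-68 inner lip. Nine landmarks are
#' midline: the nasal bridge and tip (28-31, 34) and the outer/inner lip
#' midpoints (52, 58, 63, 67).
#'
#' @return Named list of integer index vectors.
#' @export
landmark_scheme <- function() {
  list(jaw = 1:17, brow_right = 18:22, brow_left = 23:27,
       nose_bridge = 28:31, nose_lower = 32:36,
       eye_right = 37:42, eye_left = 43:48,
       mouth_outer = 49:60, mouth_inner = 61:68,
       midline = c(28:31, 34, 52, 58, 63, 67))
}

as_landmark_matrix <- function(landmarks, d = 3L) {
  if (is.data.frame(landmarks)) {
    cols <- intersect(c("x", "y", "z"), names(landmarks))[seq_len(d)]
    m <- as.matrix(landmarks[cols])
    if ("index" %in% names(landmarks)) m <- m[order(landmarks$index), , drop = FALSE]
  } else {
    m <- matrix(as.numeric(landmarks), ncol = d)
  }
  if (any(!is.finite(m))) {
    am_stop("landmark coordinates must be finite", "arterymap_argument_error")
  }
  m
}

check_landmark_count <- function(m) {
  if (nrow(m) != 68L) {
    am_stop(sprintf("expected 68 landmarks, got %d", nrow(m)),
            "arterymap_argument_error")
  }
  m
}

#' Fit the midsagittal plane of a 3-D landmark set
#'
#' Least-squares plane through the nine midline landmarks; the normal is the
#' direction of least variance, oriented towards the left-eye landmarks so
#' that positive signed distance means the subject's left.
#'
#' @param landmarks3d 68 x 3 matrix or tibble with `x`, `y`, `z`.
#' @return List with unit `normal`, a `point` on the plane, and a
#'   `reflect(points)` function.
#' @export
fit_midsagittal_plane <- function(landmarks3d) {
  m <- check_landmark_count(as_landmark_matrix(landmarks3d))
  sc <- landmark_scheme()
  mid <- m[sc$midline, , drop = FALSE]
  ctr <- colMeans(mid)
  sv <- svd(sweep(mid, 2, ctr))
  normal <- sv$v[, 3]
  left_eye <- colMeans(m[sc$eye_left, , drop = FALSE])
  if (sum((left_eye - ctr) * normal) < 0) normal <- -normal
  reflect <- function(p) {
    p <- matrix(as.numeric(p), ncol = 3)
    s <- (p - matrix(ctr, nrow(p), 3, byrow = TRUE)) %*% normal
    p - 2 * s %*% t(normal)
  }
  list(normal = normal, point = ctr, reflect = reflect)
}

#' Build the landmark-anchored artery region atlas
#'
#' Deterministic spherical regions, one per artery and side, anchored on
#' named landmarks: the facial-artery corridor between mid-jaw and mouth
#' corner, labial bands above/below the mouth, the angular/lateral-nasal
#' nose-wing flank, the nasal dorsum, the medial and central eyebrow for the
#' supratrochlear/supraorbital arteries, and a temporal box lateral to the
#' eye for the superficial temporal artery. Left regions are constructed
#' from left-side anchors; right regions are their exact mirror images
#' across the fitted midsagittal plane. All sizes scale with the outer
#' inter-ocular distance, so the construction is equivariant under rigid
#' motion and scaling.
#'
#' Region geometry (anchor recipe, relative offsets and radii) is calibration
#' data, stored in `inst/extdata/region_atlas.json`.
#'
#' @param landmarks3d 68 x 3 matrix or tibble (`index`, `x`, `y`, `z`) in mm.
#' @return An object of class `region_atlas`: a tibble (artery, side,
#'   cx, cy, cz, radius_mm) plus the midplane fit as attribute.
#' @export
build_region_atlas <- function(landmarks3d) {
  m <- check_landmark_count(as_landmark_matrix(landmarks3d))
  plane <- fit_midsagittal_plane(m)
  cfg_all <- region_atlas_config()
  cfg <- cfg_all$regions
  depth_pull <- cfg_all$depth_pull %||% 0
  face_centroid <- colMeans(m)
  face_scale <- sqrt(sum((m[37, ] - m[46, ])^2))  # outer eye-corner distance
  up <- m[28, ] - m[9, ]
  up <- up / sqrt(sum(up^2))
  down <- -up
  lat_left <- plane$normal  # unit, towards subject left
  anchors <- list(
    mid_jaw_left = m[13, ], mouth_corner_left = m[55, ],
    lip_top_mid = m[52, ], lip_bottom_mid = m[58, ],
    nose_wing_left = m[36, ], eye_inner_left = m[43, ],
    eye_outer_left = m[46, ], brow_inner_left = m[23, ],
    brow_mid_left = m[25, ], bridge_mid = (m[29, ] + m[30, ]) / 2,
    nose_tip = m[34, ]
  )
  dirs <- list(up = up, down = down, lat = lat_left)
  rows <- lapply(cfg, function(rg) {
    ctr <- Reduce(`+`, lapply(rg$anchors, function(a) anchors[[a]])) /
      length(rg$anchors)
    for (k in seq_along(rg$offsets)) {
      ctr <- ctr + rg$offsets[[k]]$amount * face_scale *
        dirs[[rg$offsets[[k]]$dir]]
    }
    if (depth_pull > 0) {
      inward <- face_centroid - ctr
      inward <- inward / sqrt(sum(inward^2))
      ctr <- ctr + depth_pull * face_scale * inward
    }
    tibble::tibble(artery = rg$artery, cx = ctr[1], cy = ctr[2], cz = ctr[3],
                   radius_mm = rg$radius * face_scale)
  })
  left <- dplyr::bind_rows(rows) |> dplyr::mutate(side = "left")
  rctr <- plane$reflect(as.matrix(left[, c("cx", "cy", "cz")]))
  right <- left |>
    dplyr::mutate(cx = rctr[, 1], cy = rctr[, 2], cz = rctr[, 3],
                  side = "right")
  atlas <- dplyr::bind_rows(left, right) |>
    dplyr::select("artery", "side", "cx", "cy", "cz", "radius_mm")
  structure(atlas, class = c("region_atlas", class(atlas)), plane = plane)
}

region_atlas_config <- function() {
  path <- system.file("extdata", "region_atlas.json", package = "arterymap")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Label centerlines with artery names
#'
#' Each polyline receives the artery/side whose region contains the largest
#' fraction of its points, provided that fraction is at least `min_fraction`;
#' otherwise it stays `"unclassified"`. Ties are broken by distance to the
#' region centroid, then by the fixed label order. Labeling is deterministic
#' and independent of input order.
#'
#' @param centerlines List of [centerline_polyline()] in the atlas frame.
#' @param atlas A `region_atlas` from [build_region_atlas()].
#' @param min_fraction Minimum contained point fraction (default 0.5).
#' @return The list with `label` set to `"<artery>_<side>"` or
#'   `"unclassified"`.
#' @export
label_centerlines <- function(centerlines, atlas, min_fraction = 0.5) {
  stopifnot(inherits(atlas, "region_atlas"))
  centers <- as.matrix(atlas[, c("cx", "cy", "cz")])
  radii <- atlas$radius_mm
  labels <- paste(atlas$artery, atlas$side, sep = "_")
  lapply(centerlines, function(cl) {
    p <- cl$points
    d2 <- outer(rowSums(p^2), rowSums(centers^2), `+`) -
      2 * p %*% t(centers)   # n x 36 squared distances
    inside <- sweep(sqrt(pmax(d2, 0)), 2, radii, `<=`)
    frac <- colMeans(inside)
    best <- max(frac)
    if (best < min_fraction) {
      cl$label <- "unclassified"
      return(cl)
    }
    cand <- which(frac == best)
    if (length(cand) > 1L) {
      ctr <- colMeans(p)
      dc <- sqrt(rowSums((centers[cand, , drop = FALSE] -
                            matrix(ctr, length(cand), 3, byrow = TRUE))^2))
      cand <- cand[order(dc, cand)]
    }
    cl$label <- labels[cand[1]]
    cl
  })
}

#' Tally which arteries were visualized across subjects
#'
#' @param per_subject_labels Either a list (one element per subject) of
#'   character labels `"<artery>_<side>"`, or a tibble with columns
#'   `subject`, `artery`, `side`.
#' @param n_subjects Number of subjects (defaults to the number of list
#'   elements / distinct subjects).
#' @return Tibble (artery, left, right, total, percentage), percentage of
#'   `2 * n_subjects` to one decimal, rows in fixed artery order.
#' @export
tally_visualization <- function(per_subject_labels, n_subjects = NULL) {
  if (is.data.frame(per_subject_labels)) {
    df <- tibble::as_tibble(per_subject_labels)
  } else {
    df <- purrr::imap_dfr(per_subject_labels, function(labs, i) {
      labs <- labs[labs != "unclassified"]
      if (length(labs) == 0) return(tibble::tibble())
      parts <- strsplit(labs, "_", fixed = TRUE)
      tibble::tibble(subject = i,
                     artery = vapply(parts, `[`, "", 1),
                     side = vapply(parts, `[`, "", 2))
    })
  }
  if (is.null(n_subjects)) {
    n_subjects <- if (is.data.frame(per_subject_labels)) {
      dplyr::n_distinct(df$subject)
    } else {
      length(per_subject_labels)
    }
  }
  if (nrow(df) > 0 && anyDuplicated(df[c("subject", "artery", "side")])) {
    am_stop("a subject contributes the same artery label twice",
            "arterymap_consistency_error")
  }
  counts <- df |>
    dplyr::count(.data$artery, .data$side) |>
    tidyr::pivot_wider(names_from = "side", values_from = "n",
                       values_fill = 0L)
  out <- tibble::tibble(artery = artery_order()) |>
    dplyr::left_join(counts, by = "artery")
  for (cn in c("left", "right")) {
    if (!cn %in% names(out)) out[[cn]] <- 0L
    out[[cn]][is.na(out[[cn]])] <- 0L
  }
  out |>
    dplyr::mutate(total = .data$left + .data$right,
                  percentage = round(100 * .data$total / (2 * n_subjects), 1)) |>
    dplyr::select("artery", "left", "right", "total", "percentage")
}
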