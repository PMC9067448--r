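#' Centerline polyline
#'
#' Ordered 3-D points (mm) tracing one artery branch, with an optional
#' per-point radius estimate (mm) and an anatomical label.
#'
#' @param points Numeric matrix (n x 3), n >= 2, finite, in mm.
#' @param radius_mm Optional per-point radius estimates (length n).
#' @param label Artery label string; `"unclassified"` when unknown.
#' @return An object of class `centerline_polyline`.
#' @export
centerline_polyline <- function(points, radius_mm = NULL,
                                label = "unclassified") {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 2L || any(!is.finite(points))) {
    am_stop("a centerline needs at least 2 finite points",
            "arterymap_geometry_error")
  }
  structure(list(points = points, radius_mm = radius_mm, label = label),
            class = "centerline_polyline")
}

#' @export
print.centerline_polyline <- function(x, ...) {
  cat("<centerline_polyline> ", nrow(x$points), " points, length ",
      signif(polyline_length(x), 5), " mm, label ", x$label, "\n", sep = "")
  invisible(x)
}

#' Arc length of a polyline (mm)
#' @param polyline A [centerline_polyline()] or an (n x 3) point matrix.
#' @export
polyline_length <- function(polyline) {
  p <- if (inherits(polyline, "centerline_polyline")) polyline$points else polyline
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Extract labeled centerlines from a vessel mask
#'
#' Thins the mask to a unit-width 26-connected curve skeleton
#' (topology-preserving directional thinning), decomposes the skeleton graph
#' into branches at junction voxels (3 or more skeleton neighbours), prunes
#' branches shorter than `min_branch_mm`, and reports each branch as
#' a polyline in mm world coordinates. Per-point radii are estimated from the
#' distance transform of the mask. Branch ordering and point ordering are
#' deterministic (lexicographic voxel order).
#'
#' A mask without elongated structure (e.g. a ball) may thin to a cluster
#' whose branches are all shorter than `min_branch_mm`; the result is then an
#' empty list.
#'
#' @param mask A non-empty [binary_mask()].
#' @param min_branch_mm Minimum terminal branch length retained, in mm.
#' @return List of [centerline_polyline()].
#' @export
skeletonize_centerlines <- function(mask, min_branch_mm = 5) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) {
    am_stop("mask has no foreground voxels", "arterymap_empty_geometry_error")
  }
  skel <- array(cpp_thin3d(as.logical(mask$data), as.integer(dim(mask$data))),
                dim(mask$data))
  idx <- which(skel)
  if (length(idx) < 2) return(list())
  d <- dim(skel)
  co <- cbind((idx - 1) %% d[1],
              ((idx - 1) %/% d[1]) %% d[2],
              (idx - 1) %/% (d[1] * d[2])) + 1L  # 1-based voxel coords
  # adjacency among skeleton voxels (26-neighbourhood)
  key <- (co[, 3] - 1) * (d[1] * d[2]) + (co[, 2] - 1) * d[1] + co[, 1]
  lookup <- setNames(seq_along(idx), key)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nbkey <- (nb[, 3] - 1) * (d[1] * d[2]) + (nb[, 2] - 1) * d[1] + nb[, 1]
    j <- lookup[as.character(nbkey)]
    hit <- ok & !is.na(j)
    if (any(hit)) {
      e <- cbind(which(hit), j[hit])
      edges <- rbind(edges, e[e[, 1] < e[, 2], , drop = FALSE])
    }
  }
  if (is.null(edges) || nrow(edges) == 0) return(list())
  edges <- unique(edges)
  deg <- tabulate(c(edges[, 1], edges[, 2]), length(idx))
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  adj <- lapply(adj, sort)
  get_adj <- function(v) adj[[as.character(v)]]
  is_node <- deg != 2L
  visited_edge <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  walk <- function(start, nxt) {
    path <- c(start, nxt)
    assign(ekey(start, nxt), TRUE, envir = visited_edge)
    prev <- start; cur <- nxt
    while (!is_node[cur]) {
      nbrs <- get_adj(cur)
      nxt2 <- nbrs[nbrs != prev][1]
      if (is.na(nxt2)) break
      if (!is.null(visited_edge[[ekey(cur, nxt2)]])) break
      assign(ekey(cur, nxt2), TRUE, envir = visited_edge)
      path <- c(path, nxt2)
      prev <- cur; cur <- nxt2
    }
    path
  }
  branches <- list()
  node_order <- order(!is_node, co[, 1], co[, 2], co[, 3])
  for (v in node_order) {
    if (!is_node[v] && deg[v] == 2L) next
    for (nb in get_adj(v)) {
      if (is.null(visited_edge[[ekey(v, nb)]])) {
        branches[[length(branches) + 1L]] <- walk(v, nb)
      }
    }
  }
  # pure cycles (all degree 2) remain unvisited
  for (v in seq_along(idx)) {
    if (deg[v] == 2L) {
      for (nb in get_adj(v)) {
        if (is.null(visited_edge[[ekey(v, nb)]])) {
          branches[[length(branches) + 1L]] <- walk(v, nb)
        }
      }
    }
  }
  radii <- distance_transform(!mask$data, mask$spacing)
  vol_like <- list(spacing = mask$spacing, origin = mask$origin,
                   orientation = mask$orientation)
  out <- list()
  for (b in branches) {
    if (length(b) < 2) next
    pts <- voxel_to_world(vol_like, co[b, , drop = FALSE])
    len <- polyline_length(pts)
    if (len < min_branch_mm) next
    r <- radii[cbind(co[b, 1], co[b, 2], co[b, 3])]
    out[[length(out) + 1L]] <- centerline_polyline(pts, radius_mm = r)
  }
  out
}
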