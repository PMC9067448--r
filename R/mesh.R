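# Marching cubes on a binary field at iso-level 0.5.
#
# The 256-case triangulation table is generated programmatically when first
# needed: per cube face, marching-squares crossing segments are produced with
# a fixed rule for the ambiguous diagonal case and oriented so that the
# inside region lies to the left when the face is viewed from outside the
# cube; segments chain into closed loops on the cube surface, which are
# fan-triangulated from their centroid. Because the field is binary, every
# crossing sits at an edge midpoint, so each of the 256 configurations has a
# fixed triangle geometry relative to the cube corner.

.mc_env <- new.env(parent = emptyenv())

mc_corner_offsets <- function() {
  k <- 0:7
  cbind(k %% 2, (k %/% 2) %% 2, k %/% 4)
}

# faces as corner indices (0-based), counter-clockwise viewed from outside
mc_faces <- list(
  c(0L, 4L, 6L, 2L),  # -x
  c(1L, 3L, 7L, 5L),  # +x
  c(0L, 1L, 5L, 4L),  # -y
  c(2L, 6L, 7L, 3L),  # +y
  c(0L, 2L, 3L, 1L),  # -z
  c(4L, 5L, 7L, 6L)   # +z
)

mc_build_table <- function() {
  offs <- mc_corner_offsets()
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  edge_mid <- function(a, b) (offs[a + 1L, ] + offs[b + 1L, ]) / 2
  table <- vector("list", 256L)
  for (cfg in 0:255) {
    inside <- bitwAnd(cfg, bitwShiftL(1L, 0:7)) > 0L
    if (all(inside) || !any(inside)) {
      table[[cfg + 1L]] <- matrix(0, 0, 9)
      next
    }
    seg_from <- character(0); seg_to <- character(0)
    add_seg <- function(a1, b1, a2, b2) {
      seg_from <<- c(seg_from, edge_key(a1, b1))
      seg_to <<- c(seg_to, edge_key(a2, b2))
    }
    for (fc in mc_faces) {
      ins <- inside[fc + 1L]
      cyc <- function(i) fc[(i - 1L) %% 4L + 1L]
      # midpoint m(i) = midpoint of face edge (corner i, corner i+1)
      m <- function(i) c(cyc(i), cyc(i + 1L))
      n_in <- sum(ins)
      if (n_in == 0L || n_in == 4L) next
      pos <- which(ins)
      if (n_in == 1L) {
        i <- pos
        e1 <- m(i); e2 <- m(i - 1L)
        add_seg(e1[1], e1[2], e2[1], e2[2])
      } else if (n_in == 3L) {
        j <- which(!ins)
        e1 <- m(j - 1L); e2 <- m(j)
        add_seg(e1[1], e1[2], e2[1], e2[2])
      } else if (all(diff(pos) == 1L) || identical(pos, c(1L, 4L))) {
        i <- if (identical(pos, c(1L, 4L))) 4L else pos[1]  # adjacent pair i, i+1
        e1 <- m(i + 1L); e2 <- m(i - 1L)
        add_seg(e1[1], e1[2], e2[1], e2[2])
      } else {
        for (i in pos) {  # diagonal pair: two single-corner cuts
          e1 <- m(i); e2 <- m(i - 1L)
          add_seg(e1[1], e1[2], e2[1], e2[2])
        }
      }
    }
    # chain segments into closed loops
    tris <- matrix(0, 0, 9)
    used <- rep(FALSE, length(seg_from))
    mid_of <- function(key) {
      ab <- as.integer(strsplit(key, " ")[[1]])
      edge_mid(ab[1], ab[2])
    }
    while (any(!used)) {
      start <- which(!used)[1]
      loop_keys <- seg_from[start]
      cur <- start
      used[cur] <- TRUE
      repeat {
        nxt_key <- seg_to[cur]
        if (nxt_key == seg_from[start]) break
        cur <- which(!used & seg_from == nxt_key)[1]
        if (is.na(cur)) stop("open marching-cubes loop; table bug")
        loop_keys <- c(loop_keys, seg_from[cur])
        used[cur] <- TRUE
      }
      pts <- do.call(rbind, lapply(loop_keys, mid_of))
      k <- nrow(pts)
      if (k == 3L) {
        tris <- rbind(tris, c(pts[1, ], pts[3, ], pts[2, ]))
      } else {
        ctr <- colMeans(pts)
        for (t in seq_len(k)) {
          t2 <- t %% k + 1L
          tris <- rbind(tris, c(ctr, pts[t2, ], pts[t, ]))
        }
      }
    }
    table[[cfg + 1L]] <- tris
  }
  table
}

mc_table <- function() {
  if (is.null(.mc_env$table)) .mc_env$table <- mc_build_table()
  .mc_env$table
}

# core: binary array (already padded) -> triangle soup in 0-based voxel coords
mc_triangles <- function(vol) {
  d <- dim(vol)
  nx <- d[1] - 1L; ny <- d[2] - 1L; nz <- d[3] - 1L
  offs <- mc_corner_offsets()
  cfg <- array(0L, c(nx, ny, nz))
  for (k in 1:8) {
    o <- offs[k, ]
    cfg <- cfg + bitwShiftL(1L, k - 1L) *
      (vol[(1 + o[1]):(nx + o[1]), (1 + o[2]):(ny + o[2]),
           (1 + o[3]):(nz + o[3])] > 0)
  }
  mixed <- which(cfg > 0L & cfg < 255L)
  if (length(mixed) == 0) return(matrix(0, 0, 9))
  base <- cbind((mixed - 1) %% nx,
                ((mixed - 1) %/% nx) %% ny,
                (mixed - 1) %/% (nx * ny))
  cfg_v <- cfg[mixed]
  tab <- mc_table()
  out <- vector("list", 256L)
  for (cv in unique(cfg_v)) {
    tmpl <- tab[[cv + 1L]]
    nt <- nrow(tmpl)
    if (nt == 0) next
    rows <- which(cfg_v == cv)
    b <- base[rows, , drop = FALSE]
    reps <- b[rep(seq_len(nrow(b)), each = nt), , drop = FALSE]
    tris <- tmpl[rep(seq_len(nt), times = nrow(b)), , drop = FALSE]
    tris[, c(1, 4, 7)] <- tris[, c(1, 4, 7)] + reps[, 1]
    tris[, c(2, 5, 8)] <- tris[, c(2, 5, 8)] + reps[, 2]
    tris[, c(3, 6, 9)] <- tris[, c(3, 6, 9)] + reps[, 3]
    out[[cv + 1L]] <- tris
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Marching-cubes surface mesh of a binary mask
#'
#' Extracts the iso-surface at level 0.5 of the \{0,1\} field (the mask is
#' padded by one background voxel so surfaces close), then applies Taubin
#' mesh smoothing with per-component restoration of the enclosed volume to
#' remove voxelization staircase bias. Vertices are in mm world coordinates
#' with outward-oriented faces; the mesh is watertight.
#'
#' @param mask A non-empty [binary_mask()].
#' @param smooth_iterations Taubin smoothing iterations (0 disables
#'   smoothing and returns the raw midpoint marching-cubes surface).
#' @param smooth_lambda,smooth_mu Taubin shrink/inflate factors.
#' @return A [surface_mesh()].
#' @export
marching_cubes_mesh <- function(mask, smooth_iterations = 10L,
                                smooth_lambda = 0.5, smooth_mu = 0.53) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) {
    am_stop("mask has no foreground voxels", "arterymap_empty_geometry_error")
  }
  d <- dim(mask$data)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask$data
  tris <- mc_triangles(padded)
  # vertex coordinates are 0-based padded voxel units; voxel (i,j,k) of the
  # mask sits at padded coordinate (i, j, k) (0-based index + 1 for the pad),
  # and its world position is origin + orientation %*% (spacing * (i-1)).
  pts <- rbind(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  ord <- as.vector(t(matrix(seq_len(3 * nrow(tris)), ncol = 3)))
  pts <- pts[ord, , drop = FALSE]
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  vox <- pts[uk, , drop = FALSE] - 1  # 0-based mask voxel units
  world <- sweep(vox, 2, mask$spacing, `*`) %*% t(mask$orientation) +
    matrix(mask$origin, sum(uk), 3, byrow = TRUE)
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  mesh <- surface_mesh(world, faces)
  if (smooth_iterations > 0) {
    mesh <- taubin_smooth(mesh, iterations = smooth_iterations,
                          lambda = smooth_lambda, mu = smooth_mu,
                          restore_volume = TRUE)
  }
  mesh
}

#' Taubin mesh smoothing
#'
#' Alternating shrink (`lambda`) / inflate (`-mu`) Laplacian smoothing.
#' With `restore_volume = TRUE`, each connected component is rescaled about
#' its vertex centroid so its enclosed volume matches the input mesh.
#'
#' @param mesh A [surface_mesh()].
#' @param iterations Number of shrink/inflate passes.
#' @param lambda,mu Positive step factors.
#' @param restore_volume Restore per-component enclosed volume.
#' @return A smoothed [surface_mesh()].
#' @export
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.5, mu = 0.53,
                          restore_volume = TRUE) {
  V <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0 || iterations <= 0) return(mesh)
  src <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  dst <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  deg <- tabulate(src, nbins = nrow(V))
  deg[deg == 0] <- 1
  lap <- function(V) {
    s <- rowsum(V[dst, , drop = FALSE], src, reorder = TRUE)
    idx <- as.integer(rownames(s))
    avg <- V
    avg[idx, ] <- s / deg[idx]
    avg - V
  }
  for (i in seq_len(iterations)) {
    V <- V + lambda * lap(V)
    V <- V - mu * lap(V)
  }
  out <- surface_mesh(V, f)
  if (restore_volume) {
    g <- igraph::graph_from_edgelist(cbind(src, dst), directed = FALSE)
    if (igraph::vcount(g) < nrow(V)) {
      g <- igraph::add_vertices(g, nrow(V) - igraph::vcount(g))
    }
    comp <- igraph::components(g)$membership
    face_comp <- comp[f[, 1]]
    for (cid in unique(face_comp)) {
      fsel <- face_comp == cid
      vsel <- comp == cid
      sub0 <- surface_mesh(mesh$vertices, f[fsel, , drop = FALSE])
      sub1 <- surface_mesh(V, f[fsel, , drop = FALSE])
      v0 <- mesh_volume(sub0)
      v1 <- mesh_volume(sub1)
      if (abs(v1) < .Machine$double.eps || v0 * v1 <= 0) next
      s <- (v0 / v1)^(1 / 3)
      ctr <- colMeans(V[vsel, , drop = FALSE])
      V[vsel, ] <- sweep(sweep(V[vsel, , drop = FALSE], 2, ctr, `-`) * s,
                         2, ctr, `+`)
    }
    out <- surface_mesh(V, f)
  }
  out
}
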