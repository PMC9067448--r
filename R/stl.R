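#' Triangulated surface mesh
#'
#' Triangle-soup container used for the arterial surface: vertices in mm
#' world coordinates and counter-clockwise (outward-normal) vertex-index
#' triples.
#'
#' @param vertices Numeric matrix (n x 3), finite coordinates in mm.
#' @param faces Integer matrix (m x 3) of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (any(!is.finite(vertices))) {
    am_stop("mesh vertices must be finite", "arterymap_geometry_error")
  }
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      am_stop("face indices out of range", "arterymap_geometry_error")
    }
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(degen)) {
      am_stop(sprintf("%d faces reference a vertex twice", sum(degen)),
              "arterymap_geometry_error")
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, area ", signif(mesh_area(x), 6), " mm^2\n", sep = "")
  invisible(x)
}

face_cross_products <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c3 - a
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Total surface area of a mesh (mm^2)
#' @param mesh A [surface_mesh()].
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  cr <- face_cross_products(mesh)
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Signed enclosed volume of a closed mesh (mm^3)
#'
#' Divergence-theorem integral; positive for outward-oriented closed meshes.
#' @param mesh A [surface_mesh()].
#' @export
mesh_volume <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  cr <- face_cross_products(mesh)
  sum(rowSums(a * cr)) / 6
}

#' Euler characteristic (V - E + F) of a mesh
#' @param mesh A [surface_mesh()].
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ne <- nrow(unique(e))
  nrow(mesh$vertices) - ne + nrow(f)
}

#' Write a mesh as STL
#'
#' Binary STL is the default dialect; ASCII is available for inspection.
#' Facet normals are recomputed from the vertex winding.
#'
#' @param mesh A non-empty [surface_mesh()].
#' @param path Output path.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0) {
    am_stop("cannot export an empty mesh", "arterymap_empty_geometry_error")
  }
  cr <- face_cross_products(mesh)
  nrm <- cr / pmax(sqrt(rowSums(cr^2)), .Machine$double.xmin)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  nf <- nrow(mesh$faces)
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("arterymap binary STL", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    block <- t(cbind(nrm, v1, v2, v3))  # 12 floats per facet, column = facet
    fl <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
    per_face <- matrix(fl, nrow = 48)
    writeBin(as.vector(rbind(per_face, as.raw(0), as.raw(0))), con)
  } else {
    lines <- character(0)
    tri <- function(i) {
      c(sprintf("  facet normal %.12e %.12e %.12e", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.12e %.12e %.12e", v1[i, 1], v1[i, 2], v1[i, 3]),
        sprintf("      vertex %.12e %.12e %.12e", v2[i, 1], v2[i, 2], v2[i, 3]),
        sprintf("      vertex %.12e %.12e %.12e", v3[i, 1], v3[i, 2], v3[i, 3]),
        "    endloop",
        "  endfacet")
    }
    lines <- c("solid arterymap", unlist(lapply(seq_len(nf), tri)),
               "endsolid arterymap")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an STL file
#'
#' Reads binary or ASCII STL and reassembles shared vertices by snapping
#' coordinates to a tolerance grid.
#'
#' @param path STL file path.
#' @param tolerance Vertex de-duplication tolerance in mm.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path, tolerance = 1e-6) {
  raw <- readBin(path, "raw", n = file.size(path))
  is_ascii <- length(raw) > 5 && identical(rawToChar(raw[1:5]), "solid") &&
    !any(raw[seq_len(min(length(raw), 1000))] == as.raw(0))
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vx <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    tris <- nums
  } else {
    if (length(raw) < 84) {
      am_stop(sprintf("%s: truncated binary STL", path), "arterymap_format_error")
    }
    nf <- readBin(raw[81:84], "integer", size = 4, endian = "little")
    need <- 84 + nf * 50
    if (length(raw) < need) {
      am_stop(sprintf("%s: binary STL shorter than its facet count", path),
              "arterymap_format_error")
    }
    body <- raw[85:need]
    # each 50-byte facet: 12 little-endian floats + 2 attribute bytes
    idx <- rep(seq_len(nf) - 1, each = 48) * 50 + rep(seq_len(48), nf)
    floats <- readBin(body[idx], "numeric", n = nf * 12, size = 4,
                      endian = "little")
    m <- matrix(floats, ncol = 12, byrow = TRUE)
    tris <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                  m[, 10:12, drop = FALSE])
    ord <- as.vector(t(matrix(seq_len(3 * nf), ncol = 3)))
    tris <- tris[ord, , drop = FALSE]
  }
  if (nrow(tris) %% 3 != 0 || nrow(tris) == 0) {
    am_stop(sprintf("%s: malformed STL triangle list", path),
            "arterymap_format_error")
  }
  key <- paste(round(tris[, 1] / tolerance), round(tris[, 2] / tolerance),
               round(tris[, 3] / tolerance))
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts <- tris[uk, , drop = FALSE]
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}
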