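#' Triangulated surface meshes
#'
#' A `surface_mesh` is the carrier of all scene geometry: a list with
#' `vertices` (n x 3 matrix, scene units are meters), `faces` (m x 3 integer
#' matrix of vertex indices) and `normals` (m x 3 matrix of unit face
#' normals). The coordinate system is right-handed with z up.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates.
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @param normals optional m x 3 matrix of unit face normals; recomputed from
#'   the face winding when omitted.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as_mat3(vertices, "vertices")
  check_finite(vertices, "vertices")
  if (length(faces) == 0) {
    faces <- matrix(integer(0), ncol = 3)
  }
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 && (max(faces) > nrow(vertices) || min(faces) < 1)) {
    stop_invalid("face indices must reference existing vertices")
  }
  if (is.null(normals)) {
    normals <- face_normals(vertices, faces)
  } else if (nrow(faces) > 0) {
    normals <- as_mat3(normals, "normals")
    normals <- normals / row_norms(normals)
  } else {
    normals <- matrix(numeric(0), ncol = 3)
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# unit normals from the face winding (right-hand rule)
face_normals <- function(vertices, faces) {
  if (nrow(faces) == 0) return(matrix(numeric(0), ncol = 3))
  v0 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - v0
  e2 <- vertices[faces[, 3], , drop = FALSE] - v0
  n <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  len <- row_norms(n)
  len[len == 0] <- 1  # degenerate faces keep a zero normal
  n / len
}

#' Unit sphere primitive
#'
#' Builds a closed, triangulated unit sphere centred at the origin by
#' latitude-longitude subdivision: `resolution` latitude bands and
#' `2 * resolution` longitude steps. Face windings are chosen so normals
#' point outward from the centre. This is the sole primitive from which
#' objects are composed; everything else is affine transformation.
#'
#' @param resolution number of latitude bands, at least 3.
#' @return A `surface_mesh` whose vertices all lie at distance 1 from the
#'   origin.
#' @export
make_sphere_mesh <- function(resolution) {
  if (!is.numeric(resolution) || length(resolution) != 1 ||
      !is.finite(resolution) || resolution < 3 ||
      resolution != round(resolution)) {
    stop_invalid("`resolution` must be an integer >= 3")
  }
  res <- as.integer(resolution)
  nlon <- 2L * res
  # interior rings (exclude poles)
  lat <- pi / 2 - (seq_len(res - 1)) * pi / res   # from north to south
  lon <- (seq_len(nlon) - 1L) * 2 * pi / nlon
  ring <- function(phi) cbind(cos(phi) * cos(lon), cos(phi) * sin(lon),
                              rep(sin(phi), nlon))
  verts <- do.call(rbind, lapply(lat, ring))
  north <- nrow(verts) + 1L
  south <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 1), c(0, 0, -1))

  idx <- function(i, j) (i - 1L) * nlon + ((j - 1L) %% nlon) + 1L
  faces <- vector("list", res)
  # north cap: ring 1 with the north pole (CCW seen from outside/above)
  j <- seq_len(nlon)
  faces[[1]] <- cbind(rep(north, nlon), idx(1L, j), idx(1L, j + 1L))
  # body quads between ring i and i+1
  if (res > 2) {
    for (i in seq_len(res - 2L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      a2 <- idx(i, j + 1L); b2 <- idx(i + 1L, j + 1L)
      faces[[i + 1L]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
    }
  }
  # south cap
  faces[[res]] <- cbind(rep(south, nlon), idx(res - 1L, j + 1L), idx(res - 1L, j))
  mesh <- surface_mesh(verts, do.call(rbind, faces))
  orient_outward(mesh)
}

# flip any face whose normal points toward the vertex centroid
orient_outward <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(mesh)
  ctr <- colMeans(mesh$vertices)
  fc <- face_centroids(mesh)
  out <- sweep(fc, 2, ctr)
  flip <- rowSums(out * mesh$normals) < 0
  if (any(flip)) {
    mesh$faces[flip, c(2, 3)] <- mesh$faces[flip, c(3, 2)]
    mesh$normals[flip, ] <- -mesh$normals[flip, ]
  }
  mesh
}

face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

#' Anisotropic scaling of a mesh
#'
#' Scaling parameters are log-scale (dimensionless): vertex coordinates are
#' multiplied componentwise by `exp(scale)`, so a zero parameter leaves that
#' axis untouched and scales are positive by construction. Face topology is
#' unchanged; normals are recomputed from the scaled geometry (anisotropic
#' scaling does not preserve normal directions).
#'
#' @param mesh a `surface_mesh`.
#' @param scale length-3 numeric `(alpha, beta, gamma)` of log scale factors.
#' @return The scaled `surface_mesh`.
#' @export
scale_mesh <- function(mesh, scale) {
  check_finite(scale, "scale")
  if (length(scale) != 3) stop_invalid("`scale` must have 3 components")
  s <- exp(scale)
  v <- sweep(mesh$vertices, 2, s, `*`)
  surface_mesh(v, mesh$faces)
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic rotations composed as `R = Rz(varphi) %*% Ry(phi) %*% Rx(theta)`
#' (roll about x first, then pitch about y, then yaw about z), all angles in
#' radians. The result is orthogonal with determinant +1.
#'
#' @param angles length-3 numeric `(theta, phi, varphi)` in radians.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(angles) {
  check_finite(angles, "angles")
  if (length(angles) != 3) stop_invalid("`angles` must have 3 components")
  ct <- cos(angles[1]); st <- sin(angles[1])
  cp <- cos(angles[2]); sp <- sin(angles[2])
  cv <- cos(angles[3]); sv <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, ct, st, 0, -st, ct), 3, 3)
  Ry <- matrix(c(cp, 0, -sp, 0, 1, 0, sp, 0, cp), 3, 3)
  Rz <- matrix(c(cv, sv, 0, -sv, cv, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotate a mesh
#'
#' Applies `rotation_matrix(angles)` to every vertex. Rotation is an
#' isometry: pairwise vertex distances are preserved and normals rotate
#' rigidly with the geometry.
#'
#' @inheritParams scale_mesh
#' @param angles length-3 Euler angles in radians (see [rotation_matrix()]).
#' @export
rotate_mesh <- function(mesh, angles) {
  R <- rotation_matrix(angles)
  v <- mesh$vertices %*% t(R)
  n <- if (nrow(mesh$faces) > 0) mesh$normals %*% t(R) else mesh$normals
  surface_mesh(v, mesh$faces, n)
}

#' Translate a mesh
#'
#' Adds the same offset vector to every vertex; normals are unchanged.
#'
#' @inheritParams scale_mesh
#' @param offset length-3 numeric translation in meters.
#' @export
translate_mesh <- function(mesh, offset) {
  check_finite(offset, "offset")
  if (length(offset) != 3) stop_invalid("`offset` must have 3 components")
  v <- sweep(mesh$vertices, 2, offset, `+`)
  surface_mesh(v, mesh$faces, mesh$normals)
}

#' Concatenate meshes
#'
#' Joins several meshes into one by stacking vertices and re-indexing faces.
#'
#' @param meshes list of `surface_mesh` objects.
#' @return A single `surface_mesh`; empty input yields an empty mesh.
#' @export
concat_meshes <- function(meshes) {
  meshes <- Filter(Negate(is.null), meshes)
  if (length(meshes) == 0) {
    return(surface_mesh(matrix(numeric(0), ncol = 3),
                        matrix(integer(0), ncol = 3)))
  }
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices),
                              integer(1))))
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  faces <- do.call(rbind, Map(function(m, o) m$faces + o,
                              meshes, offs[seq_along(meshes)]))
  norms <- do.call(rbind, lapply(meshes, `[[`, "normals"))
  surface_mesh(verts, faces, norms)
}

#' Axis-aligned room walls
#'
#' Builds the bounding surfaces of a room: the floor and the four side
#' walls, with normals facing the interior (the viewer stands inside).
#' There is no ceiling, so a mostly-vertical directional light reaches the
#' interior; a closed box would leave every interior surface in shadow.
#'
#' @param min_corner,max_corner length-3 numeric box corners (meters).
#' @param ceiling include a ceiling face (default `FALSE`).
#' @return A `surface_mesh` with inward-facing normals.
#' @export
make_room_walls <- function(min_corner = c(-2, -2, 0),
                            max_corner = c(2, 2, 3),
                            ceiling = FALSE) {
  check_finite(min_corner, "min_corner")
  check_finite(max_corner, "max_corner")
  if (any(max_corner <= min_corner)) {
    stop_invalid("`max_corner` must exceed `min_corner` componentwise")
  }
  x0 <- min_corner[1]; y0 <- min_corner[2]; z0 <- min_corner[3]
  x1 <- max_corner[1]; y1 <- max_corner[2]; z1 <- max_corner[3]
  quad <- function(a, b, c, d) {
    # two triangles; winding fixed by the caller to face inward
    v <- rbind(a, b, c, d)
    surface_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)))
  }
  walls <- list(
    # floor, normal +z (up, into the room)
    quad(c(x0, y0, z0), c(x1, y0, z0), c(x1, y1, z0), c(x0, y1, z0)),
    # south wall (y = y0), normal +y
    quad(c(x0, y0, z0), c(x0, y0, z1), c(x1, y0, z1), c(x1, y0, z0)),
    # north wall (y = y1), normal -y
    quad(c(x0, y1, z0), c(x1, y1, z0), c(x1, y1, z1), c(x0, y1, z1)),
    # west wall (x = x0), normal +x
    quad(c(x0, y0, z0), c(x0, y1, z0), c(x0, y1, z1), c(x0, y0, z1)),
    # east wall (x = x1), normal -x
    quad(c(x1, y0, z0), c(x1, y0, z1), c(x1, y1, z1), c(x1, y1, z0))
  )
  if (ceiling) {
    walls <- c(walls, list(
      quad(c(x0, y0, z1), c(x0, y1, z1), c(x1, y1, z1), c(x1, y0, z1))
    ))
  }
  concat_meshes(walls)
}
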