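#' Directional light source
#'
#' A single directional (infinitely distant) light. `direction` is a unit
#' vector pointing from the scene toward the source. The shading constants
#' are the ambient level `ambient`, the diffuse and specular coefficients
#' and the specular (shininess) exponent of the Blinn-Phong model.
#'
#' @param direction length-3 vector toward the light source (normalized
#'   internally).
#' @param ambient ambient intensity, >= 0.
#' @param diffuse diffuse coefficient c1, >= 0.
#' @param specular specular coefficient c2, >= 0.
#' @param shininess specular exponent c3, > 0.
#' @return An object of class `light_source`.
#' @export
light_source <- function(direction = c(0.2, 0.1, 0.97), ambient = 0.1,
                         diffuse = 0.6, specular = 0.3, shininess = 8) {
  check_finite(direction, "direction")
  if (length(direction) != 3) stop_invalid("`direction` must have 3 components")
  if (ambient < 0 || diffuse < 0 || specular < 0 || shininess <= 0) {
    stop_invalid("shading constants must satisfy ambient,c1,c2 >= 0 and c3 > 0")
  }
  structure(list(direction = unit_vec(direction), ambient = ambient,
                 diffuse = diffuse, specular = specular,
                 shininess = shininess),
            class = "light_source")
}

#' Lesion configurations
#'
#' Modes: `"none"`; `"monocular"` (one eye's image zeroed, as in monocular
#' blindness); `"hemianopia"` / `"scene_side_removal"` (synonyms: every
#' surface whose egocentric lateral position falls on the stated side is
#' deleted from the generative model before rendering, which blanks the same
#' side of both retinal images -- the homonymous hemianopia pattern of a
#' post-chiasmatic lesion).
#'
#' @param mode one of `"none"`, `"monocular"`, `"hemianopia"`,
#'   `"scene_side_removal"`.
#' @param eye for `"monocular"`: `"left"` or `"right"`.
#' @param side for the scene-side modes: `"left"` or `"right"` (egocentric).
#' @return An object of class `lesion_config`.
#' @export
lesion_config <- function(mode = c("none", "monocular", "hemianopia",
                                   "scene_side_removal"),
                          eye = NULL, side = NULL) {
  mode <- match.arg(mode)
  if (mode == "monocular" && !isTRUE(eye %in% c("left", "right"))) {
    stop_invalid("monocular lesion needs `eye` = 'left' or 'right'")
  }
  if (mode %in% c("hemianopia", "scene_side_removal") &&
      !isTRUE(side %in% c("left", "right"))) {
    stop_invalid("scene-side lesion needs `side` = 'left' or 'right'")
  }
  structure(list(mode = mode, eye = eye, side = side),
            class = "lesion_config")
}

#' Cast rays against a mesh
#'
#' Moller-Trumbore ray-triangle intersection of a batch of rays against
#' every face of a mesh, returning for each ray the nearest hit with
#' distance `> 1e-9` (ties at exactly equal distance are broken toward the
#' lowest face index). Degenerate zero-area faces are skipped with a
#' warning.
#'
#' @param origins k x 3 matrix of ray origins (a single row is recycled).
#' @param dirs k x 3 matrix of unit ray directions.
#' @param mesh a `surface_mesh`.
#' @return List with `face` (integer, `NA` = no hit), `dist`, and `point`
#'   (k x 3), one entry per ray.
#' @export
cast_rays <- function(origins, dirs, mesh) {
  dirs <- as_mat3(dirs, "dirs")
  origins <- as_mat3(origins, "origins")
  k <- nrow(dirs)
  if (nrow(origins) == 1 && k > 1) {
    origins <- origins[rep(1, k), , drop = FALSE]
  }
  best_t <- rep(Inf, k)
  best_f <- rep(NA_integer_, k)
  eps <- 1e-9
  n_deg <- 0L
  V <- mesh$vertices
  Fc <- mesh$faces
  for (f in seq_len(nrow(Fc))) {
    v0 <- V[Fc[f, 1], ]
    e1 <- V[Fc[f, 2], ] - v0
    e2 <- V[Fc[f, 3], ] - v0
    if (sum(cross3(e1, e2)^2) < 1e-24) { n_deg <- n_deg + 1L; next }
    pvec <- cross_rows_vec(dirs, e2)
    det <- pvec[, 1] * e1[1] + pvec[, 2] * e1[2] + pvec[, 3] * e1[3]
    ok <- abs(det) > 1e-12
    if (!any(ok)) next
    tvec <- sweep(origins, 2, v0)
    u <- rowSums(tvec * pvec) / det
    qvec <- cross_rows_vec(tvec, e1)
    v <- rowSums(dirs * qvec) / det
    tt <- (qvec[, 1] * e2[1] + qvec[, 2] * e2[2] + qvec[, 3] * e2[3]) / det
    hit <- ok & u >= -eps & v >= -eps & (u + v) <= 1 + eps & tt > eps &
      tt < best_t
    if (any(hit)) {
      best_t[hit] <- tt[hit]
      best_f[hit] <- f
    }
  }
  if (n_deg > 0) {
    warning(sprintf("skipped %d degenerate (zero-area) face(s)", n_deg))
  }
  pts <- origins + dirs * best_t
  pts[is.na(best_f), ] <- NA_real_
  list(face = best_f, dist = ifelse(is.na(best_f), NA_real_, best_t),
       point = pts)
}

#' @rdname cast_rays
#' @param origin,direction single ray origin and unit direction.
#' @return `cast_ray()` returns `NULL` for a miss, else a list with `face`,
#'   `point` and `distance`.
#' @export
cast_ray <- function(origin, direction, mesh) {
  res <- cast_rays(matrix(origin, ncol = 3), matrix(direction, ncol = 3), mesh)
  if (is.na(res$face[1])) return(NULL)
  list(face = res$face[1], point = res$point[1, ], distance = res$dist[1])
}

#' Line-of-sight indicator
#'
#' Returns 1 iff the nearest surface intersection along `toward` from
#' `from_point` is the stated target point (within a distance tolerance),
#' and 0 otherwise -- including when the target lies behind the origin or an
#' occluder sits strictly in between. The same indicator, aimed along the
#' light direction, is what produces cast shadows.
#'
#' @param from_point origin of the sight line.
#' @param toward unit direction of the sight line.
#' @param target a point on some surface of `scene`.
#' @param scene a `surface_mesh`.
#' @param tol distance tolerance (default 1e-6).
#' @return 0 or 1.
#' @export
eta <- function(from_point, toward, target, scene, tol = 1e-6) {
  d_target <- sum((target - from_point) * toward)
  if (d_target <= 0) return(0L)  # behind the origin
  hit <- cast_ray(from_point, toward, scene)
  if (is.null(hit)) return(0L)
  if (abs(hit$distance - d_target) <= tol &&
      sqrt(sum((hit$point - target)^2)) <= max(tol, 1e-6 * d_target)) 1L else 0L
}

#' Blinn-Phong shading of a surface point
#'
#' Intensity `= ambient + lit * (c1 * max(0, v_n . z) + c2 * max(0, v_n .
#' h)^c3)` where `z` is the light direction, `h = (u_n + z) / ||u_n + z||`
#' the half vector, `u_n` the viewing ray direction (lens outward) and `v_n`
#' the surface normal. A shadowed point (`lit = 0`) receives exactly the
#' ambient level. When `u_n + z` vanishes the specular term is defined as 0.
#'
#' @param u_n unit viewing direction (from the lens toward the surface).
#' @param v_n unit surface normal.
#' @param light a `light_source`.
#' @param lit 0/1 shadow indicator.
#' @return Non-negative scalar intensity.
#' @export
shade_point <- function(u_n, v_n, light, lit = 1L) {
  if (!lit) return(light$ambient)
  z <- light$direction
  hraw <- u_n + z
  hn <- sqrt(sum(hraw^2))
  spec <- if (hn < 1e-12) 0 else {
    light$specular * max(0, sum(v_n * (hraw / hn)))^light$shininess
  }
  light$ambient + light$diffuse * max(0, sum(v_n * z)) + spec
}

# vectorized shading for k hits; U, N are k x 3, lit length-k 0/1
shade_points <- function(U, N, light, lit) {
  z <- light$direction
  H <- sweep(U, 2, z, `+`)
  hn <- row_norms(H)
  safe <- hn > 1e-12
  H[safe, ] <- H[safe, ] / hn[safe]
  spec <- ifelse(safe,
                 light$specular * pmax(0, rowSums(N * H))^light$shininess, 0)
  diff <- light$diffuse * pmax(0, N %*% z)
  light$ambient + lit * (as.numeric(diff) + spec)
}

#' Render one eye's shaded retinal image
#'
#' Casts every retinal cell's line of sight into the scene; each hit is
#' shaded by the Blinn-Phong model with a shadow test toward the light
#' (shadow rays originate at the hit point offset by `1e-6` along the
#' normal). Intensities are written at the retinally inverted grid location
#' -- flipped across both image axes, as the optics of a pinhole eye
#' dictate -- so a surface up and to the left in the visual field activates
#' cells down and to the right on the retina. Cells whose rays hit nothing
#' are 0.
#'
#' @param fov_eye one eye of a [field_of_view()] (fields `origin`, `dirs`).
#' @param scene a `surface_mesh`.
#' @param light a `light_source`.
#' @param array the `retinal_array` used to build the field of view.
#' @return `n_rows x n_cols` matrix of non-negative intensities (the shaded
#'   image, before blurring).
#' @export
render_eye <- function(fov_eye, scene, light, array) {
  nr <- array$n_rows; nc <- array$n_cols
  img_vf <- matrix(0, nr, nc)  # visual-field layout: row 1 top, col 1 left
  if (nrow(scene$faces) > 0) {
    hits <- cast_rays(matrix(fov_eye$origin, ncol = 3), fov_eye$dirs, scene)
    hi <- which(!is.na(hits$face))
    if (length(hi) > 0) {
      N <- scene$normals[hits$face[hi], , drop = FALSE]
      P <- hits$point[hi, , drop = FALSE]
      # shadow test: offset along the normal, cast toward the light
      sh_orig <- P + 1e-6 * N
      sh_dirs <- matrix(light$direction, nrow = length(hi), ncol = 3,
                        byrow = TRUE)
      sh <- cast_rays(sh_orig, sh_dirs, scene)
      lit <- as.numeric(is.na(sh$face))
      U <- fov_eye$dirs[hi, , drop = FALSE]
      vals <- shade_points(U, N, light, lit)
      # row-major cell order: cell index -> (row, col) in visual field
      rows <- ((hi - 1L) %/% nc) + 1L
      cols <- ((hi - 1L) %% nc) + 1L
      img_vf[cbind(rows, cols)] <- vals
    }
  }
  # retinal inversion across both axes
  img_vf[nr:1, nc:1, drop = FALSE]
}

# orthonormal DCT-II matrix of order n (rows index frequency, 0-based)
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  D[1, ] <- sqrt(1 / n)
  D
}

#' Low-pass blur in the DCT domain
#'
#' Takes the 2-D type-II DCT of the image, multiplies coefficient `(p, q)`
#' (zero-based) by `exp(-(p^2 + q^2) / (2 * sigma_freq^2))`, and inverts the
#' transform. The DC coefficient is multiplied by exactly 1, so the image
#' mean is preserved. The inverse transform can produce tiny negative
#' excursions; these are clamped at 0 and the pre-clamp minimum is attached
#' as attribute `min_preclamp`.
#'
#' @param image numeric matrix of non-negative intensities.
#' @param sigma_freq Gaussian width in DCT coefficient-index units, > 0.
#'   A sensible default for an `n x n` image is `n / 6`.
#' @param clamp clamp small negative outputs at 0 (default `TRUE`).
#' @return Blurred image matrix with attribute `min_preclamp`.
#' @export
blur_image <- function(image, sigma_freq, clamp = TRUE) {
  if (!is.matrix(image)) stop_invalid("`image` must be a matrix")
  if (!is.finite(sigma_freq) || sigma_freq <= 0) {
    stop_invalid("`sigma_freq` must be > 0")
  }
  nr <- nrow(image); nc <- ncol(image)
  Dr <- dct_matrix(nr); Dc <- dct_matrix(nc)
  coef <- Dr %*% image %*% t(Dc)
  p2 <- (0:(nr - 1))^2
  q2 <- (0:(nc - 1))^2
  mask <- exp(-outer(p2, q2, `+`) / (2 * sigma_freq^2))
  out <- t(Dr) %*% (coef * mask) %*% Dc
  mn <- min(out)
  if (clamp) out <- pmax(out, 0)
  attr(out, "min_preclamp") <- mn
  out
}

# delete faces whose centroid lies on the given egocentric side of the head
remove_scene_side <- function(scene, pose, side) {
  if (nrow(scene$faces) == 0) return(scene)
  hh <- pose$head_dir[1]
  left_axis <- c(-sin(hh), cos(hh), 0)
  lat <- sweep(face_centroids(scene), 2, pose$place) %*% left_axis
  keep <- if (side == "left") lat <= 0 else lat > 0
  keep_faces(scene, as.vector(keep))
}

keep_faces <- function(mesh, keep) {
  surface_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE],
               mesh$normals[keep, , drop = FALSE])
}

#' Render a binocular pair of retinal images
#'
#' The full image-generation pipeline: build the binocular field of view,
#' render each eye's shaded image, blur each in the DCT domain, and apply
#' the lesion mode. Scene-side lesions delete surfaces before rendering
#' (they are lesions of the generative model, not image masks); a monocular
#' lesion zeroes that eye's images last. Deterministic throughout.
#'
#' @param pose a `head_pose`.
#' @param eyes an `eye_direction`.
#' @param array a `retinal_array`.
#' @param scene a `surface_mesh` (typically [assemble_room()] output).
#' @param light a `light_source`.
#' @param lesion a `lesion_config` (default none).
#' @param baseline interocular baseline in meters.
#' @param sigma_freq blur width; default `min(n_rows, n_cols) / 6`.
#' @return An object of class `binocular_image`: `left`/`right` blurred
#'   retinal images and `shaded_left`/`shaded_right` pre-blur images.
#' @export
render_binocular <- function(pose, eyes, array, scene, light,
                             lesion = lesion_config("none"),
                             baseline = 0.06, sigma_freq = NULL) {
  if (!inherits(lesion, "lesion_config")) {
    stop_invalid("`lesion` must be a lesion_config")
  }
  sigma_freq <- sigma_freq %||% (min(array$n_rows, array$n_cols) / 6)
  if (lesion$mode %in% c("hemianopia", "scene_side_removal")) {
    scene <- remove_scene_side(scene, pose, lesion$side)
  }
  fov <- field_of_view(pose, eyes, array, baseline)
  shaded <- list(left = render_eye(fov$left, scene, light, array),
                 right = render_eye(fov$right, scene, light, array))
  blurred <- lapply(shaded, blur_image, sigma_freq = sigma_freq)
  if (lesion$mode == "monocular") {
    zero <- matrix(0, array$n_rows, array$n_cols)
    shaded[[lesion$eye]] <- zero
    blurred[[lesion$eye]] <- zero
  }
  structure(list(left = blurred$left, right = blurred$right,
                 shaded_left = shaded$left, shaded_right = shaded$right),
            class = "binocular_image")
}

#' Write an image as a plain PGM file
#'
#' Plain-text (P2) portable greymap with a 16-bit intensity range. The image
#' is linearly mapped from `[0, white]` to `[0, 65535]`; by default `white`
#' is the image maximum (or 1 for an all-zero image).
#'
#' @param image numeric matrix of non-negative intensities.
#' @param path output file path.
#' @param white intensity mapped to full white.
#' @return The path, invisibly.
#' @export
write_pgm <- function(image, path, white = NULL) {
  if (!is.matrix(image)) stop_invalid("`image` must be a matrix")
  white <- white %||% max(image, 0)
  if (white <= 0) white <- 1
  q <- pmin(pmax(round(image / white * 65535), 0), 65535)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(image), nrow(image)), "65535"),
             con)
  apply(q, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
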