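#' Head pose and eye direction
#'
#' `head_pose()` bundles the allocentric place of the head (meters) with its
#' direction as a `(heading, elevation)` pair in radians; heading is wrapped
#' into `(-pi, pi]`. `eye_direction()` holds the egocentric eye direction
#' (relative to the head) and the convergence angle `omega >= 0` between the
#' two eyes' lines of sight.
#'
#' @param place length-3 numeric position in meters.
#' @param head_dir length-2 `(heading, elevation)` in radians.
#' @return `head_pose()` returns a `head_pose`; `eye_direction()` an
#'   `eye_direction`.
#' @export
head_pose <- function(place = c(0, 0, 0), head_dir = c(0, 0)) {
  check_finite(place, "place")
  check_finite(head_dir, "head_dir")
  if (length(place) != 3 || length(head_dir) != 2) {
    stop_invalid("`place` needs 3 components and `head_dir` 2")
  }
  structure(list(place = as.numeric(place),
                 head_dir = c(wrap_angle(head_dir[1]), head_dir[2])),
            class = "head_pose")
}

#' @rdname head_pose
#' @param ego_dir length-2 `(heading, elevation)` of the eyes relative to the
#'   head, radians; components must lie in `(-pi/2, pi/2)`.
#' @param convergence convergence angle `omega >= 0` in radians.
#' @export
eye_direction <- function(ego_dir = c(0, 0), convergence = 0) {
  check_finite(ego_dir, "ego_dir")
  check_finite(convergence, "convergence")
  if (length(ego_dir) != 2 || any(abs(ego_dir) >= pi / 2)) {
    stop_invalid("`ego_dir` must be 2 angles with magnitude < pi/2")
  }
  if (convergence < 0) stop_invalid("`convergence` must be >= 0")
  structure(list(ego_dir = as.numeric(ego_dir),
                 convergence = as.numeric(convergence)),
            class = "eye_direction")
}

#' Allocentric gaze direction
#'
#' The allocentric eye direction is the head direction plus the egocentric
#' eye direction, componentwise; the heading component is wrapped into
#' `(-pi, pi]`.
#'
#' @param head_dir,ego_dir length-2 `(heading, elevation)` angle pairs in
#'   radians.
#' @return Length-2 `(heading, elevation)` allocentric gaze.
#' @export
allocentric_gaze <- function(head_dir, ego_dir) {
  check_finite(head_dir, "head_dir")
  check_finite(ego_dir, "ego_dir")
  s <- head_dir + ego_dir
  c(wrap_angle(s[1]), s[2])
}

#' Uniformly spaced retinal array
#'
#' A pinhole-camera array of retinal cells: each cell is a tuple of a
#' position in front of the lens (at unit distance, in the eye's local frame
#' with +x the optical axis, +y left, +z up) and a unit preferred-incidence
#' direction. Cells span a uniform angular grid of the stated extent centred
#' on the optical axis, with the outermost cells at exactly `+/- extent/2`
#' (global retinal topography is deliberately ignored; this is a small
#' foveal patch).
#'
#' @param n_rows,n_cols grid dimensions, at least 1.
#' @param angular_extent full angular width of the grid in radians, in
#'   `(0, pi)`.
#' @return An object of class `retinal_array` with fields `n_rows`,
#'   `n_cols`, `angular_extent`, `az`/`el` (per-column / per-row angular
#'   offsets; column 1 is leftmost, row 1 uppermost in the visual field) and
#'   `dirs` (cells x 3 matrix of unit directions, row-major cell order).
#' @export
build_retinal_array <- function(n_rows = 32, n_cols = 32,
                                angular_extent = 40 * pi / 180) {
  if (n_rows < 1 || n_cols < 1) stop_invalid("grid dimensions must be >= 1")
  if (!is.finite(angular_extent) || angular_extent <= 0 ||
      angular_extent >= pi) {
    stop_invalid("`angular_extent` must lie in (0, pi)")
  }
  grid1 <- function(n) {
    if (n == 1) 0 else seq(angular_extent / 2, -angular_extent / 2,
                           length.out = n)
  }
  el <- grid1(n_rows)   # row 1 = top of visual field (+elevation)
  az <- grid1(n_cols)   # col 1 = left of visual field (+azimuth, CCW)
  ee <- rep(el, each = n_cols)
  aa <- rep(az, times = n_rows)
  dirs <- cbind(cos(ee) * cos(aa), cos(ee) * sin(aa), sin(ee))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 angular_extent = angular_extent, az = az, el = el,
                 dirs = dirs),
            class = "retinal_array")
}

# rotation taking the eye-local frame (+x optical axis) to a world gaze
# direction (heading h, elevation e)
gaze_rotation <- function(h, e) {
  Rz <- matrix(c(cos(h), sin(h), 0, -sin(h), cos(h), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(-e), 0, -sin(-e), 0, 1, 0, sin(-e), 0, cos(-e)), 3, 3)
  Rz %*% Ry
}

#' Binocular field of view
#'
#' Places the two eyes at the head position offset by half the interocular
#' baseline along the head-left axis, points each at the allocentric gaze
#' (left heading `p + omega/2`, right heading `p - omega/2`, shared
#' elevation), and orients the retinal array accordingly. With zero baseline
#' and zero convergence the two eyes coincide.
#'
#' @param pose a `head_pose`.
#' @param eyes an `eye_direction`.
#' @param array a `retinal_array`.
#' @param baseline interocular distance in meters (default 0.06).
#' @return An object of class `field_of_view`: per eye a list with `origin`
#'   (lens position), `gaze` (`(heading, elevation)`), and `dirs` (world-frame
#'   unit line-of-sight directions per retinal cell).
#' @export
field_of_view <- function(pose, eyes, array, baseline = 0.06) {
  if (!inherits(pose, "head_pose")) stop_invalid("`pose` must be a head_pose")
  if (!inherits(eyes, "eye_direction")) {
    stop_invalid("`eyes` must be an eye_direction")
  }
  if (!inherits(array, "retinal_array")) {
    stop_invalid("`array` must be a retinal_array")
  }
  p <- allocentric_gaze(pose$head_dir, eyes$ego_dir)
  w <- eyes$convergence
  hh <- pose$head_dir[1]
  left_axis <- c(-sin(hh), cos(hh), 0)   # head-left, horizontal
  eye_one <- function(side) {
    sgn <- if (side == "left") 1 else -1
    h <- wrap_angle(p[1] + sgn * w / 2)
    origin <- pose$place + sgn * (baseline / 2) * left_axis
    R <- gaze_rotation(h, p[2])
    list(origin = origin, gaze = c(h, p[2]), dirs = array$dirs %*% t(R))
  }
  structure(list(left = eye_one("left"), right = eye_one("right"),
                 gaze = p, array = array, baseline = baseline),
            class = "field_of_view")
}
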