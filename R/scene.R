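#' Affine transform parameters
#'
#' The parameter bundle attached to every component of an object and to every
#' object placement in a room. Application order is fixed: scale (log-scale
#' parameters, see [scale_mesh()]), then rotate (see [rotation_matrix()]),
#' then translate.
#'
#' @param scale length-3 log scale parameters (dimensionless); `c(0,0,0)` is
#'   the identity.
#' @param rotation length-3 Euler angles `(theta, phi, varphi)` in radians.
#' @param translation length-3 offset in meters.
#' @return An object of class `affine_params`.
#' @export
affine_params <- function(scale = c(0, 0, 0), rotation = c(0, 0, 0),
                          translation = c(0, 0, 0)) {
  check_finite(scale, "scale")
  check_finite(rotation, "rotation")
  check_finite(translation, "translation")
  if (length(scale) != 3 || length(rotation) != 3 || length(translation) != 3) {
    stop_invalid("affine parameters must each have 3 components")
  }
  structure(list(scale = as.numeric(scale), rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "affine_params")
}

apply_affine <- function(mesh, params) {
  mesh <- scale_mesh(mesh, params$scale)
  mesh <- rotate_mesh(mesh, params$rotation)
  translate_mesh(mesh, params$translation)
}

# the 4x4 homogeneous matrix equivalent of affine_params (scale->rotate->translate)
affine_matrix <- function(params) {
  S <- diag(exp(params$scale))
  R <- rotation_matrix(params$rotation)
  M <- diag(4)
  M[1:3, 1:3] <- R %*% S
  M[1:3, 4] <- params$translation
  M
}

#' Object specifications
#'
#' An object is either a sphere primitive or a composite: a list of child
#' specs, each paired with the affine parameters that place the assembled
#' child within the parent's frame. Composites nest to arbitrary (finite)
#' depth, so complex shapes are built from configurations of simpler ones.
#'
#' @param label identity label for the object (used by
#'   [lesion_object_hypothesis()]).
#' @param resolution sphere tessellation resolution (see
#'   [make_sphere_mesh()]).
#' @return An object of class `object_spec`.
#' @export
sphere_spec <- function(label = "sphere", resolution = 6) {
  structure(list(kind = "sphere", label = label,
                 resolution = as.integer(resolution)),
            class = "object_spec")
}

#' @rdname sphere_spec
#' @param children list of `list(child = <object_spec>, params =
#'   <affine_params>)` entries; at least one is required.
#' @export
composite_spec <- function(label, children) {
  if (length(children) == 0) stop_invalid("a composite needs >= 1 component")
  for (ch in children) {
    if (!inherits(ch$child, "object_spec") ||
        !inherits(ch$params, "affine_params")) {
      stop_invalid("each child must be list(child = object_spec, params = affine_params)")
    }
  }
  structure(list(kind = "composite", label = label, children = children),
            class = "object_spec")
}

#' Assemble an object's surface mesh
#'
#' Depth-first assembly of the recursive object spec: each child is
#' assembled, then scaled, rotated and translated by its parameters, and all
#' children's faces are concatenated. Deterministic for a given spec.
#'
#' @param spec an `object_spec`.
#' @param depth_limit recursion guard; exceeded depth raises an error rather
#'   than looping forever on a cyclic spec.
#' @return A `surface_mesh`.
#' @export
assemble_object <- function(spec, depth_limit = 32) {
  if (!inherits(spec, "object_spec")) stop_invalid("`spec` must be an object_spec")
  if (depth_limit <= 0) {
    stop_invalid("object spec exceeds the recursion depth limit",
                 class = "activevision_recursion_error")
  }
  if (spec$kind == "sphere") {
    return(make_sphere_mesh(spec$resolution))
  }
  parts <- lapply(spec$children, function(ch) {
    apply_affine(assemble_object(ch$child, depth_limit - 1), ch$params)
  })
  concat_meshes(parts)
}

#' Rooms and room libraries
#'
#' A room is a labelled list of object placements plus optional walls; a
#' room library pairs a list of rooms with a categorical prior over them.
#' The prior is the top of the generative hierarchy: conditioned on the
#' room, the objects present (and hence every surface) are determined.
#'
#' @param label room label.
#' @param placements list of `list(object = <object_spec>, params =
#'   <affine_params>)`; may be empty.
#' @param walls optional `surface_mesh` of bounding walls (see
#'   [make_room_walls()]).
#' @return `room()` returns a `room`; `room_library()` a `room_library`.
#' @export
room <- function(label, placements = list(), walls = NULL) {
  for (pl in placements) {
    if (!inherits(pl$object, "object_spec") ||
        !inherits(pl$params, "affine_params")) {
      stop_invalid("each placement must be list(object = object_spec, params = affine_params)")
    }
  }
  if (!is.null(walls) && !inherits(walls, "surface_mesh")) {
    stop_invalid("`walls` must be a surface_mesh or NULL")
  }
  structure(list(label = label, placements = placements, walls = walls),
            class = "room")
}

#' @rdname room
#' @param rooms list of `room` objects.
#' @param prior probability vector over rooms (non-negative, sums to 1).
#' @export
room_library <- function(rooms, prior = NULL) {
  if (is.null(prior)) prior <- rep(1 / length(rooms), length(rooms))
  check_finite(prior, "prior")
  if (length(prior) != length(rooms)) {
    stop_invalid("`prior` must have one entry per room")
  }
  if (any(prior < 0) || abs(sum(prior) - 1) > 1e-12) {
    stop_invalid("`prior` entries must be >= 0 and sum to 1")
  }
  structure(list(rooms = rooms, prior = as.numeric(prior)),
            class = "room_library")
}

#' Assemble a room's full surface mesh
#'
#' Concatenates the assembled, placed object meshes (walls last, if
#' present). The face count is the sum over components.
#'
#' @param x a `room`.
#' @return A `surface_mesh`.
#' @export
assemble_room <- function(x) {
  if (!inherits(x, "room")) stop_invalid("`x` must be a room")
  parts <- lapply(x$placements, function(pl) {
    apply_affine(assemble_object(pl$object), pl$params)
  })
  if (!is.null(x$walls)) parts <- c(parts, list(x$walls))
  concat_meshes(parts)
}

#' The three-room demonstration world
#'
#' Builds the fixture world used throughout: three 4 x 4 x 3 m rooms under a
#' uniform prior, a viewer position at the room centre, and two object
#' types. Object 1 (a two-sphere "snowman") sits in the southeast corner of
#' rooms 2 and 3 but is absent from room 1; the northeast corner is empty in
#' every room; rooms 2 and 3 differ only in whether object 2 (a prolate
#' ellipsoid) occupies the southwest or the northwest corner (room 1 has
#' object 2 in both). Looking southeast therefore discriminates room 1 from
#' rooms 2-3, looking northeast discriminates nothing, and after seeing
#' object 1 the southwest/northwest corners become the informative views.
#'
#' Compass convention: +x is east, +y is north, z is up; heading is the
#' angle from +x, counterclockwise.
#'
#' @param resolution sphere tessellation used for all objects.
#' @return A `room_library` of three rooms with uniform prior.
#' @export
build_demo_library <- function(resolution = 6) {
  object1 <- composite_spec("object1", list(
    list(child = sphere_spec("object1_base", resolution),
         params = affine_params(scale = rep(log(0.28), 3))),
    list(child = sphere_spec("object1_head", resolution),
         params = affine_params(scale = rep(log(0.20), 3),
                                translation = c(0, 0, 0.38)))
  ))
  object2 <- composite_spec("object2", list(
    list(child = sphere_spec("object2_body", resolution),
         params = affine_params(scale = log(c(0.35, 0.15, 0.15))))
  ))
  se <- affine_params(translation = c(1.3, -1.3, 1.1))
  sw <- affine_params(translation = c(-1.3, -1.3, 1.1))
  nw <- affine_params(translation = c(-1.3, 1.3, 1.1))
  walls <- make_room_walls(c(-2, -2, 0), c(2, 2, 3))
  room_library(list(
    room("room1", list(
      list(object = object2, params = sw),
      list(object = object2, params = nw)
    ), walls = walls),
    room("room2", list(
      list(object = object1, params = se),
      list(object = object2, params = sw)
    ), walls = walls),
    room("room3", list(
      list(object = object1, params = se),
      list(object = object2, params = nw)
    ), walls = walls)
  ), prior = rep(1 / 3, 3))
}

#' Delete an object hypothesis from a room library
#'
#' Models object agnosia at the level of the generative model: every
#' placement of the named object is removed from every room, so nothing
#' sampled from the lesioned model ever contains that object's surfaces.
#' The room prior is unchanged.
#'
#' @param library a `room_library`.
#' @param object_label label of the object spec to delete.
#' @return The lesioned `room_library`.
#' @export
lesion_object_hypothesis <- function(library, object_label) {
  if (!inherits(library, "room_library")) {
    stop_invalid("`library` must be a room_library")
  }
  found <- FALSE
  rooms <- lapply(library$rooms, function(rm) {
    keep <- vapply(rm$placements,
                   function(pl) pl$object$label != object_label, logical(1))
    if (any(!keep)) found <<- TRUE
    room(rm$label, rm$placements[keep], rm$walls)
  })
  if (!found) {
    stop_invalid(sprintf("no placement of object '%s' in any room", object_label),
                 class = "activevision_key_error")
  }
  room_library(rooms, library$prior)
}

## ---- structured-text (JSON) scene configuration ----

spec_to_list <- function(spec) {
  if (spec$kind == "sphere") {
    list(label = spec$label, primitive = "sphere",
         resolution = spec$resolution)
  } else {
    list(label = spec$label, children = lapply(spec$children, function(ch) {
      c(list(object = spec_to_list(ch$child)), params_to_list(ch$params))
    }))
  }
}

params_to_list <- function(p) {
  list(scale = p$scale, rotation_rad = p$rotation, translation = p$translation)
}

list_to_params <- function(x, where) {
  affine_params(
    scale = as.numeric(x$scale %||% c(0, 0, 0)),
    rotation = as.numeric(x$rotation_rad %||% c(0, 0, 0)),
    translation = as.numeric(x$translation %||% c(0, 0, 0))
  )
}

list_to_spec <- function(x, where = "object") {
  if (!is.null(x$primitive)) {
    if (!identical(x$primitive, "sphere")) {
      stop_invalid(sprintf("%s: unknown primitive '%s'", where, x$primitive))
    }
    sphere_spec(x$label %||% "sphere", x$resolution %||% 6)
  } else if (!is.null(x$children)) {
    composite_spec(x$label %||% "object", lapply(seq_along(x$children), function(i) {
      ch <- x$children[[i]]
      list(child = list_to_spec(ch$object, sprintf("%s.children[%d]", where, i)),
           params = list_to_params(ch, where))
    }))
  } else {
    stop_invalid(sprintf("%s: needs either `primitive` or `children`", where))
  }
}

#' Read and write scene configurations
#'
#' Scene configurations are JSON: `{"rooms": [...], "prior": [...]}` with
#' each room `{"label", "walls": {"min", "max"} | null, "placements":
#' [{"object": {...}, "scale", "rotation_rad", "translation"}]}` and each
#' object either `{"primitive": "sphere", "resolution"}` or `{"children":
#' [...]}` nested recursively. Invariants are validated on read and errors
#' name the offending element. `write_scene_config()` followed by
#' `read_scene_config()` reproduces the library.
#'
#' @param path file path of the JSON scene configuration.
#' @return `read_scene_config()` returns a `room_library`.
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("scene file '%s' not found", path))
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$rooms)) stop_invalid("scene config: missing `rooms`")
  rooms <- lapply(seq_along(x$rooms), function(i) {
    rm <- x$rooms[[i]]
    where <- sprintf("rooms[%d]", i)
    walls <- NULL
    if (!is.null(rm$walls)) {
      walls <- make_room_walls(as.numeric(unlist(rm$walls$min)),
                               as.numeric(unlist(rm$walls$max)),
                               ceiling = isTRUE(rm$walls$ceiling))
    }
    placements <- lapply(seq_along(rm$placements %||% list()), function(j) {
      pl <- rm$placements[[j]]
      pw <- sprintf("%s.placements[%d]", where, j)
      list(object = list_to_spec(pl$object, pw),
           params = list_to_params(pl, pw))
    })
    room(rm$label %||% sprintf("room%d", i), placements, walls)
  })
  prior <- as.numeric(unlist(x$prior %||% rep(1 / length(rooms), length(rooms))))
  room_library(rooms, prior)
}

#' @rdname read_scene_config
#' @param library a `room_library` to serialize.
#' @export
write_scene_config <- function(library, path) {
  if (!inherits(library, "room_library")) {
    stop_invalid("`library` must be a room_library")
  }
  rooms <- lapply(library$rooms, function(rm) {
    walls <- NULL
    if (!is.null(rm$walls)) {
      v <- rm$walls$vertices
      walls <- list(min = apply(v, 2, min), max = apply(v, 2, max),
                    ceiling = nrow(rm$walls$faces) >= 12)
    }
    list(label = rm$label, walls = walls,
         placements = lapply(rm$placements, function(pl) {
           c(list(object = spec_to_list(pl$object)), params_to_list(pl$params))
         }))
  })
  jsonlite::write_json(list(rooms = rooms, prior = library$prior), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
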