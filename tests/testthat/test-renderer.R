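test_that("ray casting matches the analytic ray-sphere oracle", {
  sph <- translate_mesh(make_sphere_mesh(24), c(0, 0, 5))
  hit <- cast_ray(c(0, 0, 0), c(0, 0, 1), sph)
  # oracle: nearest root of the ray-sphere quadratic, |p - c|^2 = 1
  # along p = t * (0,0,1), c = (0,0,5): t^2 - 10 t + 24 = 0 -> t = 4
  expect_false(is.null(hit))
  expect_lt(abs(hit$distance - 4), 0.02)   # tessellation error bound
  expect_lt(max(abs(hit$point - c(0, 0, hit$distance))), 1e-9)
  # a ray pointing away from everything misses
  expect_null(cast_ray(c(0, 0, 0), c(0, 0, -1), sph))
})

test_that("equal-distance hits break ties toward the lowest face index", {
  tri <- rbind(c(-1, -1, 2), c(1, -1, 2), c(0, 1, 2))
  stacked <- surface_mesh(tri, rbind(c(1, 2, 3), c(1, 2, 3)))
  hit <- cast_ray(c(0, 0, 0), c(0, 0, 1), stacked)
  expect_identical(hit$face, 1L)
})

test_that("degenerate faces are skipped with a warning", {
  bad <- surface_mesh(rbind(c(0, 0, 1), c(1, 0, 1), c(2, 0, 1),
                            c(-1, -1, 2), c(1, -1, 2), c(0, 1, 2)),
                      rbind(c(1, 2, 3), c(4, 5, 6)))  # face 1 is collinear
  expect_warning(hit <- cast_ray(c(0, 0, 0), c(0, 0, 1), bad),
                 "degenerate")
  expect_identical(hit$face, 2L)
})

test_that("the line-of-sight indicator detects occlusion and misses", {
  target <- surface_mesh(rbind(c(2, -1, -1), c(2, 1, -1), c(2, 0, 1)),
                         rbind(c(1, 2, 3)))
  occluder <- surface_mesh(rbind(c(1, -1, -1), c(1, 1, -1), c(1, 0, 1)),
                           rbind(c(1, 2, 3)))
  pt <- c(2, 0, 0)  # a point on the target face
  expect_identical(eta(c(0, 0, 0), c(1, 0, 0), pt, target), 1L)
  both <- concat_meshes(list(target, occluder))
  expect_identical(eta(c(0, 0, 0), c(1, 0, 0), pt, both), 0L)
  expect_identical(eta(c(0, 0, 0), c(-1, 0, 0), pt, target), 0L)
})

test_that("Blinn-Phong shading obeys its clamps and limiting cases", {
  lt <- light_source(c(0, 0, 1), ambient = 0.1, diffuse = 0.6,
                     specular = 0.3, shininess = 8)
  # normal facing away from the light: no diffuse, ambient + specular only
  v_away <- unit_vec(c(1, 0, -0.2))
  u <- unit_vec(c(0.3, 0, -1))
  h <- unit_vec(u + c(0, 0, 1))
  expect_equal(shade_point(u, v_away, lt, 1L),
               0.1 + 0.3 * max(0, sum(v_away * h))^8)
  # all vectors aligned with the light: ambient + c1 + c2
  z <- c(0, 0, 1)
  expect_equal(shade_point(z, z, lt, 1L), 0.1 + 0.6 + 0.3)
  # shadow: exactly the ambient level regardless of geometry
  expect_equal(shade_point(u, v_away, lt, 0L), 0.1)
  # view exactly opposite the light: specular term defined as 0
  expect_equal(shade_point(-z, z, lt, 1L), 0.1 + 0.6)
})

test_that("render_eye matches an exhaustive per-ray nearest-hit reference", {
  # a small (<= 20 face) scene: distorted tetrahedron + floor triangle
  scene <- concat_meshes(list(
    translate_mesh(generic_mesh(), c(3, 0, 0)),
    surface_mesh(rbind(c(2, -2, -1), c(5, -2, -1), c(3.5, 2, -1)),
                 rbind(c(1, 2, 3)))
  ))
  lt <- light_source(c(0.2, 0.3, 0.93))
  arr <- build_retinal_array(9, 9, 1.0)
  fov <- field_of_view(head_pose(c(0, 0, 0), c(0, 0)), eye_direction(), arr,
                       baseline = 0)
  got <- render_eye(fov$left, scene, lt, arr)
  # independent oracle: brute-force nearest hit + scalar shading per cell
  ref <- matrix(0, 9, 9)
  for (cell in seq_len(nrow(fov$left$dirs))) {
    d <- fov$left$dirs[cell, ]
    hit <- brute_force_hit(fov$left$origin, d, scene)
    if (!is.na(hit$face)) {
      p <- fov$left$origin + hit$dist * d
      n <- scene$normals[hit$face, ]
      sh <- brute_force_hit(p + 1e-6 * n, lt$direction, scene)
      val <- shade_point(d, n, lt, as.integer(is.na(sh$face)))
      i <- (cell - 1) %/% 9 + 1; j <- (cell - 1) %% 9 + 1
      ref[9 + 1 - i, 9 + 1 - j] <- val   # retinal inversion
    }
  }
  expect_lt(max(abs(got - ref)), 1e-12)
})

test_that("shadowed pixels sit at the ambient level and recover when the occluder goes", {
  floor <- surface_mesh(rbind(c(-2, -2, 0), c(2, -2, 0), c(2, 2, 0),
                              c(-2, 2, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 4)))
  occ <- surface_mesh(rbind(c(0.2, -0.4, 1), c(1.0, -0.4, 1),
                            c(1.0, 0.4, 1), c(0.2, 0.4, 1)),
                      rbind(c(1, 2, 3), c(1, 3, 4)))
  lt <- light_source(c(0, 0, 1), ambient = 0.1)
  arr <- build_retinal_array(15, 15, 1.2)
  pose <- head_pose(c(-3, 0, 2.5), c(0, -0.65))
  fov <- field_of_view(pose, eye_direction(), arr, baseline = 0)
  with_occ <- render_eye(fov$left, concat_meshes(list(floor, occ)), lt, arr)
  no_occ <- render_eye(fov$left, floor, lt, arr)
  shadowed <- which(with_occ == lt$ambient & no_occ > 0)
  expect_gt(length(shadowed), 0)
  # shadowed floor pixels carry exactly the ambient intensity; removing the
  # occluder strictly raises them (the diffuse term returns)
  expect_true(all(no_occ[shadowed] >= with_occ[shadowed]))
  expect_gt(max(no_occ[shadowed] - with_occ[shadowed]), 0.1)
})

test_that("the retinal image is inverted across both axes", {
  # a lone small sphere up and to the viewer's left (heading 0: +y is left,
  # +z is up) must activate the lower-right of the retinal image
  sph <- translate_mesh(scale_mesh(make_sphere_mesh(8), rep(log(0.3), 3)),
                        c(3, 0.5, 0.9))
  lt <- light_source()
  arr <- build_retinal_array(15, 15, 40 * pi / 180)
  for (eye in c("left", "right")) {
    fov <- field_of_view(head_pose(c(0, 0, 0), c(0, 0)), eye_direction(),
                         arr, baseline = 0.06)
    img <- render_eye(fov[[eye]], sph, lt, arr)
    on <- which(img > 0, arr.ind = TRUE)
    expect_gt(nrow(on), 0)
    expect_true(all(on[, "row"] > 8))   # lower half
    expect_true(all(on[, "col"] > 8))   # right half
  }
  # shifting the object further egocentric-left moves the blob rightward
  sph2 <- translate_mesh(sph, c(0, 0.4, 0))
  fov <- field_of_view(head_pose(c(0, 0, 0), c(0, 0)), eye_direction(),
                       arr, baseline = 0)
  c1 <- mean(which(render_eye(fov$left, sph, lt, arr) > 0, arr.ind = TRUE)[, "col"])
  c2 <- mean(which(render_eye(fov$left, sph2, lt, arr) > 0, arr.ind = TRUE)[, "col"])
  expect_gt(c2, c1)
})

test_that("DCT blur preserves the mean, is linear, and matches the naive DCT", {
  const <- matrix(3.7, 6, 8)
  expect_lt(max(abs(blur_image(const, 1.5) - const)), 1e-9)
  set.seed(31)
  img <- matrix(stats::runif(48), 6, 8)
  bl <- blur_image(img, 1.2)
  expect_lt(abs(mean(bl) - mean(img)), 1e-9)
  # near-infinite bandwidth: the impulse passes through unchanged
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  expect_lt(max(abs(blur_image(imp, 1e6) - imp)), 1e-6)
  # linearity (unclamped)
  a <- 2.3; b <- -0.7
  i2 <- matrix(stats::runif(48), 6, 8)
  lhs <- blur_image(a * img + b * i2, 1.2, clamp = FALSE)
  rhs <- a * blur_image(img, 1.2, clamp = FALSE) +
    b * blur_image(i2, 1.2, clamp = FALSE)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  # forward transform agrees with the double-sum DCT-II definition
  D6 <- activevision:::dct_matrix(6); D8 <- activevision:::dct_matrix(8)
  expect_lt(max(abs(D6 %*% img %*% t(D8) - naive_dct2(img))), 1e-10)
  # spectral energy never grows
  coef0 <- D6 %*% img %*% t(D8)
  coef1 <- D6 %*% blur_image(img, 1.2, clamp = FALSE) %*% t(D8)
  expect_lte(sum(coef1^2), sum(coef0^2) + 1e-9)
})

test_that("blur clamping only trims numerically tiny negatives", {
  set.seed(32)
  img <- matrix(stats::rexp(16 * 16), 16, 16)
  bl <- blur_image(img, 16 / 6)
  expect_gte(min(bl), 0)
  expect_gte(attr(bl, "min_preclamp"), -1e-6 * max(img))
})

test_that("monocular lesion blanks one eye and leaves the other untouched", {
  lib <- build_demo_library()
  scene <- assemble_room(lib$rooms[[2]])
  arr <- build_retinal_array(12, 12)
  pose <- head_pose(c(0, 0, 1.5), c(-pi / 4, -0.2))
  intact <- render_binocular(pose, eye_direction(), arr, scene,
                             light_source())
  les <- render_binocular(pose, eye_direction(), arr, scene, light_source(),
                          lesion = lesion_config("monocular", eye = "left"))
  expect_true(all(les$left == 0))
  expect_equal(les$right, intact$right)
})

test_that("scene-side removal reproduces the homonymous hemianopia pattern", {
  # two spheres, one per egocentric side; nothing else in the scene
  ball <- scale_mesh(make_sphere_mesh(8), rep(log(0.4), 3))
  scene <- concat_meshes(list(translate_mesh(ball, c(3, 1, 0)),    # left
                              translate_mesh(ball, c(3, -1, 0)))) # right
  arr <- build_retinal_array(14, 14)
  pose <- head_pose(c(0, 0, 0), c(0, 0))
  les <- render_binocular(pose, eye_direction(), arr, scene, light_source(),
                          lesion = lesion_config("hemianopia", side = "right"),
                          baseline = 0.06)
  # right-of-head surfaces project to the left of both retinas, so the left
  # image half is dark in BOTH eyes while the right half still responds
  for (img in list(les$shaded_left, les$shaded_right)) {
    expect_true(all(img[, 1:7] == 0))
    expect_gt(max(img[, 8:14]), 0)
  }
  # a scene entirely on the lesioned side goes completely dark
  right_only <- translate_mesh(ball, c(3, -1, 0))
  dark <- render_binocular(pose, eye_direction(), arr, right_only,
                           light_source(),
                           lesion = lesion_config("scene_side_removal",
                                                  side = "right"))
  expect_true(all(dark$left == 0) && all(dark$right == 0))
})

test_that("coincident eyes see identical images and intensities stay non-negative", {
  lib <- build_demo_library()
  scene <- assemble_room(lib$rooms[[3]])
  arr <- build_retinal_array(12, 12)
  img <- render_binocular(head_pose(c(0, 0, 1.5), c(-pi / 4, -0.2)),
                          eye_direction(), arr, scene, light_source(),
                          baseline = 0)
  expect_lt(max(abs(img$left - img$right)), 1e-9)
  expect_gte(min(img$shaded_left), 0)
  expect_gte(min(img$left), 0)
  # empty scene renders to zero everywhere
  empty <- surface_mesh(matrix(numeric(0), ncol = 3),
                        matrix(integer(0), ncol = 3))
  fov <- field_of_view(head_pose(), eye_direction(), arr, baseline = 0)
  expect_true(all(render_eye(fov$left, empty, light_source(), arr) == 0))
})
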