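# shared fixtures and independent oracles, built in code at test time

# small render context: keeps planner/renderer tests fast while leaving the
# demo-room geometry untouched
small_ctx <- function(n = 16) {
  render_context(array = build_retinal_array(n, n), baseline = 0)
}

# a generic (asymmetric) test mesh: a distorted tetrahedron
generic_mesh <- function() {
  surface_mesh(
    rbind(c(0.2, 0.1, 0.3), c(1.1, -0.2, 0), c(-0.4, 0.9, 0.1),
          c(0.1, 0.2, 1.3)),
    rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  )
}

# independent brute-force nearest-hit reference: per ray, solve the
# barycentric linear system for every face and keep the smallest distance
# (lowest face index on ties)
brute_force_hit <- function(origin, dir, mesh, eps = 1e-9) {
  best <- list(face = NA_integer_, dist = Inf)
  for (f in seq_len(nrow(mesh$faces))) {
    v0 <- mesh$vertices[mesh$faces[f, 1], ]
    e1 <- mesh$vertices[mesh$faces[f, 2], ] - v0
    e2 <- mesh$vertices[mesh$faces[f, 3], ] - v0
    A <- cbind(-dir, e1, e2)
    if (abs(det(A)) < 1e-12) next
    sol <- solve(A, origin - v0)
    tt <- sol[1]; u <- sol[2]; v <- sol[3]
    if (tt > eps && u >= -eps && v >= -eps && u + v <= 1 + eps &&
        tt < best$dist) {
      best <- list(face = f, dist = tt)
    }
  }
  best
}

# flatten a recursive object spec into one homogeneous matrix per sphere
# leaf; the oracle applies each composite matrix to a fresh sphere mesh
flatten_spec_oracle <- function(spec, M = diag(4)) {
  aff4 <- function(p) {
    out <- diag(4)
    out[1:3, 1:3] <- rotation_matrix(p$rotation) %*% diag(exp(p$scale))
    out[1:3, 4] <- p$translation
    out
  }
  if (spec$kind == "sphere") {
    mesh <- make_sphere_mesh(spec$resolution)
    v <- cbind(mesh$vertices, 1) %*% t(M)
    return(list(surface_mesh(v[, 1:3], mesh$faces)))
  }
  do.call(c, lapply(spec$children, function(ch) {
    flatten_spec_oracle(ch$child, M %*% aff4(ch$params))
  }))
}

# random affine parameters and specs for property tests
random_params <- function() {
  affine_params(scale = stats::runif(3, -0.5, 0.5),
                rotation = stats::runif(3, -pi, pi),
                translation = stats::runif(3, -2, 2))
}

random_spec <- function(depth) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    return(sphere_spec(resolution = 4))
  }
  n <- sample(1:3, 1)
  composite_spec("node", lapply(seq_len(n), function(i) {
    list(child = random_spec(depth - 1), params = random_params())
  }))
}

# naive double-sum orthonormal 2-D DCT-II (independent of the package's
# matrix-product implementation)
naive_dct2 <- function(X) {
  n <- nrow(X); m <- ncol(X)
  out <- matrix(0, n, m)
  for (p in 0:(n - 1)) for (q in 0:(m - 1)) {
    s <- 0
    for (i in 0:(n - 1)) for (j in 0:(m - 1)) {
      s <- s + X[i + 1, j + 1] *
        cos(pi * (2 * i + 1) * p / (2 * n)) *
        cos(pi * (2 * j + 1) * q / (2 * m))
    }
    cp <- if (p == 0) sqrt(1 / n) else sqrt(2 / n)
    cq <- if (q == 0) sqrt(1 / m) else sqrt(2 / m)
    out[p + 1, q + 1] <- cp * cq * s
  }
  out
}

# random probability table (rows x cols), strictly positive
random_joint <- function(nr, nc) {
  J <- matrix(stats::rexp(nr * nc), nr, nc)
  J / sum(J)
}

# demo-world policies (shared by planner and acceptance tests)
demo_policies <- function() {
  list(
    southeast = policy("southeast", head_dir = c(-pi / 4, -0.2)),
    northeast = policy("northeast", head_dir = c(pi / 4, -0.2)),
    southwest = policy("southwest", head_dir = c(-3 * pi / 4, -0.2)),
    northwest = policy("northwest", head_dir = c(3 * pi / 4, -0.2))
  )
}
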