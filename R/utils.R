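# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(msg, class = "activevision_invalid_parameter") {
  stop(structure(
    class = c(class, "activevision_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid(sprintf("`%s` must be finite numeric", name))
  }
  invisible(x)
}

# wrap an angle into (-pi, pi]
wrap_angle <- function(a) {
  a - 2 * pi * ceiling((a - pi) / (2 * pi))
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop_invalid("cannot normalize a zero vector")
  v / n
}

# rowwise cross product of a k x 3 matrix with a length-3 vector
cross_rows_vec <- function(A, b) {
  cbind(
    A[, 2] * b[3] - A[, 3] * b[2],
    A[, 3] * b[1] - A[, 1] * b[3],
    A[, 1] * b[2] - A[, 2] * b[1]
  )
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

row_norms <- function(A) sqrt(rowSums(A^2))

as_mat3 <- function(x, name = "x") {
  if (is.null(dim(x))) {
    if (length(x) != 3) stop_invalid(sprintf("`%s` must have 3 components", name))
    x <- matrix(x, ncol = 3)
  }
  if (ncol(x) != 3) stop_invalid(sprintf("`%s` must be a k x 3 matrix", name))
  x
}
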