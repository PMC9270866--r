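# Small vector-geometry helpers shared across modules.

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product for n x 3 matrices.
rowwise_cross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

vec_norm <- function(a) sqrt(sum(a^2))

unit_vec <- function(a) {
  n <- vec_norm(a)
  if (n == 0) stop("cannot normalize a zero vector")
  a / n
}

row_norms <- function(A) sqrt(rowSums(A^2))

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` radians about the (non-zero) `axis`.
#' Used to express rigid motions when testing objectivity of geometry
#' and strain outputs, and to pose phantom states.
#'
#' @param axis length-3 numeric, rotation axis (need not be unit).
#' @param angle rotation angle in radians.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- unit_vec(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Apply a 3x3 linear map (rows are points): X %*% t(M)
apply_linear <- function(X, M) X %*% t(M)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
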