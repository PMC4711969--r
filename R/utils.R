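# Internal helpers shared across modules.

# Canonicalize eigenvalue input: a length-3 vector or an n x 3 matrix of
# sorted (descending) eigenvalues. Returns an n x 3 matrix.
as_eval_matrix <- function(evals, check_sorted = TRUE, check_nonneg = TRUE) {
  if (is.null(dim(evals))) {
    if (length(evals) != 3L)
      stop("eigenvalues must be a length-3 vector or an n x 3 matrix")
    evals <- matrix(as.numeric(evals), nrow = 1L)
  }
  evals <- as.matrix(evals)
  if (ncol(evals) != 3L)
    stop("eigenvalue matrix must have 3 columns (lambda1 >= lambda2 >= lambda3)")
  storage.mode(evals) <- "double"
  ok <- stats::complete.cases(evals)
  if (check_sorted && any(ok) &&
      any(evals[ok, 1L] < evals[ok, 2L] - 1e-300 | evals[ok, 2L] < evals[ok, 3L] - 1e-300))
    stop("eigenvalues must be sorted in descending order")
  if (check_nonneg && any(ok) && any(evals[ok, 3L] < 0))
    stop("eigenvalues must be nonnegative (clamp negatives before invariants)")
  evals
}

# 4x4 identity affine with given voxel sizes (mm).
default_affine <- function(voxdim = c(1, 1, 1)) {
  aff <- diag(4)
  diag(aff)[1:3] <- voxdim
  aff
}

is_affine <- function(x) {
  is.matrix(x) && all(dim(x) == c(4L, 4L)) && all(is.finite(x)) &&
    abs(det(x[1:3, 1:3])) > .Machine$double.eps
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation taking the z-axis onto a given unit direction (any valid choice).
rotation_z_to <- function(dir) {
  dir <- dir / sqrt(sum(dir^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * dir[3] - z[3] * dir[2],
         z[3] * dir[1] - z[1] * dir[3],
         z[1] * dir[2] - z[2] * dir[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(z * dir)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 degrees about x
  }
  rotation_about(v / s, atan2(s, c_))
}

# Uniform random rotation (Arvo-style from three uniforms on current RNG).
random_rotation <- function() {
  u <- stats::runif(3)
  theta <- 2 * pi * u[1]
  phi <- acos(2 * u[2] - 1)
  psi <- 2 * pi * u[3]
  axis <- c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  rotation_about(axis, psi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
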