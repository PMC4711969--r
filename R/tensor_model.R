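# Tensor estimation and eigen-analysis.
#
# In-memory tensor component order is (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz); the
# on-disk NIfTI order is lower-triangular (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz),
# see write_tensor().

#' Diffusion-weighted volume container
#'
#' Bundles a 4D signal array with its gradient table. The gradient table must
#' contain at least one b=0 (T2-weighted reference) volume and at least six
#' non-collinear diffusion-sensitizing directions, the minimum for a tensor
#' fit. Nonzero-b directions are normalized to unit length; b=0 rows may carry
#' zero vectors.
#'
#' @param signal 4D numeric array (x, y, z, gradient), nonnegative.
#' @param bvals numeric vector of b-values in s/mm^2, one per gradient.
#' @param bvecs numeric n x 3 matrix of gradient directions (FSL convention,
#'   transposed to rows here).
#' @param affine 4x4 voxel-to-world (RAS) transform.
#' @param TE echo time in ms (metadata only; the time window over which the
#'   displacement encoded by the tensor accrues).
#' @return An object of class \code{dwi_volume}.
#' @export
dwi_volume <- function(signal, bvals, bvecs, affine = default_affine(), TE = NA_real_) {
  signal <- as.array(signal)
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4D array (x, y, z, gradient); got ",
         length(dim(signal)), " dimensions")
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  dimnames(bvecs) <- NULL
  dimnames(signal) <- NULL
  if (ncol(bvecs) != 3L) stop("bvecs must be an n x 3 matrix")
  n <- dim(signal)[4L]
  if (length(bvals) != n || nrow(bvecs) != n)
    stop(sprintf("gradient count mismatch: %d volumes, %d b-values, %d b-vectors",
                 n, length(bvals), nrow(bvecs)))
  if (!any(bvals == 0))
    stop("at least one b=0 reference volume is required")
  nz <- bvals > 0
  if (sum(nz) < 6L)
    stop("at least 6 nonzero-b gradient directions are required to fit a tensor")
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(nz & nrm < 1e-12))
    stop("zero gradient vector with nonzero b-value")
  bvecs[nz, ] <- bvecs[nz, , drop = FALSE] / nrm[nz]
  if (!is_affine(affine)) stop("affine must be an invertible 4x4 matrix")
  if (any(signal < 0, na.rm = TRUE)) stop("signal must be nonnegative")
  structure(list(signal = signal, bvals = bvals, bvecs = bvecs,
                 affine = affine, TE = TE),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_volume> %d x %d x %d grid, %d gradients (%d b=0), b in [%g, %g] s/mm^2\n",
              d[1], d[2], d[3], d[4], sum(x$bvals == 0), min(x$bvals), max(x$bvals)))
  invisible(x)
}

#' Diffusion tensor field container
#'
#' @param D 4D numeric array (x, y, z, 6) of tensor components in the order
#'   Dxx, Dxy, Dxz, Dyy, Dyz, Dzz (mm^2/s).
#' @param mask logical 3D array; masked-out voxels hold the fill value 0 and
#'   are excluded from all downstream statistics.
#' @param affine 4x4 voxel-to-world transform.
#' @return An object of class \code{tensor_field}.
#' @export
tensor_field <- function(D, mask = NULL, affine = default_affine()) {
  D <- as.array(D)
  if (length(dim(D)) != 4L || dim(D)[4L] != 6L)
    stop("D must be a 4D array with 6 components per voxel")
  dims <- dim(D)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  mask <- array(as.logical(mask), dims)
  if (!is_affine(affine)) stop("affine must be an invertible 4x4 matrix")
  bad <- !is.finite(D)
  if (any(bad)) {
    vox_bad <- apply(array(bad, c(prod(dims), 6L)), 1L, any)
    mask[vox_bad] <- FALSE
    D[bad] <- 0
    message(sum(vox_bad), " voxel(s) with non-finite tensor components masked out")
  }
  D_flat <- array(D, c(prod(dims), 6L))
  D_flat[!mask, ] <- 0
  structure(list(D = array(D_flat, c(dims, 6L)), mask = mask, affine = affine),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf("<tensor_field> %d x %d x %d grid, %d voxels in mask\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

# n x 6 component matrix -> list of symmetric 3x3 reconstruction indices
tensor6_to_mat <- function(d6) {
  matrix(d6[c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3)
}

# Design matrix row for direction g: -b * (gx^2, 2gxgy, 2gxgz, gy^2, 2gygz, gz^2)
dti_design <- function(bvals, bvecs) {
  g <- bvecs
  -bvals * cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                 g[, 2]^2, 2 * g[, 2] * g[, 3], g[, 3]^2)
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Per voxel, solves \code{ln(S_i/S0) = -b_i g_i' D g_i} in the least-squares
#' sense, with S0 the mean of the b=0 volumes. \code{method = "wlls"} weights
#' the log-domain residuals by the squared predicted signal (one-step weighted
#' LLS), the usual correction for the log transform's noise heteroscedasticity.
#' Non-positive signals are clipped to \code{1e-6 * S0} before the log; clip
#' and all-zero-voxel counts are reported via \code{message()}.
#'
#' @param dwi a \code{\link{dwi_volume}}.
#' @param mask optional logical 3D array restricting the fit.
#' @param method \code{"lls"} (default) or \code{"wlls"}.
#' @return A \code{\link{tensor_field}}.
#' @export
fit_tensor <- function(dwi, mask = NULL, method = c("lls", "wlls")) {
  stopifnot(inherits(dwi, "dwi_volume"))
  method <- match.arg(method)
  dims <- dim(dwi$signal)[1:3]
  nvox <- prod(dims)
  sig <- array(dwi$signal, c(nvox, dim(dwi$signal)[4L]))

  if (is.null(mask)) mask <- array(TRUE, dims)
  mask <- as.logical(array(mask, dims))

  b0 <- dwi$bvals == 0
  nz <- !b0
  X <- dti_design(dwi$bvals[nz], dwi$bvecs[nz, , drop = FALSE])
  if (qr(X)$rank < 6L)
    stop("gradient scheme is rank-deficient: fewer than 6 independent directions")

  S0 <- rowMeans(sig[, b0, drop = FALSE])
  zero_vox <- mask & (S0 <= 0)
  if (any(zero_vox)) {
    message(sum(zero_vox), " all-zero signal voxel(s) masked out")
    mask[zero_vox] <- FALSE
  }

  idx <- which(mask)
  D_flat <- matrix(0, nvox, 6L)
  if (length(idx)) {
    S <- sig[idx, nz, drop = FALSE]
    floor_ <- 1e-6 * S0[idx]
    n_clip <- sum(S <= floor_)
    if (n_clip > 0)
      message(n_clip, " non-positive/underflow signal value(s) clipped before log")
    S <- pmax(S, floor_)
    Y <- log(S / S0[idx])           # n_vox x n_grad
    # one unweighted solve for all voxels
    coefs <- t(qr.solve(X, t(Y)))   # n_vox x 6
    if (method == "wlls") {
      # voxelwise weighted refit, weights = predicted squared signal
      W2 <- exp(2 * (coefs %*% t(X)))  # predicted (S/S0)^2
      for (v in seq_along(idx)) {
        w <- W2[v, ]
        XtW <- t(X * w)
        coefs[v, ] <- solve(XtW %*% X, XtW %*% Y[v, ])
      }
    }
    D_flat[idx, ] <- coefs
  }
  tensor_field(array(D_flat, c(dims, 6L)), mask = mask, affine = dwi$affine)
}

#' Predict DWI signals from a tensor field
#'
#' Monoexponential forward model \code{S = S0 exp(-b g' D g)}; the noiseless
#' inverse of \code{\link{fit_tensor}}.
#'
#' @param field a \code{\link{tensor_field}}.
#' @param bvals,bvecs gradient table (b in s/mm^2; directions as rows).
#' @param S0 reference signal level.
#' @return 4D signal array.
#' @export
predict_signal <- function(field, bvals, bvecs, S0 = 1000) {
  stopifnot(inherits(field, "tensor_field"))
  dims <- dim(field$D)[1:3]
  nvox <- prod(dims)
  D_flat <- array(field$D, c(nvox, 6L))
  X <- dti_design(bvals, as.matrix(bvecs))   # n_grad x 6 (includes b=0 rows as 0)
  S <- S0 * exp(D_flat %*% t(X))
  S[!field$mask, ] <- 0
  array(S, c(dims, length(bvals)))
}

#' Eigendecompose a tensor field
#'
#' Per-voxel symmetric eigendecomposition with eigenvalues sorted descending
#' (lambda1 >= lambda2 >= lambda3). Negative eigenvalues -- a noise artifact;
#' the toroidal formulas assume nonnegative eigenvalues -- are clamped to zero
#' and counted. Eigenvector signs are fixed by making each vector's
#' largest-magnitude component positive, for reproducible orientation colors.
#'
#' @param field a \code{\link{tensor_field}}.
#' @param clamp_negative clamp negative eigenvalues to 0 (default TRUE).
#' @return An object of class \code{eigen_system}: \code{values} (x,y,z,3),
#'   \code{vectors} (x,y,z,3,3; \code{vectors[..,,k]} is the k-th eigenvector),
#'   plus \code{mask} and \code{affine}.
#' @export
tensor_eigen <- function(field, clamp_negative = TRUE) {
  stopifnot(inherits(field, "tensor_field"))
  dims <- dim(field$D)[1:3]
  nvox <- prod(dims)
  D_flat <- array(field$D, c(nvox, 6L))
  vals <- matrix(0, nvox, 3L)
  vecs <- array(0, c(nvox, 3L, 3L))
  vecs[, 1L, 1L] <- 1; vecs[, 2L, 2L] <- 1; vecs[, 3L, 3L] <- 1
  idx <- which(field$mask)
  n_neg <- 0L
  for (v in idx) {
    e <- eigen(tensor6_to_mat(D_flat[v, ]), symmetric = TRUE)
    lam <- e$values   # eigen() returns descending for symmetric
    if (clamp_negative && lam[3L] < 0) {
      n_neg <- n_neg + sum(lam < 0)
      lam <- pmax(lam, 0)
    }
    V <- e$vectors
    for (k in 1:3) {
      m <- which.max(abs(V[, k]))
      if (V[m, k] < 0) V[, k] <- -V[, k]
    }
    vals[v, ] <- lam
    vecs[v, , ] <- V
  }
  if (n_neg > 0L)
    message(n_neg, " negative eigenvalue(s) clamped to zero")
  structure(list(values = array(vals, c(dims, 3L)),
                 vectors = array(vecs, c(dims, 3L, 3L)),
                 mask = field$mask, affine = field$affine),
            class = "eigen_system")
}

#' @export
print.eigen_system <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<eigen_system> %d x %d x %d grid, %d voxels in mask\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

# Flatten an eigen_system (masked voxels only) to an n x 3 eigenvalue matrix.
eigen_values_matrix <- function(eigs, masked_only = TRUE) {
  dims <- dim(eigs$values)[1:3]
  m <- array(eigs$values, c(prod(dims), 3L))
  if (masked_only) m[eigs$mask, , drop = FALSE] else m
}

#' Westin-style geometric shape metrics
#'
#' Linear, planar and spherical shape coefficients
#' \code{CL = (l1 - l2)/sum}, \code{CP = 2 (l2 - l3)/sum},
#' \code{CS = 3 l3/sum}; a barycentric decomposition with
#' \code{CL + CP + CS = 1}. For a zero tensor (sum of eigenvalues 0) the
#' degenerate convention \code{(CL, CP, CS) = (0, 0, 1)} is returned with a
#' warning: the zero tensor has no preferred direction.
#'
#' @param evals length-3 vector or n x 3 matrix of sorted nonnegative
#'   eigenvalues.
#' @return n x 3 matrix with columns CL, CP, CS.
#' @export
shape_metrics <- function(evals) {
  ev <- as_eval_matrix(evals)
  s <- rowSums(ev)
  zero <- s <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-trace tensor(s): shape metrics set to (0, 0, 1)")
    s[zero] <- 1
  }
  out <- cbind(CL = (ev[, 1] - ev[, 2]) / s,
               CP = 2 * (ev[, 2] - ev[, 3]) / s,
               CS = 3 * ev[, 3] / s)
  out[zero, ] <- rep(c(0, 0, 1), each = sum(zero))
  out
}

#' Classify the eigenvalue configuration of each tensor
#'
#' Four-way degeneracy classes: ORTHOTROPIC (l1 > l2 > l3), PROLATE
#' (l1 > l2 = l3, transversely isotropic), OBLATE (l1 = l2 > l3), ISOTROPIC
#' (l1 = l2 = l3). Equality \code{li = lj} is declared when
#' \code{(li - lj)/l1 <= rel_tol}; the classification is therefore invariant
#' to uniform scaling of the eigenvalues. A zero tensor is ISOTROPIC by
#' convention.
#'
#' @param evals length-3 vector or n x 3 matrix of sorted nonnegative
#'   eigenvalues.
#' @param rel_tol relative equality tolerance (default 0.05).
#' @return factor with levels ORTHOTROPIC, PROLATE, OBLATE, ISOTROPIC.
#' @export
classify_configuration <- function(evals, rel_tol = 0.05) {
  ev <- as_eval_matrix(evals)
  l1 <- ev[, 1]
  safe_l1 <- ifelse(l1 > 0, l1, 1)
  eq12 <- (ev[, 1] - ev[, 2]) / safe_l1 <= rel_tol
  eq23 <- (ev[, 2] - ev[, 3]) / safe_l1 <= rel_tol
  lab <- ifelse(l1 <= 0, "ISOTROPIC",
         ifelse(eq12 & eq23, "ISOTROPIC",
         ifelse(eq12, "OBLATE",
         ifelse(eq23, "PROLATE", "ORTHOTROPIC"))))
  factor(lab, levels = c("ORTHOTROPIC", "PROLATE", "OBLATE", "ISOTROPIC"))
}

#' Display colors for the eigenvalue-configuration classes
#'
#' Purple (orthotropic), orange (prolate), green (oblate), gray (isotropic).
#'
#' @return named 4 x 3 RGB matrix in \code{[0, 1]}.
#' @export
config_colors <- function() {
  m <- rbind(ORTHOTROPIC = c(0.5, 0, 0.5),
             PROLATE     = c(1, 0.55, 0),
             OBLATE      = c(0, 0.6, 0),
             ISOTROPIC   = c(0.5, 0.5, 0.5))
  colnames(m) <- c("r", "g", "b")
  m
}
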