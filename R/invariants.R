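# Scalar invariants: MD, FA (classical) and TV, TC (toroidal).
#
# The toroidal surface is
#   T(theta, phi) = ( cos(theta) (alpha + beta cos(phi)),
#                     sin(theta) (alpha + beta cos(phi)),
#                     gamma sin(phi) ),
# with alpha = (2 l2 + l3)/4, beta = l3/4, gamma = l1/2: l1 is the extent
# along the rotational axis, l2 the diameter of the central opening, and
# l3/2 the thickness of the toroidal cross-section. TC is computed on the
# l1-normalized surface (alpha' = alpha/l1, beta' = beta/l1, gamma' = 1/2),
# so it is a dimensionless curvature, not in physical mm^-2 s^2 units.

#' Mean diffusivity
#'
#' Arithmetic mean of the eigenvalues, \code{(l1 + l2 + l3)/3} (mm^2/s):
#' the average displacement of a water molecule over the echo time.
#'
#' @param evals length-3 vector or n x 3 matrix of sorted nonnegative
#'   eigenvalues.
#' @return numeric vector.
#' @export
mean_diffusivity <- function(evals) {
  ev <- as_eval_matrix(evals)
  rowMeans(ev)
}

#' Fractional anisotropy
#'
#' \deqn{FA = \sqrt{\tfrac{1}{2}
#'   \frac{(l_1-l_2)^2 + (l_2-l_3)^2 + (l_1-l_3)^2}{l_1^2+l_2^2+l_3^2}}}
#' Dimensionless, in \code{[0, 1]}; 0 for isotropy, 1 for a purely linear
#' tensor. The all-zero tensor is assigned FA = 0 (limit convention) with a
#' warning.
#'
#' @inheritParams mean_diffusivity
#' @return numeric vector in \code{[0, 1]}.
#' @export
fractional_anisotropy <- function(evals) {
  ev <- as_eval_matrix(evals)
  ss <- rowSums(ev^2)
  zero <- ss <= 0
  if (any(zero)) {
    warning(sum(zero), " zero tensor(s): FA set to 0")
    ss[zero] <- 1
  }
  num <- (ev[, 1] - ev[, 2])^2 + (ev[, 2] - ev[, 3])^2 + (ev[, 1] - ev[, 3])^2
  fa <- sqrt(0.5 * num / ss)
  fa[zero] <- 0
  pmin(fa, 1)
}

#' Toroid parameters from eigenvalues
#'
#' \code{alpha = (2 l2 + l3)/4}, \code{beta = l3/4}, \code{gamma = l1/2}
#' (mm^2/s), plus the l1-normalized \code{alpha_p}, \code{beta_p},
#' \code{gamma_p} (dimensionless; \code{gamma_p} is always 1/2). For
#' \code{l1 = 0} the normalized parameters are NA and the voxel is flagged
#' \code{degenerate}.
#'
#' @inheritParams mean_diffusivity
#' @return data.frame with columns alpha, beta, gamma, alpha_p, beta_p,
#'   gamma_p, degenerate.
#' @export
toroid_params <- function(evals) {
  ev <- as_eval_matrix(evals)
  alpha <- (2 * ev[, 2] + ev[, 3]) / 4
  beta <- ev[, 3] / 4
  gamma <- ev[, 1] / 2
  deg <- ev[, 1] <= 0
  l1 <- ifelse(deg, NA_real_, ev[, 1])
  data.frame(alpha = alpha, beta = beta, gamma = gamma,
             alpha_p = alpha / l1, beta_p = beta / l1,
             gamma_p = gamma / l1, degenerate = deg)
}

#' Toroidal volume (TV)
#'
#' \deqn{TV = (l_1 \pi / 3)\,(l_2 l_3 + l_3^2/2)}
#' A volumetric diffusivity index (mm^6/s^3), nonlinear in the eigenvalues
#' (it involves their product, unlike the affine MD). TV = 0 whenever
#' \code{l3 = 0}. Note TV follows this printed form, not the geometric volume
#' enclosed by the toroidal surface, which is \code{2 pi^2 alpha beta gamma =
#' (pi^2/8) l1 (l2 l3 + l3^2/2)} -- the two differ by the constant factor
#' \code{3 pi / 8}.
#'
#' @inheritParams mean_diffusivity
#' @return numeric vector, nonnegative.
#' @export
toroidal_volume <- function(evals) {
  ev <- as_eval_matrix(evals)
  (ev[, 1] * pi / 3) * (ev[, 2] * ev[, 3] + ev[, 3]^2 / 2)
}

#' Gaussian curvature profile of the normalized toroidal surface
#'
#' Closed-form Gaussian curvature of the toroidal surface as a function of
#' the polar angle phi:
#' \deqn{tc(\phi) = \frac{4 \beta' \gamma'^2 \cos\phi}
#'   {(\alpha' + \beta'\cos\phi)\,[\beta'^2 + \gamma'^2 +
#'    (\gamma'^2 - \beta'^2)\cos 2\phi]^2}}
#' which equals \eqn{\beta'\gamma'^2\cos\phi / ((\alpha'+\beta'\cos\phi)
#' (\beta'^2\sin^2\phi + \gamma'^2\cos^2\phi)^2)}, the curvature obtained
#' from the first and second fundamental forms. When \code{beta_p = gamma_p}
#' it reduces to the classical circular-torus curvature
#' \code{cos(phi) / (beta_p (alpha_p + beta_p cos(phi)))}.
#'
#' @param phi polar angle(s), radians.
#' @param alpha_p,beta_p,gamma_p normalized toroid parameters (scalars);
#'   \code{alpha_p + beta_p cos(phi)} must stay positive.
#' @return numeric vector of curvatures, same length as \code{phi}.
#' @export
tc_profile <- function(phi, alpha_p, beta_p, gamma_p = 0.5) {
  stopifnot(length(alpha_p) == 1L, length(beta_p) == 1L, length(gamma_p) == 1L)
  if (beta_p < 0 || gamma_p <= 0 || alpha_p < beta_p)
    stop("invalid toroid parameters: need alpha_p >= beta_p >= 0, gamma_p > 0")
  ring <- alpha_p + beta_p * cos(phi)
  if (any(ring <= 0))
    stop("singular geometry: alpha_p + beta_p*cos(phi) <= 0")
  br <- beta_p^2 + gamma_p^2 + (gamma_p^2 - beta_p^2) * cos(2 * phi)
  4 * beta_p * gamma_p^2 * cos(phi) / (ring * br^2)
}

# Vectorized-over-voxels curvature evaluation on a shared phi grid.
# a, b: vectors (alpha_p, beta_p); phi: vector; returns length(a) x length(phi).
tc_profile_grid <- function(a, b, phi, gamma_p = 0.5) {
  cph <- cos(phi)
  c2ph <- cos(2 * phi)
  ring <- outer(a, rep(1, length(phi))) + outer(b, cph)
  br <- outer(b^2, rep(1, length(phi))) + gamma_p^2 +
    outer(gamma_p^2 - b^2, c2ph)
  4 * outer(b, cph) * gamma_p^2 / (ring * br^2)
}

#' Toroidal curvature (TC)
#'
#' The maximum Gaussian curvature of the l1-normalized toroidal surface:
#' \code{TC = max over phi in [0, pi] of tc(phi)} (see
#' \code{\link{tc_profile}}). Because only the l1-normalized parameters
#' enter, TC is invariant to uniform scaling of the eigenvalues. The maximum
#' can be interior (not at phi = 0) whenever \code{gamma_p > beta_p}, so it
#' is located by a dense grid search followed by bounded golden-section
#' refinement (\code{stats::optimize}); no closed-form argmax is attempted.
#' For \code{l1 = 0} TC is undefined and 0 is returned.
#'
#' @inheritParams mean_diffusivity
#' @param n_grid number of phi grid points on \code{[0, pi]} (default 2048).
#' @param refine refine the grid maximum with \code{stats::optimize}
#'   (default TRUE).
#' @return numeric vector of dimensionless curvature maxima, >= 0.
#' @export
toroidal_curvature <- function(evals, n_grid = 2048L, refine = TRUE) {
  ev <- as_eval_matrix(evals)
  n <- nrow(ev)
  out <- numeric(n)
  ok <- ev[, 1] > 0
  if (!any(ok)) return(out)
  a <- (2 * ev[ok, 2] + ev[ok, 3]) / (4 * ev[ok, 1])
  b <- ev[ok, 3] / (4 * ev[ok, 1])
  phi <- seq(0, pi, length.out = n_grid)
  tcv <- numeric(sum(ok))
  chunk <- max(1L, floor(4e6 / n_grid))
  starts <- seq(1L, length(a), by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, length(a))
    prof <- tc_profile_grid(a[s:e], b[s:e], phi)
    jmax <- max.col(prof, ties.method = "first")
    vmax <- prof[cbind(seq_len(e - s + 1L), jmax)]
    if (refine) {
      for (i in seq_len(e - s + 1L)) {
        if (b[s + i - 1L] <= 0) { tcv[s + i - 1L] <- 0; next }
        j <- jmax[i]
        lo <- phi[max(1L, j - 1L)]
        hi <- phi[min(n_grid, j + 1L)]
        if (hi > lo) {
          ai <- a[s + i - 1L]; bi <- b[s + i - 1L]
          opt <- stats::optimize(function(p) tc_profile(p, ai, bi),
                                 interval = c(lo, hi), maximum = TRUE,
                                 tol = 1e-10)
          tcv[s + i - 1L] <- max(opt$objective, vmax[i])
        } else tcv[s + i - 1L] <- vmax[i]
      }
    } else {
      tcv[s:e] <- pmax(vmax, 0)
    }
  }
  out[ok] <- pmax(tcv, 0)
  out
}

#' Scalar map container
#'
#' @param values 3D numeric array.
#' @param mask logical 3D array; masked-out voxels hold 0 and are excluded
#'   from statistics and normalization.
#' @param affine 4x4 voxel-to-world transform.
#' @param name invariant name tag (e.g. "MD", "FA", "TV", "TC").
#' @param units unit string ("mm^2/s", "", "mm^6/s^3", ...).
#' @return An object of class \code{scalar_map}.
#' @export
scalar_map <- function(values, mask = NULL, affine = default_affine(),
                       name = "map", units = "") {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  mask <- array(as.logical(mask), dim(values))
  values[!mask] <- 0
  if (any(!is.finite(values)))
    stop("scalar map contains non-finite values inside the mask")
  structure(list(values = values, mask = mask, affine = affine,
                 name = name, units = units),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<scalar_map> %s [%s], %d voxels, range [%g, %g]\n",
              x$name, x$units, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

map_units <- c(MD = "mm^2/s", FA = "", TV = "mm^6/s^3", TC = "")

#' Compute a scalar invariant map over a tensor field
#'
#' @param x a \code{\link{tensor_field}} or \code{eigen_system}.
#' @param which one of "MD", "FA", "TV", "TC".
#' @param ... passed to \code{\link{toroidal_curvature}} for TC.
#' @return A \code{\link{scalar_map}}.
#' @export
compute_map <- function(x, which = c("MD", "FA", "TV", "TC"), ...) {
  which <- match.arg(which)
  eigs <- if (inherits(x, "tensor_field")) tensor_eigen(x) else x
  if (!inherits(eigs, "eigen_system")) stop("x must be a tensor_field or eigen_system")
  dims <- dim(eigs$values)[1:3]
  ev <- eigen_values_matrix(eigs, masked_only = FALSE)
  ev <- pmax(ev, 0)  # masked voxels are zero-filled; clamp guards stragglers
  idx <- which(eigs$mask)
  vals <- numeric(prod(dims))
  f <- switch(which,
              MD = mean_diffusivity,
              FA = function(e) suppressWarnings(fractional_anisotropy(e)),
              TV = toroidal_volume,
              TC = function(e) toroidal_curvature(e, ...))
  if (length(idx)) vals[idx] <- f(ev[idx, , drop = FALSE])
  scalar_map(array(vals, dims), mask = eigs$mask, affine = eigs$affine,
             name = which, units = map_units[[which]])
}

#' Min-max normalize a scalar map to [0, 1]
#'
#' Rescales over unmasked voxels only. A constant map normalizes to all
#' zeros (so constant backgrounds render dark rather than dividing by zero).
#'
#' @param map a \code{\link{scalar_map}}.
#' @return A \code{\link{scalar_map}} with values in \code{[0, 1]}.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  v <- map$values[map$mask]
  if (!length(v)) stop("cannot normalize a map with an empty mask")
  rng <- range(v)
  out <- map$values
  if (rng[2] > rng[1]) {
    out[map$mask] <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    out[map$mask] <- 0
  }
  out[!map$mask] <- 0
  scalar_map(out, mask = map$mask, affine = map$affine,
             name = paste0(map$name, "_norm"), units = "")
}
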