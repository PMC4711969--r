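# Synthetic brain-like tensor phantoms: a spherical high-diffusivity
# near-isotropic "tumor core", a surrounding intermediate-diffusivity
# "edema" shell, anisotropic white-matter bundles (one straight, one 90-degree
# arc, so orientation encodings are exercised), and near-isotropic gray-matter
# background. Default eigenvalues are literature-typical brain values (mm^2/s)
# chosen to produce the qualitative regional orderings a GBM cohort shows
# (MD/TV: tumor > edema > parenchyma; FA/TC: WM >> GM); they are synthetic
# defaults, not measured values.

REGION_LEVELS <- c("tumor", "edema", "GM", "WM")

#' Phantom specification
#'
#' Geometry, per-region eigenvalues, and randomness controls for
#' \code{\link{generate_phantom}}. All eigenvalues in mm^2/s; geometry in
#' voxel units relative to \code{shape}.
#'
#' @param shape grid dimensions (x, y, z), default \code{c(32, 32, 16)}.
#' @param evals named list of length-3 descending eigenvalue triples for
#'   tumor, edema, GM, WM.
#' @param tumor_center,tumor_radius tumor-core sphere (voxel units); defaults
#'   scale with the grid.
#' @param edema_thickness edema shell thickness in voxels.
#' @param gm_box GM sampling-box half-width in voxels.
#' @param voxel_size isotropic voxel size in mm.
#' @param equal_volume trim every ROI label to the same voxel count (the
#'   equal-volume sampling design), keeping voxels nearest each region's
#'   reference point.
#' @param seed RNG seed used by \code{\link{generate_phantom}} for random
#'   isotropic-region orientations.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 16L),
                         evals = list(tumor = c(1.8e-3, 1.7e-3, 1.6e-3),
                                      edema = c(1.3e-3, 1.1e-3, 1.0e-3),
                                      GM    = c(0.9e-3, 0.8e-3, 0.75e-3),
                                      WM    = c(1.7e-3, 0.4e-3, 0.3e-3)),
                         tumor_center = NULL, tumor_radius = NULL,
                         edema_thickness = NULL, gm_box = NULL,
                         voxel_size = 2.5, equal_volume = TRUE, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  if (!all(REGION_LEVELS %in% names(evals)))
    stop("evals must name tumor, edema, GM and WM triples")
  for (r in REGION_LEVELS) {
    ev <- evals[[r]]
    if (length(ev) != 3L || any(diff(ev) > 0) || any(ev < 0))
      stop("evals$", r, " must be a descending nonnegative triple")
  }
  structure(list(
    shape = shape,
    evals = evals[REGION_LEVELS],
    tumor_center = tumor_center %||% c(0.62, 0.30, 0.50) * shape,
    tumor_radius = tumor_radius %||% 0.125 * shape[1],
    edema_thickness = edema_thickness %||% 0.09 * shape[1],
    gm_box = gm_box %||% max(3, round(0.09 * shape[1])),
    voxel_size = voxel_size,
    equal_volume = isTRUE(equal_volume),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' ROI label set container
#'
#' @param labels integer 3D array: 0 = background, 1 = tumor, 2 = edema,
#'   3 = GM, 4 = WM.
#' @param affine 4x4 voxel-to-world transform.
#' @return An object of class \code{roi_set}.
#' @export
roi_set <- function(labels, affine = default_affine()) {
  labels <- array(as.integer(labels), dim(as.array(labels)))
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (any(!labels %in% 0:4)) stop("labels must be integers in 0..4")
  structure(list(labels = labels, affine = affine,
                 region_names = REGION_LEVELS), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  n <- vapply(1:4, function(l) sum(x$labels == l), integer(1))
  cat(sprintf("<roi_set> %s voxels (tumor/edema/GM/WM)\n",
              paste(n, collapse = "/")))
  invisible(x)
}

#' Generate a brain-like synthetic tensor phantom
#'
#' Paints the four region types with precedence tumor core > edema > WM > GM
#' (overlaps are resolved in that order), assigns each voxel the tensor
#' \code{R diag(lambda) R'} with R aligned to the local tract tangent in WM
#' bundles and drawn uniformly at random for the (near-)isotropic regions,
#' and returns the tensor field together with ROI labels. Deterministic given
#' \code{spec$seed}.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with elements \code{field} (a \code{\link{tensor_field}}) and
#'   \code{rois} (a \code{\link{roi_set}}).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dm <- spec$shape
  affine <- default_affine(rep(spec$voxel_size, 3))
  coords <- cbind(rep(seq_len(dm[1]), times = dm[2] * dm[3]),
                  rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
                  rep(seq_len(dm[3]), each = dm[1] * dm[2]))

  region <- integer(prod(dm))          # 0=GM background, 1=tumor, 2=edema, 4=WM
  tangent <- matrix(0, prod(dm), 3L)

  # WM straight bundle along +y, left side of the grid
  zb <- round(c(0.31, 0.69) * dm[3])
  xs <- round(c(0.06, 0.17) * dm[1])
  straight <- coords[, 1] >= xs[1] & coords[, 1] <= xs[2] &
    coords[, 3] >= zb[1] & coords[, 3] <= zb[2]
  region[straight] <- 4L
  tangent[straight, ] <- rep(c(0, 1, 0), each = sum(straight))

  # WM 90-degree arc bundle in the xy-plane, centered near the grid origin
  arc_c <- c(2, 2); arc_r <- 0.40 * dm[1]; arc_h <- 0.05 * dm[1] + 1
  dxy <- sqrt((coords[, 1] - arc_c[1])^2 + (coords[, 2] - arc_c[2])^2)
  arc <- abs(dxy - arc_r) <= arc_h &
    coords[, 3] >= zb[1] & coords[, 3] <= zb[2] &
    coords[, 1] >= arc_c[1] & coords[, 2] >= arc_c[2] & region == 0L
  psi <- atan2(coords[arc, 2] - arc_c[2], coords[arc, 1] - arc_c[1])
  region[arc] <- 4L
  tangent[arc, ] <- cbind(-sin(psi), cos(psi), 0)

  # tumor core sphere and edema shell (precedence over WM)
  dist_t <- sqrt(rowSums(sweep(coords, 2L, spec$tumor_center)^2))
  shell <- dist_t <= spec$tumor_radius + spec$edema_thickness
  n_overlap <- sum(shell & region == 4L)
  if (n_overlap > 0)
    message(n_overlap, " WM voxel(s) overridden by tumor/edema precedence")
  region[shell] <- 2L
  region[dist_t <= spec$tumor_radius] <- 1L

  # region -> eigenvalues; orientation
  ev_by_region <- rbind(spec$evals$GM, spec$evals$tumor, spec$evals$edema,
                        NA, spec$evals$WM)   # index region+1
  D <- matrix(0, prod(dm), 6L)
  for (v in seq_len(prod(dm))) {
    lam <- ev_by_region[region[v] + 1L, ]
    if (region[v] == 4L) {
      # columns: e1 = tract tangent, e2/e3 span the normal plane
      e1 <- tangent[v, ]
      e2 <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e2 <- e2 - sum(e2 * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
      e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      R <- cbind(e1, e2, e3)
    } else {
      R <- random_rotation()
    }
    Dm <- R %*% diag(lam) %*% t(R)
    D[v, ] <- Dm[c(1, 4, 7, 5, 8, 9)]   # Dxx, Dxy, Dxz, Dyy, Dyz, Dzz
  }
  field <- tensor_field(array(D, c(dm, 6L)), affine = affine)

  # ROI labels: 1 tumor, 2 edema, 3 GM sampling box, 4 WM
  labels <- region
  gm_c <- round(c(0.75, 0.78, 0.5) * dm)
  gm_in <- abs(coords[, 1] - gm_c[1]) <= spec$gm_box &
    abs(coords[, 2] - gm_c[2]) <= spec$gm_box &
    abs(coords[, 3] - gm_c[3]) <= max(2, round(spec$gm_box * dm[3] / dm[1])) &
    region == 0L
  labels[gm_in] <- 3L

  if (spec$equal_volume) {
    counts <- vapply(1:4, function(l) sum(labels == l), integer(1))
    if (any(counts == 0L)) stop("empty ROI in phantom: ", REGION_LEVELS[counts == 0L][1])
    n_keep <- min(counts)
    refs <- rbind(spec$tumor_center, spec$tumor_center, gm_c,
                  c(mean(xs), 0.5 * dm[2], 0.5 * dm[3]))
    new_labels <- integer(length(labels))
    for (l in 1:4) {
      idx <- which(labels == l)
      d <- rowSums(sweep(coords[idx, , drop = FALSE], 2L, refs[l, ])^2)
      new_labels[idx[order(d)[seq_len(n_keep)]]] <- l
    }
    labels <- new_labels
  }
  list(field = field, rois = roi_set(array(labels, dm), affine = affine))
}

#' Deterministic DTI gradient table
#'
#' \code{n_b0} null gradients followed by \code{n_dirs} diffusion directions
#' placed by a spherical Fibonacci spiral on the upper hemisphere (a
#' well-spread deterministic scheme).
#'
#' @param n_dirs number of diffusion-sensitizing directions (default 32).
#' @param bval b-value in s/mm^2 for the sensitized volumes (default 800).
#' @param n_b0 number of b=0 reference volumes (default 1).
#' @return list with \code{bvals} and n x 3 \code{bvecs}.
#' @export
gradient_table <- function(n_dirs = 32L, bval = 800, n_b0 = 1L) {
  stopifnot(n_dirs >= 6L, n_b0 >= 1L, bval > 0)
  i <- seq_len(n_dirs) - 0.5
  z <- i / n_dirs
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n_dirs) - 1L)
  dirs <- cbind(r * cos(th), r * sin(th), z)
  list(bvals = c(rep(0, n_b0), rep(bval, n_dirs)),
       bvecs = rbind(matrix(0, n_b0, 3L), dirs))
}

#' Synthesize diffusion-weighted signals from a tensor field
#'
#' Monoexponential model \code{S_i = S0 exp(-b_i g_i' D g_i)} plus optional
#' noise: Rician (the magnitude-MRI standard: independent Gaussian noise of
#' scale \code{sigma * S0} on two quadrature channels, then the magnitude) or
#' plain Gaussian for debugging. \code{sigma = 0} returns noiseless signals.
#'
#' @param field a \code{\link{tensor_field}}.
#' @param bvals,bvecs gradient table; see \code{\link{gradient_table}}.
#' @param S0 b=0 signal level (default 1000).
#' @param sigma noise scale as a fraction of S0 (default 0).
#' @param seed RNG seed (required when \code{sigma > 0}).
#' @param noise "rician" (default) or "gaussian".
#' @return A \code{\link{dwi_volume}}.
#' @export
synthesize_dwi <- function(field, bvals, bvecs, S0 = 1000, sigma = 0,
                           seed = NULL, noise = c("rician", "gaussian")) {
  stopifnot(inherits(field, "tensor_field"))
  noise <- match.arg(noise)
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma > 0 && is.null(seed)) stop("a seed is required for noisy synthesis")
  S <- predict_signal(field, bvals, bvecs, S0 = S0)
  if (sigma > 0) {
    set.seed(seed)
    s <- sigma * S0
    n <- length(S)
    if (noise == "rician") {
      S <- array(sqrt((as.vector(S) + stats::rnorm(n, 0, s))^2 +
                      stats::rnorm(n, 0, s)^2), dim(S))
    } else {
      S <- array(pmax(as.vector(S) + stats::rnorm(n, 0, s), 0), dim(S))
    }
  }
  dwi_volume(S, bvals, bvecs, affine = field$affine)
}

#' Generate a multi-subject phantom cohort
#'
#' Replicates the phantom across subjects with per-subject multiplicative
#' eigenvalue jitter: one lognormal factor with log-sd \code{jitter_sd} per
#' (subject, region), applied to the whole eigenvalue triple, so the
#' cross-subject coefficient of variation of each region's MD is about
#' \code{jitter_sd}. Per-subject seeds are derived from the master seed by
#' fixed increments.
#'
#' @param n_subjects number of subjects (>= 2; default 18).
#' @param spec a \code{\link{phantom_spec}} used as template.
#' @param jitter_sd lognormal sd of the per-region scale factors
#'   (default 0.05).
#' @param seed master seed.
#' @return list of per-subject lists with \code{field} and \code{rois}.
#' @export
generate_cohort <- function(n_subjects = 18L, spec = phantom_spec(),
                            jitter_sd = 0.05, seed = 1L) {
  stopifnot(n_subjects >= 2L, jitter_sd >= 0)
  lapply(seq_len(n_subjects), function(s) {
    subj_seed <- as.integer(seed) + 1000L * s
    set.seed(subj_seed)
    fac <- stats::rlnorm(4L, meanlog = 0, sdlog = jitter_sd)
    names(fac) <- REGION_LEVELS
    ev <- lapply(REGION_LEVELS, function(r) spec$evals[[r]] * fac[[r]])
    names(ev) <- REGION_LEVELS
    sp <- spec
    sp$evals <- ev
    sp$seed <- subj_seed
    generate_phantom(sp)
  })
}
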