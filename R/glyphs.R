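# Supertoroidal / toroidal glyph geometry and color encodings.
#
# Both surfaces are sampled on a closed (theta, phi) grid over [0, 2pi)^2
# without duplicated seam rows; faces wrap around, so the raw quad mesh is
# topologically a torus. Degenerate shapes (collapsed amplitudes, pole rings)
# are handled by coordinate welding and face deduplication in tessellate().

#' Sign-preserving power
#'
#' \code{sign(x) * |x|^eta}: the superquadric convention for
#' \code{cos^eta}/\code{sin^eta} terms, continuous and odd in \code{x}
#' (a plain power of a negative base is undefined for fractional exponents).
#'
#' @param x numeric.
#' @param eta positive exponent.
#' @return numeric, same shape as \code{x}.
#' @export
signed_power <- function(x, eta) {
  stopifnot(all(eta > 0))
  sign(x) * abs(x)^eta
}

new_surface_grid <- function(x, y, z, degenerate_hint = FALSE) {
  structure(list(x = x, y = y, z = z, degenerate_hint = degenerate_hint),
            class = "surface_grid")
}

#' Supertoroidal glyph surface
#'
#' Parametric supertoroid driven by the shape metrics (CL, CP, CS). With
#' \code{c = CS >= CP} selecting the branch, the surface is
#' \deqn{x = \cos^{\eta_1}\theta \,\{A + B\cos^{\eta_2}\phi\},\quad
#'       y = \sin^{\eta_1}\theta \,\{A + B\cos^{\eta_2}\phi\},\quad
#'       z = \sin^{\eta_2}\phi,}
#' where \code{(A, B) = (CL + CP, CS)} when \code{CS >= CP} and
#' \code{(CS, CL + CP)} otherwise, and the exponents
#' \code{eta1 = (1 - CP)^gamma1}, \code{eta2 = (1 - CP)^gamma2} blend between
#' shapes (powers are sign-preserving, see \code{\link{signed_power}}).
#' \code{gamma1} controls the sharpness in the medium/minor diffusion
#' directions and \code{gamma2} the shape along the rotational axis, which is
#' aligned with the principal diffusion direction. In the isotropic limit
#' (CS = 1) the ring amplitude vanishes and the glyph closes into a genus-0
#' blob with no central opening; at high linear anisotropy it collapses
#' toward a ring. The z-amplitude is unity (no CS/CL scaling).
#'
#' @param metrics length-3 vector (CL, CP, CS), each in \code{[0, 1]},
#'   summing to 1.
#' @param gamma1 sharpness exponent (default 4).
#' @param gamma2 axial exponent (default 0.5).
#' @param n_theta,n_phi tessellation resolution (>= 8).
#' @param eta_floor lower clamp on eta exponents to avoid numerically flat
#'   powers as CP approaches 1 (default 0.05).
#' @return A \code{surface_grid} (matrices x, y, z of size n_theta x n_phi).
#' @export
supertoroid_surface <- function(metrics, gamma1 = 4, gamma2 = 0.5,
                                n_theta = 64L, n_phi = 64L, eta_floor = 0.05) {
  metrics <- as.numeric(metrics)
  if (length(metrics) != 3L || any(!is.finite(metrics)))
    stop("metrics must be a finite length-3 vector (CL, CP, CS)")
  if (gamma1 <= 0 || gamma2 <= 0) stop("gamma1 and gamma2 must be positive")
  if (n_theta < 8L || n_phi < 8L) stop("tessellation resolution must be >= 8")
  CL <- metrics[1]; CP <- metrics[2]; CS <- metrics[3]
  eta1 <- max((1 - CP)^gamma1, eta_floor)
  eta2 <- max((1 - CP)^gamma2, eta_floor)
  if (CS >= CP) { A <- CL + CP; B <- CS } else { A <- CS; B <- CL + CP }
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  ct <- signed_power(cos(theta), eta1)
  st <- signed_power(sin(theta), eta1)
  cp <- signed_power(cos(phi), eta2)
  sp <- signed_power(sin(phi), eta2)
  R <- A + B * outer(rep(1, n_theta), cp)   # n_theta x n_phi radial term
  new_surface_grid(x = ct * R, y = st * R,
                   z = outer(rep(1, n_theta), sp),
                   degenerate_hint = (A + max(B, 0) <= 1e-12))
}

#' Toroidal glyph surface
#'
#' The eigenvalue-parameterized toroid
#' \code{(cos(theta) (alpha + beta cos(phi)), sin(theta) (alpha + beta
#' cos(phi)), gamma sin(phi))} with \code{alpha = (2 l2 + l3)/4},
#' \code{beta = l3/4}, \code{gamma = l1/2}: the z-extent equals l1, the
#' central-opening diameter \code{2 (alpha - beta)} equals l2, and the
#' cross-section thickness is l3/2. Shape varies from a tube (high
#' anisotropy) to an ordinary torus (isotropy).
#'
#' @param evals length-3 vector of sorted nonnegative eigenvalues.
#' @param n_theta,n_phi tessellation resolution (>= 8).
#' @return A \code{surface_grid}.
#' @export
toroid_surface <- function(evals, n_theta = 64L, n_phi = 64L) {
  ev <- as_eval_matrix(evals)
  if (nrow(ev) != 1L) stop("toroid_surface expects a single eigenvalue triple")
  if (n_theta < 8L || n_phi < 8L) stop("tessellation resolution must be >= 8")
  tp <- toroid_params(ev)
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  ring <- tp$alpha + tp$beta * cos(phi)     # length n_phi
  R <- outer(rep(1, n_theta), ring)
  new_surface_grid(x = cos(theta) * R, y = sin(theta) * R,
                   z = outer(rep(1, n_theta), tp$gamma * sin(phi)),
                   degenerate_hint = (tp$alpha + tp$beta <= 1e-12))
}

#' Glyph mesh container
#'
#' @param vertices N x 3 matrix of local coordinates.
#' @param faces M x 3 integer matrix of 1-based triangle indices.
#' @param colors optional N x 3 RGB matrix in \code{[0, 1]}.
#' @param transform 4x4 placement transform (local -> world).
#' @param degenerate flag for collapsed placeholder meshes.
#' @return An object of class \code{glyph_mesh}.
#' @export
glyph_mesh <- function(vertices, faces, colors = NULL, transform = diag(4),
                       degenerate = FALSE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (ncol(vertices) != 3L) stop("vertices must be N x 3")
  if (any(!is.finite(vertices))) stop("vertices must be finite")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("faces index vertices out of range")
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    stopifnot(nrow(colors) == nrow(vertices), ncol(colors) == 3L)
  }
  structure(list(vertices = vertices, faces = faces, colors = colors,
                 transform = transform, degenerate = degenerate),
            class = "glyph_mesh")
}

#' @export
print.glyph_mesh <- function(x, ...) {
  cat(sprintf("<glyph_mesh> %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$colors)) "" else ", per-vertex RGB",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Tessellate a parametric surface grid into a welded triangle mesh
#'
#' Splits each (wrapping) quad of the grid into two triangles and welds
#' coincident vertices within \code{weld_tol}. Quad diagonals are chosen by
#' the shorter geometric diagonal (ties broken by welded vertex indices), a
#' rule that depends only on vertex geometry; where a degenerate
#' parameterization traverses the same surface region more than once (e.g.
#' the sphere-like isotropic supertoroid) the duplicated triangles therefore
#' coincide exactly and are removed, leaving a single cover. Collapsed
#' (repeated-vertex) faces are dropped. A fully collapsed glyph yields a
#' placeholder point/ring mesh flagged \code{degenerate} rather than an
#' error, so slice-wide exports never abort.
#'
#' @param grid a \code{surface_grid} from \code{\link{supertoroid_surface}}
#'   or \code{\link{toroid_surface}}.
#' @param weld_tol welding tolerance on coordinates (default 1e-9).
#' @return A \code{\link{glyph_mesh}} with outward-consistent winding on
#'   non-degenerate surfaces.
#' @export
tessellate <- function(grid, weld_tol = 1e-9) {
  stopifnot(inherits(grid, "surface_grid"))
  nt <- nrow(grid$x); np <- ncol(grid$x)
  verts <- cbind(as.vector(grid$x), as.vector(grid$y), as.vector(grid$z))
  # weld: map each vertex to the first vertex in its rounding bin
  key <- paste(round(verts[, 1] / weld_tol), round(verts[, 2] / weld_tol),
               round(verts[, 3] / weld_tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  wverts <- verts[first, , drop = FALSE]

  vid <- function(i, j) (j - 1L) * nt + i   # column-major index into grid
  ii <- rep(seq_len(nt), np)
  jj <- rep(seq_len(np), each = nt)
  i2 <- ifelse(ii == nt, 1L, ii + 1L)
  j2 <- ifelse(jj == np, 1L, jj + 1L)
  v00 <- remap[vid(ii, jj)]; v10 <- remap[vid(i2, jj)]
  v01 <- remap[vid(ii, j2)]; v11 <- remap[vid(i2, j2)]

  d2 <- function(a, b) rowSums((wverts[a, , drop = FALSE] - wverts[b, , drop = FALSE])^2)
  len_d1 <- d2(v00, v11)   # diagonal v00-v11
  len_d2 <- d2(v10, v01)   # diagonal v10-v01
  tol2 <- (4 * weld_tol)^2
  tie <- abs(len_d1 - len_d2) <= tol2
  # tie-break on welded indices so coincident quads pick the same diagonal
  key1 <- pmin(v00, v11) * (nrow(wverts) + 1) + pmax(v00, v11)
  key2 <- pmin(v10, v01) * (nrow(wverts) + 1) + pmax(v10, v01)
  use_d1 <- ifelse(tie, key1 <= key2, len_d1 < len_d2)

  f1 <- cbind(ifelse(use_d1, v00, v10),
              ifelse(use_d1, v10, v11),
              ifelse(use_d1, v11, v01))
  f2 <- cbind(ifelse(use_d1, v00, v10),
              ifelse(use_d1, v11, v01),
              ifelse(use_d1, v01, v00))
  faces <- rbind(f1, f2)
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  faces <- faces[ok, , drop = FALSE]
  # drop duplicate faces (same vertex set, either orientation)
  if (nrow(faces)) {
    sorted <- t(apply(faces, 1L, sort))
    faces <- faces[!duplicated(sorted), , drop = FALSE]
  }
  degen <- nrow(faces) == 0L || grid$degenerate_hint
  if (nrow(faces) == 0L) {
    return(glyph_mesh(wverts, matrix(integer(0), 0, 3), degenerate = TRUE))
  }
  used <- sort(unique(as.vector(faces)))
  remap2 <- integer(nrow(wverts)); remap2[used] <- seq_along(used)
  glyph_mesh(wverts[used, , drop = FALSE],
             matrix(remap2[faces], ncol = 3L), degenerate = degen)
}

#' Euler characteristic of a triangle mesh
#'
#' \code{V - E + F} with edges counted as unique unordered vertex pairs:
#' 2 for a sphere-like (genus 0) mesh, 0 for a torus (genus 1).
#'
#' @param mesh a \code{\link{glyph_mesh}}.
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  stopifnot(inherits(mesh, "glyph_mesh"))
  f <- mesh$faces
  if (!nrow(f)) return(NA_integer_)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  n_e <- sum(!duplicated(e))
  nrow(mesh$vertices) - n_e + nrow(f)
}

#' Volume enclosed by a closed triangle mesh
#'
#' Divergence-theorem quadrature (sum of signed tetrahedron volumes).
#'
#' @param mesh a \code{\link{glyph_mesh}} that is closed and consistently
#'   oriented.
#' @return nonnegative volume.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6)
}

#' Place a glyph in world space
#'
#' Builds the placement transform mapping the glyph's local frame onto the
#' voxel eigenframe: the local z-axis (the toroid's rotational axis, i.e. the
#' central opening direction) maps to the principal eigenvector e1, local x
#' to e2 and local y to e3. The rotation determinant is forced to +1 by
#' flipping the e3 image if needed.
#'
#' @param mesh a \code{\link{glyph_mesh}}.
#' @param vectors 3x3 matrix with unit eigenvectors e1, e2, e3 as columns.
#' @param center length-3 world coordinates of the voxel center.
#' @param scale uniform display scale.
#' @return The mesh with its \code{transform} set.
#' @export
place_glyph <- function(mesh, vectors, center, scale = 1) {
  stopifnot(inherits(mesh, "glyph_mesh"))
  V <- as.matrix(vectors)
  if (any(abs(crossprod(V) - diag(3)) > 1e-6))
    stop("eigenvector frame is not orthonormal")
  R <- cbind(V[, 2], V[, 3], V[, 1])   # local x->e2, y->e3, z->e1
  if (det(R) < 0) R[, 2] <- -R[, 2]
  tf <- diag(4)
  tf[1:3, 1:3] <- scale * R
  tf[1:3, 4] <- center
  mesh$transform <- tf
  mesh
}

#' Apply a mesh's placement transform to its vertices
#'
#' @param mesh a \code{\link{glyph_mesh}}.
#' @return The mesh with transformed vertices and identity transform.
#' @export
bake_transform <- function(mesh) {
  stopifnot(inherits(mesh, "glyph_mesh"))
  v <- cbind(mesh$vertices, 1) %*% t(mesh$transform)
  mesh$vertices <- v[, 1:3, drop = FALSE]
  mesh$transform <- diag(4)
  mesh
}

#' Orientation color of the principal eigenvector
#'
#' Standard DTI convention: \code{RGB = (|e1x|, |e1y|, |e1z|)} (red =
#' left-right, green = anterior-posterior, blue = superior-inferior),
#' optionally weighted by FA.
#'
#' @param e1 unit principal eigenvector (length 3) or n x 3 matrix.
#' @param fa optional FA weight(s) in \code{[0, 1]}.
#' @return n x 3 RGB matrix in \code{[0, 1]}.
#' @export
color_by_orientation <- function(e1, fa = NULL) {
  if (is.null(dim(e1))) e1 <- matrix(e1, nrow = 1L)
  rgb <- pmin(abs(e1), 1)
  if (!is.null(fa)) rgb <- rgb * pmin(pmax(fa, 0), 1)
  rgb
}

#' Eigenvalue-configuration color with TV brightness modulation
#'
#' Base colors purple/orange/green/gray for the orthotropic / prolate /
#' oblate / isotropic classes; the HSV value channel is scaled by
#' \code{floor + (1 - floor) * tv_norm}, so low-TV voxels stay visible at
#' floor brightness. \code{tv_norm} outside \code{[0, 1]} is clipped with a
#' warning.
#'
#' @param cls factor from \code{\link{classify_configuration}} (or character).
#' @param tv_norm normalized TV in \code{[0, 1]} (recycled).
#' @param floor brightness floor in \code{[0, 1)} (default 0.2).
#' @return n x 3 RGB matrix.
#' @export
color_by_configuration <- function(cls, tv_norm = 1, floor = 0.2) {
  cls <- as.character(cls)
  base <- config_colors()
  if (any(!cls %in% rownames(base))) stop("unknown configuration class")
  if (any(tv_norm < 0 | tv_norm > 1)) {
    warning("tv_norm outside [0, 1] clipped")
    tv_norm <- pmin(pmax(tv_norm, 0), 1)
  }
  rgb <- base[cls, , drop = FALSE]
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
  hsv[3, ] <- hsv[3, ] * (floor + (1 - floor) * tv_norm)
  out <- t(grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ]))) / 255
  dimnames(out) <- list(NULL, c("r", "g", "b"))
  out
}

#' Hot-to-cold color ramp
#'
#' Piecewise-linear blue -> cyan -> green -> yellow -> red ramp on
#' \code{[0, 1]}; out-of-range values are clipped.
#'
#' @param v numeric values.
#' @return n x 3 RGB matrix.
#' @export
hot_to_cold <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  r <- ifelse(v < 0.5, 0, ifelse(v < 0.75, 4 * (v - 0.5), 1))
  g <- ifelse(v < 0.25, 4 * v, ifelse(v < 0.75, 1, 1 - 4 * (v - 0.75)))
  b <- ifelse(v < 0.25, 1, ifelse(v < 0.5, 1 - 4 * (v - 0.25), 0))
  cbind(r = pmin(pmax(r, 0), 1), g = pmin(pmax(g, 0), 1), b = pmin(pmax(b, 0), 1))
}

#' Build a colored glyph mesh for one axial slice of a tensor field
#'
#' Generates one glyph per masked voxel of slice \code{z}, colors it by the
#' requested encoding, orients it by the local eigenframe, scales it to
#' \code{0.45 * voxel size} (so neighboring glyphs do not overlap), and
#' merges everything into a single mesh in world coordinates.
#'
#' @param field a \code{\link{tensor_field}}.
#' @param z 1-based slice index.
#' @param mode "supertoroid" or "toroid".
#' @param color "orientation", "config" or "tv".
#' @param gamma1,gamma2 supertoroid exponents.
#' @param n_theta,n_phi per-glyph resolution (default 24 for slice export).
#' @param scale_frac glyph radius as a fraction of voxel size (default 0.45).
#' @param rel_tol configuration-equality tolerance for "config" coloring.
#' @return A merged \code{\link{glyph_mesh}} in world coordinates.
#' @export
glyph_slice <- function(field, z, mode = c("supertoroid", "toroid"),
                        color = c("orientation", "config", "tv"),
                        gamma1 = 4, gamma2 = 0.5, n_theta = 24L, n_phi = 24L,
                        scale_frac = 0.45, rel_tol = 0.05) {
  stopifnot(inherits(field, "tensor_field"))
  mode <- match.arg(mode); color <- match.arg(color)
  dims <- dim(field$D)[1:3]
  if (z < 1L || z > dims[3L]) stop("slice index out of range")
  eigs <- tensor_eigen(field)
  vox_size <- mean(sqrt(colSums(field$affine[1:3, 1:3]^2)))
  idx <- which(field$mask[, , z], arr.ind = TRUE)
  if (!nrow(idx)) stop("no masked voxels in slice ", z)
  ev_all <- matrix(eigs$values[cbind(rep(idx[, 1], 3), rep(idx[, 2], 3),
                                     z, rep(1:3, each = nrow(idx)))],
                   nrow(idx), 3L)
  ev_all <- pmax(ev_all, 0)
  tv_norm <- NULL
  if (color != "orientation") {
    tv <- toroidal_volume(ev_all)
    rng <- range(tv)
    tv_norm <- if (rng[2] > rng[1]) (tv - rng[1]) / (rng[2] - rng[1]) else rep(0, length(tv))
  }
  fa <- fractional_anisotropy(ev_all)
  cls <- classify_configuration(ev_all, rel_tol = rel_tol)

  verts_list <- vector("list", nrow(idx))
  faces_list <- vector("list", nrow(idx))
  colors_list <- vector("list", nrow(idx))
  offset <- 0L
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ev <- ev_all[k, ]
    grid <- if (mode == "supertoroid") {
      supertoroid_surface(shape_metrics(ev)[1, ], gamma1 = gamma1,
                          gamma2 = gamma2, n_theta = n_theta, n_phi = n_phi)
    } else {
      toroid_surface(ev, n_theta = n_theta, n_phi = n_phi)
    }
    mesh <- tessellate(grid)
    if (!nrow(mesh$faces)) next
    ext <- max(sqrt(rowSums(mesh$vertices^2)))
    if (ext <= 0) next
    V <- matrix(eigs$vectors[i, j, z, , ], 3L, 3L)
    center <- (field$affine %*% c(i - 1, j - 1, z - 1, 1))[1:3]
    mesh <- place_glyph(mesh, V, center, scale = scale_frac * vox_size / ext)
    mesh <- bake_transform(mesh)
    col <- switch(color,
                  orientation = color_by_orientation(V[, 1], fa[k]),
                  config = color_by_configuration(as.character(cls[k]), tv_norm[k]),
                  tv = hot_to_cold(tv_norm[k]))
    verts_list[[k]] <- mesh$vertices
    faces_list[[k]] <- mesh$faces + offset
    colors_list[[k]] <- matrix(col, nrow(mesh$vertices), 3L, byrow = TRUE)
    offset <- offset + nrow(mesh$vertices)
  }
  keep <- !vapply(verts_list, is.null, logical(1))
  if (!any(keep)) stop("all glyphs in slice ", z, " are degenerate")
  glyph_mesh(do.call(rbind, verts_list[keep]),
             do.call(rbind, faces_list[keep]),
             colors = do.call(rbind, colors_list[keep]))
}
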