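# Readers/writers for the on-disk artifacts: NIfTI volumes (DWI, tensor,
# scalar maps, ROI labels), FSL bval/bvec tables, PLY/OBJ meshes, YAML
# phantom specs, CSV/JSON reports.
#
# Conventions: the NIfTI sform (code 2) carries the voxel-to-RAS-world
# affine; tensor components are stored on disk in lower-triangular order
# (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), documented in the header description
# (in-memory order is Dxx, Dxy, Dxz, Dyy, Dyz, Dzz). All writers are
# deterministic: fixed field order, no timestamps.

write_nifti_vol <- function(arr, path, affine, descrip = "", datatype = "float") {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img$descrip <- substr(descrip, 1L, 79L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_nifti_vol <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  list(data = array(as.vector(img), dim(img)),  # plain array, no image class
       affine = matrix(as.numeric(aff), 4, 4),
       descrip = RNifti::niftiHeader(img)$descrip)
}

# FSL dialect: .bval is one whitespace-separated row; .bvec is three rows
# (x, y, z components). Whitespace-tolerant.
read_bvals_bvecs <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("no such file: ", p)
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bvec_rows <- lapply(readLines(bvec_path), function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
    v[!is.na(v)]
  })
  bvec_rows <- bvec_rows[lengths(bvec_rows) > 0]
  if (length(bvec_rows) != 3L)
    stop("bvec file must have 3 rows (x, y, z); got ", length(bvec_rows))
  if (length(unique(lengths(bvec_rows))) != 1L)
    stop("bvec rows have unequal lengths")
  bvecs <- t(do.call(rbind, bvec_rows))
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("gradient count mismatch: %d b-values vs %d b-vectors",
                 length(bvals), nrow(bvecs)))
  list(bvals = bvals, bvecs = bvecs)
}

write_bvals_bvecs <- function(bvals, bvecs, bval_path, bvec_path) {
  writeLines(paste(format(bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(bvecs), 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' Read a DWI dataset (NIfTI + FSL bval/bvec)
#'
#' @param nifti_path 4D NIfTI file.
#' @param bval_path,bvec_path FSL-dialect gradient table files.
#' @return A \code{\link{dwi_volume}} (nonzero-b directions normalized to
#'   unit length; zero vectors on b=0 rows preserved).
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  vol <- read_nifti_vol(nifti_path)
  if (length(dim(vol$data)) != 4L)
    stop("DWI image must be 4D; got ", length(dim(vol$data)), "D")
  gt <- read_bvals_bvecs(bval_path, bvec_path)
  if (dim(vol$data)[4L] != length(gt$bvals))
    stop(sprintf("gradient count mismatch: %d volumes vs %d b-values",
                 dim(vol$data)[4L], length(gt$bvals)))
  dwi_volume(vol$data, gt$bvals, gt$bvecs, affine = vol$affine)
}

#' Write a DWI dataset (NIfTI + FSL bval/bvec)
#'
#' @param dwi a \code{\link{dwi_volume}}.
#' @param prefix output path prefix; writes \code{<prefix>.nii.gz},
#'   \code{<prefix>.bval}, \code{<prefix>.bvec}.
#' @return the NIfTI path, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_volume"))
  nii <- paste0(prefix, ".nii.gz")
  write_nifti_vol(dwi$signal, nii, dwi$affine, descrip = "DWI signal",
                  datatype = "double")
  write_bvals_bvecs(dwi$bvals, dwi$bvecs,
                    paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(nii)
}

LOWER_TRI_DESCRIP <- "DTI lower-tri: Dxx Dxy Dyy Dxz Dyz Dzz (mm^2/s)"
# in-memory (Dxx,Dxy,Dxz,Dyy,Dyz,Dzz) -> disk lower-tri (Dxx,Dxy,Dyy,Dxz,Dyz,Dzz)
MEM_TO_DISK <- c(1L, 2L, 4L, 3L, 5L, 6L)
DISK_TO_MEM <- order(MEM_TO_DISK)

#' Write a tensor field as a 4D NIfTI volume
#'
#' Components are stored in lower-triangular order (Dxx, Dxy, Dyy, Dxz,
#' Dyz, Dzz), recorded in the header description field. A sidecar
#' \code{<path minus extension>_mask.nii.gz} stores the fit mask.
#'
#' @param field a \code{\link{tensor_field}}.
#' @param path output NIfTI path.
#' @return path, invisibly.
#' @export
write_tensor <- function(field, path) {
  stopifnot(inherits(field, "tensor_field"))
  write_nifti_vol(field$D[, , , MEM_TO_DISK, drop = FALSE], path,
                  field$affine, descrip = LOWER_TRI_DESCRIP,
                  datatype = "double")
  write_nifti_vol(array(as.numeric(field$mask), dim(field$mask)),
                  mask_path(path), field$affine, descrip = "mask",
                  datatype = "uint8")
  invisible(path)
}

mask_path <- function(path) {
  sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
}

#' Read a tensor field written by \code{\link{write_tensor}}
#'
#' @param path NIfTI path (6 lower-triangular components per voxel).
#' @return A \code{\link{tensor_field}}.
#' @export
read_tensor <- function(path) {
  vol <- read_nifti_vol(path)
  if (length(dim(vol$data)) != 4L || dim(vol$data)[4L] != 6L)
    stop("tensor image must be 4D with 6 components per voxel")
  mask <- NULL
  mp <- mask_path(path)
  if (file.exists(mp)) mask <- read_nifti_vol(mp)$data > 0.5
  tensor_field(vol$data[, , , DISK_TO_MEM, drop = FALSE],
               mask = mask, affine = vol$affine)
}

#' Write a scalar map as float32 NIfTI
#'
#' The invariant name and units go into the header description; masked
#' voxels are stored as zeros (NaN-free) with a sidecar mask volume.
#'
#' @param map a \code{\link{scalar_map}}.
#' @param path output NIfTI path.
#' @return path, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  desc <- if (nzchar(map$units)) paste0(map$name, " [", map$units, "]") else map$name
  write_nifti_vol(map$values, path, map$affine, descrip = desc)
  write_nifti_vol(array(as.numeric(map$mask), dim(map$mask)),
                  mask_path(path), map$affine, descrip = "mask",
                  datatype = "uint8")
  invisible(path)
}

#' Read a scalar map written by \code{\link{write_map}}
#'
#' @param path NIfTI path.
#' @return A \code{\link{scalar_map}} (name/units parsed from the header
#'   description).
#' @export
read_map <- function(path) {
  vol <- read_nifti_vol(path)
  if (length(dim(vol$data)) != 3L) stop("scalar map must be a 3D image")
  mask <- NULL
  mp <- mask_path(path)
  if (file.exists(mp)) mask <- read_nifti_vol(mp)$data > 0.5
  name <- vol$descrip; units <- ""
  m <- regmatches(name, regexec("^(.*) \\[(.*)\\]$", name))[[1]]
  if (length(m) == 3L) { name <- m[2]; units <- m[3] }
  scalar_map(vol$data, mask = mask, affine = vol$affine,
             name = if (nzchar(name)) name else "map", units = units)
}

#' Write / read ROI labels as NIfTI
#'
#' @param rois a \code{\link{roi_set}}.
#' @param path NIfTI path.
#' @return path (write) or a \code{\link{roi_set}} (read).
#' @export
write_roi <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  write_nifti_vol(rois$labels, path, rois$affine,
                  descrip = "ROI labels: 1=tumor 2=edema 3=GM 4=WM",
                  datatype = "int16")
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  vol <- read_nifti_vol(path)
  if (length(dim(vol$data)) != 3L) stop("ROI label image must be 3D")
  roi_set(round(vol$data), affine = vol$affine)
}

#' Write a glyph mesh to PLY or OBJ
#'
#' PLY: binary little-endian, float32 positions, per-vertex uchar RGB.
#' OBJ: ASCII positions/faces plus a sidecar \code{<path>.colors.csv} with
#' per-vertex RGB (OBJ has no standard vertex-color slot). The placement
#' transform is baked into the vertices before writing.
#'
#' @param mesh a \code{\link{glyph_mesh}} with at least one face.
#' @param path output path.
#' @param format "ply" or "obj".
#' @return path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ply", "obj")) {
  stopifnot(inherits(mesh, "glyph_mesh"))
  format <- match.arg(format)
  if (nrow(mesh$faces) == 0L) stop("refusing to write an empty mesh")
  mesh <- bake_transform(mesh)
  v <- mesh$vertices
  col <- mesh$colors %||% matrix(0.8, nrow(v), 3L)
  col255 <- as.integer(round(pmin(pmax(col, 0), 1) * 255))
  f0 <- mesh$faces - 1L
  if (format == "ply") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("ply", "format binary_little_endian 1.0",
             paste("element vertex", nrow(v)),
             "property float x", "property float y", "property float z",
             "property uchar red", "property uchar green", "property uchar blue",
             paste("element face", nrow(f0)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con, sep = "\n")
    colm <- matrix(col255, nrow(v), 3L)
    for (i in seq_len(nrow(v))) {
      writeBin(as.numeric(v[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(colm[i, ]), con)
    }
    for (i in seq_len(nrow(f0))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]))
    writeLines(lines, path)
    colm <- matrix(col255, nrow(v), 3L)
    utils::write.csv(data.frame(r = colm[, 1], g = colm[, 2], b = colm[, 3]),
                     paste0(path, ".colors.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a binary PLY mesh written by \code{\link{write_mesh}}
#'
#' @param path PLY file path.
#' @return A \code{\link{glyph_mesh}}.
#' @export
read_mesh_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    l <- readLines(con, n = 1L)
    hdr <- c(hdr, l)
    if (identical(l, "end_header")) break
    if (length(hdr) > 100L) stop("malformed PLY header")
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  v <- matrix(0, nv, 3L); col <- matrix(0, nv, 3L)
  for (i in seq_len(nv)) {
    v[i, ] <- readBin(con, numeric(), n = 3L, size = 4L, endian = "little")
    col[i, ] <- as.integer(readBin(con, raw(), n = 3L)) / 255
  }
  f <- matrix(0L, nf, 3L)
  for (i in seq_len(nf)) {
    cnt <- as.integer(readBin(con, raw(), n = 1L))
    if (cnt != 3L) stop("only triangle PLY faces are supported")
    f[i, ] <- readBin(con, integer(), n = 3L, size = 4L, endian = "little") + 1L
  }
  glyph_mesh(v, f, colors = col)
}

#' Write / read a phantom spec as YAML
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param path YAML file path.
#' @return path (write) or a \code{\link{phantom_spec}} (read).
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- yaml::read_yaml(path)
  do.call(phantom_spec, x[intersect(names(x), names(formals(phantom_spec)))])
}

#' Write tidy ROI means as CSV
#'
#' Long format: subject, region, invariant, mean.
#'
#' @param means subjects x regions x invariants array
#'   (\code{\link{cohort_roi_means}}).
#' @param path CSV path.
#' @return path, invisibly.
#' @export
write_roi_means_csv <- function(means, path) {
  stopifnot(length(dim(means)) == 3L)
  dn <- dimnames(means)
  df <- expand.grid(subject = seq_len(dim(means)[1]),
                    region = dn[[2]] %||% seq_len(dim(means)[2]),
                    invariant = dn[[3]] %||% seq_len(dim(means)[3]),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$mean <- as.vector(means)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort statistics report as JSON
#'
#' @param stats a \code{cohort_stats} object from
#'   \code{\link{cohort_analysis}}.
#' @param path JSON path.
#' @return path, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  stopifnot(inherits(stats, "cohort_stats"))
  rep_ <- list(
    alpha = stats$alpha,
    n_subjects = dim(stats$means)[1],
    omnibus = lapply(stats$omnibus, function(o)
      list(statistic = o$statistic, df = o$df, p = o$p.value)),
    posthoc = stats$posthoc
  )
  jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
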