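#' 3D scalar volumes with world geometry
#'
#' A \code{cf_volume} stores a 3D intensity array together with its voxel
#' spacing (mm), world origin (position of voxel index \code{(0,0,0)}) and a
#' 3x3 orthonormal direction matrix, so that index-to-world mapping is the
#' affine \code{w = origin + axes \%*\% (spacing * index)}.
#'
#' The package-wide world convention is right-handed with X mediolateral
#' (positive toward the patient's left), Y anteroposterior (positive
#' anterior) and Z superoinferior (positive superior). NIfTI (RAS) and DICOM
#' (LPS) coordinates are converted to this convention on ingest and converted
#' back on write, so round trips reproduce the original headers.
#'
#' @param voxels 3D numeric array of intensities (arbitrary units).
#' @param spacing per-axis voxel size, mm (all > 0).
#' @param origin world position of voxel (0,0,0), mm.
#' @param axes 3x3 orthonormal direction matrix; columns are the world
#'   directions of increasing i, j, k.
#' @return An object of class \code{cf_volume}.
#' @export
cf_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      axes = diag(3)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) cf_error("HeaderError", "voxels must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  axes <- unname(as.matrix(axes))
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_header("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_header("origin must be 3 finite values (mm)")
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6)
    stop_header("direction matrix must be orthonormal")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 axes = axes), class = "cf_volume")
}

#' @export
print.cf_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("cf_volume %dx%dx%d, spacing (%.4g, %.4g, %.4g) mm, origin (%.4g, %.4g, %.4g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Index/world coordinate maps for a volume
#'
#' Indices are zero-based and continuous (voxel centres at integers).
#' @param vol a \code{cf_volume}.
#' @param idx n x 3 matrix (or length-3 vector) of zero-based indices.
#' @param world n x 3 matrix (or length-3 vector) of world positions, mm.
#' @return n x 3 matrix of mapped coordinates.
#' @export
index_to_world <- function(vol, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, 1)
  sweep(idx %*% t(vol$axes * rep(vol$spacing, each = 3)), 2, vol$origin, "+")
}

#' @rdname index_to_world
#' @export
world_to_index <- function(vol, world) {
  if (is.null(dim(world))) world <- matrix(world, 1)
  sweep(world, 2, vol$origin, "-") %*% (vol$axes / rep(vol$spacing, each = 3))
}

# Trilinear sampling at continuous zero-based indices; out-of-field -> fill.
trilinear_sample <- function(voxels, cidx, fill = 0) {
  d <- dim(voxels)
  i0 <- floor(cidx)
  f <- cidx - i0
  inside <- cidx[, 1] >= 0 & cidx[, 1] <= d[1] - 1 &
            cidx[, 2] >= 0 & cidx[, 2] <= d[2] - 1 &
            cidx[, 3] >= 0 & cidx[, 3] <= d[3] - 1
  out <- rep(fill, nrow(cidx))
  if (!any(inside)) return(out)
  i0 <- i0[inside, , drop = FALSE]
  f <- f[inside, , drop = FALSE]
  # clamp the upper corner so exact-boundary samples stay in range
  i1 <- pmin(i0 + 1, rep(d - 1, each = nrow(i0)))
  lin <- function(a, b, c) 1 + a + d[1] * (b + d[2] * c)
  v000 <- voxels[lin(i0[, 1], i0[, 2], i0[, 3])]
  v100 <- voxels[lin(i1[, 1], i0[, 2], i0[, 3])]
  v010 <- voxels[lin(i0[, 1], i1[, 2], i0[, 3])]
  v110 <- voxels[lin(i1[, 1], i1[, 2], i0[, 3])]
  v001 <- voxels[lin(i0[, 1], i0[, 2], i1[, 3])]
  v101 <- voxels[lin(i1[, 1], i0[, 2], i1[, 3])]
  v011 <- voxels[lin(i0[, 1], i1[, 2], i1[, 3])]
  v111 <- voxels[lin(i1[, 1], i1[, 2], i1[, 3])]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Sample a volume at world positions
#' @param vol a \code{cf_volume}.
#' @param world n x 3 matrix of world positions, mm.
#' @param fill value returned for positions outside the field of view.
#' @return Numeric vector of interpolated intensities (trilinear).
#' @export
sample_volume <- function(vol, world, fill = 0) {
  trilinear_sample(vol$voxels, world_to_index(vol, world), fill = fill)
}

#' Resample a moving volume through a rigid transform onto a grid
#'
#' Evaluates \code{moving} at \code{t^{-1}(x)} for every voxel centre
#' \code{x} of \code{grid}'s lattice, i.e. \code{t} maps moving-world to
#' grid-world (the registration convention, moving to fixed). Trilinear
#' interpolation; out-of-field voxels take \code{fill}.
#'
#' @param moving a \code{cf_volume} to be resampled.
#' @param t a \code{rigid_transform} (moving to grid world).
#' @param grid a \code{cf_volume} supplying the target lattice.
#' @param fill fill value for voxels mapping outside \code{moving}.
#' @return A \code{cf_volume} on \code{grid}'s lattice.
#' @export
resample_volume <- function(moving, t, grid, fill = 0) {
  d <- dim(grid$voxels)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1)))
  w <- index_to_world(grid, idx)
  wm <- apply_transform(invert_transform(t), w)
  vals <- sample_volume(moving, wm, fill = fill)
  cf_volume(array(vals, dim = d), spacing = grid$spacing,
            origin = grid$origin, axes = grid$axes)
}

#' Gaussian smoothing of a volume (separable, voxel units)
#' @param vol a \code{cf_volume}.
#' @param sigma_vox Gaussian sigma in voxels; 0 returns the input.
#' @return A smoothed \code{cf_volume}.
#' @export
smooth_volume <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  v <- vol$voxels
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  smooth_dim <- function(a, dimi) {
    d <- dim(a)
    n <- d[dimi]
    # banded kernel matrix with edge renormalization (reflect-free, truncated)
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      tgt <- idx + off
      ok <- tgt >= 1 & tgt <= n
      K[cbind(idx[ok], tgt[ok])] <- K[cbind(idx[ok], tgt[ok])] + k[off + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(dimi, setdiff(1:3, dimi))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    sm <- K %*% m
    aperm(array(sm, dim = d[perm]), order(perm))
  }
  for (dimi in 1:3) v <- smooth_dim(v, dimi)
  cf_volume(v, spacing = vol$spacing, origin = vol$origin, axes = vol$axes)
}

# ---- NIfTI I/O --------------------------------------------------------------

# RAS (NIfTI world) <-> internal: flip X (internal X is toward patient's left)
.ras_to_internal <- diag(c(-1, 1, 1))

#' Read a volume from NIfTI or a DICOM series directory
#'
#' @param path a \code{.nii}/\code{.nii.gz} file (\code{format = "nifti"}) or
#'   a directory holding one DICOM series (\code{format = "dicom_dir"}).
#' @param format input format; inferred from \code{path} when missing.
#' @return A \code{cf_volume} in the internal world convention.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (format == "nifti") read_volume_nifti(path) else read_dicom_series(path)
}

read_volume_nifti <- function(path) {
  if (!file.exists(path)) stop_header(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  m <- unclass(RNifti::xform(img))   # 4x4, index -> RAS world
  A <- .ras_to_internal %*% m[1:3, 1:3]
  origin <- as.numeric(.ras_to_internal %*% m[1:3, 4])
  spacing <- sqrt(colSums(A^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop_header("NIfTI header has missing or invalid voxel spacing")
  axes <- sweep(A, 2, spacing, "/")
  vox <- as.array(img)
  attributes(vox) <- list(dim = dim(vox))
  cf_volume(vox, spacing = spacing, origin = origin, axes = axes)
}

#' Write a volume to NIfTI
#'
#' The stored sform encodes the volume's geometry converted back to the RAS
#' convention NIfTI uses, so external viewers see standard coordinates and
#' \code{\link{read_volume}} reproduces the volume exactly.
#' @param vol a \code{cf_volume}.
#' @param path output \code{.nii} or \code{.nii.gz} path.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  A <- .ras_to_internal %*% (vol$axes * rep(vol$spacing, each = 3))
  m <- rbind(cbind(A, as.numeric(.ras_to_internal %*% vol$origin)), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
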