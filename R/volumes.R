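#' Volume container
#'
#' A minimal container for regularly gridded image volumes: a numeric array
#' with 3 (scalar) or 4 (multi-channel, channel-last) dimensions plus a 4x4
#' voxel-to-world affine in mm. Continuous voxel coordinates are 0-based with
#' voxel centers at integer positions; world positions are obtained through
#' the affine. Streamlines are always stored in world mm.
#'
#' @param data numeric array, dims `(H,W,D)` or `(H,W,D,C)`.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to a scaled
#'   identity built from `voxel_size`.
#' @param voxel_size isotropic voxel edge length in mm, used only when
#'   `affine` is `NULL`. Default 1.2 mm, the working resolution for fetal
#'   dMRI reconstructions this package targets.
#' @return an object of class `vmf_volume`.
#' @export
vmf_volume <- function(data, affine = NULL, voxel_size = 1.2) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) {
    stop("volume data must have 3 or 4 dimensions, got ", nd)
  }
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size, 3), 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  structure(list(data = data, affine = affine), class = "vmf_volume")
}

#' @export
print.vmf_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<vmf_volume> grid ", paste(d[1:3], collapse = "x"),
      if (length(d) == 4L) paste0(", ", d[4], " channel(s)") else "",
      ", voxel ", paste(signif(vol_voxel_size(x), 4), collapse = "x"),
      " mm\n", sep = "")
  invisible(x)
}

#' Grid dimensions of a volume (spatial part only)
#' @param vol a `vmf_volume`.
#' @return integer vector length 3.
#' @export
vol_dim <- function(vol) dim(vol$data)[1:3]

#' Number of channels of a volume
#' @param vol a `vmf_volume`.
#' @return integer; 1 for scalar volumes.
#' @export
vol_channels <- function(vol) {
  d <- dim(vol$data)
  if (length(d) == 4L) d[4] else 1L
}

#' Voxel edge lengths implied by the affine
#' @param vol a `vmf_volume`.
#' @return numeric length 3, mm.
#' @export
vol_voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Volume data as a (n_voxels x channels) matrix
#'
#' Column-major flattening: voxel (i,j,k) (0-based) maps to row
#' `1 + i + j*H + k*H*W`.
#' @param vol a `vmf_volume`.
#' @return numeric matrix.
#' @export
vol_matrix <- function(vol) {
  d <- dim(vol$data)
  matrix(vol$data, nrow = prod(d[1:3]), ncol = vol_channels(vol))
}

#' Map voxel coordinates to world mm
#' @param vol a `vmf_volume`.
#' @param v numeric matrix (n x 3) or vector of 0-based voxel coordinates.
#' @return matrix (n x 3) of world positions in mm.
#' @export
vox_to_world <- function(vol, v) {
  v <- rbind3(v)
  sweep(v %*% t(vol$affine[1:3, 1:3]), 2, vol$affine[1:3, 4], "+")
}

#' Map world mm positions to continuous voxel coordinates
#' @param vol a `vmf_volume`.
#' @param w numeric matrix (n x 3) or vector of world mm positions.
#' @return matrix (n x 3) of 0-based voxel coordinates.
#' @export
world_to_vox <- function(vol, w) {
  w <- rbind3(w)
  inv <- solve(vol$affine)
  sweep(w %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
}

# coerce a vector or matrix to an n x 3 matrix
rbind3 <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

# 1-based linear index from 0-based integer voxel coordinates (n x 3)
vox_linear_index <- function(dims, ijk) {
  1 + ijk[, 1] + ijk[, 2] * dims[1] + ijk[, 3] * dims[1] * dims[2]
}

#' Trilinear interpolation of a volume at continuous voxel coordinates
#'
#' Standard trilinear weighting of the 8 voxel centers surrounding each
#' query point, applied channel-wise. Points must lie inside the grid
#' (`0 <= p <= dim-1` in every axis); it is the caller's job to decide what
#' an out-of-bounds point means (the tracker treats it as leaving the brain).
#'
#' @param vol a `vmf_volume` (scalar or multi-channel).
#' @param p matrix (n x 3) or vector of continuous 0-based voxel coordinates.
#' @return numeric matrix (n x channels).
#' @export
trilinear_sample <- function(vol, p) {
  p <- rbind3(p)
  dims <- vol_dim(vol)
  if (any(!is.finite(p))) stop("non-finite interpolation coordinates")
  if (any(p < 0) || any(sweep(p, 2, dims - 1L, ">"))) {
    stop("interpolation point outside grid bounds")
  }
  X <- vol_matrix(vol)
  trilinear_gather(X, dims, p)
}

# core gather used by trilinear_sample and the pyramid interpolation:
# X is (n_voxels x C) for a grid `dims`, p are in-bounds voxel coords.
trilinear_gather <- function(X, dims, p) {
  n <- nrow(p)
  i0 <- floor(p)
  # clamp the base corner so that i0+1 stays inside even when p sits exactly
  # on the upper boundary (fraction becomes 1 there is impossible: f in [0,1))
  i0 <- pmin(i0, matrix(rep(dims - 2L, each = n), n, 3))
  i0 <- pmax(i0, 0)
  f <- p - i0
  out <- matrix(0, n, ncol(X))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- vox_linear_index(dims, cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz))
    out <- out + X[idx, , drop = FALSE] * w
  }
  out
}

# as trilinear_gather but also returns indices/weights so gradients can be
# scattered back during training (8 corners per point).
trilinear_plan <- function(dims, p) {
  n <- nrow(p)
  i0 <- floor(p)
  i0 <- pmin(i0, matrix(rep(dims - 2L, each = n), n, 3))
  i0 <- pmax(i0, 0)
  f <- p - i0
  idx <- matrix(0L, n, 8)
  w <- matrix(0, n, 8)
  k <- 0L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    k <- k + 1L
    w[, k] <- (if (dx) f[, 1] else 1 - f[, 1]) *
              (if (dy) f[, 2] else 1 - f[, 2]) *
              (if (dz) f[, 3] else 1 - f[, 3])
    idx[, k] <- vox_linear_index(dims, cbind(i0[, 1] + dx, i0[, 2] + dy,
                                             i0[, 3] + dz))
  }
  list(idx = idx, w = w, n_vox = prod(dims))
}

plan_gather <- function(plan, X) {
  out <- matrix(0, nrow(plan$idx), ncol(X))
  for (k in 1:ncol(plan$idx)) {
    out <- out + X[plan$idx[, k], , drop = FALSE] * plan$w[, k]
  }
  out
}

# scatter-add of per-point gradients back onto the grid (transpose of
# plan_gather); duplicate indices are accumulated.
plan_scatter <- function(plan, G) {
  out <- matrix(0, plan$n_vox, ncol(G))
  for (k in 1:ncol(plan$idx)) {
    gi <- plan$idx[, k]
    gw <- G * plan$w[, k]
    s <- rowsum(gw, group = gi)
    rows <- as.integer(rownames(s))
    out[rows, ] <- out[rows, ] + s
  }
  out
}

#' Read a NIfTI volume
#'
#' @param path NIfTI-1/2 file (.nii or .nii.gz).
#' @return a `vmf_volume`; 5D files with a singleton 4th dimension are
#'   squeezed to channel-last 4D.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  dat <- as.array(img)
  d <- dim(dat)
  if (length(d) == 5L && d[4] == 1L) dim(dat) <- d[-4]
  if (!length(dim(dat)) %in% c(3L, 4L)) {
    stop("expected a 3D or 4D NIfTI volume, got ", length(dim(dat)), "D")
  }
  vmf_volume(dat, affine = a)
}

#' Write a volume to NIfTI
#'
#' Integer-valued label volumes round-trip exactly; float data are written
#' as 32-bit float (round-trip within 1e-7 relative).
#'
#' @param vol a `vmf_volume`.
#' @param path output path (.nii or .nii.gz).
#' @param datatype passed to [RNifti::writeNifti()]; `"auto"` picks int32 for
#'   integer-valued data and float32 otherwise.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "auto") {
  dat <- vol$data
  if (identical(datatype, "auto")) {
    datatype <- if (is.integer(dat) ||
                    (max(abs(dat)) < 2^30 && all(dat == round(dat)))) {
      "int32"
    } else {
      "float"
    }
  }
  img <- RNifti::asNifti(dat)
  # pixdim must be set before the xforms or RNifti rescales the affine
  RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
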