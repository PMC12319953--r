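#' Resample a streamline at fixed arc-length spacing
#'
#' Linear interpolation along the polyline; both endpoints are kept.
#'
#' @param S streamline matrix (points x 3, world mm).
#' @param spacing target spacing in mm.
#' @return resampled matrix.
#' @export
resample_streamline <- function(S, spacing) {
  if (nrow(S) < 2) return(S)
  seg <- sqrt(rowSums(diff(S)^2))
  cl <- c(0, cumsum(seg))
  L <- cl[length(cl)]
  if (L == 0) return(S[1, , drop = FALSE])
  s <- unique(c(seq(0, L, by = spacing), L))
  cbind(stats::approx(cl, S[, 1], xout = s)$y,
        stats::approx(cl, S[, 2], xout = s)$y,
        stats::approx(cl, S[, 3], xout = s)$y)
}

#' Streamline density map
#'
#' Counts, per voxel, the number of *distinct* streamlines that visit it.
#' Each streamline is first resampled at half-voxel spacing so no voxel on
#' its path is skipped, then mapped to the set of nearest voxels it touches;
#' each streamline contributes at most 1 per voxel regardless of how many of
#' its points fall there.
#'
#' @param streamlines list of streamline matrices (world mm) or a
#'   `vmf_tractogram` (all streamlines, regardless of status).
#' @param grid a reference `vmf_volume` supplying dims and affine.
#' @return integer-valued scalar `vmf_volume` of counts.
#' @export
density_map <- function(streamlines, grid) {
  if (inherits(streamlines, "vmf_tractogram")) {
    streamlines <- streamlines$streamlines
  }
  dims <- vol_dim(grid)
  counts <- numeric(prod(dims))
  spacing <- min(vol_voxel_size(grid)) / 2
  for (S in streamlines) {
    S <- resample_streamline(S, spacing)
    v <- round(world_to_vox(grid, S))
    inb <- v[, 1] >= 0 & v[, 1] <= dims[1] - 1 &
           v[, 2] >= 0 & v[, 2] <= dims[2] - 1 &
           v[, 3] >= 0 & v[, 3] <= dims[3] - 1
    if (!any(inb)) next
    idx <- unique(vox_linear_index(dims, v[inb, , drop = FALSE]))
    counts[idx] <- counts[idx] + 1
  }
  vmf_volume(array(counts, dims), affine = grid$affine)
}

#' Binary tract mask from a density map
#'
#' Removes voxels whose streamline density falls strictly below the given
#' percentile of the *nonzero* density values (including zeros would make a
#' low percentile trivially 0), then binarizes.
#'
#' @param d density `vmf_volume` from [density_map()].
#' @param pct percentile in (0, 100), default 5.
#' @return binary scalar `vmf_volume`.
#' @export
tract_mask <- function(d, pct = 5) {
  x <- vol_matrix(d)[, 1]
  nz <- x[x > 0]
  if (!length(nz)) stop("density map has no nonzero voxels")
  thr <- stats::quantile(nz, pct / 100, names = FALSE)
  vmf_volume(array(as.integer(x >= thr & x > 0), vol_dim(d)),
             affine = d$affine)
}

#' Overlap metrics between two binary masks
#'
#' Dice = 2|A∩B| / (|A|+|B|), precision = |A∩B|/|A|, recall = |A∩B|/|B|,
#' with A the reconstruction and B the reference.
#'
#' @param a reconstructed binary `vmf_volume` (or logical/numeric array).
#' @param b reference mask on the same grid.
#' @return named list `dice`, `precision`, `recall`.
#' @export
overlap_metrics <- function(a, b) {
  av <- if (inherits(a, "vmf_volume")) vol_matrix(a)[, 1] else as.numeric(a)
  bv <- if (inherits(b, "vmf_volume")) vol_matrix(b)[, 1] else as.numeric(b)
  if (length(av) != length(bv)) stop("masks live on different grids")
  av <- av > 0; bv <- bv > 0
  na <- sum(av); nb <- sum(bv)
  if (na == 0 && nb == 0) stop("both masks are empty")
  inter <- sum(av & bv)
  list(dice = 2 * inter / (na + nb),
       precision = if (na > 0) inter / na else 0,
       recall = if (nb > 0) inter / nb else 0)
}
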