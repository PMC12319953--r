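#' Fiber-bundle specification for synthetic phantoms
#'
#' A bundle is a tube around a parametric centerline: a straight segment,
#' a circular arc, or a polyline. FA varies linearly from the tube axis to
#' its edge; each end of the tube is capped by a ball of cortical gray
#' matter so streamlines can seed and terminate anatomically.
#'
#' @param type `"straight"`, `"arc"` or `"polyline"`.
#' @param from,to endpoints (world mm) for a straight bundle.
#' @param center,radius,normal,angles arc geometry: circle center (mm),
#'   radius (mm), plane normal, and the angle range (radians, length 2).
#' @param points control points (n x 3, mm) for a polyline bundle.
#' @param tube_radius tube radius in mm.
#' @param fa_center,fa_edge FA at the tube axis and at its edge. The
#'   defaults span the fetal white-matter range (about 0.05-0.25), i.e. the
#'   kappa regime 4-100 at alpha = 1600.
#' @param cap_radius radius (mm) of the gray-matter caps at the tube ends.
#' @return list of class `vmf_bundle_spec`.
#' @export
bundle_spec <- function(type = c("straight", "arc", "polyline"),
                        from = NULL, to = NULL,
                        center = NULL, radius = NULL, normal = c(0, 0, 1),
                        angles = c(0, pi / 2), points = NULL,
                        tube_radius = 3.6, fa_center = 0.25, fa_edge = 0.05,
                        cap_radius = 2.4) {
  type <- match.arg(type)
  if (fa_center < 0 || fa_center >= 1 || fa_edge < 0 || fa_edge >= 1) {
    stop("FA values must lie in [0, 1)")
  }
  structure(list(type = type, from = from, to = to, center = center,
                 radius = radius, normal = normal / sqrt(sum(normal^2)),
                 angles = angles, points = points,
                 tube_radius = tube_radius, fa_center = fa_center,
                 fa_edge = fa_edge, cap_radius = cap_radius),
            class = "vmf_bundle_spec")
}

# densely sampled centerline with unit tangents and a transported normal
# frame (N1, N2); spacing in mm
centerline_frame <- function(b, spacing = 0.4) {
  if (b$type == "straight") {
    d <- b$to - b$from
    L <- sqrt(sum(d^2))
    t_hat <- d / L
    s <- seq(0, L, length.out = max(2, ceiling(L / spacing) + 1))
    P <- outer(s, t_hat) + matrix(b$from, length(s), 3, byrow = TRUE)
    Tm <- matrix(t_hat, length(s), 3, byrow = TRUE)
    n1 <- orth_complement(t_hat)
    N1 <- matrix(n1$a, length(s), 3, byrow = TRUE)
    N2 <- matrix(n1$b, length(s), 3, byrow = TRUE)
  } else if (b$type == "arc") {
    nrm <- b$normal
    e <- orth_complement(nrm)
    th <- seq(b$angles[1], b$angles[2],
              length.out = max(2, ceiling(abs(diff(b$angles)) * b$radius /
                                            spacing) + 1))
    ring <- outer(cos(th), e$a) + outer(sin(th), e$b)
    P <- b$radius * ring + matrix(b$center, length(th), 3, byrow = TRUE)
    Tm <- outer(-sin(th), e$a) + outer(cos(th), e$b)
    N1 <- ring                              # radial direction
    N2 <- matrix(nrm, length(th), 3, byrow = TRUE)
  } else {
    P0 <- as.matrix(b$points)
    seg <- sqrt(rowSums(diff(P0)^2))
    cl <- c(0, cumsum(seg))
    s <- seq(0, cl[length(cl)],
             length.out = max(2, ceiling(cl[length(cl)] / spacing) + 1))
    P <- cbind(stats::approx(cl, P0[, 1], xout = s)$y,
               stats::approx(cl, P0[, 2], xout = s)$y,
               stats::approx(cl, P0[, 3], xout = s)$y)
    Tm <- rbind(P[2, ] - P[1, ], (P[-1, , drop = FALSE] -
                                    P[-nrow(P), , drop = FALSE]))
    Tm <- Tm / sqrt(rowSums(Tm^2))
    # parallel-transport an initial normal along the polyline
    N1 <- matrix(0, nrow(P), 3)
    N2 <- matrix(0, nrow(P), 3)
    f <- orth_complement(Tm[1, ])
    N1[1, ] <- f$a; N2[1, ] <- f$b
    for (i in 2:nrow(P)) {
      n1 <- N1[i - 1, ] - sum(N1[i - 1, ] * Tm[i, ]) * Tm[i, ]
      n1 <- n1 / sqrt(sum(n1^2))
      N1[i, ] <- n1
      N2[i, ] <- c(Tm[i, 2] * n1[3] - Tm[i, 3] * n1[2],
                   Tm[i, 3] * n1[1] - Tm[i, 1] * n1[3],
                   Tm[i, 1] * n1[2] - Tm[i, 2] * n1[1])
    }
  }
  list(P = P, T = Tm, N1 = N1, N2 = N2)
}

# exact tube membership for a point cloud: lateral distance to the
# centerline and the local unit tangent. Straight segments and arcs use
# closed-form geometry with flat tube ends (the parameter must lie inside
# the segment/angle range); polylines fall back to the densely sampled
# centerline (rounded ends).
bundle_geometry <- function(b, Vw) {
  n <- nrow(Vw)
  if (b$type == "straight") {
    d <- b$to - b$from
    L <- sqrt(sum(d^2))
    t_hat <- d / L
    w <- sweep(Vw, 2, b$from)
    t_raw <- drop(w %*% t_hat)
    lat <- sqrt(pmax(rowSums(w^2) - t_raw^2, 0))
    inside <- t_raw >= 0 & t_raw <= L & lat <= b$tube_radius
    tang <- matrix(t_hat, n, 3, byrow = TRUE)
    list(inside = inside, dist = lat, tangent = tang)
  } else if (b$type == "arc") {
    nrm <- b$normal
    e <- orth_complement(nrm)
    v <- sweep(Vw, 2, b$center)
    vn <- drop(v %*% nrm)
    x1 <- drop(v %*% e$a)
    x2 <- drop(v %*% e$b)
    theta <- atan2(x2, x1)
    rho <- sqrt(x1^2 + x2^2)
    lat <- sqrt((rho - b$radius)^2 + vn^2)
    inside <- theta >= b$angles[1] & theta <= b$angles[2] &
      lat <= b$tube_radius
    tang <- outer(-sin(theta), e$a) + outer(cos(theta), e$b)
    list(inside = inside, dist = lat, tangent = tang)
  } else {
    fr <- centerline_frame(b, spacing = 0.2)
    best_d2 <- rep(Inf, n)
    best_i <- rep(1L, n)
    chunk <- max(1L, floor(2e7 / nrow(fr$P)))
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(n, start + chunk - 1L)
      d2 <- outer(rowSums(Vw[idx, , drop = FALSE]^2),
                  rep(1, nrow(fr$P))) -
        2 * Vw[idx, , drop = FALSE] %*% t(fr$P) +
        outer(rep(1, length(idx)), rowSums(fr$P^2))
      mi <- max.col(-d2, ties.method = "first")
      best_i[idx] <- mi
      best_d2[idx] <- d2[cbind(seq_along(idx), mi)]
    }
    dist <- sqrt(pmax(best_d2, 0))
    list(inside = dist <= b$tube_radius, dist = dist,
         tangent = fr$T[best_i, , drop = FALSE])
  }
}

# which points lie beyond the start (element 1) / end (element 2) of the
# centerline parameter range; polylines use the nearest sampled point
bundle_beyond_ends <- function(b, Vw) {
  if (b$type == "straight") {
    d <- b$to - b$from
    L <- sqrt(sum(d^2))
    t_raw <- drop(sweep(Vw, 2, b$from) %*% (d / L))
    list(t_raw < 0, t_raw > L)
  } else if (b$type == "arc") {
    e <- orth_complement(b$normal)
    v <- sweep(Vw, 2, b$center)
    theta <- atan2(drop(v %*% e$b), drop(v %*% e$a))
    list(theta < b$angles[1], theta > b$angles[2])
  } else {
    fr <- centerline_frame(b, spacing = 0.5)
    n <- nrow(fr$P)
    near1 <- rowSums(sweep(Vw, 2, fr$P[1, ])^2)
    near2 <- rowSums(sweep(Vw, 2, fr$P[n, ])^2)
    ax1 <- drop(sweep(Vw, 2, fr$P[1, ]) %*% fr$T[1, ])
    ax2 <- drop(sweep(Vw, 2, fr$P[n, ]) %*% fr$T[n, ])
    list(near1 <= near2 & ax1 < 0, near2 < near1 & ax2 > 0)
  }
}

# two unit vectors orthogonal to v and to each other
orth_complement <- function(v) {
  v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a <- ref - sum(ref * v) * v
  a <- a / sqrt(sum(a^2))
  b <- c(v[2] * a[3] - v[3] * a[2],
         v[3] * a[1] - v[1] * a[3],
         v[1] * a[2] - v[2] * a[1])
  list(a = a, b = b)
}

#' Prolate eigenvalues with prescribed FA and mean diffusivity
#'
#' Closed-form inversion for the axially symmetric case
#' (`lambda2 = lambda3`): returns eigenvalues with mean `md` whose FA equals
#' the request. `fa = 1` is degenerate (zero radial diffusivity) and is an
#' error.
#'
#' @param fa target FA in `[0, 1)`.
#' @param md mean diffusivity in mm^2/s.
#' @return numeric length 3, `(lambda1, lambda2, lambda3)` descending.
#' @export
fa_to_eigenvalues <- function(fa, md) {
  if (fa < 0 || fa >= 1) stop("fa must lie in [0, 1)")
  if (md <= 0) stop("md must be positive")
  delta <- fa * sqrt(3 / (9 - 6 * fa^2))
  md * c(1 + 2 * delta, 1 - delta, 1 - delta)
}

#' Phantom specification
#'
#' Describes a synthetic dataset: grid, bundle geometry, tissue layout and
#' the ground-truth streamline sampling. Default values mimic the scale of
#' the fetal setting this package targets (1.2 mm voxels, FA 0.05-0.25).
#'
#' @param grid grid shape (3 integers).
#' @param voxel_size isotropic voxel edge, mm.
#' @param bundles list of [bundle_spec()] objects (at least one).
#' @param md mean diffusivity inside bundles and GM, mm^2/s.
#' @param csf_md mean diffusivity of CSF, mm^2/s.
#' @param csf_rim CSF shell thickness around the brain tissue, mm.
#' @param keypoint_frac 5 x 3 matrix of keypoint ball centers as fractions
#'   of the grid extent (must be non-coplanar); a default non-coplanar set
#'   is used when `NULL`.
#' @param n_gt_per_bundle ground-truth streamlines per bundle (each emitted
#'   in both orientations, as fibers are direction-symmetric).
#' @param gt_spacing point spacing of ground-truth streamlines, mm.
#' @param seed RNG seed for the ground-truth offset sampling.
#' @return list of class `vmf_phantom_spec`.
#' @export
phantom_spec <- function(grid = c(48, 48, 48), voxel_size = 1.2,
                         bundles = list(), md = 1e-3, csf_md = 3e-3,
                         csf_rim = 2.4, keypoint_frac = NULL,
                         n_gt_per_bundle = 100, gt_spacing = 0.6,
                         seed = 1) {
  if (!length(bundles)) stop("at least one bundle is required")
  if (is.null(keypoint_frac)) {
    keypoint_frac <- rbind(c(0.15, 0.15, 0.15),
                           c(0.85, 0.25, 0.20),
                           c(0.25, 0.85, 0.30),
                           c(0.75, 0.75, 0.80),
                           c(0.20, 0.30, 0.85))
  }
  if (nrow(keypoint_frac) != 5) stop("exactly five keypoints are required")
  # non-coplanarity: some 4-subset spans a tetrahedron of nonzero volume
  vol4 <- function(idx) {
    M <- sweep(keypoint_frac[idx[-1], , drop = FALSE], 2,
               keypoint_frac[idx[1], ])
    abs(det(M)) / 6
  }
  if (max(apply(utils::combn(5, 4), 2, vol4)) < 1e-6) {
    stop("keypoints are coplanar; position encoding would be ambiguous")
  }
  structure(list(grid = as.integer(grid), voxel_size = voxel_size,
                 bundles = bundles, md = md, csf_md = csf_md,
                 csf_rim = csf_rim, keypoint_frac = keypoint_frac,
                 n_gt_per_bundle = as.integer(n_gt_per_bundle),
                 gt_spacing = gt_spacing, seed = as.integer(seed)),
            class = "vmf_phantom_spec")
}

# 6-connected binary dilation of a 3D logical array, k iterations
dilate6 <- function(mask, k) {
  d <- dim(mask)
  for (it in seq_len(k)) {
    m <- mask
    m[-1, , ] <- m[-1, , ] | mask[-d[1], , ]
    m[-d[1], , ] <- m[-d[1], , ] | mask[-1, , ]
    m[, -1, ] <- m[, -1, ] | mask[, -d[2], ]
    m[, -d[2], ] <- m[, -d[2], ] | mask[, -1, ]
    m[, , -1] <- m[, , -1] | mask[, , -d[3]]
    m[, , -d[3]] <- m[, , -d[3]] | mask[, , -1]
    mask <- m
  }
  mask
}

#' Generate a synthetic phantom dataset
#'
#' Builds every input the tractography pipeline consumes, with known ground
#' truth: a diffusion-tensor volume (prolate tensors aligned with the local
#' bundle tangent, eigenvalues chosen to hit the requested FA profile at
#' fixed mean diffusivity; overlapping bundles average their tensors and
#' record both tangents as fixels), the FA map, the order-8 SH ODF volume,
#' a tissue segmentation (bundle tubes = WM, caps at the tube ends =
#' cortical GM, a CSF rim around the brain, background elsewhere), the
#' two-fixel direction volume, a 5-region keypoint parcellation,
#' centerline-parallel ground-truth streamlines resampled at `gt_spacing`
#' (each curve in both orientations), and per-bundle ground-truth tube
#' masks.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `vmf_phantom`: list with `tensors`, `fa`, `odf`,
#'   `seg`, `fixels`, `parcellation`, `keypoint_ids`, `gt` (a
#'   `vmf_tractogram`), `gt_masks`, and `spec`.
#' @export
make_phantom <- function(spec) {
  set.seed(spec$seed)
  dims <- spec$grid
  vs <- spec$voxel_size
  affine <- diag(c(vs, vs, vs, 1))
  nvox <- prod(dims)
  ref <- vmf_volume(array(0, dims), affine = affine)
  ix <- rep(seq_len(dims[1]) - 1L, times = dims[2] * dims[3])
  iy <- rep(rep(seq_len(dims[2]) - 1L, each = dims[1]), times = dims[3])
  iz <- rep(seq_len(dims[3]) - 1L, each = dims[1] * dims[2])
  Vw <- vox_to_world(ref, cbind(ix, iy, iz))
  world_max <- (dims - 1) * vs

  T6 <- matrix(0, nvox, 6)
  n_overlap <- numeric(nvox)
  fixels <- matrix(0, nvox, 6)
  wm <- logical(nvox)
  gm <- logical(nvox)
  gt_masks <- vector("list", length(spec$bundles))
  gt_sl <- list()

  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    fr <- centerline_frame(b, spacing = vs / 3)
    margin <- b$tube_radius + b$cap_radius
    lo <- apply(fr$P, 2, min) - margin
    hi <- apply(fr$P, 2, max) + margin
    if (any(lo < -vs / 2) || any(hi > world_max + vs / 2)) {
      stop("bundle ", bi, " (plus caps) exits the grid")
    }
    geo <- bundle_geometry(b, Vw)
    inside <- geo$inside
    wm <- wm | inside
    gt_masks[[bi]] <- as.integer(inside)
    vidx <- which(inside)
    fa_v <- b$fa_center + (b$fa_edge - b$fa_center) *
      geo$dist[vidx] / b$tube_radius
    tang <- geo$tangent[vidx, , drop = FALSE]
    for (j in seq_along(vidx)) {
      lam <- fa_to_eigenvalues(fa_v[j], spec$md)
      e1 <- tang[j, ]
      D <- lam[2] * diag(3) + (lam[1] - lam[2]) * tcrossprod(e1)
      v <- vidx[j]
      T6[v, ] <- T6[v, ] + c(D[1, 1], D[2, 2], D[3, 3],
                             D[1, 2], D[1, 3], D[2, 3])
      slot <- n_overlap[v]
      if (slot < 2) fixels[v, slot * 3 + 1:3] <- e1
      n_overlap[v] <- slot + 1
    }
    # gray-matter caps over the tube end faces: voxels beyond the ends of
    # the centerline, within tube_radius + cap_radius of the endpoint. The
    # cap covers the flat WM end face (so seeding adjacency exists) without
    # sleeving the tube sides, where real cortex would not be.
    beyond <- bundle_beyond_ends(b, Vw)
    for (side in 1:2) {
      endp <- if (side == 1) fr$P[1, ] else fr$P[nrow(fr$P), ]
      d2e <- rowSums(sweep(Vw, 2, endp)^2)
      gm <- gm | (beyond[[side]] & d2e <= (b$tube_radius + b$cap_radius)^2)
    }
    # ground-truth streamlines: centerline-parallel curves at fixed offsets
    # in the transported normal frame, interior to the tube
    rr <- 0.8 * b$tube_radius * sqrt(stats::runif(spec$n_gt_per_bundle))
    th <- 2 * pi * stats::runif(spec$n_gt_per_bundle)
    for (g in seq_len(spec$n_gt_per_bundle)) {
      off_a <- rr[g] * cos(th[g])
      off_b <- rr[g] * sin(th[g])
      S <- fr$P + off_a * fr$N1 + off_b * fr$N2
      S <- resample_streamline(S, spec$gt_spacing)
      gt_sl <- c(gt_sl, list(S), list(S[rev(seq_len(nrow(S))), ]))
    }
  }
  gm <- gm & !wm
  T6[n_overlap > 1, ] <- T6[n_overlap > 1, ] / n_overlap[n_overlap > 1]

  # isotropic GM tissue
  gidx <- which(gm)
  T6[gidx, 1:3] <- spec$md

  # CSF rim around the brain (WM + GM), then background
  brain <- array(wm | gm, dims)
  rim_vox <- max(1L, ceiling(spec$csf_rim / vs))
  csf <- as.logical(dilate6(brain, rim_vox)) & !as.logical(brain)
  cidx <- which(csf)
  T6[cidx, 1:3] <- spec$csf_md

  seg <- integer(nvox)
  seg[which(wm)] <- seg_labels[["wm"]]
  seg[gidx] <- seg_labels[["cgm"]]
  seg[cidx] <- seg_labels[["csf"]]

  # keypoint parcellation: five labeled balls
  parc <- integer(nvox)
  kp_world <- sweep(spec$keypoint_frac, 2, world_max, "*")
  for (k in 1:5) {
    d2k <- rowSums(sweep(Vw, 2, kp_world[k, ])^2)
    parc[d2k <= (1.5 * vs)^2] <- k
  }

  tensors <- vmf_volume(array(T6, c(dims, 6)), affine = affine)
  fa <- fa_volume(tensors)
  structure(list(
    tensors = tensors,
    fa = fa,
    odf = tensor_to_dodf_sh(tensors),
    seg = vmf_volume(array(seg, dims), affine = affine),
    fixels = vmf_volume(array(fixels, c(dims, 6)), affine = affine),
    parcellation = vmf_volume(array(parc, dims), affine = affine),
    keypoint_ids = 1:5,
    gt = vmf_tractogram(gt_sl),
    gt_masks = lapply(gt_masks, function(m) {
      vmf_volume(array(m, dims), affine = affine)
    }),
    spec = spec), class = "vmf_phantom")
}

#' @export
print.vmf_phantom <- function(x, ...) {
  cat("<vmf_phantom> grid ", paste(vol_dim(x$fa), collapse = "x"),
      ", ", length(x$spec$bundles), " bundle(s), ",
      length(x$gt$streamlines), " ground-truth streamlines\n", sep = "")
  invisible(x)
}

#' Ground-truth tube mask of one bundle
#'
#' @param phantom a `vmf_phantom`.
#' @param bundle_index which bundle.
#' @return binary scalar `vmf_volume`.
#' @export
ground_truth_mask <- function(phantom, bundle_index = 1) {
  if (bundle_index < 1 || bundle_index > length(phantom$gt_masks)) {
    stop("no bundle ", bundle_index, " in this phantom")
  }
  phantom$gt_masks[[bundle_index]]
}

#' Volumes list of a phantom, as consumed by the tracker and trainer
#' @param phantom a `vmf_phantom`.
#' @return named list with `odf`, `fa`, `seg`, `fixels`, `parcellation`,
#'   `keypoint_ids`.
#' @export
phantom_volumes <- function(phantom) {
  phantom[c("odf", "fa", "seg", "fixels", "parcellation", "keypoint_ids")]
}
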