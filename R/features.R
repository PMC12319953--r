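#' Interpolate a feature pyramid at tracking points
#'
#' Trilinear samples each pyramid level at the point expressed in that
#' level's own voxel coordinates (`p` at F1, `p/2` at F2, `p/4` at F3) and
#' concatenates the results. Full-resolution points must be inside the grid;
#' the derived coarse-scale coordinates are clamped to their level's border
#' (replication at the half-voxel rim the coarse grids do not cover).
#'
#' @param pyr a `vmf_pyramid`.
#' @param p matrix (n x 3) or vector of full-resolution 0-based voxel
#'   coordinates.
#' @return matrix (n x (C1+C2+C3)).
#' @export
interp_pyramid <- function(pyr, p) {
  p <- rbind3(p)
  if (any(p < 0) || any(sweep(p, 2, pyr$dims - 1L, ">"))) {
    stop("tracking point outside grid bounds")
  }
  out <- vector("list", 3)
  for (s in 1:3) {
    lev <- pyr[[c("F1", "F2", "F3")[s]]]
    ps <- p / 2^(s - 1)
    ps <- pmin(ps, matrix(rep(lev$dims - 1L, each = nrow(p)), nrow(p), 3))
    out[[s]] <- trilinear_gather(lev$X, lev$dims, ps)
  }
  do.call(cbind, out)
}

# gather plan across the three scales (for gradient flow during training)
interp_pyramid_plan <- function(pyr, p) {
  p <- rbind3(p)
  lapply(1:3, function(s) {
    lev <- pyr[[c("F1", "F2", "F3")[s]]]
    ps <- p / 2^(s - 1)
    ps <- pmin(ps, matrix(rep(lev$dims - 1L, each = nrow(p)), nrow(p), 3))
    trilinear_plan(lev$dims, ps)
  })
}

#' Raw feature values on the 3x3x3 voxel neighborhood
#'
#' Returns the F1 (full-resolution) feature values at the centers of the 27
#' voxels around each point's nearest voxel, in a fixed scan order (x
#' fastest), clamped at the grid edge. These raw neighborhood values are
#' concatenated to the interpolated features so the predictor sees both the
#' smooth local field and its discrete surroundings.
#'
#' @param pyr a `vmf_pyramid`.
#' @param p matrix (n x 3) of full-resolution voxel coordinates.
#' @return matrix (n x 27*C1).
#' @export
center_values <- function(pyr, p) {
  plan <- center_values_plan(pyr, p)
  lev <- pyr$F1
  out <- matrix(0, nrow(plan$idx), 27L * ncol(lev$X))
  for (j in 1:27) {
    out[, (j - 1L) * ncol(lev$X) + seq_len(ncol(lev$X))] <-
      lev$X[plan$idx[, j], , drop = FALSE]
  }
  out
}

center_values_plan <- function(pyr, p) {
  p <- rbind3(p)
  dims <- pyr$F1$dims
  ctr <- round(p)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)) # x fastest
  idx <- matrix(0L, nrow(p), 27L)
  for (j in 1:27) {
    ijk <- sweep(ctr, 2, off[j, ], "+")
    ijk <- pmax(ijk, 0)
    ijk <- pmin(ijk, matrix(rep(dims - 1L, each = nrow(p)), nrow(p), 3))
    idx[, j] <- vox_linear_index(dims, ijk)
  }
  list(idx = idx, n_vox = prod(dims))
}

center_values_scatter <- function(plan, G, n_channels) {
  out <- matrix(0, plan$n_vox, n_channels)
  for (j in 1:27) {
    cols <- (j - 1L) * n_channels + seq_len(n_channels)
    s <- rowsum(G[, cols, drop = FALSE], group = plan$idx[, j])
    rows <- as.integer(rownames(s))
    out[rows, ] <- out[rows, ] + s
  }
  out
}

#' Look-ahead point
#'
#' The provisional next position `p + delta * u_prev` (in voxel
#' coordinates): where the streamline would land if it kept its last
#' direction. Features are also gathered there so the model can anticipate
#' what lies ahead.
#'
#' @param p point(s), (n x 3) voxel coordinates.
#' @param u_prev last step direction(s), unit vectors in voxel axes.
#' @param delta look-ahead step in voxels, default 0.5.
#' @return matrix (n x 3).
#' @export
lookahead_point <- function(p, u_prev, delta = 0.5) {
  rbind3(p) + delta * rbind3(u_prev)
}

#' History feature vector from a direction buffer
#'
#' Extracts the directions at lags 1, 3, 5, 7, 9 and 11 steps back
#' (most recent step first) and flattens them to 18 numbers. Lags beyond the
#' buffer length are filled with the oldest available direction, so a
#' freshly seeded streamline repeats its launch direction.
#'
#' @param h matrix (k x 3) of past unit step directions, most recent last.
#' @return numeric vector of length 18.
#' @export
history_vector <- function(h) {
  h <- rbind3(h)
  k <- nrow(h)
  if (k == 0) stop("empty history buffer")
  rows <- pmax(k - c(1, 3, 5, 7, 9, 11) + 1, 1)
  as.numeric(t(h[rows, , drop = FALSE]))
}

# batched variant: H is (n x 3 x k) array of step directions (k most recent
# last), n_steps gives per-streamline valid prefix length
history_matrix <- function(H, n_steps) {
  n <- dim(H)[1]
  out <- matrix(0, n, 18)
  lags <- c(1, 3, 5, 7, 9, 11)
  for (j in 1:6) {
    rows <- pmax(n_steps - lags[j] + 1, 1)
    for (cc in 1:3) {
      out[, (j - 1) * 3 + cc] <- H[cbind(seq_len(n), cc, rows)]
    }
  }
  out
}

#' Centroids of parcellation keypoint regions
#'
#' Unweighted mean of the member voxel centers of each labeled region,
#' mapped to world mm. These five anchors (non-coplanar cortical regions in
#' the real-data setting; labeled balls in phantoms) define the global
#' position encoding.
#'
#' @param parcellation scalar label `vmf_volume`.
#' @param ids the five keypoint label values.
#' @return matrix (5 x 3) of world-mm centroids.
#' @export
keypoint_centroids <- function(parcellation, ids = 1:5) {
  lab <- as.integer(vol_matrix(parcellation))
  dims <- vol_dim(parcellation)
  out <- matrix(0, length(ids), 3)
  for (i in seq_along(ids)) {
    w <- which(lab == ids[i]) - 1L
    if (!length(w)) stop("keypoint label ", ids[i], " absent from parcellation")
    ijk <- cbind(w %% dims[1],
                 (w %/% dims[1]) %% dims[2],
                 w %/% (dims[1] * dims[2]))
    out[i, ] <- colMeans(vox_to_world(parcellation, ijk))
  }
  out
}

#' Global position encoding
#'
#' Euclidean distances from a point to the five keypoint centroids,
#' normalized to sum to one. Components are strictly positive whenever the
#' point does not coincide with a centroid, and always sum to 1.
#'
#' @param p_world point(s) in world mm, (n x 3) or length 3.
#' @param keypoints (5 x 3) centroid matrix from [keypoint_centroids()].
#' @return matrix (n x 5), rows summing to 1.
#' @export
position_vector <- function(p_world, keypoints) {
  p <- rbind3(p_world)
  r <- sapply(seq_len(nrow(keypoints)), function(k) {
    sqrt(rowSums(sweep(p, 2, keypoints[k, ])^2))
  })
  r <- matrix(r, nrow(p))
  s <- rowSums(r)
  if (any(s <= 0)) stop("point coincides with every keypoint centroid")
  r / s
}

#' Assemble the model input vector
#'
#' Fixed concatenation: ODF pyramid features at the current point, ODF
#' features at the look-ahead point, raw 3x3x3 F1 neighborhood values,
#' tissue features, fixel features, 18 history numbers, 5 position numbers.
#'
#' @param parts named list with elements `odf_p`, `odf_look`, `center`,
#'   `tissue`, `fixel`, `history`, `position` (matrices with equal row
#'   counts).
#' @param expected_dim optional total dimension to enforce.
#' @return matrix (n x total dimension).
#' @export
assemble_input <- function(parts, expected_dim = NULL) {
  need <- c("odf_p", "odf_look", "center", "tissue", "fixel", "history",
            "position")
  miss <- setdiff(need, names(parts))
  if (length(miss)) stop("missing input parts: ", paste(miss, collapse = ", "))
  X <- do.call(cbind, lapply(need, function(nm) rbind3(parts[[nm]])))
  if (!is.null(expected_dim) && ncol(X) != expected_dim) {
    stop("assembled input has dimension ", ncol(X), ", expected ",
         expected_dim)
  }
  if (any(!is.finite(X))) stop("non-finite values in assembled model input")
  X
}

#' Total model-input dimension for a configuration
#' @param cfg an [encoder_config()].
#' @return integer.
#' @export
model_input_dim <- function(cfg) {
  C <- cfg$channels; a <- cfg$aux_channels
  as.integer(2 * sum(C) + 27 * C[1] + 2 * sum(a) + 18 + 5)
}

# Build all input parts for a batch of points. `p` are full-res voxel
# coordinates, `u_prev` unit directions in voxel axes (for the look-ahead),
# `hist18` precomputed history features, `p_world` the world positions.
# Returns the assembled matrix plus (optionally) the gather plans needed to
# push gradients back into the pyramids during joint training.
model_features <- function(odf_pyr, tissue_pyr, fixel_pyr, p, u_prev,
                           hist18, p_world, keypoints, cfg,
                           lookahead_delta = 0.5, keep_plans = FALSE) {
  p <- rbind3(p)
  look <- lookahead_point(p, u_prev, lookahead_delta)
  # the look-ahead may poke past the border; clamp it into the grid
  look <- pmax(look, 0)
  look <- pmin(look, matrix(rep(odf_pyr$dims - 1L, each = nrow(p)),
                            nrow(p), 3))
  plans <- list(
    odf_p = interp_pyramid_plan(odf_pyr, p),
    odf_look = interp_pyramid_plan(odf_pyr, look),
    center = center_values_plan(odf_pyr, p),
    tissue = interp_pyramid_plan(tissue_pyr, p),
    fixel = interp_pyramid_plan(fixel_pyr, p))
  parts <- list(
    odf_p = feature_gather(plans$odf_p, odf_pyr),
    odf_look = feature_gather(plans$odf_look, odf_pyr),
    center = center_gather(plans$center, odf_pyr),
    tissue = feature_gather(plans$tissue, tissue_pyr),
    fixel = feature_gather(plans$fixel, fixel_pyr),
    history = hist18,
    position = position_vector(p_world, keypoints))
  X <- assemble_input(parts, expected_dim = model_input_dim(cfg))
  if (keep_plans) attr(X, "plans") <- plans
  X
}

feature_gather <- function(plan3, pyr) {
  do.call(cbind, lapply(1:3, function(s) {
    plan_gather(plan3[[s]], pyr[[c("F1", "F2", "F3")[s]]]$X)
  }))
}

center_gather <- function(plan, pyr) {
  C1 <- ncol(pyr$F1$X)
  out <- matrix(0, nrow(plan$idx), 27L * C1)
  for (j in 1:27) {
    out[, (j - 1L) * C1 + seq_len(C1)] <- pyr$F1$X[plan$idx[, j], , drop = FALSE]
  }
  out
}

# split gradient on the assembled input back into pyramid-level gradients.
# Returns list(odf = list(g1,g2,g3), tissue = ..., fixel = ...).
model_features_bwd <- function(G, plans, cfg) {
  C <- cfg$channels; a <- cfg$aux_channels
  cuts <- cumsum(c(sum(C), sum(C), 27 * C[1], sum(a), sum(a), 18, 5))
  slice <- function(i) {
    lo <- if (i == 1) 1L else cuts[i - 1] + 1L
    G[, lo:cuts[i], drop = FALSE]
  }
  split3 <- function(Gs, widths) {
    ends <- cumsum(widths)
    lapply(1:3, function(s) {
      lo <- if (s == 1) 1L else ends[s - 1] + 1L
      Gs[, lo:ends[s], drop = FALSE]
    })
  }
  scat3 <- function(plan3, Gs, widths) {
    gs <- split3(Gs, widths)
    lapply(1:3, function(s) plan_scatter(plan3[[s]], gs[[s]]))
  }
  g_odf <- scat3(plans$odf_p, slice(1), C)
  g_odf_l <- scat3(plans$odf_look, slice(2), C)
  g_odf <- lapply(1:3, function(s) g_odf[[s]] + g_odf_l[[s]])
  g_odf[[1]] <- g_odf[[1]] + center_values_scatter(plans$center, slice(3), C[1])
  list(odf = g_odf,
       tissue = scat3(plans$tissue, slice(4), a),
       fixel = scat3(plans$fixel, slice(5), a))
}
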