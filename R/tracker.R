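#' Tracking configuration
#'
#' Inference-time parameters of the probabilistic tracker.
#'
#' @param step propagation step in mm (0.6 mm, half the working voxel size).
#' @param alphas FA-to-kappa scales to track with; the final tractogram
#'   merges the streamlines of all levels. Smaller alpha means broader vMF
#'   sampling (better for highly curved tracts), larger alpha tighter
#'   sampling (better for straight tracts).
#' @param max_length streamlines longer than this (mm) are discarded.
#' @param seeds_per_neighbor streamlines launched per gray-white neighboring
#'   voxel pair.
#' @param pos_jitter uniform seed-position jitter, +/- mm per axis.
#' @param angle_jitter uniform jitter, +/- degrees, added independently to
#'   the polar and azimuth angles of the launch direction.
#' @param seed master RNG seed; all randomness (seed jitter, per-streamline
#'   vMF draws) is derived from it through named substreams, so results do
#'   not depend on iteration order.
#' @return list of class `vmf_tracking_config`.
#' @export
tracking_config <- function(step = 0.6, alphas = c(1600, 3200, 6400),
                            max_length = 130, seeds_per_neighbor = 5,
                            pos_jitter = 0.6, angle_jitter = 30, seed = 1) {
  stopifnot(step > 0, max_length > step, seeds_per_neighbor >= 1)
  structure(list(step = step, alphas = alphas, max_length = max_length,
                 seeds_per_neighbor = as.integer(seeds_per_neighbor),
                 pos_jitter = pos_jitter, angle_jitter = angle_jitter,
                 seed = as.integer(seed)),
            class = "vmf_tracking_config")
}

# deterministic substream seed derivation (kept below 2^31)
rng_substream <- function(master, i) {
  as.integer((as.double(master %% 65521L) * 48271 + as.double(i) * 16807 +
                1) %% 2147483647)
}

#' Tractogram container
#'
#' @param streamlines list of streamline point matrices (world mm).
#' @param status per-streamline status: `accepted`, `rejected_csf`,
#'   `rejected_exit` (left the intracranial mask) or `rejected_length`.
#' @return object of class `vmf_tractogram`.
#' @export
vmf_tractogram <- function(streamlines,
                           status = rep("accepted", length(streamlines))) {
  stopifnot(length(streamlines) == length(status))
  ok <- c("accepted", "rejected_csf", "rejected_exit", "rejected_length")
  if (!all(status %in% ok)) {
    stop("unknown status value(s): ",
         paste(setdiff(unique(status), ok), collapse = ", "))
  }
  structure(list(streamlines = streamlines, status = status),
            class = "vmf_tractogram")
}

#' @export
print.vmf_tractogram <- function(x, ...) {
  cat("<vmf_tractogram> ", length(x$streamlines), " streamlines (",
      sum(x$status == "accepted"), " accepted)\n", sep = "")
  invisible(x)
}

#' Surface seeding on the gray-white interface
#'
#' For every cortical gray-matter voxel with at least one white-matter
#' 6-neighbor, launches `seeds_per_neighbor` streamlines toward each such
#' neighbor: the base direction connects the two voxel centers, the seed
#' position is the gray-matter voxel center jittered uniformly by
#' `+/- pos_jitter` mm per axis, and the direction is jittered by
#' `+/- angle_jitter` degrees independently on its polar and azimuth angles.
#' Uses the current R RNG state (the tracker seeds it from the master seed).
#'
#' @param seg scalar label `vmf_volume` (codes in [seg_labels]).
#' @param cfg a [tracking_config()].
#' @return list with `pos` (n x 3 world mm), `dir` (n x 3 unit vectors) and
#'   `voxel` (n x 3 integer GM voxel of each seed); zero rows (with a
#'   warning) when no gray-white adjacency exists.
#' @export
generate_seeds <- function(seg, cfg = tracking_config()) {
  lab <- array(as.integer(vol_matrix(seg)), vol_dim(seg))
  dims <- vol_dim(seg)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  gm <- which(lab == seg_labels["cgm"], arr.ind = TRUE)
  pairs_gm <- NULL
  pairs_wm <- NULL
  if (nrow(gm)) {
    for (o in seq_len(6)) {
      nb <- sweep(gm, 2, offs[o, ], "+")
      inb <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
             nb[, 2] >= 1 & nb[, 2] <= dims[2] &
             nb[, 3] >= 1 & nb[, 3] <= dims[3]
      if (!any(inb)) next
      g <- gm[inb, , drop = FALSE]
      w <- nb[inb, , drop = FALSE]
      iswm <- lab[w] == seg_labels["wm"]
      if (any(iswm)) {
        pairs_gm <- rbind(pairs_gm, g[iswm, , drop = FALSE])
        pairs_wm <- rbind(pairs_wm, w[iswm, , drop = FALSE])
      }
    }
  }
  if (is.null(pairs_gm) || !nrow(pairs_gm)) {
    warning("no gray-white adjacency found; no seeds generated")
    return(list(pos = matrix(0, 0, 3), dir = matrix(0, 0, 3),
                voxel = matrix(0L, 0, 3)))
  }
  k <- cfg$seeds_per_neighbor
  n_pairs <- nrow(pairs_gm)
  rep_idx <- rep(seq_len(n_pairs), each = k)
  gm_w <- vox_to_world(seg, pairs_gm[rep_idx, , drop = FALSE] - 1L)
  wm_w <- vox_to_world(seg, pairs_wm[rep_idx, , drop = FALSE] - 1L)
  base <- wm_w - gm_w
  base <- base / sqrt(rowSums(base^2))
  n <- n_pairs * k
  pos <- gm_w + matrix(stats::runif(3 * n, -cfg$pos_jitter, cfg$pos_jitter),
                       n, 3)
  ang <- to_spherical(base)
  jit <- cfg$angle_jitter * pi / 180
  ang[, 1] <- ang[, 1] + stats::runif(n, -jit, jit)
  ang[, 2] <- ang[, 2] + stats::runif(n, -jit, jit)
  list(pos = pos, dir = from_spherical(ang),
       voxel = pairs_gm[rep_idx, , drop = FALSE] - 1L)
}

#' Classify a candidate next point against the tissue segmentation
#'
#' Nearest-voxel lookup: white matter means "keep propagating"; cortical or
#' subcortical gray matter terminates the streamline as anatomically
#' plausible; CSF, background, or leaving the grid rejects it.
#'
#' @param p_next candidate point(s), world mm (n x 3 or length 3).
#' @param seg scalar label `vmf_volume`.
#' @return character vector: `continue`, `accepted`, `rejected_csf` or
#'   `rejected_exit`.
#' @export
classify_termination <- function(p_next, seg) {
  p <- rbind3(p_next)
  dims <- vol_dim(seg)
  v <- round(world_to_vox(seg, p))
  out <- rep("rejected_exit", nrow(p))
  inb <- v[, 1] >= 0 & v[, 1] <= dims[1] - 1 &
         v[, 2] >= 0 & v[, 2] <= dims[2] - 1 &
         v[, 3] >= 0 & v[, 3] <= dims[3] - 1
  if (any(inb)) {
    lab <- vol_matrix(seg)[vox_linear_index(dims, v[inb, , drop = FALSE]), 1]
    cls <- rep("rejected_exit", sum(inb))
    cls[lab == seg_labels["wm"]] <- "continue"
    cls[lab %in% seg_labels[c("cgm", "scgm")]] <- "accepted"
    cls[lab == seg_labels["csf"]] <- "rejected_csf"
    out[inb] <- cls
  }
  out
}

# tracking context: everything propagate needs, computed once per volume set
track_context <- function(model, volumes) {
  pyr <- model_pyramids(model, volumes, keep_cache = FALSE)
  keypoints <- keypoint_centroids(volumes$parcellation, volumes$keypoint_ids
                                  %||% 1:5)
  list(model = model, pyr = pyr, fa = volumes$fa, seg = volumes$seg,
       keypoints = keypoints, dims = vol_dim(volumes$odf),
       affine = volumes$odf$affine,
       A3inv = solve(volumes$odf$affine)[1:3, 1:3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# batched propagation of many seeds at one alpha level.
# U is the (n x 2*max_steps) matrix of per-streamline uniforms.
propagate_batch <- function(ctx, pos, dir, alpha, cfg, U) {
  n <- nrow(pos)
  max_steps <- floor(cfg$max_length / cfg$step)
  dims <- ctx$dims
  P <- array(NA_real_, c(n, 3, max_steps + 1L))
  P[, , 1] <- pos
  H <- array(0, c(n, 3, max_steps + 1L))
  H[, , 1] <- dir
  status <- rep(NA_character_, n)
  steps <- rep(0L, n)          # points appended beyond the seed
  cur <- pos
  active <- rep(TRUE, n)
  segm <- vol_matrix(ctx$seg)
  for (t in seq_len(max_steps)) {
    if (!any(active)) break
    ai <- which(active)
    if (t == 1L) {
      # the launch step follows the (jittered) seed direction itself; the
      # model takes over once the streamline has entered the white matter
      mu_s <- dir[ai, , drop = FALSE]
    } else {
      p_vox <- world_to_vox(ctx$fa, cur[ai, , drop = FALSE])
      # clamp feature-extraction coords into the grid (the point itself may
      # sit in the outer half-voxel rim of a border voxel)
      p_feat <- pmax(p_vox, 0)
      p_feat <- pmin(p_feat, matrix(rep(dims - 1L, each = length(ai)),
                                    length(ai), 3))
      u_prev <- matrix(0, length(ai), 3)
      for (cc in 1:3) u_prev[, cc] <- H[cbind(ai, cc, steps[ai] + 1L)]
      upv <- u_prev %*% t(ctx$A3inv)
      upv <- upv / sqrt(rowSums(upv^2))
      hist18 <- history_matrix(H[ai, , , drop = FALSE], steps[ai] + 1L)
      X <- model_features(ctx$pyr$odf, ctx$pyr$tissue, ctx$pyr$fixel,
                          p_feat, upv, hist18, cur[ai, , drop = FALSE],
                          ctx$keypoints, ctx$model$cfg)
      mu <- predict_direction(ctx$model, X)
      fa <- drop(plan_gather(trilinear_plan(dims, p_feat),
                             vol_matrix(ctx$fa)))
      kappa <- alpha * fa^2
      mu_s <- vmf_sample_rows(mu, kappa, U[ai, 2 * t - 1], U[ai, 2 * t])
    }
    p_next <- cur[ai, , drop = FALSE] + cfg$step * mu_s
    cls <- classify_termination(p_next, ctx$seg)
    if (t == 1L) {
      # a plausible streamline must traverse white matter: terminating in
      # gray matter on the launch step means it never entered WM
      cls[cls == "accepted"] <- "rejected_exit"
    }
    app <- cls %in% c("continue", "accepted")
    if (any(app)) {
      rows <- ai[app]
      k <- steps[rows] + 2L
      P[cbind(rep(rows, 3), rep(1:3, each = sum(app)), rep(k, 3))] <-
        p_next[app, ]
      H[cbind(rep(rows, 3), rep(1:3, each = sum(app)), rep(k, 3))] <-
        mu_s[app, ]
      steps[rows] <- steps[rows] + 1L
      cur[rows, ] <- p_next[app, , drop = FALSE]
    }
    done_acc <- ai[cls == "accepted"]
    status[done_acc] <- "accepted"
    status[ai[cls == "rejected_csf"]] <- "rejected_csf"
    status[ai[cls == "rejected_exit"]] <- "rejected_exit"
    active[ai] <- cls == "continue"
    if (t == max_steps) status[which(active)] <- "rejected_length"
  }
  status[is.na(status)] <- "rejected_length"
  sl <- lapply(seq_len(n), function(i) {
    t(P[i, , seq_len(steps[i] + 1L), drop = TRUE])
  })
  # single-point streamlines come back as a column; normalize shape
  sl <- lapply(sl, function(S) if (is.null(dim(S))) matrix(S, 1, 3) else S)
  vmf_tractogram(sl, status)
}

#' Propagate a single seed into a streamline
#'
#' The launch step follows the seed's (jittered) direction; from then on the
#' tracker assembles the model input at the current point (with look-ahead),
#' predicts the mean direction, draws the actual step direction from
#' \eqn{vMF(\mu, \alpha FA^2)}, and advances by `step` mm while the next
#' point stays in white matter. Termination is classified by
#' [classify_termination()]; a streamline that terminates in gray matter on
#' its launch step never traversed white matter and is rejected; over-long
#' streamlines are discarded.
#'
#' @param model a `vmf_tract_model`.
#' @param volumes named list: `odf`, `fa`, `seg`, `fixels`, `parcellation`
#'   (and optionally `keypoint_ids`).
#' @param seed list with `pos` (world mm) and `dir` (unit launch direction).
#' @param alpha vMF concentration scale.
#' @param cfg a [tracking_config()].
#' @param unif optional vector of `2 * floor(max_length/step)` uniforms.
#' @return list with `streamline` (points x 3, world mm) and `status`.
#' @export
propagate <- function(model, volumes, seed, alpha, cfg = tracking_config(),
                      unif = NULL) {
  ctx <- track_context(model, volumes)
  max_steps <- floor(cfg$max_length / cfg$step)
  if (is.null(unif)) unif <- stats::runif(2 * max_steps)
  tg <- propagate_batch(ctx, rbind3(seed$pos), rbind3(seed$dir), alpha, cfg,
                        matrix(unif, nrow = 1))
  list(streamline = tg$streamlines[[1]], status = tg$status)
}

#' Whole-brain (whole-phantom) tractography
#'
#' Generates gray-white interface seeds once, then tracks every seed at each
#' `alpha` level; the final tractogram merges the accepted streamlines of
#' all levels. All randomness derives from `cfg$seed`: seeding uses one
#' substream, and every (streamline, alpha) pair gets its own uniform
#' stream, so the result is reproducible and independent of scheduling.
#'
#' @param model a trained `vmf_tract_model`.
#' @param volumes named list: `odf`, `fa`, `seg`, `fixels`, `parcellation`
#'   (optionally `keypoint_ids`).
#' @param cfg a [tracking_config()].
#' @param keep_rejected also return rejected streamlines (default FALSE:
#'   accepted only, as in the merged tractogram).
#' @return list with `tractogram` (a `vmf_tractogram`), `stats` (data frame
#'   of per-alpha status counts) and `retained` (overall accepted fraction).
#' @export
track_whole_brain <- function(model, volumes, cfg = tracking_config(),
                              keep_rejected = FALSE) {
  ctx <- track_context(model, volumes)
  set.seed(rng_substream(cfg$seed, 1L))
  seeds <- generate_seeds(volumes$seg, cfg)
  n <- nrow(seeds$pos)
  max_steps <- floor(cfg$max_length / cfg$step)
  all_sl <- list()
  all_st <- character(0)
  all_alpha <- numeric(0)
  stats_rows <- list()
  for (a_i in seq_along(cfg$alphas)) {
    alpha <- cfg$alphas[a_i]
    U <- matrix(0, n, 2 * max_steps)
    for (i in seq_len(n)) {
      set.seed(rng_substream(cfg$seed, 1000L + a_i * 400000L + i))
      U[i, ] <- stats::runif(2 * max_steps)
    }
    tg <- propagate_batch(ctx, seeds$pos, seeds$dir, alpha, cfg, U)
    keep <- if (keep_rejected) rep(TRUE, n) else tg$status == "accepted"
    all_sl <- c(all_sl, tg$streamlines[keep])
    all_st <- c(all_st, tg$status[keep])
    all_alpha <- c(all_alpha, rep(alpha, sum(keep)))
    stats_rows[[a_i]] <- data.frame(
      alpha = alpha,
      n_seeds = n,
      accepted = sum(tg$status == "accepted"),
      rejected_csf = sum(tg$status == "rejected_csf"),
      rejected_exit = sum(tg$status == "rejected_exit"),
      rejected_length = sum(tg$status == "rejected_length"))
  }
  stats <- do.call(rbind, stats_rows)
  out <- vmf_tractogram(all_sl, all_st)
  list(tractogram = out, stats = stats,
       retained = sum(stats$accepted) / max(1L, sum(stats$n_seeds)),
       alpha = all_alpha)
}

#' Total length of a streamline in mm
#' @param S streamline point matrix (world mm).
#' @return numeric scalar.
#' @export
streamline_length <- function(S) {
  if (nrow(S) < 2) return(0)
  sum(sqrt(rowSums(diff(S)^2)))
}
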