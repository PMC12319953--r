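#' Construct an untrained tractography propagation model
#'
#' Bundles the ODF encoder, the two auxiliary (tissue / fixel)
#' convolutional encoders and the final MLP head that maps the assembled
#' feature vector to spherical coordinates `(theta, phi)` of the next step
#' direction. All weights are initialized from the current R RNG state (set
#' a seed first for reproducibility).
#'
#' @param cfg an [encoder_config()].
#' @param head_hidden hidden-layer widths of the prediction MLP.
#' @param odf_channels input channels of the ODF volume (45 at SH order 8).
#' @return object of class `vmf_tract_model`.
#' @export
tract_model <- function(cfg, head_hidden = c(1024, 256, 64),
                        odf_channels = 45) {
  d_in <- model_input_dim(cfg)
  widths <- c(d_in, head_hidden, 2L)
  head <- lapply(seq_len(length(widths) - 1L), function(i) {
    gain <- if (i == length(widths) - 1L) 1 else 2
    nn_init_linear(widths[i], widths[i + 1L], gain = gain)
  })
  structure(list(cfg = cfg,
                 head_hidden = head_hidden,
                 odf_channels = odf_channels,
                 input_dim = d_in,
                 enc = encoder_init(cfg, odf_channels),
                 tissue = aux_encoder_init(cfg, 4L),
                 fixel = aux_encoder_init(cfg, 6L),
                 head = head,
                 x_center = NULL,
                 x_scale = NULL,
                 epochs_trained = 0L,
                 loss_history = numeric(0)),
            class = "vmf_tract_model")
}

#' @export
print.vmf_tract_model <- function(x, ...) {
  np <- length(nn_flatten(x$enc)) + length(nn_flatten(x$tissue)) +
    length(nn_flatten(x$fixel)) + length(nn_flatten(x$head))
  cat("<vmf_tract_model> input dim ", x$input_dim,
      ", ", format(np, big.mark = ","), " parameters, ",
      x$epochs_trained, " training epoch(s)", sep = "")
  if (length(x$loss_history)) {
    cat(", final loss ", signif(utils::tail(x$loss_history, 1), 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

# MLP head forward; returns angles (n x 2) and caches
head_fwd <- function(head, X) {
  caches <- vector("list", 2L * length(head) - 1L)
  cur <- X
  k <- 0L
  for (i in seq_along(head)) {
    k <- k + 1L
    caches[[k]] <- nn_linear_fwd(head[[i]], cur)
    cur <- caches[[k]]$out
    if (i < length(head)) {
      k <- k + 1L
      caches[[k]] <- nn_relu_fwd(cur)
      cur <- caches[[k]]$out
    }
  }
  list(out = cur, caches = caches)
}

head_bwd <- function(head, caches, G) {
  grads <- vector("list", length(head))
  k <- length(caches)
  for (i in rev(seq_along(head))) {
    b <- nn_linear_bwd(head[[i]], caches[[k]], G)
    grads[[i]] <- b$grad
    G <- b$gX
    k <- k - 1L
    if (i > 1L) {
      G <- nn_relu_bwd(caches[[k]], G)
      k <- k - 1L
    }
  }
  list(grad = grads, gX = G)
}

# angles (n x 2) -> unit vectors, plus backward of that map
angles_to_dir <- function(ang) from_spherical(ang)

angles_to_dir_bwd <- function(ang, gU) {
  st <- sin(ang[, 1]); ct <- cos(ang[, 1])
  sp <- sin(ang[, 2]); cp <- cos(ang[, 2])
  gtheta <- gU[, 1] * ct * cp + gU[, 2] * ct * sp - gU[, 3] * st
  gphi <- -gU[, 1] * st * sp + gU[, 2] * st * cp
  cbind(gtheta, gphi)
}

#' Predict the next propagation direction
#'
#' Runs the MLP head on assembled input features; the two outputs are read
#' as spherical coordinates and converted to a unit vector, so predictions
#' have unit norm by construction.
#'
#' @param model a `vmf_tract_model`.
#' @param x assembled model-input matrix (n x input_dim), e.g. from
#'   [assemble_input()].
#' @return matrix (n x 3) of unit direction vectors.
#' @export
predict_direction <- function(model, x) {
  x <- rbind3(x)
  if (any(!is.finite(x))) stop("non-finite model input")
  x <- standardize_input(model, x)
  ang <- head_fwd(model$head, x)$out
  if (any(!is.finite(ang))) stop("non-finite activations in prediction head")
  angles_to_dir(ang)
}

#' @export
predict.vmf_tract_model <- function(object, features, ...) {
  predict_direction(object, features)
}

#' Build training samples from a tractogram
#'
#' One sample per streamline point that has a successor: the input point,
#' the unit target direction to the next point, the history features (lags
#' 1,3,...,11 with oldest-direction padding; the first point of a streamline
#' uses its own launch direction, mirroring how seeds carry an initial
#' direction at test time), and the interpolated FA at the point.
#' Zero-length steps are skipped and counted.
#'
#' @param tractogram list of streamline matrices (ordered points, world mm)
#'   or a `vmf_tractogram`.
#' @param fa the FA `vmf_volume` (also supplies the reference grid).
#' @return object of class `vmf_training_set`: a list with `p_vox`,
#'   `p_world`, `u_prev_vox`, `hist18`, `target`, `fa`, `n_skipped`.
#' @export
make_training_samples <- function(tractogram, fa) {
  sl <- if (inherits(tractogram, "vmf_tractogram")) tractogram$streamlines
        else tractogram
  if (!length(sl)) stop("empty tractogram")
  A3 <- solve(fa$affine)[1:3, 1:3]
  lst_p <- lst_t <- lst_h <- lst_up <- vector("list", length(sl))
  skipped <- 0L
  for (s in seq_along(sl)) {
    S <- sl[[s]]
    if (nrow(S) < 2) { skipped <- skipped + (nrow(S) > 0); next }
    d <- diff(S)
    len <- sqrt(rowSums(d^2))
    ok <- len > 1e-9
    skipped <- skipped + sum(!ok)
    U <- d[ok, , drop = FALSE] / len[ok]
    P <- S[c(ok, FALSE), , drop = FALSE]
    m <- nrow(U)
    if (!m) next
    lags <- c(1, 3, 5, 7, 9, 11)
    Hm <- matrix(0, m, 18)
    for (j in 1:6) {
      rows <- pmax(seq_len(m) - lags[j], 1)
      Hm[, (j - 1) * 3 + 1:3] <- U[rows, , drop = FALSE]
    }
    lst_p[[s]] <- P
    lst_t[[s]] <- U
    lst_h[[s]] <- Hm
    lst_up[[s]] <- U[pmax(seq_len(m) - 1, 1), , drop = FALSE]
  }
  P <- do.call(rbind, lst_p)
  if (is.null(P) || !nrow(P)) stop("no usable training samples")
  Uprev <- do.call(rbind, lst_up)
  # previous direction expressed in voxel axes for the look-ahead
  Uv <- Uprev %*% t(A3)
  Uv <- Uv / sqrt(rowSums(Uv^2))
  p_vox <- world_to_vox(fa, P)
  structure(list(p_vox = p_vox,
                 p_world = P,
                 u_prev_vox = Uv,
                 hist18 = do.call(rbind, lst_h),
                 target = do.call(rbind, lst_t),
                 fa = drop(trilinear_sample(fa, p_vox)),
                 n_skipped = skipped),
            class = "vmf_training_set")
}

#' @export
print.vmf_training_set <- function(x, ...) {
  cat("<vmf_training_set> ", nrow(x$p_vox), " samples (",
      x$n_skipped, " degenerate steps skipped)\n", sep = "")
  invisible(x)
}

#' Training configuration
#'
#' @param batch_size samples per SGD iteration; 16,000 at full scale
#'   (phantom runs use what the dataset affords).
#' @param lr SGD learning rate (initial rate 1e-3 at full scale; the
#'   desk-scale default here is larger because the scaled-down model and
#'   batch sizes support it).
#' @param momentum SGD momentum.
#' @param alpha FA-to-kappa scale for target augmentation, default 1600.
#' @param max_epochs epoch cap.
#' @param patience,tol plateau rule: stop when the epoch loss fails to
#'   improve on its best value by more than `tol` for `patience` consecutive
#'   epochs.
#' @param loss `"cosine"` (default: cosine similarity against the
#'   vMF-augmented target) or `"vmf_nll"` (full negative log-likelihood with
#'   FA-modulated kappa).
#' @param joint also backpropagate into the encoders (default); `FALSE`
#'   freezes the encoders and trains the head only.
#' @param warmup_epochs with `joint = TRUE`, number of initial epochs during
#'   which only the head is updated (against the frozen initial encoders)
#'   before the joint phase begins. A converged head makes the joint phase
#'   stable; gradients reach every encoder parameter once it starts.
#' @param joint_epochs length of the joint phase. Epochs after
#'   `warmup_epochs + joint_epochs` train the head only again (a polish
#'   phase), letting it re-converge to the updated encoder features.
#' @param enc_lr_scale learning-rate multiplier for the encoder weights in
#'   the joint phase (they receive much larger raw gradients than the head).
#' @param joint_lr_scale learning-rate multiplier applied to the head during
#'   the joint phase, so the converged head adapts gently while the feature
#'   distribution shifts under it.
#' @param clip per-module global gradient-norm clip.
#' @param verbose print per-epoch losses.
#' @return list of class `vmf_train_config`.
#' @export
train_config <- function(batch_size = 16000, lr = 0.05, momentum = 0.9,
                         alpha = 1600, max_epochs = 100, patience = 10,
                         tol = 1e-3, loss = c("cosine", "vmf_nll"),
                         joint = TRUE, warmup_epochs = 50,
                         joint_epochs = 10, enc_lr_scale = 0.02,
                         joint_lr_scale = 0.1, clip = 5, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(batch_size >= 1, lr > 0, alpha > 0, max_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, alpha = alpha,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), tol = tol, loss = loss,
                 joint = isTRUE(joint),
                 warmup_epochs = as.integer(warmup_epochs),
                 joint_epochs = as.integer(joint_epochs),
                 enc_lr_scale = enc_lr_scale,
                 joint_lr_scale = joint_lr_scale, clip = clip,
                 verbose = isTRUE(verbose)),
            class = "vmf_train_config")
}

# rescale a gradient tree so its global L2 norm is at most `maxn`
nn_clip_norm <- function(g, maxn) {
  n <- sqrt(sum(nn_flatten(g)^2))
  if (is.finite(n) && n > maxn) {
    nn_map2(g, g, function(a, b) a * (maxn / n))
  } else {
    g
  }
}

# fixed per-feature affine standardization; stats are estimated once from
# the training set (with the initial encoder weights) and stored on the
# model so training and inference see identically scaled inputs
standardize_input <- function(model, X) {
  if (is.null(model$x_center)) return(X)
  sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
}

estimate_standardization <- function(X) {
  s <- apply(X, 2, stats::sd)
  # near-constant features are left unscaled rather than amplified
  floor_s <- max(1e-3, 1e-3 * stats::median(s[s > 0]))
  s[!is.finite(s) | s < floor_s] <- 1
  list(center = colMeans(X), scale = s)
}

# loss value and gradient on predicted unit directions
direction_loss <- function(u_pred, target, kappa, type) {
  n <- nrow(u_pred)
  if (type == "cosine") {
    u_aug <- augment_directions(target, kappa)
    list(value = mean(cosine_loss(u_pred, u_aug)), gU = -u_aug / n)
  } else {
    list(value = mean(vmf_nll_loss(u_pred, target, kappa)),
         gU = -(kappa * target) / n)
  }
}

#' One SGD step of the prediction head
#'
#' Augments the batch targets with vMF noise (`kappa = alpha * FA^2`),
#' computes the configured loss of the predicted directions, and applies one
#' SGD update to the head weights. The full joint loop (including encoder
#' updates) lives in [train_model()]; this exposed step covers the
#' head-only case and is what the unit tests exercise.
#'
#' @param model a `vmf_tract_model`.
#' @param X assembled input batch (n x input_dim).
#' @param target unit target directions (n x 3).
#' @param fa FA values at the batch points.
#' @param cfg a [train_config()].
#' @param state optional momentum state from a previous call.
#' @return list: updated `model`, scalar `loss`, updated `state`.
#' @export
training_step <- function(model, X, target, fa, cfg = train_config(),
                          state = NULL) {
  if (!nrow(rbind3(X))) stop("empty training batch")
  kappa <- kappa_from_fa(fa, cfg$alpha)
  hf <- head_fwd(model$head, standardize_input(model, X))
  u_pred <- angles_to_dir(hf$out)
  ls <- direction_loss(u_pred, target, kappa, cfg$loss)
  gang <- angles_to_dir_bwd(hf$out, ls$gU)
  hb <- head_bwd(model$head, hf$caches, gang)
  if (is.null(state)) state <- nn_zeros_like(model$head)
  upd <- nn_sgd_step(model$head, hb$grad, state, cfg$lr, cfg$momentum)
  model$head <- upd$params
  list(model = model, loss = ls$value, state = upd$velocity)
}

#' Encode all input volumes into the three pyramids
#'
#' @param model a `vmf_tract_model`.
#' @param volumes named list with `odf` (SH volume), `seg` (label volume)
#'   and `fixels` (6-channel direction volume).
#' @param keep_cache keep activations (training).
#' @return list of pyramids `odf`, `tissue`, `fixel`.
#' @export
model_pyramids <- function(model, volumes, keep_cache = FALSE) {
  list(odf = encode_odf(volumes$odf, model$cfg, model$enc, keep_cache),
       tissue = encode_labels(seg_one_hot(volumes$seg), model$cfg,
                              model$tissue, keep_cache),
       fixel = encode_labels(volumes$fixels, model$cfg, model$fixel,
                             keep_cache))
}

#' Train the propagation model
#'
#' Mini-batch SGD over the training samples. Targets are re-augmented with
#' fresh vMF noise every epoch. With `cfg$joint = TRUE` training runs in
#' three phases: a head-only warm-up against the frozen initial encoders, a
#' joint phase in which the encoders are re-run and updated at every
#' iteration (gradients flow from the loss through the head, the feature
#' gathers, and the decoder/transformer back to all weights), and a
#' head-only polish phase that re-converges the head to the updated
#' features. With `joint = FALSE` only the head ever learns. Training stops
#' at `max_epochs` or when the loss plateaus.
#'
#' @param model a `vmf_tract_model`.
#' @param samples a `vmf_training_set` from [make_training_samples()].
#' @param volumes named list with `odf`, `seg`, `fixels` volumes.
#' @param keypoints (5 x 3) world-mm centroid matrix.
#' @param cfg a [train_config()].
#' @return the trained model, with `loss_history` and `epochs_trained`
#'   updated.
#' @export
train_model <- function(model, samples, volumes, keypoints,
                        cfg = train_config()) {
  n <- nrow(samples$p_vox)
  if (!n) stop("no training samples")
  kappa <- kappa_from_fa(samples$fa, cfg$alpha)
  joint <- cfg$joint
  if (is.null(model$x_center)) {
    pyr0 <- model_pyramids(model, volumes, keep_cache = FALSE)
    X0 <- model_features(pyr0$odf, pyr0$tissue, pyr0$fixel, samples$p_vox,
                         samples$u_prev_vox, samples$hist18,
                         samples$p_world, keypoints, model$cfg)
    st <- estimate_standardization(X0)
    model$x_center <- st$center
    model$x_scale <- st$scale
  }
  pyr <- model_pyramids(model, volumes, keep_cache = FALSE)
  vel <- list(head = nn_zeros_like(model$head),
              enc = nn_zeros_like(model$enc),
              tissue = nn_zeros_like(model$tissue),
              fixel = nn_zeros_like(model$fixel))
  history <- numeric(0)
  best <- Inf
  stall <- 0L
  X_frozen <- NULL   # features cached while the encoders are frozen
  pyr_stale <- FALSE # encoders updated since `pyr` was computed
  for (epoch in seq_len(cfg$max_epochs)) {
    joint_now <- joint && epoch > cfg$warmup_epochs &&
      epoch <= cfg$warmup_epochs + cfg$joint_epochs
    if (!joint_now && is.null(X_frozen)) {
      if (pyr_stale) {
        pyr <- model_pyramids(model, volumes, keep_cache = FALSE)
        pyr_stale <- FALSE
      }
      X_frozen <- model_features(pyr$odf, pyr$tissue, pyr$fixel,
                                 samples$p_vox, samples$u_prev_vox,
                                 samples$hist18, samples$p_world,
                                 keypoints, model$cfg)
    }
    perm <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(n, start + cfg$batch_size - 1L)]
      if (joint_now) {
        pyr <- model_pyramids(model, volumes, keep_cache = TRUE)
        X_frozen <- NULL
        X <- model_features(pyr$odf, pyr$tissue, pyr$fixel,
                            samples$p_vox[idx, , drop = FALSE],
                            samples$u_prev_vox[idx, , drop = FALSE],
                            samples$hist18[idx, , drop = FALSE],
                            samples$p_world[idx, , drop = FALSE],
                            keypoints, model$cfg, keep_plans = TRUE)
      } else {
        X <- X_frozen[idx, , drop = FALSE]
      }
      hf <- head_fwd(model$head, standardize_input(model, X))
      if (any(!is.finite(hf$out))) {
        stop("training diverged: non-finite head output at epoch ", epoch)
      }
      u_pred <- angles_to_dir(hf$out)
      ls <- direction_loss(u_pred, samples$target[idx, , drop = FALSE],
                           kappa[idx], cfg$loss)
      if (!is.finite(ls$value)) {
        stop("training diverged: loss is ", ls$value, " at epoch ", epoch)
      }
      gang <- angles_to_dir_bwd(hf$out, ls$gU)
      hb <- head_bwd(model$head, hf$caches, gang)
      lr_head <- if (joint_now) cfg$lr * cfg$joint_lr_scale else cfg$lr
      upd <- nn_sgd_step(model$head, nn_clip_norm(hb$grad, cfg$clip),
                         vel$head, lr_head, cfg$momentum)
      model$head <- upd$params
      vel$head <- upd$velocity
      if (joint_now) {
        # undo the standardization scaling before pushing gradients back
        # into the raw feature gathers
        gX_raw <- sweep(hb$gX, 2, model$x_scale, "/")
        gf <- model_features_bwd(gX_raw, attr(X, "plans"), model$cfg)
        g_enc <- encode_odf_bwd(model$enc, pyr$odf,
                                gf$odf[[1]], gf$odf[[2]], gf$odf[[3]])
        g_tis <- encode_labels_bwd(model$tissue, pyr$tissue,
                                   gf$tissue[[1]], gf$tissue[[2]],
                                   gf$tissue[[3]])
        g_fix <- encode_labels_bwd(model$fixel, pyr$fixel,
                                   gf$fixel[[1]], gf$fixel[[2]],
                                   gf$fixel[[3]])
        for (part in c("enc", "tissue", "fixel")) {
          g <- switch(part, enc = g_enc, tissue = g_tis, fixel = g_fix)
          upd <- nn_sgd_step(model[[part]], nn_clip_norm(g, cfg$clip),
                             vel[[part]], cfg$lr * cfg$enc_lr_scale,
                             cfg$momentum)
          model[[part]] <- upd$params
          vel[[part]] <- upd$velocity
        }
        pyr_stale <- TRUE
      }
      ep_loss <- ep_loss + ls$value
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    history <- c(history, ep_loss)
    if (cfg$verbose) {
      message(sprintf("epoch %3d  loss %.5f", epoch, ep_loss))
    }
    # plateau rule on the loss scale (cosine loss lives in [-1, 1])
    if (ep_loss < best - cfg$tol) {
      best <- ep_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  model$loss_history <- c(model$loss_history, history)
  model$epochs_trained <- model$epochs_trained + length(history)
  model
}
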