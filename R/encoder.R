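#' Encoder configuration
#'
#' Hyperparameters of the volumetric encoders. The defaults mirror the
#' full-scale configuration (8^3 patches on a 128^3 grid, 4 transformer
#' blocks of 3 units, pyramid channel widths 64/128/256); phantom-scale work
#' uses the same code path with a smaller patch side, embedding and widths.
#'
#' @param patch_side cubic patch edge in voxels; must be a power of two
#'   >= 4 (default 16, giving 8^3 patches on a 128^3 grid).
#' @param embed_dim transformer embedding width.
#' @param n_blocks number of transformer encoder blocks.
#' @param units_per_block transformer units per block.
#' @param n_heads attention heads (must divide `embed_dim`).
#' @param mlp_ratio width multiplier of the transformer MLPs.
#' @param channels pyramid widths `c(C1, C2, C3)`, increasing.
#' @param aux_channels widths of the tissue/fixel convolutional encoders.
#' @return list of class `vmf_encoder_config`.
#' @export
encoder_config <- function(patch_side = 16, embed_dim = 128, n_blocks = 4,
                           units_per_block = 3, n_heads = 8, mlp_ratio = 4,
                           channels = c(64, 128, 256),
                           aux_channels = c(8, 16, 32)) {
  if (patch_side < 4 || bitwAnd(patch_side, patch_side - 1L) != 0) {
    stop("patch_side must be a power of two >= 4")
  }
  if (embed_dim %% n_heads != 0) stop("n_heads must divide embed_dim")
  if (!(channels[1] < channels[2] && channels[2] < channels[3])) {
    stop("pyramid channels must increase: C1 < C2 < C3")
  }
  structure(list(patch_side = as.integer(patch_side),
                 embed_dim = as.integer(embed_dim),
                 n_blocks = as.integer(n_blocks),
                 units_per_block = as.integer(units_per_block),
                 n_heads = as.integer(n_heads),
                 mlp_ratio = mlp_ratio,
                 channels = as.integer(channels),
                 aux_channels = as.integer(aux_channels)),
            class = "vmf_encoder_config")
}

#' Initialize ODF-encoder weights
#'
#' @param cfg an [encoder_config()].
#' @param in_channels input channels (45 for the order-8 SH ODF volume).
#' @return nested list of parameter arrays.
#' @export
encoder_init <- function(cfg, in_channels = 45) {
  ps <- cfg$patch_side
  E <- cfg$embed_dim
  C <- cfg$channels
  n_pre <- as.integer(log2(ps)) - 2L
  units <- lapply(seq_len(cfg$n_blocks * cfg$units_per_block), function(i) {
    nn_init_tr_unit(E, cfg$n_heads, cfg$mlp_ratio)
  })
  list(embed = nn_init_linear(ps^3 * in_channels, E, gain = 1),
       units = units,
       dec_pre = lapply(seq_len(n_pre), function(i) nn_init_conv3(E, E)),
       conv_f3 = nn_init_conv3(E, C[3], gain = 1),
       conv_f2 = nn_init_conv3(C[3], C[2]),
       conv_f1 = nn_init_conv3(C[2], C[1]),
       in_proj = nn_init_linear(in_channels, C[1]),
       in_conv = nn_init_conv3(C[1], C[1]))
}

# pad a (nvox x C) grid matrix with zeros up to dims_pad, returning the new
# matrix plus the linear indices of the original voxels inside the padding
pad_grid <- function(X, dims, dims_pad) {
  if (all(dims == dims_pad)) {
    return(list(X = X, idx = seq_len(prod(dims))))
  }
  ix <- rep(seq_len(dims[1]) - 1L, times = dims[2] * dims[3])
  iy <- rep(rep(seq_len(dims[2]) - 1L, each = dims[1]), times = dims[3])
  iz <- rep(seq_len(dims[3]) - 1L, each = dims[1] * dims[2])
  idx <- 1L + ix + iy * dims_pad[1] + iz * dims_pad[1] * dims_pad[2]
  Xp <- matrix(0, prod(dims_pad), ncol(X))
  Xp[idx, ] <- X
  list(X = Xp, idx = idx)
}

crop_idx <- function(dims_pad, dims) {
  ix <- rep(seq_len(dims[1]) - 1L, times = dims[2] * dims[3])
  iy <- rep(rep(seq_len(dims[2]) - 1L, each = dims[1]), times = dims[3])
  iz <- rep(seq_len(dims[3]) - 1L, each = dims[1] * dims[2])
  1L + ix + iy * dims_pad[1] + iz * dims_pad[1] * dims_pad[2]
}

# patch gather plan: Pidx[q, j] = linear index (in padded grid) of the j-th
# voxel (column-major within patch) of patch q (patches column-major)
patch_plan <- function(dims_pad, ps) {
  pg <- dims_pad %/% ps
  np <- prod(pg)
  qx <- rep(seq_len(pg[1]) - 1L, times = pg[2] * pg[3])
  qy <- rep(rep(seq_len(pg[2]) - 1L, each = pg[1]), times = pg[3])
  qz <- rep(seq_len(pg[3]) - 1L, each = pg[1] * pg[2])
  ox <- rep(seq_len(ps) - 1L, times = ps * ps)
  oy <- rep(rep(seq_len(ps) - 1L, each = ps), times = ps)
  oz <- rep(seq_len(ps) - 1L, each = ps * ps)
  Pidx <- matrix(0L, np, ps^3)
  for (j in seq_len(ps^3)) {
    Pidx[, j] <- 1L + (qx * ps + ox[j]) +
      (qy * ps + oy[j]) * dims_pad[1] +
      (qz * ps + oz[j]) * dims_pad[1] * dims_pad[2]
  }
  list(Pidx = Pidx, pg = pg)
}

patchify <- function(Xp, plan, cin) {
  ps3 <- ncol(plan$Pidx)
  out <- matrix(0, nrow(plan$Pidx), ps3 * cin)
  for (j in seq_len(ps3)) {
    out[, (seq_len(cin) - 1L) * ps3 + j] <- Xp[plan$Pidx[, j], , drop = FALSE]
  }
  out
}

unpatchify_grad <- function(G, plan, cin, n_pad) {
  ps3 <- ncol(plan$Pidx)
  Gp <- matrix(0, n_pad, cin)
  for (j in seq_len(ps3)) {
    Gp[plan$Pidx[, j], ] <- Gp[plan$Pidx[, j], ] +
      G[, (seq_len(cin) - 1L) * ps3 + j, drop = FALSE]
  }
  Gp
}

#' Encode an ODF SH volume into a three-scale feature pyramid
#'
#' The volume is zero-padded to a multiple of the patch side, split into
#' non-overlapping cubic patches which are vectorized, linearly embedded and
#' summed with a fixed sinusoidal positional encoding, then processed by the
#' transformer units. A convolutional decoder with nearest-neighbor
#' upsampling (the transposed-convolution shortcut path) emits feature maps
#' `F3 (H/4)`, `F2 (H/2)` and `F1 (H)`; `F1` additionally mixes features
#' from convolutions applied directly to the input volume. Padding is
#' cropped away so pyramid coordinates align with input voxel coordinates
#' (level `s` is sampled at `p / 2^(s-1)`).
#'
#' @param vol the ODF SH `vmf_volume` (45 channels at order 8).
#' @param cfg an [encoder_config()].
#' @param weights from [encoder_init()].
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return object of class `vmf_pyramid` with levels `F1`, `F2`, `F3`
#'   (each `list(X, dims)` with `X` a voxels-by-channels matrix).
#' @export
encode_odf <- function(vol, cfg, weights, keep_cache = FALSE) {
  X <- vol_matrix(vol)
  if (any(!is.finite(X))) stop("non-finite values in encoder input")
  exp_in <- nrow(weights$embed$W) / cfg$patch_side^3
  if (ncol(X) != exp_in) {
    stop("encoder expects ", exp_in, " input channels, got ", ncol(X))
  }
  dims <- vol_dim(vol)
  ps <- cfg$patch_side
  dims_pad <- as.integer(ceiling(dims / ps) * ps)
  pad <- pad_grid(X, dims, dims_pad)
  pplan <- patch_plan(dims_pad, ps)
  cin <- ncol(X)

  Xpat <- patchify(pad$X, pplan, cin)
  emb <- nn_linear_fwd(weights$embed, Xpat)
  pe <- positional_encoding_3d(pplan$pg, cfg$embed_dim)
  Tk <- emb$out + pe
  ucaches <- vector("list", length(weights$units))
  for (i in seq_along(weights$units)) {
    ucaches[[i]] <- nn_tr_unit_fwd(weights$units[[i]], Tk)
    Tk <- ucaches[[i]]$out
  }

  # decoder: token grid -> H/4 -> F3 -> F2 -> F1
  gdims <- pplan$pg
  Dcur <- Tk
  pre_caches <- vector("list", length(weights$dec_pre))
  pre_plans_up <- vector("list", length(weights$dec_pre))
  pre_plans_cv <- vector("list", length(weights$dec_pre))
  for (i in seq_along(weights$dec_pre)) {
    upl <- upsample2_plan(gdims)
    Du <- nn_upsample2_fwd(Dcur, upl)
    gdims <- upl$dims_out
    cpl <- conv3_plan(gdims, 1L)
    cv <- nn_conv3_fwd(weights$dec_pre[[i]], Du, cpl)
    rl <- nn_relu_fwd(cv$out)
    Dcur <- rl$out
    pre_caches[[i]] <- list(cv = cv, rl = rl)
    pre_plans_up[[i]] <- upl
    pre_plans_cv[[i]] <- cpl
  }
  d3dims <- gdims                              # = dims_pad / 4
  pl3 <- conv3_plan(d3dims, 1L)
  c3 <- nn_conv3_fwd(weights$conv_f3, Dcur, pl3)
  F3p <- c3$out

  up2 <- upsample2_plan(d3dims)
  r3 <- nn_relu_fwd(nn_upsample2_fwd(F3p, up2))
  pl2 <- conv3_plan(up2$dims_out, 1L)
  c2 <- nn_conv3_fwd(weights$conv_f2, r3$out, pl2)
  F2p <- c2$out

  up1 <- upsample2_plan(up2$dims_out)
  r2 <- nn_relu_fwd(nn_upsample2_fwd(F2p, up1))
  pl1 <- conv3_plan(up1$dims_out, 1L)
  c1 <- nn_conv3_fwd(weights$conv_f1, r2$out, pl1)

  ip <- nn_linear_fwd(weights$in_proj, pad$X)
  ri <- nn_relu_fwd(ip$out)
  plin <- conv3_plan(dims_pad, 1L)
  ci <- nn_conv3_fwd(weights$in_conv, ri$out, plin)
  F1p <- c1$out + ci$out

  d1 <- dims; d2 <- as.integer(ceiling(dims / 2)); d3 <- as.integer(ceiling(dims / 4))
  ci1 <- crop_idx(dims_pad, d1)
  ci2 <- crop_idx(as.integer(dims_pad / 2), d2)
  ci3 <- crop_idx(as.integer(dims_pad / 4), d3)
  pyr <- structure(list(
    F1 = list(X = F1p[ci1, , drop = FALSE], dims = d1),
    F2 = list(X = F2p[ci2, , drop = FALSE], dims = d2),
    F3 = list(X = F3p[ci3, , drop = FALSE], dims = d3),
    dims = dims, affine = vol$affine), class = "vmf_pyramid")
  if (keep_cache) {
    pyr$cache <- list(pad = pad, pplan = pplan, emb = emb,
                      ucaches = ucaches, pre_caches = pre_caches,
                      pre_plans_up = pre_plans_up, pre_plans_cv = pre_plans_cv,
                      c3 = c3, up2 = up2, r3 = r3, c2 = c2,
                      up1 = up1, r2 = r2, c1 = c1,
                      ip = ip, ri = ri, ci = ci,
                      dims_pad = dims_pad, cin = cin,
                      crops = list(ci1, ci2, ci3))
  }
  pyr
}

#' @export
print.vmf_pyramid <- function(x, ...) {
  cat("<vmf_pyramid> F1 ", paste(x$F1$dims, collapse = "x"), "x", ncol(x$F1$X),
      "  F2 ", paste(x$F2$dims, collapse = "x"), "x", ncol(x$F2$X),
      "  F3 ", paste(x$F3$dims, collapse = "x"), "x", ncol(x$F3$X), "\n",
      sep = "")
  invisible(x)
}

# backward pass of encode_odf: gF1/gF2/gF3 are gradients on the *cropped*
# pyramid matrices; returns the weight-gradient structure.
encode_odf_bwd <- function(weights, pyr, gF1, gF2, gF3) {
  ca <- pyr$cache
  if (is.null(ca)) stop("pyramid was computed without keep_cache = TRUE")
  uncrop <- function(G, dims_pad_s, idx) {
    Gp <- matrix(0, prod(dims_pad_s), ncol(G))
    Gp[idx, ] <- G
    Gp
  }
  dp <- ca$dims_pad
  gF1p <- uncrop(gF1, dp, ca$crops[[1]])
  gF2p <- uncrop(gF2, as.integer(dp / 2), ca$crops[[2]])
  gF3p <- uncrop(gF3, as.integer(dp / 4), ca$crops[[3]])

  # input-mixing path
  b_ci <- nn_conv3_bwd(weights$in_conv, ca$ci, gF1p)
  g_ri <- nn_relu_bwd(ca$ri, b_ci$gX)
  b_ip <- nn_linear_bwd(weights$in_proj, ca$ip, g_ri)

  # decoder chain
  b_c1 <- nn_conv3_bwd(weights$conv_f1, ca$c1, gF1p)
  g_r2 <- nn_relu_bwd(ca$r2, b_c1$gX)
  gF2p <- gF2p + nn_upsample2_bwd(g_r2, ca$up1)
  b_c2 <- nn_conv3_bwd(weights$conv_f2, ca$c2, gF2p)
  g_r3 <- nn_relu_bwd(ca$r3, b_c2$gX)
  gF3p <- gF3p + nn_upsample2_bwd(g_r3, ca$up2)
  b_c3 <- nn_conv3_bwd(weights$conv_f3, ca$c3, gF3p)
  gD <- b_c3$gX
  g_pre <- vector("list", length(weights$dec_pre))
  for (i in rev(seq_along(weights$dec_pre))) {
    g_rl <- nn_relu_bwd(ca$pre_caches[[i]]$rl, gD)
    b_cv <- nn_conv3_bwd(weights$dec_pre[[i]], ca$pre_caches[[i]]$cv, g_rl)
    g_pre[[i]] <- b_cv$grad
    gD <- nn_upsample2_bwd(b_cv$gX, ca$pre_plans_up[[i]])
  }

  gTk <- gD
  g_units <- vector("list", length(weights$units))
  for (i in rev(seq_along(weights$units))) {
    b_u <- nn_tr_unit_bwd(weights$units[[i]], ca$ucaches[[i]], gTk)
    g_units[[i]] <- b_u$grad
    gTk <- b_u$gX
  }
  b_emb <- nn_linear_bwd(weights$embed, ca$emb, gTk)

  list(embed = b_emb$grad, units = g_units, dec_pre = g_pre,
       conv_f3 = b_c3$grad, conv_f2 = b_c2$grad, conv_f1 = b_c1$grad,
       in_proj = b_ip$grad, in_conv = b_ci$grad)
}

# --- auxiliary encoders (tissue segmentation / fixel atlas) ----------------

#' Tissue label codes used throughout the package
#'
#' 0 background, 1 white matter, 2 cortical gray matter, 3 subcortical gray
#' matter, 4 cerebrospinal fluid.
#' @export
seg_labels <- c(background = 0L, wm = 1L, cgm = 2L, scgm = 3L, csf = 4L)

#' One-hot encode a tissue segmentation volume
#'
#' Channels in order WM, cortical GM, subcortical GM, CSF; background voxels
#' are all-zero. Unknown label values are an error.
#'
#' @param seg scalar `vmf_volume` of labels from [seg_labels].
#' @return 4-channel `vmf_volume`.
#' @export
seg_one_hot <- function(seg) {
  lab <- as.integer(vol_matrix(seg))
  if (!all(lab %in% seg_labels)) {
    stop("unknown tissue label id(s): ",
         paste(setdiff(unique(lab), seg_labels), collapse = ", "))
  }
  oh <- matrix(0, length(lab), 4)
  for (k in 1:4) oh[lab == k, k] <- 1
  vmf_volume(array(oh, c(vol_dim(seg), 4)), affine = seg$affine)
}

#' Initialize an auxiliary (tissue/fixel) convolutional encoder
#'
#' @param cfg an [encoder_config()] (uses `aux_channels`).
#' @param in_channels 4 for a one-hot segmentation, 6 for a two-fixel
#'   direction volume.
#' @return nested parameter list.
#' @export
aux_encoder_init <- function(cfg, in_channels) {
  a <- cfg$aux_channels
  list(conv1 = nn_init_conv3(in_channels, a[1]),
       conv2 = nn_init_conv3(a[1], a[2]),
       conv3 = nn_init_conv3(a[2], a[3]))
}

#' Encode a label or direction volume with three convolutional layers
#'
#' Three learnable 3x3x3 convolutions with stride-2 downsampling between
#' scales produce feature maps at full, half and quarter resolution,
#' mirroring the shape contract of the main pyramid.
#'
#' @param vol multi-channel `vmf_volume` (one-hot segmentation from
#'   [seg_one_hot()], or a 6-channel fixel direction volume).
#' @param cfg an [encoder_config()].
#' @param weights from [aux_encoder_init()].
#' @param keep_cache keep activations for the backward pass.
#' @return a `vmf_pyramid` with `aux_channels` widths.
#' @export
encode_labels <- function(vol, cfg, weights, keep_cache = FALSE) {
  X <- vol_matrix(vol)
  dims <- vol_dim(vol)
  dims_pad <- as.integer(ceiling(dims / 4) * 4)
  pad <- pad_grid(X, dims, dims_pad)
  pl1 <- conv3_plan(dims_pad, 1L)
  cv1 <- nn_conv3_fwd(weights$conv1, pad$X, pl1)
  r1 <- nn_relu_fwd(cv1$out)
  pl2 <- conv3_plan(dims_pad, 2L)
  cv2 <- nn_conv3_fwd(weights$conv2, r1$out, pl2)
  r2 <- nn_relu_fwd(cv2$out)
  pl3 <- conv3_plan(as.integer(dims_pad / 2), 2L)
  cv3 <- nn_conv3_fwd(weights$conv3, r2$out, pl3)

  d1 <- dims; d2 <- as.integer(ceiling(dims / 2)); d3 <- as.integer(ceiling(dims / 4))
  ci1 <- crop_idx(dims_pad, d1)
  ci2 <- crop_idx(as.integer(dims_pad / 2), d2)
  ci3 <- crop_idx(as.integer(dims_pad / 4), d3)
  pyr <- structure(list(
    F1 = list(X = cv1$out[ci1, , drop = FALSE], dims = d1),
    F2 = list(X = cv2$out[ci2, , drop = FALSE], dims = d2),
    F3 = list(X = cv3$out[ci3, , drop = FALSE], dims = d3),
    dims = dims, affine = vol$affine), class = "vmf_pyramid")
  if (keep_cache) {
    pyr$cache <- list(cv1 = cv1, r1 = r1, cv2 = cv2, r2 = r2, cv3 = cv3,
                      dims_pad = dims_pad, crops = list(ci1, ci2, ci3))
  }
  pyr
}

# note: F1 of an aux pyramid is the *pre-activation* conv1 output; the relu
# feeds only the deeper layers. Gradients below account for that.
encode_labels_bwd <- function(weights, pyr, gF1, gF2, gF3) {
  ca <- pyr$cache
  if (is.null(ca)) stop("pyramid was computed without keep_cache = TRUE")
  dp <- ca$dims_pad
  uncrop <- function(G, n, idx) {
    Gp <- matrix(0, n, ncol(G))
    Gp[idx, ] <- G
    Gp
  }
  gF1p <- uncrop(gF1, prod(dp), ca$crops[[1]])
  gF2p <- uncrop(gF2, prod(as.integer(dp / 2)), ca$crops[[2]])
  gF3p <- uncrop(gF3, prod(as.integer(dp / 4)), ca$crops[[3]])
  b3 <- nn_conv3_bwd(weights$conv3, ca$cv3, gF3p)
  g_r2 <- nn_relu_bwd(ca$r2, b3$gX)
  b2 <- nn_conv3_bwd(weights$conv2, ca$cv2, gF2p + g_r2)
  g_r1 <- nn_relu_bwd(ca$r1, b2$gX)
  b1 <- nn_conv3_bwd(weights$conv1, ca$cv1, gF1p + g_r1)
  list(conv1 = b1$grad, conv2 = b2$grad, conv3 = b3$grad)
}
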