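# Minimal neural-network layer library: forward passes paired with
# hand-derived backward passes, on plain matrices with BLAS matmuls.
# Parameters are nested named lists of numeric arrays; gradients mirror the
# structure. Everything here is deterministic given the R RNG state at init.

nn_init_linear <- function(n_in, n_out, gain = 2) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(gain / n_in)),
                  n_in, n_out),
       b = numeric(n_out))
}

nn_linear_fwd <- function(p, X) {
  list(out = sweep(X %*% p$W, 2, p$b, "+"), X = X)
}

nn_linear_bwd <- function(p, cache, G) {
  list(grad = list(W = crossprod(cache$X, G), b = colSums(G)),
       gX = G %*% t(p$W))
}

nn_relu_fwd <- function(X) {
  out <- X * (X > 0)
  list(out = out, mask = X > 0)
}

nn_relu_bwd <- function(cache, G) G * cache$mask

nn_init_layernorm <- function(n) list(g = rep(1, n), b = numeric(n))

nn_layernorm_fwd <- function(p, X, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xn <- xc / sd
  list(out = sweep(xn * rep(p$g, each = nrow(X)), 2, p$b, "+"),
       xn = xn, sd = sd)
}

nn_layernorm_bwd <- function(p, cache, G) {
  xn <- cache$xn
  gy <- G * rep(p$g, each = nrow(G))
  gx <- (gy - rowMeans(gy) - xn * rowMeans(gy * xn)) / cache$sd
  list(grad = list(g = colSums(G * xn), b = colSums(G)), gX = gx)
}

nn_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# --- multi-head self-attention --------------------------------------------

nn_init_mha <- function(embed, heads) {
  stopifnot(embed %% heads == 0)
  list(qkv = nn_init_linear(embed, 3 * embed, gain = 1),
       out = nn_init_linear(embed, embed, gain = 1),
       heads = heads)
}

nn_mha_fwd <- function(p, X) {
  N <- nrow(X); E <- ncol(X); h <- p$heads; dh <- E / h
  f1 <- nn_linear_fwd(p$qkv, X)
  QKV <- f1$out
  Q <- QKV[, 1:E, drop = FALSE]
  K <- QKV[, E + 1:E, drop = FALSE]
  V <- QKV[, 2 * E + 1:E, drop = FALSE]
  O <- matrix(0, N, E)
  A <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- (i - 1) * dh + 1:dh
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    A[[i]] <- nn_softmax(S)
    O[, cols] <- A[[i]] %*% V[, cols, drop = FALSE]
  }
  f2 <- nn_linear_fwd(p$out, O)
  list(out = f2$out, c1 = f1, c2 = f2, A = A, Q = Q, K = K, V = V)
}

nn_mha_bwd <- function(p, cache, G) {
  E <- ncol(cache$Q); h <- p$heads; dh <- E / h
  b2 <- nn_linear_bwd(p$out, cache$c2, G)
  gO <- b2$gX
  gQ <- gK <- gV <- matrix(0, nrow(gO), E)
  for (i in seq_len(h)) {
    cols <- (i - 1) * dh + 1:dh
    A <- cache$A[[i]]
    gA <- gO[, cols, drop = FALSE] %*% t(cache$V[, cols, drop = FALSE])
    gV[, cols] <- t(A) %*% gO[, cols, drop = FALSE]
    # softmax backward row-wise
    gS <- A * (gA - rowSums(gA * A))
    gS <- gS / sqrt(dh)
    gQ[, cols] <- gS %*% cache$K[, cols, drop = FALSE]
    gK[, cols] <- t(gS) %*% cache$Q[, cols, drop = FALSE]
  }
  b1 <- nn_linear_bwd(p$qkv, cache$c1, cbind(gQ, gK, gV))
  # `heads` is a structural constant; a zero grad keeps the parameter tree
  # aligned with the gradient tree for the generic SGD walker
  list(grad = list(qkv = b1$grad, out = b2$grad, heads = 0), gX = b1$gX)
}

# --- transformer unit: LN -> MHA -> add; LN -> MLP -> add -----------------

nn_init_tr_unit <- function(embed, heads, mlp_ratio = 4) {
  list(ln1 = nn_init_layernorm(embed),
       attn = nn_init_mha(embed, heads),
       ln2 = nn_init_layernorm(embed),
       fc1 = nn_init_linear(embed, embed * mlp_ratio),
       fc2 = nn_init_linear(embed * mlp_ratio, embed, gain = 1))
}

nn_tr_unit_fwd <- function(p, X) {
  l1 <- nn_layernorm_fwd(p$ln1, X)
  at <- nn_mha_fwd(p$attn, l1$out)
  X1 <- X + at$out
  l2 <- nn_layernorm_fwd(p$ln2, X1)
  f1 <- nn_linear_fwd(p$fc1, l2$out)
  r1 <- nn_relu_fwd(f1$out)
  f2 <- nn_linear_fwd(p$fc2, r1$out)
  list(out = X1 + f2$out, l1 = l1, at = at, l2 = l2, f1 = f1, r1 = r1,
       f2 = f2)
}

nn_tr_unit_bwd <- function(p, cache, G) {
  b_f2 <- nn_linear_bwd(p$fc2, cache$f2, G)
  g_r1 <- nn_relu_bwd(cache$r1, b_f2$gX)
  b_f1 <- nn_linear_bwd(p$fc1, cache$f1, g_r1)
  b_l2 <- nn_layernorm_bwd(p$ln2, cache$l2, b_f1$gX)
  gX1 <- G + b_l2$gX
  b_at <- nn_mha_bwd(p$attn, cache$at, gX1)
  b_l1 <- nn_layernorm_bwd(p$ln1, cache$l1, b_at$gX)
  list(grad = list(ln1 = b_l1$grad, attn = b_at$grad, ln2 = b_l2$grad,
                   fc1 = b_f1$grad, fc2 = b_f2$grad),
       gX = gX1 + b_l1$gX)
}

# --- 3D convolution (kernel 3, zero padding 1) via gather + GEMM ----------

# index plan mapping each output voxel's 27 taps to a zero-padded flat grid
conv3_plan <- function(dims, stride = 1L) {
  dp <- dims + 2L
  oc <- lapply(dims, function(d) seq(0L, d - 1L, by = stride))
  dims_out <- vapply(oc, length, 1L)
  ox <- oc[[1]] + 1L; oy <- oc[[2]] + 1L; oz <- oc[[3]] + 1L
  cx <- rep(ox, times = dims_out[2] * dims_out[3])
  cy <- rep(rep(oy, each = dims_out[1]), times = dims_out[3])
  cz <- rep(oz, each = dims_out[1] * dims_out[2])
  base <- 1L + cx + cy * dp[1] + cz * dp[1] * dp[2]
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  Nidx <- matrix(0L, length(base), 27L)
  for (j in 1:27) {
    Nidx[, j] <- base + off[j, 1] + off[j, 2] * dp[1] +
      off[j, 3] * dp[1] * dp[2]
  }
  # interior (non-pad) positions of the padded grid, in input voxel order
  ix <- rep(seq_len(dims[1]), times = dims[2] * dims[3])
  iy <- rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3])
  iz <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  # 0-based padded coord = input 0-based coord + 1 = ix (etc.)
  interior <- 1L + ix + iy * dp[1] + iz * dp[1] * dp[2]
  list(Nidx = Nidx, interior = interior, n_pad = prod(dp),
       dims_out = dims_out, dims_in = dims)
}

conv3_im2col <- function(plan, X) {
  cin <- ncol(X)
  Xp <- matrix(0, plan$n_pad, cin)
  Xp[plan$interior, ] <- X
  Xc <- matrix(0, nrow(plan$Nidx), 27L * cin)
  for (j in 1:27) {
    Xc[, (j - 1L) * cin + seq_len(cin)] <- Xp[plan$Nidx[, j], , drop = FALSE]
  }
  Xc
}

nn_init_conv3 <- function(cin, cout, gain = 2) {
  nn_init_linear(27L * cin, cout, gain = gain)
}

# X: (n_vox x cin) over grid `dims`; returns (n_out x cout) over dims_out
nn_conv3_fwd <- function(p, X, plan) {
  Xc <- conv3_im2col(plan, X)
  list(out = sweep(Xc %*% p$W, 2, p$b, "+"), X = X, plan = plan)
}

nn_conv3_bwd <- function(p, cache, G) {
  plan <- cache$plan
  cin <- ncol(cache$X)
  Xc <- conv3_im2col(plan, cache$X)      # recomputed to bound memory
  gW <- crossprod(Xc, G)
  gb <- colSums(G)
  Gp <- matrix(0, plan$n_pad, cin)
  for (j in 1:27) {
    rows <- (j - 1L) * cin + seq_len(cin)
    contrib <- G %*% t(p$W[rows, , drop = FALSE])
    idx <- plan$Nidx[, j]
    Gp[idx, ] <- Gp[idx, ] + contrib
  }
  list(grad = list(W = gW, b = gb), gX = Gp[plan$interior, , drop = FALSE])
}

# --- nearest-neighbor x2 upsampling ---------------------------------------

upsample2_plan <- function(dims) {
  do <- dims * 2L
  cx <- rep(seq_len(do[1]), times = do[2] * do[3])
  cy <- rep(rep(seq_len(do[2]), each = do[1]), times = do[3])
  cz <- rep(seq_len(do[3]), each = do[1] * do[2])
  px <- (cx - 1L) %/% 2L; py <- (cy - 1L) %/% 2L; pz <- (cz - 1L) %/% 2L
  list(parent = 1L + px + py * dims[1] + pz * dims[1] * dims[2],
       dims_out = do, n_parent = prod(dims))
}

nn_upsample2_fwd <- function(X, plan) X[plan$parent, , drop = FALSE]

nn_upsample2_bwd <- function(G, plan) {
  s <- rowsum(G, group = plan$parent)
  out <- matrix(0, plan$n_parent, ncol(G))
  out[as.integer(rownames(s)), ] <- s
  out
}

# --- nested-list parameter utilities --------------------------------------

nn_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) {
      if (is.numeric(a[[i]])) {
        out[[i]] <- f(a[[i]], b[[i]])
      } else if (is.list(a[[i]])) {
        out[[i]] <- nn_map2(a[[i]], b[[i]], f)
      }
    }
    out
  } else {
    f(a, b)
  }
}

nn_zeros_like <- function(p) {
  if (is.list(p)) {
    lapply(p, function(x) if (is.numeric(x)) x * 0 else if (is.list(x))
      nn_zeros_like(x) else x)
  } else {
    p * 0
  }
}

# flatten numeric leaves to one vector (for diagnostics/gradient checks)
nn_flatten <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  unlist(lapply(p, function(x) {
    if (is.numeric(x)) as.numeric(x) else if (is.list(x)) nn_flatten(x)
    else numeric(0)
  }), use.names = FALSE)
}

# SGD with momentum; returns list(params, velocity)
nn_sgd_step <- function(params, grads, velocity, lr, momentum = 0.9) {
  velocity <- nn_map2(velocity, grads, function(v, g) momentum * v + g)
  params <- nn_map2(params, velocity, function(p, v) p - lr * v)
  list(params = params, velocity = velocity)
}

# fixed 3D sinusoidal positional encoding for a patch grid
positional_encoding_3d <- function(pdims, embed) {
  n <- prod(pdims)
  px <- rep(seq_len(pdims[1]) - 1L, times = pdims[2] * pdims[3])
  py <- rep(rep(seq_len(pdims[2]) - 1L, each = pdims[1]), times = pdims[3])
  pz <- rep(seq_len(pdims[3]) - 1L, each = pdims[1] * pdims[2])
  per_axis <- embed %/% 3L
  pe <- matrix(0, n, embed)
  fill_axis <- function(pos, offset, width) {
    half <- width %/% 2L
    for (i in seq_len(half)) {
      freq <- 1 / (100^(2 * (i - 1) / width))
      pe[, offset + 2 * i - 1] <<- sin(pos * freq)
      pe[, offset + 2 * i] <<- cos(pos * freq)
    }
  }
  fill_axis(px, 0L, per_axis)
  fill_axis(py, per_axis, per_axis)
  fill_axis(pz, 2L * per_axis, embed - 2L * per_axis)
  pe
}
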