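# Numerical-gradient checks use a few randomly sampled parameters per layer
# rather than full Jacobians to stay fast; tolerances are loose enough for
# central differences but far below any systematic error.

check_some <- function(loss, get, set, ganal, base, k = 4, eps = 1e-5) {
  v <- as.numeric(get(base))
  ii <- sample(length(v), min(k, length(v)))
  errs <- vapply(ii, function(i) {
    w1 <- set(base, replace(v, i, v[i] + eps))
    w2 <- set(base, replace(v, i, v[i] - eps))
    gn <- (loss(w1) - loss(w2)) / (2 * eps)
    abs(gn - as.numeric(ganal)[i])
  }, numeric(1))
  max(errs)
}

test_that("transformer unit backward matches numerical gradients", {
  set.seed(31)
  E <- 12; N <- 7
  p <- vmftract:::nn_init_tr_unit(E, 3, mlp_ratio = 2)
  X <- matrix(rnorm(N * E), N, E)
  R <- matrix(rnorm(N * E), N, E)
  fw <- function(p, X) sum(vmftract:::nn_tr_unit_fwd(p, X)$out * R)
  cc <- vmftract:::nn_tr_unit_fwd(p, X)
  bb <- vmftract:::nn_tr_unit_bwd(p, cc, R)
  gXn <- matrix(num_grad(function(v) fw(p, matrix(v, N, E)),
                         as.numeric(X)), N, E)
  expect_lt(max(abs(gXn - bb$gX)), 1e-6)
  loss_p <- function(p2) fw(p2, X)
  expect_lt(check_some(loss_p, function(p) p$attn$qkv$W,
                       function(p, v) { p$attn$qkv$W[] <- v; p },
                       bb$grad$attn$qkv$W, p), 1e-6)
  expect_lt(check_some(loss_p, function(p) p$fc1$W,
                       function(p, v) { p$fc1$W[] <- v; p },
                       bb$grad$fc1$W, p), 1e-6)
  expect_lt(check_some(loss_p, function(p) p$ln1$g,
                       function(p, v) { p$ln1$g[] <- v; p },
                       bb$grad$ln1$g, p), 1e-6)
})

test_that("3D convolution forward/backward are exact (stride 1 and 2)", {
  set.seed(32)
  dims <- c(4L, 3L, 5L)
  cin <- 2L; cout <- 3L
  pc <- vmftract:::nn_init_conv3(cin, cout)
  X <- matrix(rnorm(prod(dims) * cin), prod(dims), cin)
  pl <- vmftract:::conv3_plan(dims, 1L)
  R <- matrix(rnorm(nrow(pl$Nidx) * cout), nrow(pl$Nidx), cout)
  cc <- vmftract:::nn_conv3_fwd(pc, X, pl)
  bb <- vmftract:::nn_conv3_bwd(pc, cc, R)
  fwX <- function(v) sum(vmftract:::nn_conv3_fwd(
    pc, matrix(v, prod(dims), cin), pl)$out * R)
  expect_lt(max(abs(num_grad(fwX, as.numeric(X)) -
                      as.numeric(bb$gX))), 1e-7)
  fwW <- function(w) {
    p2 <- pc; p2$W[] <- w
    sum(vmftract:::nn_conv3_fwd(p2, X, pl)$out * R)
  }
  expect_lt(max(abs(num_grad(fwW, as.numeric(pc$W)) -
                      as.numeric(bb$grad$W))), 1e-7)
  # stride 2 halves even dims exactly
  pl2 <- vmftract:::conv3_plan(c(4L, 4L, 4L), 2L)
  expect_identical(pl2$dims_out, c(2L, 2L, 2L))
})

test_that("ODF encoder emits the pyramid shape contract and exact gradients", {
  set.seed(33)
  cfg <- test_encoder_config()
  cin <- 5
  vol <- vmf_volume(array(rnorm(8^3 * cin), c(8, 8, 8, cin)))
  w <- encoder_init(cfg, in_channels = cin)
  pyr <- encode_odf(vol, cfg, w, keep_cache = TRUE)
  expect_identical(dim(pyr$F1$X), c(512L, 8L))
  expect_identical(dim(pyr$F2$X), c(64L, 16L))
  expect_identical(dim(pyr$F3$X), c(8L, 32L))
  expect_true(all(is.finite(pyr$F1$X)))

  # determinism: same weights, same input, same output
  pyr2 <- encode_odf(vol, cfg, w)
  expect_identical(pyr$F1$X, pyr2$F1$X)

  # all-zero input: finite (bias-only) outputs
  z <- encode_odf(vmf_volume(array(0, c(8, 8, 8, cin))), cfg, w)
  expect_true(all(is.finite(z$F1$X)))

  # padding path: non-multiple grid crops back to input-aligned dims
  vol2 <- vmf_volume(array(rnorm(6 * 7 * 5 * cin), c(6, 7, 5, cin)))
  p2 <- encode_odf(vol2, cfg, w)
  expect_identical(p2$F1$dims, c(6L, 7L, 5L))
  expect_identical(p2$F2$dims, c(3L, 4L, 3L))
  expect_identical(p2$F3$dims, c(2L, 2L, 2L))

  # gradient flows, correctly, to parameters in every branch
  R1 <- matrix(rnorm(length(pyr$F1$X)), nrow(pyr$F1$X))
  R2 <- matrix(rnorm(length(pyr$F2$X)), nrow(pyr$F2$X))
  R3 <- matrix(rnorm(length(pyr$F3$X)), nrow(pyr$F3$X))
  loss <- function(w2) {
    p <- encode_odf(vol, cfg, w2)
    sum(p$F1$X * R1) + sum(p$F2$X * R2) + sum(p$F3$X * R3)
  }
  g <- vmftract:::encode_odf_bwd(w, pyr, R1, R2, R3)
  leaves <- list(
    embed = list(function(w) w$embed$W,
                 function(w, v) { w$embed$W[] <- v; w }, g$embed$W),
    unit_qkv = list(function(w) w$units[[1]]$attn$qkv$W,
                    function(w, v) { w$units[[1]]$attn$qkv$W[] <- v; w },
                    g$units[[1]]$attn$qkv$W),
    conv_f3 = list(function(w) w$conv_f3$W,
                   function(w, v) { w$conv_f3$W[] <- v; w }, g$conv_f3$W),
    conv_f1 = list(function(w) w$conv_f1$W,
                   function(w, v) { w$conv_f1$W[] <- v; w }, g$conv_f1$W),
    in_proj = list(function(w) w$in_proj$W,
                   function(w, v) { w$in_proj$W[] <- v; w }, g$in_proj$W),
    in_conv = list(function(w) w$in_conv$W,
                   function(w, v) { w$in_conv$W[] <- v; w }, g$in_conv$W))
  for (nm in names(leaves)) {
    l <- leaves[[nm]]
    expect_lt(check_some(loss, l[[1]], l[[2]], l[[3]], w, eps = 1e-4),
              1e-4)
  }
  # no dead branch: every gradient leaf is nonzero somewhere
  expect_true(all(vapply(
    list(g$embed$W, g$units[[1]]$attn$qkv$W, g$units[[2]]$fc1$W,
         g$conv_f3$W, g$conv_f2$W, g$conv_f1$W, g$in_proj$W, g$in_conv$W),
    function(x) any(x != 0), logical(1))))
})

test_that("label encoder honors the shape contract and distinguishes channels", {
  set.seed(34)
  cfg <- test_encoder_config()
  wa <- aux_encoder_init(cfg, 4)
  seg <- vmf_volume(array(sample(0:4, 6 * 7 * 5, TRUE), c(6, 7, 5)))
  oh <- seg_one_hot(seg)
  pa <- encode_labels(oh, cfg, wa)
  expect_identical(pa$F1$dims, c(6L, 7L, 5L))
  expect_identical(ncol(pa$F1$X), 4L)
  expect_identical(ncol(pa$F2$X), 8L)
  expect_identical(ncol(pa$F3$X), 16L)
  # permuting two label channels changes the output (no accidental pooling)
  oh_sw <- oh
  oh_sw$data <- oh$data[, , , c(2, 1, 3, 4)]
  pa_sw <- encode_labels(oh_sw, cfg, wa)
  expect_gt(max(abs(pa_sw$F1$X - pa$F1$X)), 1e-6)
  # seeded determinism
  expect_identical(encode_labels(oh, cfg, wa)$F2$X, pa$F2$X)
  # aux gradients check out
  pa_c <- encode_labels(oh, cfg, wa, keep_cache = TRUE)
  R1 <- matrix(rnorm(length(pa$F1$X)), nrow(pa$F1$X))
  R2 <- matrix(rnorm(length(pa$F2$X)), nrow(pa$F2$X))
  R3 <- matrix(rnorm(length(pa$F3$X)), nrow(pa$F3$X))
  loss <- function(w2) {
    p <- encode_labels(oh, cfg, w2)
    sum(p$F1$X * R1) + sum(p$F2$X * R2) + sum(p$F3$X * R3)
  }
  ga <- vmftract:::encode_labels_bwd(wa, pa_c, R1, R2, R3)
  for (nm in c("conv1", "conv2", "conv3")) {
    expect_lt(check_some(loss, function(w) w[[nm]]$W,
                         function(w, v) { w[[nm]]$W[] <- v; w },
                         ga[[nm]]$W, wa, eps = 1e-5), 1e-5)
  }
})

test_that("one-hot segmentation encoding rejects unknown labels", {
  seg <- vmf_volume(array(c(0, 1, 2, 3, 4, 0, 1, 2), c(2, 2, 2)))
  oh <- seg_one_hot(seg)
  expect_identical(vol_channels(oh), 4L)
  expect_equal(rowSums(vol_matrix(oh)),
               as.numeric(vol_matrix(seg) != 0))
  bad <- vmf_volume(array(c(0, 7, 0, 0, 0, 0, 0, 0), c(2, 2, 2)))
  expect_error(seg_one_hot(bad), "unknown tissue label")
})

test_that("encoder config validates its invariants", {
  expect_error(encoder_config(patch_side = 5), "power of two")
  expect_error(encoder_config(embed_dim = 30, n_heads = 8), "divide")
  expect_error(encoder_config(channels = c(64, 32, 128)), "increase")
})
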