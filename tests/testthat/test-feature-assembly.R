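make_pyramid <- function(seed = 41, dims = c(8L, 8L, 8L)) {
  set.seed(seed)
  cfg <- test_encoder_config()
  w <- encoder_init(cfg, in_channels = 5)
  encode_odf(vmf_volume(array(rnorm(prod(dims) * 5), c(dims, 5))), cfg, w)
}

test_that("pyramid interpolation concatenates per-scale trilinear samples", {
  pyr <- make_pyramid()
  set.seed(42)
  p <- cbind(runif(50, 0, 7), runif(50, 0, 7), runif(50, 0, 7))
  out <- interp_pyramid(pyr, p)
  expect_identical(ncol(out), 8L + 16L + 32L)
  # brute-force oracle per scale (with the same border clamp on coarse grids)
  brute_scale <- function(lev, ps) {
    ps <- pmin(pmax(ps, 0), matrix(rep(lev$dims - 1L, each = nrow(ps)),
                                   nrow(ps), 3))
    t(vapply(seq_len(nrow(ps)), function(i) {
      i0 <- pmin(floor(ps[i, ]), lev$dims - 2L)
      f <- ps[i, ] - i0
      acc <- numeric(ncol(lev$X))
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
        idx <- 1 + (i0[1] + dx) + (i0[2] + dy) * lev$dims[1] +
          (i0[3] + dz) * lev$dims[1] * lev$dims[2]
        acc <- acc + w * lev$X[idx, ]
      }
      acc
    }, numeric(ncol(lev$X))))
  }
  oracle <- cbind(brute_scale(pyr$F1, p), brute_scale(pyr$F2, p / 2),
                  brute_scale(pyr$F3, p / 4))
  expect_lt(max(abs(out - oracle)), 1e-10)
  # F1 component at a voxel center is that voxel's value
  out_c <- interp_pyramid(pyr, c(3, 4, 5))
  idx <- 1 + 3 + 4 * 8 + 5 * 64
  expect_equal(out_c[1, 1:8], pyr$F1$X[idx, ], tolerance = 1e-12)
  expect_error(interp_pyramid(pyr, c(-1, 0, 0)), "outside")
})

test_that("pyramid interpolation has length 448 at the full-scale widths", {
  C <- encoder_config()$channels
  expect_identical(sum(C), 448L)
})

test_that("center values gather the 27-voxel F1 neighborhood in scan order", {
  pyr <- make_pyramid(43)
  cv <- center_values(pyr, c(3.2, 4.1, 2.9))
  expect_identical(ncol(cv), 27L * 8L)
  # block for offset (+1,0,0): tap index with x fastest is 15th block... the
  # contract is checked by shifting: moving p one voxel moves the window
  cv_sh <- center_values(pyr, c(4.2, 4.1, 2.9))
  # blocks are reused: tap (x+1) of cv equals tap (x) of shifted window
  # tap order is x fastest: block j covers offset (dx,dy,dz)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (j in which(off[, 1] == -1)) {
    j2 <- which(off[, 1] == 0 & off[, 2] == off[j, 2] &
                  off[, 3] == off[j, 3])
    expect_equal(cv_sh[, (j - 1) * 8 + 1:8], cv[, (j2 - 1) * 8 + 1:8],
                 tolerance = 1e-12)
  }
  # constant field: 27 identical blocks
  pyr_c <- pyr
  pyr_c$F1$X <- matrix(rep(seq_len(8), each = nrow(pyr$F1$X)),
                       nrow(pyr$F1$X), 8)
  cvc <- center_values(pyr_c, c(3.2, 4.1, 2.9))
  expect_equal(matrix(cvc, ncol = 8, byrow = TRUE),
               matrix(seq_len(8), 27, 8, byrow = TRUE), tolerance = 1e-12)
  # full-scale widths give 27 * 64 = 1728 numbers
  expect_identical(27L * encoder_config()$channels[1], 1728L)
  # edge clamping keeps the window in bounds
  expect_silent(center_values(pyr, c(0, 0, 0)))
})

test_that("look-ahead point moves along the previous direction", {
  p <- c(10, 10, 10)
  expect_equal(lookahead_point(p, c(1, 0, 0), 0.5)[1, ], c(10.5, 10, 10))
  expect_equal(lookahead_point(p, c(0, 1, 0), 0)[1, ], p)
  u <- c(1, 2, 2) / 3
  la <- lookahead_point(p, u, 0.7)[1, ] - p
  expect_equal(la / sqrt(sum(la^2)), u, tolerance = 1e-12)
})

test_that("history vector extracts lags 1..11 with oldest-direction padding", {
  h <- runit(12)
  hv <- history_vector(h)
  expect_identical(length(hv), 18L)
  expect_equal(hv, as.numeric(t(h[c(12, 10, 8, 6, 4, 2), ])))
  # straight history: six copies of the same direction
  hs <- matrix(rep(c(0, 0, 1), 5), 5, 3, byrow = TRUE)
  expect_equal(history_vector(hs), rep(c(0, 0, 1), 6))
  # short buffer: lags 1 and 3 real, deeper lags fall back to the oldest
  h4 <- runit(4)
  hv4 <- history_vector(h4)
  expect_equal(hv4[1:3], h4[4, ])
  expect_equal(hv4[4:6], h4[2, ])
  expect_equal(hv4[7:9], h4[1, ])
  expect_equal(hv4[10:18], rep(h4[1, ], 3))
  # appending a duplicate of the oldest-padded lag leaves padded slots stable
  expect_error(history_vector(matrix(0, 0, 3)), "empty")
  # batched variant agrees with the scalar one
  H <- array(0, c(3, 3, 6))
  ns <- c(2L, 5L, 6L)
  set.seed(44)
  for (i in 1:3) for (k in seq_len(ns[i])) H[i, , k] <- runit(1)
  hm <- vmftract:::history_matrix(H, ns)
  for (i in 1:3) {
    expect_equal(hm[i, ], history_vector(t(H[i, , seq_len(ns[i])])),
                 tolerance = 1e-12)
  }
})

test_that("keypoint centroids are voxel-center means in world mm", {
  arr <- array(0L, c(10, 10, 10))
  arr[2, 3, 4] <- 1L                      # single voxel
  arr[5, 5, 5] <- 2L; arr[7, 5, 5] <- 2L  # symmetric pair
  arr[8, 8, 8] <- 3L
  arr[2, 8, 2] <- 4L
  arr[8, 2, 8] <- 5L
  parc <- vmf_volume(arr, voxel_size = 2)
  kp <- keypoint_centroids(parc, 1:5)
  expect_equal(kp[1, ], c(1, 2, 3) * 2)
  expect_equal(kp[2, ], c(5, 4, 4) * 2)   # midpoint of voxels 4 and 6 (0-based)
  expect_error(keypoint_centroids(parc, c(1, 2, 3, 4, 9)), "label 9")
  # digitized ball: centroid close to the ball center
  arr2 <- array(0L, c(21, 21, 21))
  ctr <- c(10, 10, 10)
  for (i in 1:21) for (j in 1:21) for (k in 1:21) {
    if (sum((c(i, j, k) - 1 - ctr)^2) <= 25) arr2[i, j, k] <- 1L
  }
  ball <- vmf_volume(arr2, voxel_size = 1)
  expect_lt(max(abs(keypoint_centroids(ball, 1)[1, ] - ctr)), 0.05)
})

test_that("position vector is the normalized five-distance encoding", {
  kp <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  pv <- position_vector(c(0, 0, 0), kp)
  expect_equal(drop(pv), rep(0.2, 5))
  set.seed(45)
  P <- matrix(rnorm(60), 20, 3)
  pv2 <- position_vector(P, kp)
  expect_equal(rowSums(pv2), rep(1, 20), tolerance = 1e-12)
  expect_true(all(pv2 > 0))
  # hand-computed planar case
  kp2 <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(3, 4, 0), c(0, 0, 5))
  p <- c(3, 4, 0)
  r <- c(5, 4, 3, 0 + 1e-9, sqrt(9 + 16 + 25))
  expect_equal(drop(position_vector(p, kp2)),
               r / sum(r), tolerance = 1e-6)
})

test_that("assemble_input enforces layout and dimension", {
  cfg <- test_encoder_config()
  n <- 4
  C <- cfg$channels; a <- cfg$aux_channels
  parts <- list(odf_p = matrix(1, n, sum(C)),
                odf_look = matrix(2, n, sum(C)),
                center = matrix(3, n, 27 * C[1]),
                tissue = matrix(4, n, sum(a)),
                fixel = matrix(5, n, sum(a)),
                history = matrix(6, n, 18),
                position = matrix(0.2, n, 5))
  X <- assemble_input(parts, expected_dim = model_input_dim(cfg))
  expect_identical(ncol(X), model_input_dim(cfg))
  # zeroing one part changes only its slice
  parts2 <- parts
  parts2$history <- matrix(0, n, 18)
  X2 <- assemble_input(parts2)
  diffcols <- which(colSums(abs(X - X2)) > 0)
  hist_cols <- as.integer(2 * sum(C) + 27 * C[1] + 2 * sum(a)) + 1:18
  expect_identical(diffcols, hist_cols)
  expect_error(assemble_input(parts[-3]), "missing input parts")
  expect_error(assemble_input(parts, expected_dim = 10), "expected 10")
  parts$position[1, 1] <- NA
  expect_error(assemble_input(parts), "non-finite")
})

test_that("different points give different assembled inputs on a non-constant pyramid", {
  ph <- test_phantom()
  m <- test_model()
  pyr <- model_pyramids(m, phantom_volumes(ph))
  kp <- keypoint_centroids(ph$parcellation, 1:5)
  p <- rbind(c(14, 16, 16), c(18, 16, 16))
  u <- rbind(c(1, 0, 0), c(1, 0, 0))
  h <- rbind(rep(c(1, 0, 0), 6), rep(c(1, 0, 0), 6))
  pw <- vox_to_world(ph$fa, p)
  X <- vmftract:::model_features(pyr$odf, pyr$tissue, pyr$fixel, p, u, h,
                                 pw, kp, m$cfg)
  expect_gt(max(abs(X[1, ] - X[2, ])), 1e-8)
})
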