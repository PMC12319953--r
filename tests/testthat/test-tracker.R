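toy_seg <- function() {
  # one cortical GM voxel at (2,2,2) 0-based with two WM 6-neighbors
  arr <- array(0L, c(5, 5, 5))
  arr[3, 3, 3] <- seg_labels[["cgm"]]
  arr[4, 3, 3] <- seg_labels[["wm"]]
  arr[3, 4, 3] <- seg_labels[["wm"]]
  vmf_volume(arr, voxel_size = 1.2)
}

test_that("seed count is 5 per gray-white 6-neighbor pair with bounded jitter", {
  seg <- toy_seg()
  cfg <- tracking_config(seed = 1)
  set.seed(1)
  seeds <- generate_seeds(seg, cfg)
  expect_identical(nrow(seeds$pos), 10L)   # 2 pairs x 5
  # all pre-jitter positions are the GM voxel center
  ctr <- vox_to_world(seg, c(2, 2, 2))
  expect_true(all(abs(sweep(seeds$pos, 2, ctr)) <= 0.6 + 1e-12))
  # no adjacency: zero seeds with a warning
  empty <- vmf_volume(array(0L, c(4, 4, 4)), voxel_size = 1.2)
  expect_warning(s0 <- generate_seeds(empty, cfg), "no gray-white")
  expect_identical(nrow(s0$pos), 0L)
  # jitter bounds over many seeds: positions within +/-0.6 mm per axis and
  # angles within 30 degrees of a base direction
  arr <- array(0L, c(6, 6, 6))
  arr[3, 3, 3] <- seg_labels[["cgm"]]
  arr[4, 3, 3] <- seg_labels[["wm"]]
  seg1 <- vmf_volume(arr, voxel_size = 1.2)
  cfg_many <- tracking_config(seeds_per_neighbor = 2000, seed = 2)
  set.seed(2)
  many <- generate_seeds(seg1, cfg_many)
  ctr1 <- vox_to_world(seg1, c(2, 2, 2))
  off <- sweep(many$pos, 2, ctr1)
  expect_true(all(abs(off) <= 0.6 + 1e-12))
  expect_gt(max(abs(off)), 0.55)           # jitter actually spans its range
  ang <- to_spherical(many$dir)
  base <- to_spherical(c(1, 0, 0))
  expect_true(all(abs(ang[, 1] - base[1]) <= 30 * pi / 180 + 1e-9))
  expect_true(all(abs(ang[, 2] - base[2]) <= 30 * pi / 180 + 1e-9))
})

test_that("termination classification follows the tissue rules", {
  seg <- toy_seg()
  w <- vox_to_world(seg, rbind(c(3, 2, 2),  # WM
                               c(2, 2, 2),  # cortical GM
                               c(0, 0, 0),  # background
                               c(10, 0, 0)))# outside grid
  cls <- classify_termination(w, seg)
  expect_identical(cls, c("continue", "accepted", "rejected_exit",
                          "rejected_exit"))
  arr <- seg$data
  arr[2, 3, 3] <- seg_labels[["csf"]]
  arr[3, 3, 4] <- seg_labels[["scgm"]]
  seg2 <- vmf_volume(arr, affine = seg$affine)
  w2 <- vox_to_world(seg2, rbind(c(1, 2, 2), c(2, 2, 3)))
  expect_identical(classify_termination(w2, seg2),
                   c("rejected_csf", "accepted"))
})

test_that("tractogram container validates status labels", {
  s <- list(matrix(0, 2, 3))
  expect_s3_class(vmf_tractogram(s), "vmf_tractogram")
  expect_error(vmf_tractogram(s, "bogus"), "unknown status")
  expect_error(vmf_tractogram(s, c("accepted", "accepted")), "length")
})

test_that("anatomically constrained tracking invariants hold on a phantom", {
  ph <- test_phantom()
  m <- test_model()           # untrained: invariants must hold regardless
  cfg <- tracking_config(seed = 7, alphas = c(1600, 6400))
  res <- track_whole_brain(m, phantom_volumes(ph), cfg,
                           keep_rejected = TRUE)
  tg <- res$tractogram
  expect_identical(sum(res$stats$accepted),
                   sum(tg$status == "accepted"))
  seg_m <- vol_matrix(ph$seg)[, 1]
  dims <- vol_dim(ph$seg)
  lab_at <- function(P) {
    v <- round(world_to_vox(ph$seg, P))
    seg_m[1 + v[, 1] + v[, 2] * dims[1] + v[, 3] * dims[1] * dims[2]]
  }
  acc <- tg$streamlines[tg$status == "accepted"]
  expect_gt(length(acc), 0)
  for (S in acc) {
    n <- nrow(S)
    expect_gte(n, 3)
    # uniform 0.6 mm spacing
    expect_lt(max(abs(sqrt(rowSums(diff(S)^2)) - 0.6)), 1e-6)
    # length cap
    expect_lte(streamline_length(S), 130)
    # starts in cortical GM at the gray-white boundary, interior all WM,
    # ends in (sub)cortical GM, and never touches CSF
    labs <- lab_at(S)
    expect_identical(labs[1], seg_labels[["cgm"]])
    expect_true(all(labs[2:(n - 1)] == seg_labels[["wm"]]))
    expect_true(labs[n] %in% seg_labels[c("cgm", "scgm")])
    expect_false(any(labs == seg_labels[["csf"]]))
  }
  # rejected-by-CSF streamlines exist in stats accounting
  expect_identical(nrow(res$stats), 2L)
  expect_identical(res$stats$n_seeds[1], res$stats$n_seeds[2])
  expect_equal(res$retained,
               sum(res$stats$accepted) / sum(res$stats$n_seeds))
})

test_that("a master seed makes whole-brain tracking exactly reproducible", {
  ph <- test_phantom()
  m <- test_model()
  cfg <- tracking_config(seed = 13, alphas = 3200)
  r1 <- track_whole_brain(m, phantom_volumes(ph), cfg)
  r2 <- track_whole_brain(m, phantom_volumes(ph), cfg)
  expect_identical(r1$stats, r2$stats)
  expect_equal(r1$tractogram$streamlines, r2$tractogram$streamlines,
               tolerance = 1e-15)
  # a different seed gives a different tractogram
  r3 <- track_whole_brain(m, phantom_volumes(ph),
                          tracking_config(seed = 14, alphas = 3200))
  expect_false(identical(r1$stats, r3$stats) &&
                 identical(lapply(r1$tractogram$streamlines, round, 6),
                           lapply(r3$tractogram$streamlines, round, 6)))
})

test_that("single-seed propagation matches its contract", {
  ph <- test_phantom()
  m <- test_model()
  cfg <- tracking_config(seed = 1)
  seed <- list(pos = vox_to_world(ph$seg, c(8, 16, 16))[1, ] + 0.1,
               dir = c(1, 0, 0))
  set.seed(3)
  out <- propagate(m, phantom_volumes(ph), seed, alpha = 6400, cfg)
  expect_true(out$status %in% c("accepted", "rejected_csf",
                                "rejected_exit", "rejected_length"))
  S <- out$streamline
  if (nrow(S) > 1) {
    expect_lt(max(abs(sqrt(rowSums(diff(S)^2)) - 0.6)), 1e-6)
    expect_equal(S[1, ], seed$pos, tolerance = 1e-12)
  }
})
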