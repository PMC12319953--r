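test_that("prolate eigenvalue inversion hits the requested FA and MD", {
  expect_equal(fa_to_eigenvalues(0, 1e-3), rep(1e-3, 3))
  for (fa in c(0.05, 0.1, 0.25, 0.6, 0.95)) {
    lam <- fa_to_eigenvalues(fa, 1e-3)
    expect_equal(mean(lam), 1e-3, tolerance = 1e-15)
    expect_equal(vmftract:::fa_from_eigenvalues(lam), fa, tolerance = 1e-10)
    expect_gt(lam[1], lam[2])
    expect_equal(lam[2], lam[3])
  }
  expect_error(fa_to_eigenvalues(1, 1e-3), "\\[0, 1\\)")
  expect_error(fa_to_eigenvalues(0.2, 0), "positive")
})

test_that("straight-bundle phantom hits its FA profile and tangent alignment", {
  ph <- test_phantom()
  seg <- vol_matrix(ph$seg)[, 1]
  wm <- which(seg == seg_labels[["wm"]])
  expect_gt(length(wm), 100)
  b <- ph$spec$bundles[[1]]
  # FA at each WM voxel matches the linear profile of its axis distance
  dims <- vol_dim(ph$fa)
  ijk <- cbind((wm - 1) %% dims[1],
               ((wm - 1) %/% dims[1]) %% dims[2],
               (wm - 1) %/% (dims[1] * dims[2]))
  w <- vox_to_world(ph$fa, ijk)
  # distance to the segment (pure-x centerline at y=z=19.2)
  tpar <- pmin(pmax(w[, 1], b$from[1]), b$to[1])
  dist <- sqrt((w[, 1] - tpar)^2 + (w[, 2] - 19.2)^2 + (w[, 3] - 19.2)^2)
  fa_target <- b$fa_center + (b$fa_edge - b$fa_center) * dist / b$tube_radius
  expect_lt(max(abs(vol_matrix(ph$fa)[wm, 1] - fa_target)), 1e-3)
  # principal eigenvector within 1 degree of the bundle axis
  T6 <- vol_matrix(ph$tensors)[wm, ]
  for (i in sample(length(wm), 25)) {
    D <- matrix(c(T6[i, 1], T6[i, 4], T6[i, 5],
                  T6[i, 4], T6[i, 2], T6[i, 6],
                  T6[i, 5], T6[i, 6], T6[i, 3]), 3, 3)
    e1 <- eigen(D, symmetric = TRUE)$vectors[, 1]
    expect_lt(acos(min(1, abs(e1[1]))) * 180 / pi, 1)
  }
  # first fixel stores the tangent too
  fx <- vol_matrix(ph$fixels)[wm, ]
  expect_lt(max(acos(pmin(1, abs(fx[, 1])))) * 180 / pi, 1)
  expect_true(all(fx[, 4:6] == 0))   # single bundle: one fixel only
})

test_that("identical seeds give identical phantoms", {
  b <- bundle_spec("straight", from = c(12, 14.4, 14.4),
                   to = c(16.8, 14.4, 14.4), tube_radius = 2.4,
                   cap_radius = 2.4)
  sp <- phantom_spec(grid = c(25, 25, 25), bundles = list(b),
                     n_gt_per_bundle = 5, seed = 77)
  p1 <- make_phantom(sp)
  p2 <- make_phantom(sp)
  expect_identical(p1$tensors$data, p2$tensors$data)
  expect_identical(p1$gt$streamlines, p2$gt$streamlines)
})

test_that("crossing bundles produce two fixels and averaged tensors", {
  ph <- test_phantom_crossing()
  fx <- vol_matrix(ph$fixels)
  two <- rowSums(abs(fx[, 4:6])) > 0
  expect_gt(sum(two), 5)
  # crossing voxels hold two (roughly orthogonal) unit tangents
  f1 <- fx[two, 1:3, drop = FALSE]
  f2 <- fx[two, 4:6, drop = FALSE]
  expect_lt(max(abs(rowSums(f1^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(f2^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(f1 * f2))), 0.2)
  # crossing voxels lie inside both ground-truth masks
  m1 <- vol_matrix(ground_truth_mask(ph, 1))[, 1]
  m2 <- vol_matrix(ground_truth_mask(ph, 2))[, 1]
  expect_true(all(m1[two] == 1 & m2[two] == 1))
})

test_that("ground-truth masks are tube digitizations inside the white matter", {
  ph <- test_phantom()
  m <- vol_matrix(ground_truth_mask(ph, 1))[, 1]
  seg <- vol_matrix(ph$seg)[, 1]
  expect_true(all(seg[m == 1] == seg_labels[["wm"]]))
  # voxel count close to the analytic tube volume pi r^2 L; measured on a
  # tube whose ends and radius do not coincide with voxel centers, where
  # boundary-inclusion effects would dominate the digitization error
  bno <- bundle_spec("straight", from = c(9.1, 19.7, 18.5),
                     to = c(28.3, 19.7, 18.5), tube_radius = 3.35,
                     cap_radius = 2.4)
  phno <- make_phantom(phantom_spec(grid = c(37, 37, 37),
                                    bundles = list(bno),
                                    n_gt_per_bundle = 2, seed = 8))
  mno <- sum(vol_matrix(ground_truth_mask(phno, 1))[, 1])
  L <- sqrt(sum((bno$to - bno$from)^2))
  expected <- pi * bno$tube_radius^2 * L / prod(vol_voxel_size(phno$fa))
  expect_lt(abs(mno - expected) / expected, 0.15)
  expect_error(ground_truth_mask(ph, 5), "no bundle")
  # disjoint bundles have disjoint masks
  b1 <- bundle_spec("straight", from = c(9.6, 9.6, 9.6),
                    to = c(16.8, 9.6, 9.6), tube_radius = 1.8,
                    cap_radius = 1.8)
  b2 <- bundle_spec("straight", from = c(9.6, 26.4, 26.4),
                    to = c(16.8, 26.4, 26.4), tube_radius = 1.8,
                    cap_radius = 1.8)
  ph2 <- make_phantom(phantom_spec(grid = c(31, 31, 31),
                                   bundles = list(b1, b2),
                                   n_gt_per_bundle = 3, seed = 5))
  mm1 <- vol_matrix(ground_truth_mask(ph2, 1))[, 1]
  mm2 <- vol_matrix(ground_truth_mask(ph2, 2))[, 1]
  expect_identical(sum(mm1 * mm2), 0L)
})

test_that("ground-truth streamlines stay inside the tube at the stated spacing", {
  ph <- test_phantom()
  b <- ph$spec$bundles[[1]]
  for (S in ph$gt$streamlines[1:10]) {
    seg <- sqrt(rowSums(diff(S)^2))
    expect_true(all(seg <= ph$spec$gt_spacing + 1e-9))
    dist <- sqrt((S[, 2] - 19.2)^2 + (S[, 3] - 19.2)^2)
    expect_true(all(dist <= b$tube_radius + 1e-9))
  }
  # both orientations are present (paired forward/reverse)
  s1 <- ph$gt$streamlines[[1]]
  s2 <- ph$gt$streamlines[[2]]
  expect_equal(s1, s2[rev(seq_len(nrow(s2))), ], tolerance = 1e-12)
})

test_that("phantom specification is validated", {
  expect_error(phantom_spec(bundles = list()), "at least one")
  b <- bundle_spec("straight", from = c(0, 0, 0), to = c(5, 0, 0))
  kp_flat <- matrix(c(0.1, 0.1, 0.5, 0.9, 0.1, 0.5, 0.1, 0.9, 0.5,
                      0.9, 0.9, 0.5, 0.5, 0.5, 0.5), 5, 3, byrow = TRUE)
  expect_error(phantom_spec(bundles = list(b), keypoint_frac = kp_flat),
               "coplanar")
  expect_error(bundle_spec("straight", fa_center = 1.2), "FA values")
  # a bundle leaving the grid is an error
  big <- bundle_spec("straight", from = c(2, 12, 12), to = c(60, 12, 12))
  expect_error(make_phantom(phantom_spec(grid = c(25, 25, 25),
                                         bundles = list(big),
                                         n_gt_per_bundle = 2)),
               "exits the grid")
})

test_that("arc and polyline centerlines carry consistent frames", {
  for (ty in c("arc", "polyline")) {
    b <- if (ty == "arc") {
      bundle_spec("arc", center = c(10, 10, 15), radius = 8,
                  normal = c(0, 0, 1), angles = c(0, pi / 2))
    } else {
      bundle_spec("polyline",
                  points = rbind(c(5, 5, 15), c(10, 8, 15), c(15, 14, 16)))
    }
    fr <- vmftract:::centerline_frame(b, spacing = 0.3)
    expect_lt(max(abs(rowSums(fr$T^2) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(fr$N1 * fr$T))), 1e-9)
    expect_lt(max(abs(rowSums(fr$N2 * fr$T))), 1e-9)
    expect_lt(max(abs(rowSums(fr$N1 * fr$N2))), 1e-9)
  }
})
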