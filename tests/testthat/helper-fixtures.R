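# shared fixtures, built once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

# small straight-bundle phantom (33^3, tube along +x)
test_phantom <- function() {
  memo("phantom_straight", function() {
    b <- bundle_spec("straight", from = c(13.2, 19.2, 19.2),
                     to = c(25.2, 19.2, 19.2),
                     tube_radius = 3.0, cap_radius = 2.4)
    make_phantom(phantom_spec(grid = c(33, 33, 33), bundles = list(b),
                              n_gt_per_bundle = 30, seed = 3))
  })
}

# 90-degree crossing phantom (two straight bundles)
test_phantom_crossing <- function() {
  memo("phantom_crossing", function() {
    b1 <- bundle_spec("straight", from = c(10.8, 19.2, 19.2),
                      to = c(27.6, 19.2, 19.2),
                      tube_radius = 2.4, cap_radius = 2.4)
    b2 <- bundle_spec("straight", from = c(19.2, 10.8, 19.2),
                      to = c(19.2, 27.6, 19.2),
                      tube_radius = 2.4, cap_radius = 2.4)
    make_phantom(phantom_spec(grid = c(33, 33, 33), bundles = list(b1, b2),
                              n_gt_per_bundle = 20, seed = 4))
  })
}

# small encoder configuration used across neural tests
test_encoder_config <- function() {
  encoder_config(patch_side = 4, embed_dim = 24, n_blocks = 1,
                 units_per_block = 2, n_heads = 4, mlp_ratio = 2,
                 channels = c(8, 16, 32), aux_channels = c(4, 8, 16))
}

# an untrained model on the test config (weights seeded)
test_model <- function() {
  memo("model_untrained", function() {
    set.seed(99)
    tract_model(test_encoder_config(), head_hidden = c(64, 32))
  })
}

# random unit vectors
runit <- function(n) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u / sqrt(rowSums(u^2))
}

# spherical quadrature nodes/weights (Gauss-Legendre in cos(theta) x
# uniform azimuth); integrates smooth f on the sphere to ~1e-10
sphere_quadrature <- function(n_theta = 80, n_phi = 160) {
  memo(paste0("quad", n_theta, "x", n_phi), function() {
    gl <- pracma::gaussLegendre(n_theta, -1, 1)
    phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
    ct <- rep(gl$x, times = n_phi)
    st <- sqrt(1 - ct^2)
    ph <- rep(phi, each = n_theta)
    list(points = cbind(st * cos(ph), st * sin(ph), ct),
         weights = rep(gl$w, times = n_phi) * (2 * pi / n_phi))
  })
}

# central-difference numerical gradient
num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}
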