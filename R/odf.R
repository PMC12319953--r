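#' Size of the real symmetric spherical-harmonic basis
#'
#' Number of real SH basis functions when truncating at an even order `L`
#' and keeping even degrees only (the ODF is antipodally symmetric):
#' `(L+1)(L+2)/2`. Order 8 gives the 45-coefficient per-voxel representation
#' used throughout.
#'
#' @param order maximum SH degree, even and >= 0.
#' @return integer basis size.
#' @export
sh_basis_size <- function(order) {
  if (length(order) != 1 || order < 0 || order %% 2 != 0) {
    stop("order must be a single even non-negative integer")
  }
  as.integer((order + 1) * (order + 2) / 2)
}

# (degree, order) pairs of the basis, even degrees, m = -l..l
sh_index_table <- function(order) {
  lm <- do.call(rbind, lapply(seq(0, order, by = 2), function(l) {
    cbind(l = l, m = seq(-l, l))
  }))
  lm
}

#' Evaluate the real symmetric SH basis at unit vectors
#'
#' Real basis with even degrees `l = 0, 2, ..., order` and orders
#' `m = -l..l` (in that sequence): `m = 0` terms are `N_l0 P_l0(cos theta)`,
#' positive `m` use `sqrt(2) N_lm P_lm cos(m phi)` and negative `m` the
#' matching `sin(|m| phi)` terms. The basis is orthonormal on the sphere and
#' antipodally symmetric by construction.
#'
#' @param order even SH order.
#' @param u matrix (n x 3) of unit vectors (normalized internally).
#' @return matrix (n x sh_basis_size(order)).
#' @export
real_sh_basis <- function(order, u) {
  u <- rbind3(u)
  u <- u / sqrt(rowSums(u^2))
  ang <- to_spherical(u)
  ct <- cos(ang[, 1])
  phi <- ang[, 2]
  nb <- sh_basis_size(order)
  B <- matrix(0, nrow(u), nb)
  col <- 0L
  for (l in seq(0, order, by = 2)) {
    # associated Legendre P_l^m(cos theta), rows m = 0..l
    P <- pracma::legendre(l, ct)
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in seq(-l, l)) {
      col <- col + 1L
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      if (m == 0) {
        B[, col] <- nrm * P[1, ]
      } else if (m > 0) {
        B[, col] <- sqrt(2) * nrm * P[am + 1, ] * cos(am * phi)
      } else {
        B[, col] <- sqrt(2) * nrm * P[am + 1, ] * sin(am * phi)
      }
    }
  }
  B
}

#' Evaluate an SH coefficient vector at directions
#'
#' @param coeffs coefficient vector of length `sh_basis_size(order)`, or a
#'   matrix (n_voxels x basis) to evaluate many voxels at one direction.
#' @param u unit direction(s), (n x 3) or length 3.
#' @param order even SH order; inferred from the coefficient length by
#'   default.
#' @return numeric vector of function values.
#' @export
evaluate_sh <- function(coeffs, u, order = NULL) {
  cm <- if (is.null(dim(coeffs))) matrix(coeffs, nrow = 1) else coeffs
  if (is.null(order)) {
    # invert nb = (L+1)(L+2)/2 over even L
    L <- (sqrt(8 * ncol(cm) + 1) - 3) / 2
    if (abs(L - round(L)) > 1e-9 || round(L) %% 2 != 0) {
      stop("coefficient length ", ncol(cm), " is not a valid even-order basis size")
    }
    order <- as.integer(round(L))
  }
  if (ncol(cm) != sh_basis_size(order)) {
    stop("coefficient length ", ncol(cm), " does not match order ", order)
  }
  B <- real_sh_basis(order, u)
  if (nrow(cm) == 1L) {
    drop(B %*% t(cm))
  } else {
    if (nrow(B) == 1L) drop(cm %*% t(B)) else rowSums(cm * B)
  }
}

#' Antipodally symmetric spherical point set
#'
#' Fibonacci lattice on one hemisphere plus its antipodes; used as the
#' quadrature/design set for fitting SH coefficients.
#'
#' @param n total number of points (even).
#' @return matrix (n x 3) of unit vectors.
#' @export
sphere_points_sym <- function(n = 724) {
  m <- ceiling(n / 2)
  i <- seq_len(m) - 0.5
  z <- i / m                       # upper hemisphere, z in (0, 1)
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  s <- sqrt(1 - z^2)
  up <- cbind(s * cos(phi), s * sin(phi), z)
  rbind(up, -up)
}

#' Fractional anisotropy of a diffusion tensor
#'
#' Standard FA of the eigenvalue triple, clamped to `[0, 1]`. An all-zero
#' tensor returns 0 by convention.
#'
#' @param t symmetric 3x3 tensor, or a length-6 vector
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#' @return FA in `[0, 1]`.
#' @export
fa_from_tensor <- function(t) {
  if (is.null(dim(t))) {
    t <- matrix(c(t[1], t[4], t[5],
                  t[4], t[2], t[6],
                  t[5], t[6], t[3]), 3, 3)
  }
  ev <- eigen((t + t(t)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  fa_from_eigenvalues(ev)
}

fa_from_eigenvalues <- function(ev) {
  ss <- sum(ev^2)
  if (ss == 0) return(0)
  mn <- mean(ev)
  min(1, sqrt(3 / 2) * sqrt(sum((ev - mn)^2) / ss))
}

# --- vectorized symmetric 3x3 utilities on 6-column tensor matrices -------
# column order (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)

tensor6_eigenvalues <- function(T6) {
  xx <- T6[, 1]; yy <- T6[, 2]; zz <- T6[, 3]
  xy <- T6[, 4]; xz <- T6[, 5]; yz <- T6[, 6]
  q <- (xx + yy + zz) / 3
  p2 <- ((xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * (xy^2 + xz^2 + yz^2)) / 6
  p <- sqrt(pmax(p2, 0))
  e1 <- e2 <- e3 <- q
  nz <- p > 1e-30
  bxx <- (xx - q) / p; byy <- (yy - q) / p; bzz <- (zz - q) / p
  bxy <- xy / p; bxz <- xz / p; byz <- yz / p
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  e1[nz] <- (q + 2 * p * cos(phi))[nz]
  e3[nz] <- (q + 2 * p * cos(phi + 2 * pi / 3))[nz]
  e2[nz] <- (3 * q - e1 - e3)[nz]
  cbind(e1, e2, e3)               # descending
}

tensor6_fa <- function(T6) {
  ev <- pmax(tensor6_eigenvalues(T6), 0)
  ss <- rowSums(ev^2)
  mn <- rowMeans(ev)
  fa <- sqrt(3 / 2) * sqrt(rowSums((ev - mn)^2) / pmax(ss, 1e-300))
  fa[ss == 0] <- 0
  pmin(fa, 1)
}

tensor6_det <- function(T6) {
  T6[, 1] * (T6[, 2] * T6[, 3] - T6[, 6]^2) -
    T6[, 4] * (T6[, 4] * T6[, 3] - T6[, 6] * T6[, 5]) +
    T6[, 5] * (T6[, 4] * T6[, 6] - T6[, 2] * T6[, 5])
}

# inverse of each symmetric tensor via the adjugate, same 6-column layout
tensor6_inverse <- function(T6) {
  xx <- T6[, 1]; yy <- T6[, 2]; zz <- T6[, 3]
  xy <- T6[, 4]; xz <- T6[, 5]; yz <- T6[, 6]
  det <- tensor6_det(T6)
  cbind((yy * zz - yz^2) / det,
        (xx * zz - xz^2) / det,
        (xx * yy - xy^2) / det,
        (xz * yz - xy * zz) / det,
        (xy * yz - xz * yy) / det,
        (xy * xz - xx * yz) / det)
}

#' FA map of a tensor volume
#'
#' @param tensors a `vmf_volume` with 6 channels in lower-triangular order
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#' @return scalar `vmf_volume` of FA values in `[0, 1]`.
#' @export
fa_volume <- function(tensors) {
  stopifnot(vol_channels(tensors) == 6L)
  fa <- tensor6_fa(vol_matrix(tensors))
  vmf_volume(array(fa, vol_dim(tensors)), affine = tensors$affine)
}

#' Convert a diffusion-tensor volume to ODF spherical harmonics
#'
#' Evaluates the Gaussian-diffusion orientation distribution
#' \eqn{ODF(u) = (u^\top D^{-1} u)^{-3/2} / (4\pi\sqrt{\det D})} (unit
#' integral over the sphere) on a symmetric spherical point set and fits the
#' real even-order SH basis by least squares. Tensors are regularized by
#' flooring eigenvalues at `lambda_floor` before inversion, so background
#' (zero) voxels become tiny isotropic tensors rather than singular ones.
#'
#' @param tensors a 6-channel tensor `vmf_volume` (mm^2/s), lower-triangular
#'   channel order `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#' @param order even SH order, default 8 (45 coefficients).
#' @param sphere_points size of the fitting point set, default 724.
#' @param lambda_floor eigenvalue floor in mm^2/s, default 1e-6.
#' @return a `vmf_volume` with `sh_basis_size(order)` channels.
#' @export
tensor_to_dodf_sh <- function(tensors, order = 8, sphere_points = 724,
                              lambda_floor = 1e-6) {
  stopifnot(vol_channels(tensors) == 6L)
  T6 <- vol_matrix(tensors)
  ev <- tensor6_eigenvalues(T6)
  bad <- which(ev[, 3] < lambda_floor)
  if (length(bad)) {
    for (v in bad) {
      D <- matrix(c(T6[v, 1], T6[v, 4], T6[v, 5],
                    T6[v, 4], T6[v, 2], T6[v, 6],
                    T6[v, 5], T6[v, 6], T6[v, 3]), 3, 3)
      e <- eigen(D, symmetric = TRUE)
      lam <- pmax(e$values, lambda_floor)
      D <- e$vectors %*% (lam * t(e$vectors))
      T6[v, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    }
  }
  det <- tensor6_det(T6)
  if (any(det <= 0)) {
    stop("singular tensor after eigenvalue flooring at voxel(s) ",
         paste(utils::head(which(det <= 0), 3), collapse = ", "))
  }
  invD <- tensor6_inverse(T6)
  dirs <- sphere_points_sym(sphere_points)
  # u' D^-1 u as a product with the 6 quadratic monomials of u
  U2 <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
              2 * dirs[, 1] * dirs[, 2],
              2 * dirs[, 1] * dirs[, 3],
              2 * dirs[, 2] * dirs[, 3])
  B <- real_sh_basis(order, dirs)
  fit <- solve(crossprod(B), t(B))        # (nb x npoints) least-squares map
  nvox <- nrow(T6)
  nb <- sh_basis_size(order)
  coeffs <- matrix(0, nvox, nb)
  scale <- 1 / (4 * pi * sqrt(det))
  chunk <- max(1L, floor(2e7 / nrow(dirs)))
  for (start in seq(1L, nvox, by = chunk)) {
    idx <- start:min(nvox, start + chunk - 1L)
    q <- invD[idx, , drop = FALSE] %*% t(U2)   # (chunk x npoints)
    odf <- q^(-1.5) * scale[idx]
    coeffs[idx, ] <- odf %*% t(fit)
  }
  vmf_volume(array(coeffs, c(vol_dim(tensors), nb)), affine = tensors$affine)
}
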