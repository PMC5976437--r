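# Small separable 3D filtering primitives. No installed package provides 3D
# image convolution, Otsu thresholding or 3D connected components, so these
# are implemented here and unit-tested against direct computations.

# convolve a 3D array along one axis with a (short, odd-length) kernel,
# replicating edge values so flat fields stay flat
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  half <- (length(kernel) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = d[axis])
  n <- nrow(m)
  pad <- rbind(m[rep(1L, half), , drop = FALSE], m,
               m[rep(n, half), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * pad[j:(j + n - 1L), , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# sampled second derivative of a Gaussian, forced to zero sum so that a
# constant offset produces zero response
gaussian_d2_kernel <- function(sigma_vox) {
  r <- max(2L, ceiling(4 * sigma_vox))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  k <- g * (x^2 / sigma_vox^2 - 1) / sigma_vox^2
  k - mean(k)
}

# separable Gaussian smoothing; sigma_vox is per-axis (z, y, x) in voxels
gaussian_smooth_3d <- function(a, sigma_vox) {
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) a <- conv_axis(a, gaussian_kernel(sigma_vox[ax]), ax)
  }
  a
}

# scale-normalised negated Laplacian of Gaussian: bright blobs of scale
# sigma_vox give positive local maxima. response = -sum_ax s_ax^2 d2_ax(G*a)
log_response <- function(a, sigma_vox) {
  gz <- gaussian_kernel(sigma_vox[1]); gy <- gaussian_kernel(sigma_vox[2])
  gx <- gaussian_kernel(sigma_vox[3])
  a_x <- conv_axis(a, gx, 3)
  a_xy <- conv_axis(a_x, gy, 2)
  a_xz <- conv_axis(a_x, gz, 1)
  a_yz <- conv_axis(conv_axis(a, gy, 2), gz, 1)
  term_z <- conv_axis(a_xy, gaussian_d2_kernel(sigma_vox[1]), 1)
  term_y <- conv_axis(a_xz, gaussian_d2_kernel(sigma_vox[2]), 2)
  term_x <- conv_axis(a_yz, gaussian_d2_kernel(sigma_vox[3]), 3)
  -(sigma_vox[1]^2 * term_z + sigma_vox[2]^2 * term_y + sigma_vox[3]^2 * term_x)
}

# strict 3D local maxima (26-connectivity) above `threshold` and inside
# `mask`. Plateau ties are broken toward the lexicographically smallest
# (z, y, x) voxel: a voxel must strictly exceed earlier neighbours and be >=
# later ones. Returns an integer matrix with columns z, y, x.
local_maxima_3d <- function(resp, threshold, mask = NULL) {
  d <- dim(resp)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- resp
  ok <- resp > threshold
  if (!is.null(mask)) ok <- ok & mask
  iz <- 2:(d[1] + 1L); iy <- 2:(d[2] + 1L); ix <- 2:(d[3] + 1L)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    if (!any(ok)) break
    nb <- pad[iz + dz, iy + dy, ix + dx]
    later <- dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0)))
    ok <- ok & (if (later) resp >= nb else resp > nb)
  }
  which(ok, arr.ind = TRUE, useNames = FALSE)
}

# Otsu's threshold on a numeric vector (histogram with n_bins equal bins)
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, findInterval(x, seq(rng[1], rng[2],
                                                 length.out = n_bins + 1L),
                                          rightmost.closed = TRUE)), n_bins)
  p <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = n_bins + 1L)[-1] - diff(rng) / (2 * n_bins)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# label 26-connected components of a logical 3D array; returns an integer
# array (0 = background) with labels 1..n in decreasing component size order
label_components_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE, useNames = FALSE)
  lab_arr <- array(0L, d)
  n <- nrow(idx)
  if (n == 0L) return(lab_arr)
  pos <- array(0L, d)
  pos[mask] <- seq_len(n)
  # neighbour position (row in idx) for each of the 26 offsets, 0 if absent
  nbrs <- vector("list", 26L)
  k <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    k <- k + 1L
    zz <- idx[, 1] + dz; yy <- idx[, 2] + dy; xx <- idx[, 3] + dx
    inb <- zz >= 1L & zz <= d[1] & yy >= 1L & yy <= d[2] & xx >= 1L & xx <= d[3]
    np <- integer(n)
    np[inb] <- pos[cbind(zz[inb], yy[inb], xx[inb])]
    nbrs[[k]] <- np
  }
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (np in nbrs) {
      has <- np > 0L
      if (!any(has)) next
      cand <- lab[np[has]]
      lower <- cand < lab[has]
      if (any(lower)) {
        tmp <- lab[has]
        tmp[lower] <- cand[lower]
        lab[has] <- tmp
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp <- match(lab, sort(unique(lab)))
  sizes <- tabulate(comp)
  rk <- rank(-sizes, ties.method = "first")
  lab_arr[mask] <- rk[comp]
  lab_arr
}

# integer-voxel offsets (z,y,x) whose physical displacement lies inside an
# ellipsoid with semi-axes radii_um; includes the origin
ellipsoid_offsets <- function(radii_um, voxel_size) {
  r_vox <- ceiling(radii_um / voxel_size)
  g <- expand.grid(dz = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2],
                   dx = -r_vox[3]:r_vox[3])
  off <- as.matrix(g)
  phys <- sweep(off, 2, voxel_size, "*")
  keep <- rowSums(sweep(phys, 2, radii_um, "/")^2) <= 1
  off[keep, , drop = FALSE]
}

# translate offsets to in-bounds absolute voxel indices around a centre voxel
offsets_at <- function(center_vox, offsets, shape) {
  abs_idx <- sweep(offsets, 2, center_vox, "+")
  inb <- abs_idx[, 1] >= 1L & abs_idx[, 1] <= shape[1] &
    abs_idx[, 2] >= 1L & abs_idx[, 2] <= shape[2] &
    abs_idx[, 3] >= 1L & abs_idx[, 3] <= shape[3]
  list(idx = abs_idx[inb, , drop = FALSE], truncated = !all(inb))
}
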