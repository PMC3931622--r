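# Independent brute-force oracles used to pin the behaviour of the fast
# implementations. These deliberately use naive algorithms.

# flood-fill connected components via breadth-first search in plain R
flood_fill_labels <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1L, "18" = 2L, "26" = 3L), ]
  labels <- array(0L, dim = d)
  cur <- 0L
  stack <- integer(sum(mask))
  for (i in seq_along(mask)) {
    if (!mask[i] || labels[i] != 0L) next
    cur <- cur + 1L
    labels[i] <- cur
    stack[1] <- i
    top <- 1L
    while (top > 0L) {
      v <- stack[top]
      top <- top - 1L
      x <- ((v - 1) %% d[1]) + 1
      y <- (((v - 1) %/% d[1]) %% d[2]) + 1
      z <- ((v - 1) %/% (d[1] * d[2])) + 1
      xx <- x + offs$dx; yy <- y + offs$dy; zz <- z + offs$dz
      ok <- xx >= 1 & xx <= d[1] & yy >= 1 & yy <= d[2] &
        zz >= 1 & zz <= d[3]
      w <- (zz[ok] - 1) * d[1] * d[2] + (yy[ok] - 1) * d[1] + xx[ok]
      w <- w[mask[w] & labels[w] == 0L]
      if (length(w) > 0) {
        labels[w] <- cur
        stack[top + seq_along(w)] <- w
        top <- top + length(w)
      }
    }
  }
  labels
}

# exhaustive multi-otsu for 3 classes: double loop over threshold pairs,
# between-class variance computed from scratch per split
brute_otsu3 <- function(counts, values = seq_along(counts)) {
  n <- length(counts)
  p <- counts / sum(counts)
  mu_g <- sum(p * values)
  best <- -Inf
  best_t <- c(NA, NA)
  for (t1 in 1:(n - 2)) {
    for (t2 in (t1 + 1):(n - 1)) {
      idx1 <- 1:t1; idx2 <- (t1 + 1):t2; idx3 <- (t2 + 1):n
      w <- c(sum(p[idx1]), sum(p[idx2]), sum(p[idx3]))
      if (any(w == 0)) next
      mu <- c(sum(p[idx1] * values[idx1]) / w[1],
              sum(p[idx2] * values[idx2]) / w[2],
              sum(p[idx3] * values[idx3]) / w[3])
      s <- sum(w * (mu - mu_g)^2)
      if (s > best) {
        best <- s
        best_t <- c(t1, t2)
      }
    }
  }
  (values[best_t] + values[best_t + 1]) / 2
}

# all-pairs nearest distance from every TRUE voxel of `from` to the
# nearest TRUE voxel of `to`, in voxels
brute_nearest_distances <- function(from, to) {
  d <- dim(from)
  coord <- function(idx) cbind(((idx - 1) %% d[1]) + 1,
                               (((idx - 1) %/% d[1]) %% d[2]) + 1,
                               ((idx - 1) %/% (d[1] * d[2])) + 1)
  A <- coord(which(from))
  B <- coord(which(to))
  vapply(seq_len(nrow(A)), function(i) {
    sqrt(min((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
               (B[, 3] - A[i, 3])^2))
  }, numeric(1))
}

# two-pass Jarque-Bera from explicit moment sums
brute_jarque_bera <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  S <- m3 / m2^(3 / 2)
  K <- m4 / m2^2
  n / 6 * (S^2 + (K - 3)^2 / 4)
}

# closed-form Fresnel diffraction of a sharp 1D edge: transmittance t1 for
# x' < 0 and t2 for x' >= 0, evaluated at positions x after propagating a
# distance D (all lengths in the same units). Uses the standard Fresnel
# integrals C and S (pracma), fully independent of any FFT code.
fresnel_edge_analytic <- function(t1, t2, x, wavelength, D) {
  t0 <- -x * sqrt(2 / (wavelength * D))
  C <- pracma::fresnelC(t0)
  S <- pracma::fresnelS(t0)
  pref <- exp(-1i * pi / 4) / sqrt(2)
  upper <- pref * complex(real = 0.5 - C, imaginary = 0.5 - S)
  lower <- pref * complex(real = 0.5 + C, imaginary = 0.5 + S)
  t1 * lower + t2 * upper
}

# deterministic voxelized ellipsoid volume (axis-aligned) for recon tests
make_ellipsoid_delta <- function(n, semi_axes_vox, value = 1e-6) {
  arr <- array(0, c(n, n, n))
  c0 <- (n + 1) / 2
  xs <- (seq_len(n) - c0) / semi_axes_vox[1]
  ys <- (seq_len(n) - c0) / semi_axes_vox[2]
  for (z in seq_len(n)) {
    gz <- (z - c0) / semi_axes_vox[3]
    if (abs(gz) <= 1)
      arr[, , z] <- (outer(xs^2, ys^2, `+`) + gz^2 <= 1) * value
  }
  arr
}

# random sparse binary volume
random_mask <- function(dims, fill = 0.05) {
  array(runif(prod(dims)) < fill, dim = dims)
}
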