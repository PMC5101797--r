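# Independent oracles and small fixtures shared across tests.

# small curving-tube phantom that runs through the whole pipeline in under a
# second; geometry scaled down from the validation presets
mini_phantom_spec <- function(seed = 7) {
  phantom_spec(
    dims = c(48, 48, 48),
    tubes = list(list(
      points = cbind(c(24, 22, 26, 24), c(10, 22, 34, 44), c(24, 26, 22, 24)),
      radius_start = 2.5, radius_end = 3.5)),
    target_intensity = 810,
    noise_components = list(c(148, 10, 0.4), c(187, 15, 0.4), c(228, 60, 0.2)),
    seed = seed)
}

# moment-corrected sampled Gaussian-derivative kernel, re-derived in R
kernel_1d <- function(sigma, order) {
  R <- max(1, ceiling(4 * sigma))
  x <- -R:R
  g <- exp(-0.5 * x^2 / sigma^2)
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) {
    k <- -(x / sigma^2) * g
    return(k / sum(-x * k))
  }
  k <- ((x^2 / sigma^2) - 1) / sigma^2 * g
  k <- k - mean(k)
  k / sum(0.5 * x^2 * k)
}

reflect_index <- function(i, n) {
  while (any(bad <- i < 1 | i > n)) {
    i[bad & i < 1] <- 1 - i[bad & i < 1]
    bad <- i < 1 | i > n
    i[bad & i > n] <- 2 * n + 1 - i[bad & i > n]
  }
  i
}

# direct (non-separable) 3D convolution with an outer-product kernel and
# mirror padding: the brute-force oracle for the compiled Hessian path
conv3d_direct <- function(vol, sigma, orders) {
  kx <- kernel_1d(sigma, orders[1])
  ky <- kernel_1d(sigma, orders[2])
  kz <- kernel_1d(sigma, orders[3])
  R <- (length(kx) - 1) / 2
  d <- dim(vol)
  out <- array(0, d)
  off <- -R:R
  for (ix in 1:d[1]) for (iy in 1:d[2]) for (iz in 1:d[3]) {
    px <- reflect_index(ix - off, d[1])
    py <- reflect_index(iy - off, d[2])
    pz <- reflect_index(iz - off, d[3])
    patch <- vol[px, py, pz]
    k3 <- outer(outer(kx, ky), kz)
    out[ix, iy, iz] <- sum(patch * k3)
  }
  out * sigma^2
}

# optimal 1D k-clustering by sum of squared deviations (dynamic programme)
dp_kmeans_1d <- function(x, k = 3) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  sse <- function(i, j) { # cost of segment x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  split <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- sse(1, j)
  for (m in 2:k) {
    for (j in m:n) {
      for (i in m:j) {
        v <- cost[m - 1, i - 1] + sse(i, j)
        if (v < cost[m, j]) { cost[m, j] <- v; split[m, j] <- i }
      }
    }
  }
  # recover segment means
  bounds <- integer(k + 1); bounds[k + 1] <- n
  j <- n
  for (m in k:2) { bounds[m] <- split[m, j] - 1L; j <- bounds[m] }
  bounds[1] <- 0L
  centroids <- numeric(k)
  for (m in 1:k) centroids[m] <- mean(x[(bounds[m] + 1):bounds[m + 1]])
  list(centroids = centroids, sse = cost[k, n])
}

# vessel voxels with no vessel 26-neighbour
count_isolated <- function(lab) {
  a <- if (is.array(lab)) lab else lab$data
  d <- dim(a)
  nb <- array(0L, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh2 <- array(0L, d)
    rx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ry <- max(1, 1 + dy):min(d[2], d[2] + dy)
    rz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    sh2[rx - dx, ry - dy, rz - dz] <- a[rx, ry, rz]
    nb <- nb + sh2
  }
  sum(a == 1L & nb == 0L)
}

# number of 26-connected components of the vessel class (union-find)
count_components26 <- function(lab) {
  a <- if (is.array(lab)) lab else lab$data
  d <- dim(a)
  idx <- which(a == 1L)
  if (length(idx) == 0) return(0L)
  pos <- arrayInd(idx, d)
  id <- seq_along(idx)
  lookup <- array(0L, d)
  lookup[idx] <- id
  parent <- id
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_along(idx)) {
    p <- pos[r, ]
    for (o in seq_len(nrow(offs))) {
      q <- p + offs[o, ]
      if (any(q < 1) || any(q > d)) next
      j <- lookup[q[1], q[2], q[3]]
      if (j > 0L) {
        ri <- find(r); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_along(idx), find, integer(1))))
}

# sample from an Exp+Exp+Gauss mixture (clipped at zero like the pipeline data)
sample_mixture <- function(n, lambda1, lambda2, mu_g, sigma_g, w, seed) {
  set.seed(seed)
  comp <- sample.int(3, n, replace = TRUE, prob = w)
  x <- numeric(n)
  x[comp == 1] <- rexp(sum(comp == 1), lambda1)
  x[comp == 2] <- rexp(sum(comp == 2), lambda2)
  x[comp == 3] <- rnorm(sum(comp == 3), mu_g, sigma_g)
  pmax(x, 0)
}
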