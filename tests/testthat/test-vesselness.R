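test_that("Hessian eigenvalues are exact on polynomial volumes", {
  n <- 21
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  f <- array(2 * g$x^2 + 3 * g$y^2 - g$z^2 + g$x * g$y, c(n, n, n))
  e <- hessian_eigenvalues(f, 1)
  want <- eigen(matrix(c(4, 1, 0, 1, 6, 0, 0, 0, -2), 3))$values
  want <- want[order(abs(want))]
  ctr <- c(11, 11, 11)
  got <- c(e$h1[11, 11, 11], e$h2[11, 11, 11], e$h3[11, 11, 11])
  expect_equal(got, want, tolerance = 1e-9)

  const <- hessian_eigenvalues(array(5, c(8, 8, 8)), 1.5)
  expect_lt(max(abs(const$h1), abs(const$h2), abs(const$h3)), 1e-12)
})

test_that("compiled Hessian matches a direct dense convolution oracle", {
  set.seed(4)
  d <- c(11, 10, 9)
  vol <- array(0, d)
  # smooth random field: a few Gaussian blobs
  for (b in 1:4) {
    c0 <- runif(3, 3, 8)
    g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
    vol <- vol + runif(1, 50, 200) *
      array(exp(-((g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2) / 8), d)
  }
  sigma <- 1.2
  ref <- list(
    hxx = conv3d_direct(vol, sigma, c(2, 0, 0)),
    hyy = conv3d_direct(vol, sigma, c(0, 2, 0)),
    hzz = conv3d_direct(vol, sigma, c(0, 0, 2)),
    hxy = conv3d_direct(vol, sigma, c(1, 1, 0)),
    hxz = conv3d_direct(vol, sigma, c(1, 0, 1)),
    hyz = conv3d_direct(vol, sigma, c(0, 1, 1)))
  e <- hessian_eigenvalues(vol, sigma)
  set.seed(5)
  pick <- cbind(sample(d[1], 10, TRUE), sample(d[2], 10, TRUE),
                sample(d[3], 10, TRUE))
  for (r in 1:10) {
    i <- pick[r, 1]; j <- pick[r, 2]; k <- pick[r, 3]
    H <- matrix(c(ref$hxx[i, j, k], ref$hxy[i, j, k], ref$hxz[i, j, k],
                  ref$hxy[i, j, k], ref$hyy[i, j, k], ref$hyz[i, j, k],
                  ref$hxz[i, j, k], ref$hyz[i, j, k], ref$hzz[i, j, k]), 3)
    want <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    want <- want[order(abs(want))]
    got <- c(e$h1[i, j, k], e$h2[i, j, k], e$h3[i, j, k])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("a bright cylinder gives line-like eigenvalue structure on its axis", {
  d <- c(32, 32, 32)
  g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  r2 <- (g$x - 16)^2 + (g$y - 16)^2
  vol <- array(ifelse(r2 <= 9, 100, 0), d) # radius-3 tube along z
  e <- hessian_eigenvalues(vol, 3)
  h <- c(e$h1[16, 16, 16], e$h2[16, 16, 16], e$h3[16, 16, 16])
  expect_lt(abs(h[1]), 0.1 * abs(h[2]))
  expect_lt(h[2], 0)
  expect_lt(h[3], 0)
  expect_lt(abs(h[2] - h[3]) / abs(h[3]), 0.15)
})

test_that("the vesselness formula honours its sign gate and closed-form limit", {
  mk_eig <- function(h1, h2, h3) {
    structure(list(h1 = array(h1, c(1, 1, 1)), h2 = array(h2, c(1, 1, 1)),
                   h3 = array(h3, c(1, 1, 1)), sigma = 1, dims = c(1, 1, 1)),
              class = "hessian_eigen")
  }
  p <- vesselness_params(c = 1)
  expect_equal(vesselness_single_scale(mk_eig(0, 0, 0), p)$data[1], 0)
  expect_equal(vesselness_single_scale(mk_eig(1, 5, -10), p)$data[1], 0)
  expect_equal(vesselness_single_scale(mk_eig(0, -3, 7), p)$data[1], 0)
  # ideal line structure, S >> c: v -> (1 - e^-2)
  v <- vesselness_single_scale(mk_eig(0, -1e6, -1e6), p)$data[1]
  expect_equal(v, 1 - exp(-2), tolerance = 1e-6)
})

test_that("vesselness is bounded, shift-invariant and contrast-covariant", {
  ph <- build_phantom(mini_phantom_spec())
  p <- vesselness_params(scales = c(1, 2, 3))
  v1 <- vesselness_multiscale(ph$volume, p)
  expect_true(all(v1$data >= 0 & v1$data <= 1))
  # adding a constant changes nothing (the Hessian kills constants)
  v2 <- vesselness_multiscale(volume3d(ph$volume$data + 250), p)
  expect_equal(v2$data, v1$data, tolerance = 1e-8)
  # intensity scaling scales S but leaves the eigenvalue ratios unchanged
  e1 <- hessian_eigenvalues(ph$volume, 2)
  e2 <- hessian_eigenvalues(volume3d(3 * ph$volume$data), 2)
  expect_equal(e2$h3, 3 * e1$h3, tolerance = 1e-8)
  expect_equal(e2$h1, 3 * e1$h1, tolerance = 1e-8)
})

test_that("multi-scale fusion is the pointwise maximum of single scales", {
  ph <- build_phantom(mini_phantom_spec())
  cval <- resolve_c(ph$volume, scales = c(1, 2, 3))
  single <- lapply(c(1, 2, 3), function(s) {
    vesselness_single_scale(hessian_eigenvalues(ph$volume, s),
                            vesselness_params(c = cval, scales = c(1, 2, 3)))$data
  })
  fused <- vesselness_multiscale(
    ph$volume, vesselness_params(c = cval, scales = c(1, 2, 3)))
  ref <- pmax(single[[1]], single[[2]], single[[3]])
  expect_equal(fused$data, ref, tolerance = 1e-12)
  # one-scale list degenerates to the single-scale response exactly
  one <- vesselness_multiscale(ph$volume, vesselness_params(c = cval, scales = 2))
  expect_equal(one$data, single[[2]], tolerance = 1e-12)
  expect_error(vesselness_params(scales = numeric(0)), "non-empty")
})

test_that("multi-scale vesselness separates tube voxels from background", {
  ph <- build_phantom(mini_phantom_spec())
  v <- vesselness_multiscale(ph$volume)
  inside <- v$data[ph$truth$data == 1]
  outside <- v$data[ph$truth$data == 0]
  expect_gt(median(inside), quantile(outside, 0.99))
  # threshold-free check: voxelwise AUC as a detector of the true tube
  auc <- (mean(rank(c(inside, outside))[seq_along(inside)]) -
            (length(inside) + 1) / 2) / length(outside)
  expect_gt(auc, 0.99)
})

test_that("c resolves to half the maximum Hessian norm", {
  mk_eig <- function(h1, h2, h3) {
    structure(list(h1 = array(h1, c(1, 1, 2)), h2 = array(h2, c(1, 1, 2)),
                   h3 = array(h3, c(1, 1, 2)), sigma = 1, dims = c(1, 1, 2)),
              class = "hessian_eigen")
  }
  e <- mk_eig(c(0, 0), c(-3, 0), c(-sqrt(91), 1)) # norms 10 and 1
  expect_equal(resolve_c(e), 5)
  expect_error(resolve_c(volume3d(array(1, c(8, 8, 8)))), "zero")

  ph <- build_phantom(mini_phantom_spec())
  scales <- c(1, 2)
  smax <- 0
  for (s in scales) {
    e <- hessian_eigenvalues(ph$volume, s)
    smax <- max(smax, sqrt(max(e$h1^2 + e$h2^2 + e$h3^2)))
  }
  expect_equal(resolve_c(ph$volume, scales = scales), smax / 2,
               tolerance = 1e-12)
})

test_that("rescaling restores the original intensity range monotonically", {
  orig <- volume3d(array(c(0, rep(405, 6), 810), c(2, 2, 2)))
  filt <- volume3d(array(c(0, 1, 0.5, 0.25, 0, 1, 0.75, 1), c(2, 2, 2)))
  out <- rescale_filtered(filt, orig)
  expect_equal(range(out$data), c(0, 810))
  expect_equal(out$data[1, 1, 1], 0)
  expect_equal(out$data[2, 1, 1], 810)
  expect_equal(cor(as.vector(out$data), as.vector(filt$data),
                   method = "spearman"), 1)
  # identity when the original range is already [0, 1]
  unit <- volume3d(array(seq(0, 1, length.out = 8), c(2, 2, 2)))
  expect_equal(rescale_filtered(unit, unit)$data, unit$data, tolerance = 1e-12)
  expect_warning(
    const <- rescale_filtered(volume3d(array(0.5, c(2, 2, 2))), orig),
    "constant")
  expect_true(all(const$data == 0))
})
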