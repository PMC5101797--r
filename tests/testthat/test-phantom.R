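test_that("a straight constant-radius tube rasterizes to exact disks", {
  dims <- c(64, 64, 64)
  pts <- cbind(c(32, 32), c(32, 32), c(-2, 67)) # spans the whole z axis
  tube <- rasterize_tube(dims, pts, 3, 3)
  disk <- outer((1:64 - 32)^2, (1:64 - 32)^2, `+`) <= 9
  for (k in c(1, 20, 40, 64)) {
    expect_equal(tube$data[, , k], array(as.integer(disk), c(64, 64)))
  }
  # symmetry under the reflection about the centerline (x -> 64 - x)
  expect_equal(tube$data[1:63, , ], tube$data[63:1, , ])
  expect_equal(tube$data[, 1:63, ], tube$data[, 63:1, ])
  expect_true(all(tube$data[64, , ] == 0))
  expect_error(rasterize_tube(dims, pts[1, , drop = FALSE], 3, 3),
               "at least 2")
  expect_error(rasterize_tube(dims, rbind(c(32, 32, 10), c(32, 32, 10)), 3, 3),
               "zero length")
})

test_that("a varying radius interpolates linearly along the centerline", {
  dims <- c(40, 40, 60)
  pts <- cbind(c(20, 20), c(20, 20), c(1, 60))
  tube <- rasterize_tube(dims, pts, 2, 5)
  area <- apply(tube$data, 3, sum)
  # slice areas grow with z; endpoints match the end radii
  expect_gt(cor(area, seq_along(area)), 0.97)
  expect_equal(area[1], sum(outer((1:40 - 20)^2, (1:40 - 20)^2, `+`) <= 4))
  expect_equal(area[60], sum(outer((1:40 - 20)^2, (1:40 - 20)^2, `+`) <= 25))
})

test_that("phantom volumes are seeded, clipped and component-partitioned", {
  spec <- mini_phantom_spec(seed = 9)
  a <- build_phantom(spec)
  b <- build_phantom(spec)
  expect_identical(a$volume$data, b$volume$data) # bit-identical per seed
  expect_identical(a$truth$data, b$truth$data)
  expect_true(all(a$volume$data >= 0))
  expect_identical(dim(a$volume$data), dim(a$truth$data))

  one <- phantom_spec(dims = c(48, 48, 48),
                      tubes = list(list(points = cbind(c(24, 24), c(24, 24),
                                                       c(5, 44)),
                                        radius_start = 2, radius_end = 2)),
                      target_intensity = 700,
                      noise_components = list(c(148, 10, 1)), seed = 3)
  ph <- build_phantom(one)
  bg <- ph$volume$data[ph$truth$data == 0]
  expect_gt(length(bg), 1e5)
  expect_equal(mean(bg), 148, tolerance = 0.2 / 148) # CLT bound at this n
  expect_equal(sd(bg), 10, tolerance = 0.02)
})

test_that("background intensities follow the specified Gaussian mixture", {
  spec <- mini_phantom_spec(seed = 12)
  ph <- build_phantom(spec)
  bg <- ph$volume$data[ph$truth$data == 0]
  w <- spec$noise_components[, "omega"]
  pmix <- function(q) {
    colSums(w * vapply(q, function(v)
      pnorm(v, spec$noise_components[, "mu"], spec$noise_components[, "sigma"]),
      numeric(3)))
  }
  qs <- c(-Inf, seq(120, 400, by = 10), Inf)
  p <- diff(pmix(qs))
  counts <- tabulate(findInterval(bg, qs), nbins = length(p))
  keep <- p * length(bg) >= 5
  chi <- suppressWarnings(
    chisq.test(counts[keep], p = p[keep] / sum(p[keep])))
  expect_gt(chi$p.value, 0.001)
})

test_that("specification invariants are enforced", {
  tube <- list(points = cbind(c(10, 10), c(10, 10), c(2, 20)),
               radius_start = 2, radius_end = 2)
  expect_warning(
    sp <- phantom_spec(dims = c(24, 24, 24), tubes = list(tube),
                       target_intensity = 810,
                       noise_components = list(c(148, 10, 0.4), c(187, 15, 0.4),
                                               c(228, 60, 0.24)), seed = 0),
    "renormalizing")
  expect_equal(sum(sp$noise_components[, "omega"]), 1)
  expect_error(
    suppressWarnings(phantom_spec(dims = c(24, 24, 24), tubes = list(tube),
                 target_intensity = 100,
                 noise_components = list(c(148, 10, 1)), seed = 0)),
    "exceed every noise mean")
  expect_error(phantom_spec(dims = c(24, 24, 24), tubes = list(tube),
                            target_intensity = 810,
                            noise_components = list(), seed = 0),
               "noise component")
})

test_that("the validation presets carry the published parameters", {
  pr <- phantom_presets(seed = 4)
  expect_equal(pr$phantom_I$dims, c(128L, 128L, 128L))
  expect_equal(pr$phantom_II$dims, c(240L, 240L, 240L))
  expect_equal(pr$phantom_I$target_intensity, 810)
  expect_equal(pr$phantom_II$target_intensity, 650)
  # printed proportions (0.4, 0.4, 0.24) and (0.5, 0.3) arrive renormalized
  expect_equal(pr$phantom_I$noise_components[, "omega"],
               c(0.4, 0.4, 0.24) / 1.04, tolerance = 1e-12)
  expect_equal(pr$phantom_II$noise_components[, "omega"],
               c(0.5, 0.3) / 0.8, tolerance = 1e-12)
  expect_equal(pr$phantom_I$noise_components[, "mu"], c(148, 187, 228))
  expect_equal(pr$phantom_II$noise_components[, "sigma"], c(10, 15))
  expect_length(pr$phantom_I$tubes, 1)
  expect_length(pr$phantom_II$tubes, 9)
  radii <- unlist(lapply(pr$phantom_II$tubes,
                         function(t) c(t$radius_start, t$radius_end)))
  expect_true(all(radii >= 1.5 & radii <= 6))
})
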