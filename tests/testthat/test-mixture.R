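test_that("histograms conserve counts and handle degenerate ranges", {
  set.seed(21)
  vol <- volume3d(array(runif(12^3, 0, 100), c(12, 12, 12)))
  h <- build_histogram(vol, 64)
  expect_equal(sum(h$counts), 12^3)
  expect_length(h$counts, 64)
  expect_equal(length(h$edges), 65)

  hc <- build_histogram(array(3, c(5, 5, 5)), 16)
  expect_equal(sum(hc$counts > 0), 1)
  expect_equal(sum(hc$counts), 125)
  expect_error(build_histogram(vol, 1), "n_bins")
})

test_that("histogram of exponential samples matches the density", {
  set.seed(22)
  x <- rexp(1e6, 0.01)
  h <- build_histogram(x, 256)
  p <- diff(pexp(h$edges, 0.01))
  p[1] <- p[1] + pexp(h$edges[1], 0.01)
  p[256] <- p[256] + 1 - pexp(h$edges[257], 0.01)
  keep <- p * 1e6 >= 5
  chi <- suppressWarnings(
    chisq.test(h$counts[keep], p = p[keep] / sum(p[keep]))
  )
  expect_gt(chi$p.value, 0.001)
})

test_that("peak detection finds modes and ignores slopes and flanks", {
  mids <- 1:512
  bumps <- 4e4 * dnorm(mids, 80, 12) + 3e4 * dnorm(mids, 250, 15) +
    2e4 * dnorm(mids, 420, 10)
  h <- structure(list(edges = 0:512 + 0.5, mids = mids,
                      counts = round(bumps)),
                 class = "intensity_histogram")
  pk <- detect_peaks(h, 11)
  expect_length(pk, 3)
  expect_equal(pk, c(80, 250, 420), tolerance = 2)

  uni <- structure(list(edges = 0:100 + 0.5, mids = 1:100,
                        counts = round(5e4 * dnorm(1:100, 50, 9))),
                   class = "intensity_histogram")
  expect_length(detect_peaks(uni, 5), 1)

  mono <- structure(list(edges = 0:100 + 0.5, mids = 1:100,
                         counts = round(exp(seq(10, 2, length.out = 100)))),
                    class = "intensity_histogram")
  expect_length(detect_peaks(mono, 5), 0)
})

test_that("K-means recovers separated clusters and the cold-start rule", {
  x <- c(rep(10, 500), rep(100, 300), rep(500, 200))
  km <- kmeans_init(x, peaks = c(10, 100, 500))
  expect_equal(km$mu, c(10, 100, 500))
  expect_equal(km$w, c(0.5, 0.3, 0.2))

  # no peaks: centroids start at (I_max, (I_max+I_min)/2, I_min)
  set.seed(23)
  y <- c(runif(6000, 0, 20), runif(2500, 380, 430), runif(1500, 780, 810), 0, 810)
  km2 <- kmeans_init(y, peaks = numeric(0))
  expect_equal(km2$range, c(0, 810))
  # Lloyd from the cold start lands on the optimal 3-clustering (DP oracle)
  sub <- sort(y)[seq(1, length(y), length.out = 1000)]
  dp <- dp_kmeans_1d(sub, 3)
  km3 <- kmeans_init(sub, peaks = numeric(0))
  binw <- diff(range(sub)) / 1024
  expect_equal(km3$mu, dp$centroids, tolerance = binw)

  expect_error(kmeans_init(c(1, 1, 2, 2), numeric(0)), "distinct")
})

test_that("K-means clusters map onto mixture initial values", {
  km <- structure(list(mu = c(10, 100, 500), sigma = c(5, 20, 30),
                       w = c(0.5, 0.3, 0.2), range = c(0, 810)),
                  class = "kmeans_init")
  init <- em_init_from_kmeans(km)
  expect_equal(init$lambda1, 0.1)
  expect_equal(init$lambda2, 0.01)
  expect_equal(init$mu_g, 500)
  expect_equal(init$sigma_g, 30)
  expect_equal(init$w, c(0.5, 0.3, 0.2))
  expect_equal(sum(init$w), 1)

  km$mu[1] <- 0 # degenerate lowest centroid
  init0 <- em_init_from_kmeans(km)
  expect_true(is.finite(init0$lambda1) && init0$lambda1 > 0)
  km$mu[2] <- 0
  expect_error(em_init_from_kmeans(km), "middle centroid")
})

test_that("one EM iteration reproduces hand-computed updates", {
  x <- c(10, 480, 520)
  init <- mixture_model(0.1, 0.01, 500, 30, c(0.5, 0.3, 0.2))
  # responsibilities and M-step executed by literal arithmetic
  dens <- cbind(0.1 * exp(-0.1 * x), 0.01 * exp(-0.01 * x),
                dnorm(x, 500, 30))
  wd <- sweep(dens, 2, c(0.5, 0.3, 0.2), `*`)
  resp <- wd / rowSums(wd)
  S <- colSums(resp); Sx <- colSums(resp * x)
  lam <- S[1:2] / Sx[1:2]
  mu <- Sx[3] / S[3]
  sg <- sqrt(sum(resp[, 3] * (x - mu)^2) / S[3])
  w <- S / 3

  fit <- em_fit(x, init, tol = 1e6, max_iter = 2) # exactly one M-step
  expect_equal(fit$lambda1, unname(lam[1]))
  expect_equal(fit$lambda2, unname(lam[2]))
  expect_equal(fit$mu_g, unname(mu))
  expect_equal(fit$sigma_g, unname(sg))
  expect_equal(fit$w, unname(w))
  expect_equal(sum(fit$w), 1, tolerance = 1e-12)
})

test_that("a Gaussian component pinned on one point raises a collapse error", {
  expect_error(
    em_fit(c(10, 500), mixture_model(0.1, 0.01, 500, 30, c(0.5, 0.3, 0.2)),
           tol = 1e-9, max_iter = 50),
    "collapsed")
})

test_that("EM recovers a pure exponential rate and ascends monotonically", {
  set.seed(24)
  x <- rexp(1e5, 0.02)
  fit <- em_fit(build_histogram(x, 2048),
                em_init_from_kmeans(kmeans_init(x, numeric(0))),
                tol = 1e-12, max_iter = 20000)
  dominant <- if (fit$w[1] >= fit$w[2]) fit$lambda1 else fit$lambda2
  expect_equal(dominant, 1 / mean(x), tolerance = 0.02)
  expect_true(all(diff(fit$loglik) >= -1e-8 * abs(fit$loglik[-fit$n_iter])))
})

test_that("histogram-weighted and per-voxel EM agree", {
  x <- sample_mixture(2e5, 0.05, 0.005, 700, 40, c(0.45, 0.35, 0.2), seed = 25)
  init <- em_init_from_kmeans(kmeans_init(x, numeric(0)))
  f_vox <- em_fit(x, init, tol = 1e-9, max_iter = 5000)
  f_his <- em_fit(build_histogram(x, 1024), init, tol = 1e-9, max_iter = 5000)
  for (p in c("lambda1", "lambda2", "mu_g", "sigma_g")) {
    expect_equal(f_his[[p]], f_vox[[p]], tolerance = 0.01)
  }
  expect_equal(f_his$w, f_vox$w, tolerance = 0.01)
})

test_that("the mixture density is a proper, decomposable density", {
  m <- mixture_model(0.05, 0.005, 700, 40, c(0.45, 0.35, 0.2))
  total <- integrate(function(x) mixture_pdf(m, x), 0, Inf,
                     rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  g <- mixture_model(1, 1, 50, 5, c(0, 0, 1))
  xs <- seq(30, 70, by = 0.5)
  expect_equal(mixture_pdf(g, xs), dnorm(xs, 50, 5))
  expect_equal(mixture_pdf(m, 0),
               0.45 * 0.05 + 0.35 * 0.005 + 0.2 * dnorm(0, 700, 40))
  expect_equal(mixture_pdf(m, -5), 0.2 * dnorm(-5, 700, 40))
})

test_that("invalid mixture parameters are rejected", {
  expect_error(mixture_model(1, 1, 0, 1, c(0.5, 0.6, -0.1)), "weights")
  expect_error(mixture_model(-1, 1, 0, 1, c(1, 0, 0) / 1), "rates")
  expect_error(mixture_model(1, 1, 0, 0, c(0.3, 0.3, 0.4)), "sigma_g")
})
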