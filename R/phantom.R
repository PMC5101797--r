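#' Specification of a synthetic tubular phantom
#'
#' Describes a validation volume: tube geometry (smooth centerlines with a
#' linearly varying radius), the stochastic tube intensity, and the layered
#' Gaussian background noise. Background voxels are partitioned among the
#' noise components: each voxel draws its component index with probability
#' `omega`, then an intensity from `N(mu, sigma^2)`, clipped at zero. Tube
#' voxels get `target_intensity + N(0, target_sigma^2)`, also clipped.
#'
#' Component proportions that do not sum to one (the printed triples of the
#' validation phantoms slightly overshoot) are renormalized with a warning.
#' The tube target intensity must exceed every noise mean, so the vessel
#' lobe sits above the background in the histogram.
#'
#' @param dims integer length-3 voxel counts.
#' @param tubes list of tube descriptors: each a list with `points` (an
#'   `n x 3` matrix of centerline control points, voxel coordinates),
#'   `radius_start`, `radius_end` (voxels, > 0.5).
#' @param target_intensity scalar intensity of tube voxels before
#'   perturbation; must exceed all noise means.
#' @param target_sigma standard deviation of the stochastic tube intensity
#'   (default 15, keeping the vessel lobe narrow).
#' @param noise_components list of `c(mu, sigma, omega)` triples (sigma is
#'   the standard deviation).
#' @param seed RNG seed; the phantom is fully determined by it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims, tubes, target_intensity, target_sigma = 15,
                         noise_components, seed = 0L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 8L))
  if (length(noise_components) == 0L)
    stop("phantom_spec: at least one noise component is required", call. = FALSE)
  nc <- do.call(rbind, lapply(noise_components, function(x) {
    x <- as.numeric(x)
    if (length(x) != 3L || x[2] <= 0 || x[3] <= 0)
      stop("phantom_spec: each noise component must be c(mu, sigma, omega) with sigma, omega > 0",
           call. = FALSE)
    x
  }))
  colnames(nc) <- c("mu", "sigma", "omega")
  s <- sum(nc[, "omega"])
  if (abs(s - 1) > 1e-9) {
    warning(sprintf(
      "phantom_spec: noise proportions sum to %.4g; renormalizing to 1", s))
    nc[, "omega"] <- nc[, "omega"] / s
  }
  if (target_intensity <= max(nc[, "mu"]))
    stop("phantom_spec: target intensity must exceed every noise mean",
         call. = FALSE)
  for (tb in tubes) {
    if (!is.matrix(tb$points) || ncol(tb$points) != 3L || nrow(tb$points) < 2L)
      stop("phantom_spec: each tube needs an n x 3 control-point matrix with n >= 2",
           call. = FALSE)
    if (tb$radius_start <= 0.5 || tb$radius_end <= 0.5)
      stop("phantom_spec: tube radii must exceed 0.5 voxel", call. = FALSE)
  }
  structure(list(dims = dims, tubes = tubes,
                 target_intensity = target_intensity,
                 target_sigma = target_sigma,
                 noise_components = nc, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Rasterize one tube into a binary mask
#'
#' The centerline is a natural cubic spline through the control points,
#' parameterized by arc length; the radius varies linearly from
#' `radius_start` to `radius_end` along it. A voxel (centres at integer
#' coordinates) is labeled 1 when it lies within the local radius of the
#' curve, implemented as a union of densely sampled spheres (step 0.25
#' voxel along the curve).
#'
#' @param dims integer length-3 voxel counts.
#' @param points `n x 3` matrix of centerline control points.
#' @param radius_start,radius_end radii in voxels (> 0.5).
#' @return A [label_volume()].
#' @export
rasterize_tube <- function(dims, points, radius_start, radius_end) {
  dims <- as.integer(dims)
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("rasterize_tube: centerline needs at least 2 control points",
         call. = FALSE)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (sum(seg) <= 0)
    stop("rasterize_tube: degenerate centerline (zero length)", call. = FALSE)
  t0 <- c(0, cumsum(seg))
  total <- t0[length(t0)]
  fx <- splinefun(t0, points[, 1], method = "natural")
  fy <- splinefun(t0, points[, 2], method = "natural")
  fz <- splinefun(t0, points[, 3], method = "natural")
  ts <- seq(0, total, by = 0.25)
  if (ts[length(ts)] < total) ts <- c(ts, total)
  cx <- fx(ts); cy <- fy(ts); cz <- fz(ts)
  rr <- radius_start + (radius_end - radius_start) * ts / total

  mask <- array(FALSE, dims)
  for (i in seq_along(ts)) {
    r <- rr[i]
    ix <- max(1L, floor(cx[i] - r)):min(dims[1], ceiling(cx[i] + r))
    iy <- max(1L, floor(cy[i] - r)):min(dims[2], ceiling(cy[i] + r))
    iz <- max(1L, floor(cz[i] - r)):min(dims[3], ceiling(cz[i] + r))
    if (length(ix) == 0L || length(iy) == 0L || length(iz) == 0L) next
    dx2 <- (ix - cx[i])^2
    dy2 <- (iy - cy[i])^2
    dz2 <- (iz - cz[i])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    cur <- mask[ix, iy, iz, drop = FALSE]
    mask[ix, iy, iz] <- cur | (d2 <= r^2)
  }
  label_volume(array(as.integer(mask), dims))
}

#' Build a phantom volume from its specification
#'
#' Rasterizes all tubes into the ground-truth mask, then fills the volume:
#' background voxels sample a noise component by its proportion and draw
#' `N(mu, sigma^2)`; tube voxels draw `target_intensity +
#' N(0, target_sigma^2)`. All intensities are clipped at zero. The result is
#' bit-identical for a given spec (the seed is part of the spec).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_volume`: `volume` (a [volume3d()]),
#'   `truth` (a [label_volume()]), and the `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims
  truth <- array(0L, dims)
  for (tb in spec$tubes) {
    m <- rasterize_tube(dims, tb$points, tb$radius_start, tb$radius_end)
    truth <- truth | m$data
  }
  truth <- array(as.integer(truth), dims)

  set.seed(spec$seed)
  n <- prod(dims)
  is_tube <- truth == 1L
  n_tube <- sum(is_tube)
  n_bg <- n - n_tube

  nc <- spec$noise_components
  comp <- sample.int(nrow(nc), n_bg, replace = TRUE, prob = nc[, "omega"])
  vals <- numeric(n)
  vals[!is_tube] <- rnorm(n_bg, mean = nc[comp, "mu"], sd = nc[comp, "sigma"])
  vals[is_tube] <- spec$target_intensity + rnorm(n_tube, 0, spec$target_sigma)
  vals <- pmax(vals, 0)

  structure(list(volume = volume3d(array(vals, dims)),
                 truth = label_volume(truth),
                 spec = spec),
            class = "phantom_volume")
}

#' The two validation phantom presets
#'
#' Phantom I: a 128^3 volume holding one curving (helix-like) tube whose
#' radius grows smoothly from 4 to 6 voxels, tube intensity 810, and three
#' background noise components `(148, 10^2, 0.4)`, `(187, 15^2, 0.4)`,
#' `(228, 60^2, 0.24)` (proportions renormalized to sum to one). Phantom II:
#' a 240^3 volume with a 3x3 array of straight and curved tubes of radii
#' between 1.5 and 6 voxels, tube intensity 650, and noise components
#' `(148, 10^2, 0.5)`, `(187, 15^2, 0.3)` (renormalized likewise). The
#' printed noise parameters and volume sizes are fixed; the exact centerline
#' curves are free geometry chosen to match the described morphology
#' (smoothly changing diameters, like real vessels).
#'
#' @param seed RNG seed stored in both specs.
#' @return Named list with elements `phantom_I` and `phantom_II`, each a
#'   [phantom_spec()].
#' @export
phantom_presets <- function(seed = 0L) {
  # Phantom I: single sweeping helical arc through a 128^3 volume
  t <- seq(0, 1, length.out = 11)
  theta <- pi * (-0.8 + 1.6 * t)
  p1 <- cbind(64 + 40 * cos(theta),
              64 + 40 * sin(theta),
              12 + 104 * t)
  spec1 <- suppressWarnings(phantom_spec(
    dims = c(128, 128, 128),
    tubes = list(list(points = p1, radius_start = 4, radius_end = 6)),
    target_intensity = 810,
    noise_components = list(c(148, 10, 0.4), c(187, 15, 0.4), c(228, 60, 0.24)),
    seed = seed
  ))

  # Phantom II: 3x3 grid of tubes along z, radii spanning 1.5-6 voxels,
  # alternating straight and gently curved centerlines
  centres <- expand.grid(x = c(60, 120, 180), y = c(60, 120, 180))
  radii <- list(c(1.5, 3.5), c(2, 4), c(2.5, 4.5),
                c(3, 5), c(3.5, 5.5), c(4, 6),
                c(4.5, 6), c(2, 5), c(3, 6))
  zs <- seq(12, 228, length.out = 9)
  tubes2 <- vector("list", 9L)
  for (k in 1:9) {
    bend <- if (k %% 2 == 0) 10 else 0 # even tubes curve, odd are straight
    phase <- k * pi / 4
    pts <- cbind(centres$x[k] + bend * sin(2 * pi * (zs - 12) / 216 + phase),
                 centres$y[k] + bend * cos(2 * pi * (zs - 12) / 216 + phase),
                 zs)
    tubes2[[k]] <- list(points = pts, radius_start = radii[[k]][1],
                        radius_end = radii[[k]][2])
  }
  spec2 <- suppressWarnings(phantom_spec(
    dims = c(240, 240, 240),
    tubes = tubes2,
    target_intensity = 650,
    noise_components = list(c(148, 10, 0.5), c(187, 15, 0.3)),
    seed = seed
  ))

  list(phantom_I = spec1, phantom_II = spec2)
}
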