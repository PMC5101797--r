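#' Pipeline configuration
#'
#' Collects every tunable of the segmentation pipeline with its default:
#' vesselness filter sensitivities and scales, histogram resolution and
#' smoothing, EM controls, MRF/ICM controls, and the seed used by any
#' randomized step. Unknown keys are rejected by name, so a typo in a config
#' file fails loudly rather than silently using a default.
#'
#' @param vesselness list: `alpha` (0.5), `beta` (0.5), `c` ("auto"),
#'   `scales` (0.5 plus 1 to 4 by 0.5 voxels).
#' @param histogram list: `n_bins` (1024), `smoothing_window` (11 bins).
#' @param em list: `tol` (1e-6), `max_iter` (500), `mode` ("histogram" for
#'   bin-weighted EM, "voxel" for exact per-voxel EM).
#' @param mrf list: `beta_sr` (1), `max_icm_iter` (20), `convergence_frac`
#'   (1e-4).
#' @param seed integer seed (0).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(vesselness = list(), histogram = list(),
                            em = list(), mrf = list(), seed = 0L) {
  defaults <- list(
    vesselness = list(alpha = 0.5, beta = 0.5, c = "auto",
                      scales = c(0.5, seq(1, 4, by = 0.5))),
    histogram = list(n_bins = 1024L, smoothing_window = 11L),
    em = list(tol = 1e-6, max_iter = 500L, mode = "histogram"),
    mrf = list(beta_sr = 1.0, max_icm_iter = 20L, convergence_frac = 1e-4)
  )
  merge_section <- function(name, user) {
    def <- defaults[[name]]
    if (!is.list(user))
      stop(sprintf("pipeline_config: `%s` must be a list", name), call. = FALSE)
    unknown <- setdiff(names(user), names(def))
    if (length(unknown) > 0)
      stop(sprintf("pipeline_config: unknown key%s in `%s`: %s",
                   if (length(unknown) > 1) "s" else "", name,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    modifyList(def, user)
  }
  cfg <- list(vesselness = merge_section("vesselness", vesselness),
              histogram = merge_section("histogram", histogram),
              em = merge_section("em", em),
              mrf = merge_section("mrf", mrf),
              seed = as.integer(seed))
  if (!cfg$em$mode %in% c("histogram", "voxel"))
    stop("pipeline_config: em$mode must be \"histogram\" or \"voxel\"",
         call. = FALSE)
  # construct the parameter objects now so invalid values fail here
  vp <- do.call(vesselness_params, cfg$vesselness)
  mp <- do.call(mrf_params, cfg$mrf)
  cfg$vesselness <- vp
  cfg$mrf <- mp
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may define any subset of the `pipeline_config()` sections;
#' everything else keeps its default. Unknown keys are an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_config: file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop(sprintf("read_config: unsupported config format: .%s", ext),
         call. = FALSE))
  if (is.null(raw)) raw <- list()
  known <- c("vesselness", "histogram", "em", "mrf", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop(sprintf("read_config: unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(pipeline_config, raw)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("^\\[", msg)) stop(e) # already tagged by an inner stage
    stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
  })
}

#' Segment a volume end-to-end
#'
#' Runs the full pipeline on a raw volume: multi-scale vesselness filtering,
#' intensity-range restoration, histogram construction and peak detection,
#' peak-seeded K-means, EM fitting of the Exp+Exp+Gauss mixture, MAP
#' classification, and ICM refinement under the MRF prior. Errors are tagged
#' with the stage that raised them.
#'
#' @param vol a [volume3d()], 3D array, or path readable by [read_volume()].
#' @param config a [pipeline_config()].
#' @return An object of class `vessel_segmentation`: `labels` (a
#'   [label_volume()]) and `report` (resolved `c`, detected peaks, K-means
#'   summary, fitted mixture with EM trace, ICM diagnostics, stage timings).
#' @export
segment <- function(vol, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(vol)) vol <- read_volume(vol)
  vol <- as_vol3d(vol)
  times <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  filtered <- with_stage("vesselness",
                         vesselness_multiscale(vol, config$vesselness))
  c_used <- attr(filtered, "c")
  times["vesselness"] <- tic() - t0; t0 <- tic()

  rescaled <- with_stage("rescale", rescale_filtered(filtered, vol))
  rm(filtered)
  h <- with_stage("histogram",
                  build_histogram(rescaled, config$histogram$n_bins))
  peaks <- with_stage("peaks",
                      detect_peaks(h, config$histogram$smoothing_window))
  km <- with_stage("kmeans_init", kmeans_init(rescaled, peaks))
  init <- with_stage("em_init", em_init_from_kmeans(km))
  fit_input <- if (config$em$mode == "histogram") h else rescaled
  fit <- with_stage("em_fit",
                    em_fit(fit_input, init, config$em$tol, config$em$max_iter))
  times["mixture"] <- tic() - t0; t0 <- tic()

  model <- mixture_model(fit$lambda1, fit$lambda2, fit$mu_g, fit$sigma_g, fit$w)
  labels0 <- with_stage("map_classify", map_classify(rescaled, model))
  labels <- with_stage("icm", icm_refine(rescaled, model, labels0, config$mrf))
  times["labeling"] <- tic() - t0

  report <- list(
    c = c_used,
    scales = config$vesselness$scales,
    alpha = config$vesselness$alpha,
    beta = config$vesselness$beta,
    peaks = peaks,
    kmeans = list(mu = km$mu, sigma = km$sigma, w = km$w),
    mixture = list(lambda1 = fit$lambda1, lambda2 = fit$lambda2,
                   mu_g = fit$mu_g, sigma_g = fit$sigma_g, w = fit$w),
    em = list(loglik = fit$loglik, n_iter = fit$n_iter,
              converged = fit$converged, mode = config$em$mode),
    icm = attr(labels, "icm"),
    map_vessel_voxels = sum(labels0$data),
    vessel_voxels = sum(labels$data),
    timings_sec = as.list(times)
  )
  structure(list(labels = labels, report = report, histogram = h),
            class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "<vessel_segmentation> %s voxels, %d labeled vessel (%.3f%%)\n",
    "  c = %.4g; EM %d iter (%s); ICM %d sweep(s)\n"),
    paste(dim(x$labels$data), collapse = "x"),
    r$vessel_voxels,
    100 * r$vessel_voxels / prod(dim(x$labels$data)),
    r$c, r$em$n_iter,
    if (r$em$converged) "converged" else "max_iter", r$icm$sweeps))
  invisible(x)
}

#' Run the pipeline with outputs on disk
#'
#' Resolves the input (an image path, a phantom preset name `"phantom_I"` /
#' `"phantom_II"`, or a [phantom_spec()]), segments it, and writes the label
#' volume plus an optional JSON report, mixture fit-curve plot, and Z-axis
#' projection image. When the input is a phantom, the labels are also scored
#' against its ground truth and the scores included in the report. Identical
#' config + seed + input give identical outputs.
#'
#' @param input path, preset name, [phantom_spec()], or [volume3d()].
#' @param output_path where to write the label volume (`.nii`, `.nii.gz`,
#'   `.mha`, `.mhd`); `NULL` to skip.
#' @param config a [pipeline_config()]; its `seed` seeds phantom generation
#'   when `input` is a preset name.
#' @param report_path optional JSON report path.
#' @param plot_path optional PNG path for the histogram/fit plot.
#' @param projection_path optional PNG path for the label MIP.
#' @param quiet suppress progress messages.
#' @return The `vessel_segmentation`, invisibly; if the input was a phantom,
#'   a `scores` element is attached.
#' @export
run_pipeline <- function(input, output_path = NULL,
                         config = pipeline_config(), report_path = NULL,
                         plot_path = NULL, projection_path = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  truth <- NULL
  if (is.character(input) && input %in% c("phantom_I", "phantom_II")) {
    say("generating preset %s (seed %d)", input, config$seed)
    spec <- phantom_presets(seed = config$seed)[[input]]
    ph <- build_phantom(spec)
    vol <- ph$volume
    truth <- ph$truth
  } else if (inherits(input, "phantom_spec")) {
    say("generating phantom from spec (seed %d)", input$seed)
    ph <- build_phantom(input)
    vol <- ph$volume
    truth <- ph$truth
  } else if (is.character(input)) {
    say("reading %s", input)
    vol <- read_volume(input)
  } else {
    vol <- as_vol3d(input)
  }

  say("segmenting %s volume (alpha=%.2g beta=%.2g, %d scales, beta_sr=%.2g)",
      paste(dim(vol), collapse = "x"),
      config$vesselness$alpha, config$vesselness$beta,
      length(config$vesselness$scales), config$mrf$beta_sr)
  res <- segment(vol, config)
  say("done: %d vessel voxels; stages (s): %s",
      res$report$vessel_voxels,
      paste(sprintf("%s=%.1f", names(res$report$timings_sec),
                    unlist(res$report$timings_sec)), collapse = " "))

  if (!is.null(truth)) {
    sc <- score(res$labels, truth)
    res$scores <- sc
    res$report$scores <- list(error_ratio = sc$error_ratio, dsc = sc$dsc,
                              n_over = sc$n_over, n_under = sc$n_under)
    say("vs ground truth: error ratio %.4f%%, DSC %.2f%%",
        sc$error_ratio, sc$dsc)
  }

  if (!is.null(output_path)) {
    write_volume(res$labels, output_path)
    say("labels written to %s", output_path)
  }
  if (!is.null(report_path)) {
    jsonlite::write_json(res$report, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("report written to %s", report_path)
  }
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 900, height = 600)
    plot_mixture_fit(res$histogram,
                     do.call(mixture_model, res$report$mixture))
    grDevices::dev.off()
  }
  if (!is.null(projection_path)) {
    grDevices::png(projection_path, width = 600, height = 600)
    plot_z_projection(res$labels, mode = "max")
    grDevices::dev.off()
  }
  invisible(res)
}
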