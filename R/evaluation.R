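#' Score a segmentation against ground truth
#'
#' Computes over-/under-segmentation counts, the segmentation error ratio
#' `100 * (N_over + N_under) / N_total` (misclassified voxels as a
#' percentage of the volume) and the Dice similarity coefficient
#' `100 * 2 |S_g intersect S_m| / (|S_g| + |S_m|)`. When both the truth and
#' the prediction are empty the DSC is defined as 100.
#'
#' @param pred predicted [label_volume()] (or 0/1 array).
#' @param truth ground-truth [label_volume()] (or 0/1 array).
#' @return An object of class `seg_scores`: `n_total`, `n_over`, `n_under`,
#'   `error_ratio` (%), `dsc` (%).
#' @export
score <- function(pred, truth) {
  p <- as_vol3d(pred)$data
  g <- as_vol3d(truth)$data
  if (!identical(dim(p), dim(g)))
    stop("score: prediction and truth dimensions differ", call. = FALSE)
  p <- p != 0
  g <- g != 0
  n_total <- length(p)
  n_over <- sum(p & !g)
  n_under <- sum(!p & g)
  inter <- sum(p & g)
  sizes <- sum(p) + sum(g)
  dsc <- if (sizes == 0) 100 else 100 * 2 * inter / sizes
  structure(list(n_total = n_total, n_over = n_over, n_under = n_under,
                 error_ratio = 100 * (n_over + n_under) / n_total,
                 dsc = dsc),
            class = "seg_scores")
}

#' @export
print.seg_scores <- function(x, ...) {
  cat(sprintf(paste0(
    "<seg_scores> %d voxels\n",
    "  over-segmented:  %d\n  under-segmented: %d\n",
    "  error ratio: %.4f%%\n  DSC: %.2f%%\n"),
    x$n_total, x$n_over, x$n_under, x$error_ratio, x$dsc))
  invisible(x)
}
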