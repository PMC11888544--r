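## Quantitative evaluation: CNR between lesion and fibroglandular ROIs,
## background noise from consecutive-frame subtraction, and enhancement-curve
## similarity (Pearson r + Euclidean norm of peak-normalized curves).
## All metrics operate on magnitudes, so they are invariant to a global
## complex phase of the series.

#' ROI set for CNR and noise estimation
#'
#' @param lesion logical H x W lesion mask
#' @param fibroglandular logical H x W fibroglandular mask
#' @param background list of background rectangles, each
#'   `c(row0, row1, col0, col1)` (1-based inclusive), lying outside the object
#' @return object of class `roi_set`
#' @export
roi_set <- function(lesion, fibroglandular, background) {
  if (!any(lesion) || !any(fibroglandular))
    stop_invalid("lesion and fibroglandular masks must be non-empty")
  if (any(lesion & fibroglandular))
    stop_invalid("lesion and fibroglandular masks must be disjoint")
  if (length(background) < 1L) stop_invalid("need at least one background ROI")
  structure(list(lesion = lesion, fibroglandular = fibroglandular,
                 background = background),
            class = "roi_set")
}

#' Default ROI set from a tissue label map
#'
#' Lesion and fibroglandular masks come from the labels; background
#' rectangles are placed greedily in pure-background areas near the image
#' corners and lower edge.
#'
#' @param partition a `region_partition` label map with the six DRO tissues
#' @param n_background number of background rectangles (default 6)
#' @param size rectangle side (pixels, default ~8% of image height)
#' @return an [roi_set]
#' @export
default_rois <- function(partition, n_background = 6L, size = NULL) {
  lab <- partition$label_map
  if (is.null(lab)) stop_invalid("default_rois needs a label-map partition")
  H <- nrow(lab); W <- ncol(lab)
  if (is.null(size)) size <- max(4L, round(0.08 * H))
  lesion <- lab == 1L
  fibro <- lab == 2L
  bg <- lab == 0L
  ## candidate anchors: corners, mid-edges, scanning inward
  anchors <- list(c(2, 2), c(2, W - size - 1), c(H - size - 1, 2),
                  c(H - size - 1, W - size - 1),
                  c(2, round(W / 2)), c(round(H * 0.45), 2),
                  c(round(H * 0.45), W - size - 1),
                  c(round(H * 0.65), 2), c(round(H * 0.65), W - size - 1))
  rects <- list()
  for (a in anchors) {
    if (length(rects) >= n_background) break
    r0 <- a[1]; c0 <- a[2]
    r1 <- r0 + size - 1L; c1 <- c0 + size - 1L
    if (r1 > H || c1 > W) next
    if (all(bg[r0:r1, c0:c1])) rects[[length(rects) + 1L]] <- c(r0, r1, c0, c1)
  }
  if (length(rects) < 1L) stop_invalid("could not place background ROIs")
  roi_set(lesion, fibro, rects)
}

#' Background noise from consecutive-frame subtraction
#'
#' For each consecutive post-injection frame pair, takes the difference
#' image; the noise SD is the standard deviation of the difference values
#' pooled over all background ROIs and pairs, divided by `sqrt(2)` (the
#' difference of two i.i.d. noise fields has twice the variance).
#'
#' @param series a [dynamic_series]
#' @param rois an [roi_set]
#' @param frame_range indices of post-injection frames (>= 2 frames)
#' @return noise SD (same units as the series)
#' @export
background_noise <- function(series, rois, frame_range = NULL) {
  x <- series$data
  if (is.complex(x)) x <- Mod(x)
  T <- dim(x)[3L]
  if (is.null(frame_range)) frame_range <- seq_len(T)
  if (length(frame_range) < 2L)
    stop_invalid("background_noise needs >= 2 frames")
  vals <- c()
  for (j in seq_len(length(frame_range) - 1L)) {
    d <- x[, , frame_range[j + 1L]] - x[, , frame_range[j]]
    for (r in rois$background)
      vals <- c(vals, as.vector(d[r[1]:r[2], r[3]:r[4]]))
  }
  stats::sd(vals) / sqrt(2)
}

#' Contrast-to-noise ratio
#'
#' `CNR = |mean_lesion - mean_fibroglandular| / noise_sd` at a chosen frame.
#'
#' @param series a [dynamic_series]
#' @param rois an [roi_set]
#' @param frame frame index (default: the peak-lesion-enhancement frame)
#' @param noise_sd background noise SD (> 0), e.g. from [background_noise]
#' @return CNR (unitless); the frame used is attached as attribute `frame`
#' @export
cnr <- function(series, rois, frame = NULL, noise_sd) {
  check_number(noise_sd, "noise_sd", lower = .Machine$double.xmin)
  x <- Mod(series$data)
  if (is.null(frame)) {
    lesion_course <- apply(x, 3L, function(fr) mean(fr[rois$lesion]))
    frame <- which.max(lesion_course)
  }
  fr <- x[, , frame]
  out <- abs(mean(fr[rois$lesion]) - mean(fr[rois$fibroglandular])) / noise_sd
  attr(out, "frame") <- frame
  out
}

#' Enhancement-curve similarity
#'
#' Pearson correlation of the raw curves and the Euclidean norm of their
#' difference after each curve is normalized to unit peak (so the norm
#' compares shape, not scale). A constant curve has undefined correlation,
#' reported as `NA`.
#'
#' @param curve_a,curve_b numeric vectors of equal length >= 3
#' @return named vector `c(pearson_r, euclid_norm)`
#' @export
curve_similarity <- function(curve_a, curve_b) {
  if (length(curve_a) != length(curve_b) || length(curve_a) < 3L)
    stop_invalid("curves must have equal length >= 3")
  r <- if (stats::sd(curve_a) == 0 || stats::sd(curve_b) == 0) NA_real_
       else stats::cor(curve_a, curve_b)
  na <- curve_a / max(abs(curve_a), .Machine$double.xmin)
  nb <- curve_b / max(abs(curve_b), .Machine$double.xmin)
  c(pearson_r = r, euclid_norm = sqrt(sum((na - nb)^2)))
}

#' Metrics report for one reconstruction
#'
#' @param series a [dynamic_series]
#' @param rois an [roi_set]
#' @param method method name
#' @param frame_range post-injection frames for the noise estimate
#' @return object of class `metrics_report` with `cnr`, `noise_sd`, `frame`
#' @export
metrics_report <- function(series, rois, method = "method", frame_range = NULL) {
  ns <- background_noise(series, rois, frame_range)
  cn <- cnr(series, rois, noise_sd = ns)
  structure(list(method = method, cnr = as.numeric(cn), noise_sd = ns,
                 frame = attr(cn, "frame")),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%s: CNR = %.3f (frame %d), background noise SD = %.4g\n",
              x$method, x$cnr, x$frame, x$noise_sd))
  invisible(x)
}

#' Fold changes of CNR and noise against a reference method
#'
#' Each method's CNR (and inverse noise) divided by the reference method's;
#' `fold(a vs b) * fold(b vs a) = 1` by construction.
#'
#' @param reports list of [metrics_report] objects
#' @param reference_method name of the reference (e.g. `"nufft"`)
#' @return data.frame with columns method, cnr, noise_sd, cnr_fold,
#'   noise_reduction_fold
#' @export
fold_change <- function(reports, reference_method) {
  methods <- vapply(reports, function(r) r$method, character(1))
  if (!(reference_method %in% methods))
    stop_invalid("reference method '%s' not among reports", reference_method)
  ref <- reports[[match(reference_method, methods)]]
  data.frame(
    method = methods,
    cnr = vapply(reports, function(r) r$cnr, numeric(1)),
    noise_sd = vapply(reports, function(r) r$noise_sd, numeric(1)),
    cnr_fold = vapply(reports, function(r)
      if (ref$cnr == 0) NA_real_ else r$cnr / ref$cnr, numeric(1)),
    noise_reduction_fold = vapply(reports, function(r)
      if (r$noise_sd == 0) NA_real_ else ref$noise_sd / r$noise_sd, numeric(1))
  )
}
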