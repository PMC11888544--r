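## Synthetic breast digital reference object (DRO).
##
## A 2D slice with six tissue classes (background, lesion, fibroglandular,
## pectoral muscle, skin, heart), per-tissue contrast kinetics driven by the
## two-compartment exchange model with tissue-specific rise times, and smooth
## complex coil sensitivities. Everything is deterministic under a fixed seed.

DRO_TISSUES <- c("background", "lesion", "fibroglandular", "muscle", "skin", "heart")

#' Region partition container
#'
#' Either a disjoint, exhaustive label map (tissue-segment mode) or a list of
#' possibly overlapping pixel-index sets (block mode).
#'
#' @param label_map integer matrix (H x W) with values `0..n-1`, or `NULL` in
#'   block mode
#' @param region_names character vector of region names
#' @param block_index_sets list of integer pixel-index vectors (block mode)
#' @param dim image dimensions `c(H, W)` (required in block mode)
#' @return object of class `region_partition`
#' @export
region_partition <- function(label_map = NULL, region_names = NULL,
                             block_index_sets = NULL, dim = NULL) {
  if (is.null(label_map) == is.null(block_index_sets))
    stop_invalid("provide exactly one of label_map or block_index_sets")
  if (!is.null(label_map)) {
    label_map <- as.matrix(label_map)
    labs <- sort(unique(as.integer(label_map)))
    n <- length(labs)
    if (!identical(labs, 0:(n - 1L)))
      stop_invalid("label_map values must be contiguous 0..n-1")
    if (is.null(region_names)) region_names <- paste0("region", labs)
    if (length(region_names) != n)
      stop_invalid("region_names length (%d) != number of labels (%d)",
                   length(region_names), n)
    structure(list(label_map = label_map, region_names = region_names,
                   is_blocks = FALSE, block_index_sets = NULL,
                   dim = dim(label_map)),
              class = "region_partition")
  } else {
    if (is.null(dim)) stop_invalid("block mode requires 'dim'")
    npix <- prod(dim)
    covered <- rep(FALSE, npix)
    for (s in block_index_sets) covered[s] <- TRUE
    if (!all(covered)) stop_invalid("every pixel must belong to >= 1 block")
    if (is.null(region_names))
      region_names <- paste0("block", seq_along(block_index_sets))
    structure(list(label_map = NULL, region_names = region_names,
                   is_blocks = TRUE, block_index_sets = block_index_sets,
                   dim = as.integer(dim)),
              class = "region_partition")
  }
}

#' @export
print.region_partition <- function(x, ...) {
  if (x$is_blocks)
    cat(sprintf("Block partition: %d blocks on a %dx%d grid\n",
                length(x$block_index_sets), x$dim[1], x$dim[2]))
  else
    cat(sprintf("Label partition: %d regions on a %dx%d grid (%s)\n",
                length(x$region_names), x$dim[1], x$dim[2],
                paste(x$region_names, collapse = ", ")))
  invisible(x)
}

## pixel index sets per region, in a fixed order
partition_indices <- function(partition) {
  if (partition$is_blocks) return(partition$block_index_sets)
  lapply(seq_along(partition$region_names) - 1L,
         function(l) which(as.integer(partition$label_map) == l))
}

## ellipse mask helper: centre (cy, cx), semi-axes (ay, ax), rotation radians
ellipse_mask <- function(H, W, cy, cx, ay, ax, theta = 0) {
  y <- matrix(seq_len(H), H, W) - cy
  x <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- cos(theta) * y + sin(theta) * x
  v <- -sin(theta) * y + cos(theta) * x
  (u / ay)^2 + (v / ax)^2 <= 1
}

#' Six-region breast slice label map
#'
#' Draws a stylized axial breast slice: background (0), an ellipsoidal lesion
#' (1) embedded in the fibroglandular interior (2), a posterior pectoral
#' muscle band (3), a thin skin rim (4) along the anterior breast contour, and
#' a small heart disc (5) behind the muscle. Geometry constants are fixed
#' relative to the grid; the seed jitters the lesion position inside the
#' fibroglandular tissue, deterministically.
#'
#' @param height,width grid size in pixels (>= 32)
#' @param seed integer seed for the lesion-position jitter
#' @return a `region_partition` in label-map mode with the six tissue names
#' @export
make_label_map <- function(height, width, seed = 0L) {
  height <- check_count(height, "height"); width <- check_count(width, "width")
  if (height < 32L || width < 32L)
    stop_invalid("label map dimensions must be >= 32, got %dx%d", height, width)
  H <- height; W <- width
  lab <- matrix(0L, H, W)

  ## breast: anterior (top) half-ellipse occupying ~65% of rows
  breast <- ellipse_mask(H, W, cy = 0.15 * H, cx = 0.5 * W,
                         ay = 0.55 * H, ax = 0.42 * W)
  ## skin: rim of the breast = breast minus its erosion (smaller ellipse)
  inner <- ellipse_mask(H, W, cy = 0.15 * H, cx = 0.5 * W,
                        ay = 0.55 * H - max(2, 0.02 * H),
                        ax = 0.42 * W - max(2, 0.02 * W))
  lab[breast] <- 4L            # skin rim (overwritten inside)
  lab[breast & inner] <- 2L    # fibroglandular interior

  ## posterior muscle band
  band <- matrix(FALSE, H, W)
  band[(round(0.78 * H)):(round(0.90 * H)), (round(0.18 * W)):(round(0.82 * W))] <- TRUE
  lab[band] <- 3L

  ## heart: small disc behind the muscle band
  heart <- ellipse_mask(H, W, cy = 0.95 * H, cx = 0.38 * W,
                        ay = 0.07 * H, ax = 0.09 * W)
  lab[heart] <- 5L

  ## lesion: ellipse inside the fibroglandular tissue, jittered by seed
  jit <- with_seed(seed, stats::runif(3, -1, 1))
  cy <- (0.32 + 0.06 * jit[1]) * H
  cx <- (0.50 + 0.10 * jit[2]) * W
  th <- jit[3] * pi / 4
  lesion <- ellipse_mask(H, W, cy, cx, ay = 0.06 * H, ax = 0.045 * W, theta = th)
  lesion <- lesion & (lab == 2L)   # keep the lesion strictly fibroglandular
  lab[lesion] <- 1L

  region_partition(lab, DRO_TISSUES)
}

#' Default per-tissue rise-time dictionary
#'
#' Plausible wash-in time ranges (seconds) per tissue: the blood-pool heart is
#' fastest, lesions enhance faster than fibroglandular tissue, and muscle and
#' skin are slowest. Ranges are package defaults for simulation/augmentation.
#'
#' @return named list of `c(low, high)` ranges in seconds
#' @export
default_rise_dictionary <- function() {
  list(lesion = c(15, 40), fibroglandular = c(40, 90), muscle = c(60, 120),
       skin = c(60, 120), heart = c(5, 15))
}

#' Sample tissue rise times from a dictionary
#'
#' One uniform draw per tissue within its range; reproducible for a fixed
#' seed. Tissues absent from the dictionary (e.g. background) are skipped.
#'
#' @param tissue_names character vector of tissue names
#' @param dictionary named list of `c(low, high)` second ranges
#' @param seed integer seed
#' @return named numeric vector of rise times (s)
#' @export
sample_rise_times <- function(tissue_names, dictionary = default_rise_dictionary(),
                              seed = 0L) {
  if (length(dictionary) == 0L) stop_invalid("rise-time dictionary is empty")
  for (nm in names(dictionary)) {
    rg <- dictionary[[nm]]
    if (length(rg) != 2L || rg[1] > rg[2] || any(rg <= 0))
      stop_invalid("invalid rise-time range for '%s'", nm)
  }
  keep <- tissue_names[tissue_names %in% names(dictionary)]
  with_seed(seed, {
    out <- vapply(keep, function(nm) {
      rg <- dictionary[[nm]]
      stats::runif(1, rg[1], rg[2])
    }, numeric(1))
    out
  })
}

#' Default tissue kinetics for the DRO
#'
#' Per-tissue baseline signal, enhancement amplitude and ground-truth 2CXM
#' parameters. The sampled rise time sets the plasma flow via the plasma
#' transit time `(vp + ve) / Fp = rise_time`, so faster-rising tissues have
#' proportionally higher flow. Background has zero baseline and enhancement.
#'
#' @param rise_times named vector from [sample_rise_times]
#' @return list of class `tissue_kinetics`: per-tissue `baseline`,
#'   `amplitude`, `rise_time` and [pkm_params] ground truth
#' @export
default_tissue_kinetics <- function(rise_times = sample_rise_times(DRO_TISSUES)) {
  base <- list(
    background     = list(baseline = 0.00, amplitude = 0.0, ve = 0,    vp = 0,    PS = 0),
    lesion         = list(baseline = 0.50, amplitude = 1.2, ve = 0.40, vp = 0.08, PS = 0.40),
    fibroglandular = list(baseline = 0.60, amplitude = 0.5, ve = 0.30, vp = 0.04, PS = 0.10),
    muscle         = list(baseline = 0.55, amplitude = 0.35, ve = 0.15, vp = 0.03, PS = 0.08),
    skin           = list(baseline = 0.45, amplitude = 0.40, ve = 0.25, vp = 0.04, PS = 0.08),
    heart          = list(baseline = 0.50, amplitude = 1.5, ve = 0.05, vp = 0.90, PS = 0.02)
  )
  out <- lapply(names(base), function(nm) {
    k <- base[[nm]]
    if (nm == "background") {
      k$rise_time <- NA_real_; k$params <- NULL
    } else {
      tau <- unname(rise_times[[nm]])
      if (is.null(tau) || is.na(tau)) tau <- 60
      k$rise_time <- tau
      Fp <- min(10, max(0.01, 60 * (k$vp + k$ve) / tau))
      k$params <- pkm_params(k$ve, k$vp, Fp, k$PS)
    }
    k
  })
  names(out) <- names(base)
  structure(out, class = "tissue_kinetics")
}

#' Smooth complex coil sensitivity maps
#'
#' Gaussian-lobe birdcage-style model: `n_coils` elements evenly spaced on a
#' circle around the FOV, each a smooth Gaussian magnitude profile with a
#' gentle linear phase. A single coil yields the identity map.
#'
#' @param height,width grid size in pixels
#' @param n_coils number of coils (>= 1)
#' @return complex array `n_coils x H x W` of class `coil_sensitivities`
#' @export
simulate_coils <- function(height, width, n_coils = 8L) {
  n_coils <- check_count(n_coils, "n_coils")
  H <- check_count(height, "height"); W <- check_count(width, "width")
  maps <- array(0i, c(n_coils, H, W))
  if (n_coils == 1L) {
    maps[1L, , ] <- 1 + 0i
  } else {
    y <- matrix(seq_len(H) / H - 0.5, H, W)
    x <- matrix(seq_len(W) / W - 0.5, H, W, byrow = TRUE)
    sigma <- 0.55
    for (c in seq_len(n_coils)) {
      th <- 2 * pi * (c - 1) / n_coils
      cy <- 0.75 * sin(th); cx <- 0.75 * cos(th)
      mag <- exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2))
      ph <- 2 * pi * 0.3 * (cos(th) * y + sin(th) * x) + th / 3
      maps[c, , ] <- mag * exp(1i * ph)
    }
    ## normalize so root-sum-of-squares is ~1 at centre
    rss0 <- sqrt(sum(Mod(maps[, round(H / 2), round(W / 2)])^2))
    maps <- maps / rss0
  }
  structure(maps, class = "coil_sensitivities")
}

#' Assemble a digital reference object
#'
#' @param height,width grid size (default 160; use 320 for high resolution)
#' @param n_coils number of receive coils
#' @param time_grid frame-centre times in seconds, strictly increasing
#' @param seed seed controlling geometry jitter, rise-time draws and
#'   intra-region heterogeneity
#' @param rise_dictionary per-tissue rise-time ranges
#' @param heterogeneity SD of the multiplicative Gaussian field on the
#'   enhancement amplitude (default 0.05), making region Casorati matrices
#'   rank > 1 so that multi-component subspaces are meaningful
#' @return object of class `dro_phantom`
#' @export
dro_phantom <- function(height = 160L, width = 160L, n_coils = 8L,
                        time_grid = seq(2.1, by = 4.2, length.out = 36),
                        seed = 0L,
                        rise_dictionary = default_rise_dictionary(),
                        heterogeneity = 0.05) {
  if (length(time_grid) < 2L || any(diff(time_grid) <= 0))
    stop_invalid("time_grid must be strictly increasing with >= 2 samples")
  partition <- make_label_map(height, width, seed = seed)
  rise <- sample_rise_times(DRO_TISSUES, rise_dictionary, seed = seed + 1L)
  kinetics <- default_tissue_kinetics(rise)
  coils <- simulate_coils(height, width, n_coils)
  structure(list(partition = partition, kinetics = kinetics, coils = coils,
                 time_grid = as.numeric(time_grid), seed = as.integer(seed),
                 heterogeneity = heterogeneity),
            class = "dro_phantom")
}

#' @export
print.dro_phantom <- function(x, ...) {
  cat(sprintf("DRO phantom: %dx%d, %d coils, %d frames (%.1f..%.1f s), seed %d\n",
              x$partition$dim[1], x$partition$dim[2], dim(x$coils)[1],
              length(x$time_grid), min(x$time_grid), max(x$time_grid), x$seed))
  invisible(x)
}

#' Dynamic image-series container
#'
#' @param data numeric or complex array `H x W x T`
#' @param frame_times frame-centre times (s), strictly increasing
#' @return object of class `dynamic_series`
#' @export
dynamic_series <- function(data, frame_times) {
  d <- dim(data)
  if (length(d) != 3L) stop_invalid("dynamic_series: data must be H x W x T")
  if (length(frame_times) != d[3L])
    stop_invalid("dynamic_series: %d frames but %d frame times", d[3L],
                 length(frame_times))
  if (d[3L] >= 2L && any(diff(frame_times) <= 0))
    stop_invalid("dynamic_series: frame_times must be strictly increasing")
  structure(list(data = data, frame_times = as.numeric(frame_times)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic series: %dx%d, %d frames, %s\n", d[1], d[2], d[3],
              if (is.complex(x$data)) "complex" else "real"))
  invisible(x)
}

#' Per-tissue normalized enhancement curves
#'
#' 2CXM tissue curves on the phantom time grid, scaled to unit peak.
#' @param phantom a [dro_phantom]
#' @param aif_in an [aif] covering the phantom time grid
#' @return matrix T x n_tissues (background column all zero)
#' @export
phantom_enhancement_curves <- function(phantom, aif_in) {
  tg <- phantom$time_grid
  if (min(aif_in$t) > min(tg) || max(aif_in$t) < max(tg))
    stop_invalid("AIF grid does not cover the phantom time grid")
  ## integrate on the AIF's native (fine) grid so the bolus shape is not
  ## lost to coarse frame spacing, then sample at the frame times
  curves <- sapply(names(phantom$kinetics), function(nm) {
    k <- phantom$kinetics[[nm]]
    if (is.null(k$params) || k$amplitude <= 0) return(rep(0, length(tg)))
    ct_full <- tcxm_forward(k$params, aif_in)$Ct
    ct <- stats::approx(aif_in$t, ct_full, xout = tg)$y
    pk <- max(ct)
    if (pk <= 0) rep(0, length(tg)) else ct / pk
  })
  colnames(curves) <- names(phantom$kinetics)
  curves
}

#' Render the ground-truth dynamic image series
#'
#' Frame `t` pixel value is `baseline * (1 + amplitude_px * e(t))` where
#' `e(t)` is the tissue's two-compartment exchange curve scaled to unit peak
#' and `amplitude_px` carries the optional intra-region heterogeneity field.
#' Background stays exactly zero. This is the coil-free magnitude object.
#'
#' @param phantom a [dro_phantom]
#' @param aif_in an [aif] covering the phantom time grid
#' @return a [dynamic_series] (real-valued `H x W x T`)
#' @export
generate_dynamic_phantom <- function(phantom, aif_in) {
  stopifnot(inherits(phantom, "dro_phantom"), inherits(aif_in, "aif"))
  H <- phantom$partition$dim[1]; W <- phantom$partition$dim[2]
  tg <- phantom$time_grid; T <- length(tg)
  curves <- phantom_enhancement_curves(phantom, aif_in)
  lab <- phantom$partition$label_map
  amp_field <- with_seed(phantom$seed + 2L, {
    f <- matrix(1 + phantom$heterogeneity * stats::rnorm(H * W), H, W)
    pmax(f, 0)
  })
  out <- array(0, c(H, W, T))
  for (j in seq_along(DRO_TISSUES)) {
    nm <- DRO_TISSUES[j]
    k <- phantom$kinetics[[nm]]
    idx <- which(lab == (j - 1L))
    if (length(idx) == 0L || k$baseline <= 0) next
    amp <- k$amplitude * amp_field[idx]
    for (t in seq_len(T))
      out[, , t][idx] <- k$baseline * (1 + amp * curves[t, nm])
  }
  dynamic_series(out, tg)
}
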