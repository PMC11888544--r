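## Golden-angle radial trajectory, frame binning, density compensation and
## the multi-coil dynamic encoding operator E = sqrt(w) Phi F C together with
## its exact adjoint.
##
## Conventions (used everywhere): k-space coordinates are normalized
## frequencies in cycles/FOV, range [-0.5, 0.5); image pixel (1,1) sits at the
## array corner and DC at the image centre pixel (0-based N/2); indexing of
## spokes and frames is 1-based on the R side.

GOLDEN_ANGLE_DEG <- 111.246

#' Golden-angle radial trajectory
#'
#' Spoke `i` (0-based) has angle `(i * 111.246 deg) mod 180 deg`; each spoke's
#' readout samples span the k-space diameter uniformly through the origin.
#'
#' @param n_spokes number of spokes (>= 1)
#' @param n_readout samples per spoke (even, >= 2)
#' @return object of class `radial_trajectory` with `angles` (radians) and
#'   `coords` (`n_spokes * n_readout` x 2, cycles/FOV)
#' @export
golden_angle_trajectory <- function(n_spokes, n_readout) {
  n_spokes <- check_count(n_spokes, "n_spokes")
  n_readout <- check_count(n_readout, "n_readout", lower = 2)
  if (n_readout %% 2L != 0L) stop_invalid("n_readout must be even")
  ga <- GOLDEN_ANGLE_DEG * pi / 180
  angles <- ((seq_len(n_spokes) - 1L) * ga) %% pi
  radius <- (seq_len(n_readout) - 1L - n_readout %/% 2L) / n_readout
  ## coords[(spoke, readout), ]: row = readout fastest
  kr <- outer(radius, cos(angles))   # column direction (x)
  ky <- outer(radius, sin(angles))   # row direction (y)
  coords <- cbind(as.vector(ky), as.vector(kr))
  structure(list(n_spokes = n_spokes, n_readout = n_readout,
                 angles = angles, coords = coords),
            class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf("Golden-angle radial trajectory: %d spokes x %d readout samples\n",
              x$n_spokes, x$n_readout))
  invisible(x)
}

## index rows of traj$coords belonging to spoke s (1-based)
spoke_rows <- function(traj, s) (s - 1L) * traj$n_readout + seq_len(traj$n_readout)

#' Sequential frame binning of spokes
#'
#' Groups consecutive spokes into frames of `spokes_per_frame`; trailing
#' spokes that do not fill a frame are discarded (`NA` assignment).
#'
#' @param n_spokes total spokes
#' @param spokes_per_frame spokes per frame (1..n_spokes)
#' @return integer vector of frame indices per spoke (`NA` = unused)
#' @export
bin_spokes <- function(n_spokes, spokes_per_frame) {
  n_spokes <- check_count(n_spokes, "n_spokes")
  spokes_per_frame <- check_count(spokes_per_frame, "spokes_per_frame")
  if (spokes_per_frame > n_spokes)
    stop_invalid("spokes_per_frame (%d) exceeds n_spokes (%d)",
                 spokes_per_frame, n_spokes)
  n_frames <- n_spokes %/% spokes_per_frame
  f <- rep(NA_integer_, n_spokes)
  used <- seq_len(n_frames * spokes_per_frame)
  f[used] <- rep(seq_len(n_frames), each = spokes_per_frame)
  f
}

#' Temporal resolution of a binned acquisition
#'
#' @param scan_time total scan time (s)
#' @param n_spokes total spokes acquired
#' @param spokes_per_frame spokes per reconstructed frame
#' @return seconds per frame: `scan_time * spokes_per_frame / n_spokes`
#' @export
temporal_resolution <- function(scan_time, n_spokes, spokes_per_frame) {
  check_number(scan_time, "scan_time", 1e-12)
  check_count(n_spokes, "n_spokes")
  check_count(spokes_per_frame, "spokes_per_frame")
  scan_time * spokes_per_frame / n_spokes
}

#' Ramp density compensation for radial sampling
#'
#' Weights proportional to the k-space radius (the radial area element
#' `|k| dk dtheta`), with the centre sample assigned the half-cell ramp value,
#' normalized to mean 1. The attribute `scale` holds the mean raw area weight
#' so that `weights * scale` is the calibrated Riemann measure used by the
#' density-compensated adjoint reconstruction.
#'
#' @param traj a [golden_angle_trajectory]
#' @return numeric vector of weights per (spoke, readout) sample, mean 1,
#'   with attribute `scale`
#' @export
density_compensation <- function(traj) {
  stopifnot(inherits(traj, "radial_trajectory"))
  dr <- 1 / traj$n_readout
  r <- sqrt(rowSums(traj$coords^2))
  ## every spoke passes through k = 0, so the DC cell (disk of radius dr/2)
  ## is shared by all spokes: the ramp value at dr/4 gives each centre
  ## sample exactly 1/n_spokes of the DC disk area
  r[r < dr / 2] <- dr / 4
  raw <- r * dr * (pi / traj$n_spokes)          # radial area element
  s <- mean(raw)
  structure(raw / s, scale = s)
}

#' Multi-coil radial k-space container
#'
#' @param data complex array `C x S x R` (coil x spoke x readout)
#' @param trajectory a [golden_angle_trajectory]
#' @param frame_of_spoke integer frame index per spoke (`NA` = unused)
#' @param weights density-compensation weights (recomputed if `NULL`)
#' @return object of class `multicoil_kspace`
#' @export
multicoil_kspace <- function(data, trajectory, frame_of_spoke, weights = NULL) {
  d <- dim(data)
  if (length(d) != 3L) stop_invalid("kspace data must be C x S x R")
  if (d[2L] != trajectory$n_spokes || d[3L] != trajectory$n_readout)
    stop_invalid("kspace data (%dx%d) does not match trajectory (%dx%d)",
                 d[2L], d[3L], trajectory$n_spokes, trajectory$n_readout)
  if (length(frame_of_spoke) != trajectory$n_spokes)
    stop_invalid("frame_of_spoke length mismatch")
  fv <- frame_of_spoke[!is.na(frame_of_spoke)]
  if (length(fv) && any(diff(fv) < 0))
    stop_invalid("frame_of_spoke must be non-decreasing")
  if (is.null(weights)) weights <- density_compensation(trajectory)
  if (any(weights <= 0)) stop_invalid("density weights must be positive")
  structure(list(data = data, trajectory = trajectory,
                 frame_of_spoke = as.integer(frame_of_spoke),
                 weights = weights),
            class = "multicoil_kspace")
}

#' @export
print.multicoil_kspace <- function(x, ...) {
  d <- dim(x$data)
  nf <- max(x$frame_of_spoke, na.rm = TRUE)
  cat(sprintf("Multi-coil k-space: %d coils, %d spokes x %d samples, %d frames\n",
              d[1], d[2], d[3], nf))
  invisible(x)
}

#' Encoding operator specification
#'
#' Bundles image geometry, coil maps, trajectory, frame binning and density
#' weights, and caches the per-frame sparse interpolation matrices of the
#' gridding NUFFT so repeated applications are cheap.
#'
#' @param img_dim image dimensions `c(H, W)`
#' @param coils [simulate_coils] output (or compatible `C x H x W` array)
#' @param traj a [golden_angle_trajectory]
#' @param frame_of_spoke frame assignment from [bin_spokes]
#' @param weights density weights (default: [density_compensation])
#' @param frame_times optional frame-centre times (s)
#' @return object of class `encoding_spec`
#' @export
encoding_spec <- function(img_dim, coils, traj, frame_of_spoke,
                          weights = density_compensation(traj),
                          frame_times = NULL) {
  img_dim <- as.integer(img_dim)
  cd <- dim(coils)
  if (length(cd) != 3L || cd[2L] != img_dim[1L] || cd[3L] != img_dim[2L])
    stop_invalid("coil maps (%s) do not match image size %dx%d",
                 paste(cd, collapse = "x"), img_dim[1L], img_dim[2L])
  frames <- sort(unique(frame_of_spoke[!is.na(frame_of_spoke)]))
  if (length(frames) == 0L) stop_invalid("no spokes assigned to any frame")
  n_frames <- max(frames)
  if (!identical(frames, seq_len(n_frames)))
    stop_invalid("every frame must contain at least one spoke")
  if (is.null(frame_times)) frame_times <- seq_len(n_frames)
  spec <- structure(list(img_dim = img_dim, coils = coils, traj = traj,
                         frame_of_spoke = as.integer(frame_of_spoke),
                         weights = weights, n_frames = n_frames,
                         frame_times = as.numeric(frame_times),
                         cache = new.env(parent = emptyenv())),
                    class = "encoding_spec")
  spec
}

#' @export
print.encoding_spec <- function(x, ...) {
  cat(sprintf("Encoding spec: %dx%d image, %d coils, %d frames (%d spokes/frame)\n",
              x$img_dim[1], x$img_dim[2], dim(x$coils)[1], x$n_frames,
              sum(x$frame_of_spoke == 1L, na.rm = TRUE)))
  invisible(x)
}

## rows of traj$coords (sample index within the flattened S*R layout,
## readout fastest) belonging to frame f
frame_sample_rows <- function(spec, f) {
  spokes <- which(!is.na(spec$frame_of_spoke) & spec$frame_of_spoke == f)
  as.vector(vapply(spokes, function(s) spoke_rows(spec$traj, s),
                   integer(spec$traj$n_readout)))
}

## cached per-frame interpolation matrix, apodization, sample rows, weights
spec_frame_data <- function(spec, f) {
  key <- paste0("frame", f)
  if (!is.null(spec$cache[[key]])) return(spec$cache[[key]])
  rows <- frame_sample_rows(spec, f)
  if (length(rows) == 0L) stop_invalid("frame %d has zero spokes", f)
  P <- nufft_interp_matrix(spec$traj$coords[rows, , drop = FALSE],
                           spec$img_dim[1L], spec$img_dim[2L])
  dat <- list(rows = rows, P = P, w = spec$weights[rows])
  spec$cache[[key]] <- dat
  dat
}

spec_apod <- function(spec) {
  if (is.null(spec$cache$apod))
    spec$cache$apod <- nufft_apodization(spec$img_dim[1L], spec$img_dim[2L])
  spec$cache$apod
}

## core linear map. weight_exp: exponent on the density weights applied to
## the samples (0 = raw physical samples, 0.5 = the operator E, 1 = full
## density-compensated adjoint). Returns C x S x R array.
encode_series <- function(spec, series_data, weight_exp = 0.5) {
  C <- dim(spec$coils)[1L]
  S <- spec$traj$n_spokes; R <- spec$traj$n_readout
  apod <- spec_apod(spec)
  out <- array(0i, c(C, S, R))
  flat <- array(0i, c(C, S * R))
  for (f in seq_len(spec$n_frames)) {
    fd <- spec_frame_data(spec, f)
    x <- series_data[, , f]
    stack <- array(0i, c(spec$img_dim[1L], spec$img_dim[2L], C))
    for (c in seq_len(C)) stack[, , c] <- x * spec$coils[c, , ]
    y <- nufft_apply_stack(stack, fd$P, apod)        # nsamp x C
    if (weight_exp != 0) y <- y * (fd$w ^ weight_exp)
    flat[, fd$rows] <- t(y)
  }
  dim(flat) <- c(C, R, S)   # flattened rows are readout-fastest: (R, S)
  aperm(flat, c(1L, 3L, 2L))
}

decode_series <- function(spec, ksp_data, weight_exp = 0.5) {
  C <- dim(spec$coils)[1L]
  H <- spec$img_dim[1L]; W <- spec$img_dim[2L]
  apod <- spec_apod(spec)
  flat <- aperm(ksp_data, c(1L, 3L, 2L))   # C x R x S
  dim(flat) <- c(C, spec$traj$n_spokes * spec$traj$n_readout)
  out <- array(0i, c(H, W, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    fd <- spec_frame_data(spec, f)
    y <- t(flat[, fd$rows, drop = FALSE])            # nsamp x C
    if (weight_exp != 0) y <- y * (fd$w ^ weight_exp)
    imgs <- nufft_adjoint_stack(y, fd$P, apod, H, W) # H x W x C
    acc <- matrix(0i, H, W)
    for (c in seq_len(C)) acc <- acc + Conj(spec$coils[c, , ]) * imgs[, , c]
    out[, , f] <- acc
  }
  out
}

#' Forward encoding operator E
#'
#' Per frame: coil weighting, gridding NUFFT onto that frame's spokes, and
#' `sqrt(w)` density scaling (so the adjoint pair is symmetric and
#' `<E x, y> = <x, E^H y>` holds exactly).
#'
#' @param spec an [encoding_spec]
#' @param series a [dynamic_series] (complex or real `H x W x T`)
#' @return a [multicoil_kspace] of `sqrt(w)`-weighted samples
#' @export
forward_op <- function(spec, series) {
  x <- series$data
  if (!is.complex(x)) x <- x + 0i
  d <- dim(x)
  if (d[1L] != spec$img_dim[1L] || d[2L] != spec$img_dim[2L] ||
      d[3L] != spec$n_frames)
    stop_invalid("series (%dx%dx%d) does not match encoding spec", d[1], d[2], d[3])
  multicoil_kspace(encode_series(spec, x, 0.5), spec$traj,
                   spec$frame_of_spoke, spec$weights)
}

#' Adjoint encoding operator E^H
#'
#' Exact conjugate transpose of [forward_op]: `sqrt(w)` scaling, transpose
#' gridding, conjugate coil combination.
#'
#' @param spec an [encoding_spec]
#' @param ksp a [multicoil_kspace] (in the `sqrt(w)`-weighted domain)
#' @return a [dynamic_series] (complex)
#' @export
adjoint_op <- function(spec, ksp) {
  dynamic_series(decode_series(spec, ksp$data, 0.5), spec$frame_times)
}

#' Simulate radial k-space from a dynamic object
#'
#' Unweighted forward model (raw physical samples) plus complex white
#' Gaussian noise of standard deviation `noise_sigma` per real/imaginary
#' channel; deterministic under a fixed seed.
#'
#' @param series ground-truth [dynamic_series]
#' @param spec an [encoding_spec] whose frame count matches the series
#' @param noise_sigma noise SD (>= 0), in units of the k-space samples
#' @param seed RNG seed
#' @return a [multicoil_kspace] of raw (unweighted) samples
#' @export
simulate_kspace <- function(series, spec, noise_sigma = 0, seed = 0L) {
  check_number(noise_sigma, "noise_sigma", 0)
  x <- series$data
  if (!is.complex(x)) x <- x + 0i
  y <- encode_series(spec, x, weight_exp = 0)
  if (noise_sigma > 0) {
    y <- y + with_seed(seed, {
      n <- length(y)
      array(complex(real = stats::rnorm(n, 0, noise_sigma),
                    imaginary = stats::rnorm(n, 0, noise_sigma)), dim(y))
    })
  }
  multicoil_kspace(y, spec$traj, spec$frame_of_spoke, spec$weights)
}

#' Low-resolution central k-space subset
#'
#' Retains, on every spoke, only readout samples with `|k| <= L / (2 N)`
#' (the densely sampled centre), rescales the trajectory to an `L x L` grid
#' and recomputes density weights.
#'
#' @param ksp a [multicoil_kspace] sampled for an `N x N` grid
#' @param L target grid size (even, `<= N`)
#' @param N original grid size (defaults to the readout length)
#' @return a [multicoil_kspace] for the `L x L` grid
#' @export
lowres_subset <- function(ksp, L, N = ksp$trajectory$n_readout) {
  L <- check_count(L, "L", lower = 2)
  if (L %% 2L != 0L) stop_invalid("L must be even")
  if (L > N) stop_invalid("L (%d) exceeds the grid size (%d)", L, N)
  traj <- ksp$trajectory
  radius <- (seq_len(traj$n_readout) - 1L - traj$n_readout %/% 2L) / traj$n_readout
  keep <- which(radius >= -L / (2 * N) - 1e-12 & radius < L / (2 * N) - 1e-12)
  newR <- length(keep)
  ## (L/N)^2 voxel-volume rescaling keeps the cropped samples consistent
  ## with the forward model of the Fourier-downsampled object on the L grid
  data <- ksp$data[, , keep, drop = FALSE] * (L / N)^2
  new_traj <- traj
  new_traj$n_readout <- newR
  sel <- as.vector(outer(keep, (seq_len(traj$n_spokes) - 1L) * traj$n_readout, "+"))
  new_traj$coords <- traj$coords[sel, , drop = FALSE] * (N / L)
  multicoil_kspace(data, new_traj, ksp$frame_of_spoke,
                   density_compensation(new_traj))
}

#' Downsample an encoding spec to a low-resolution grid
#'
#' Fourier-crops the coil maps to `L x L` and rebuilds the spec for the
#' trajectory of a [lowres_subset] k-space object.
#'
#' @param spec the full-resolution [encoding_spec]
#' @param ksp_low the output of [lowres_subset]
#' @param L the low-resolution grid size used in [lowres_subset]
#' @return an [encoding_spec] on the `L x L` grid
#' @export
lowres_spec <- function(spec, ksp_low, L) {
  L <- check_count(L, "L", lower = 2)
  C <- dim(spec$coils)[1L]
  coils <- array(0i, c(C, L, L))
  for (c in seq_len(C)) coils[c, , ] <- fourier_resize(spec$coils[c, , ], L)
  encoding_spec(c(L, L), coils, ksp_low$trajectory, ksp_low$frame_of_spoke,
                ksp_low$weights, spec$frame_times)
}
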