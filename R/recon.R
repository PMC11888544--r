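## Reconstruction algorithms.
##
## grasp_recon solves   argmin_M  1/2 ||y - E M||^2 + lambda ||S M||_1
## over the dynamic image-series M by nonlinear conjugate gradient with a
## smoothed l1 temporal total-variation penalty. subspace_recon solves the
## same problem over per-region subspace coefficients V with the temporal
## bases U fixed (M = sum_i U_i V_i), covering globally low-rank (one region),
## block-wise locally low-rank (overlapping blocks) and tissue-segment
## ('ELITE') modes. Bases are estimated by PCA (plain SVD of each region's
## Casorati matrix, no mean-centering) from a low-resolution reconstruction.

#' Reconstruction configuration
#'
#' @param lambda temporal TV regularization weight, relative to the peak
#'   magnitude of the initial (density-compensated adjoint) image; default 0.01
#' @param n_iter conjugate-gradient iterations per repetition (default 7)
#' @param n_repeat restarts of the CG loop (default 3)
#' @param K temporal subspace size per tissue region or block (default 6)
#' @param K_background components for the background region (default 1)
#' @param block_grid blocks per image dimension in block mode (default 10)
#' @param block_overlap fractional block overlap per side (default 0.5)
#' @return object of class `recon_config`
#' @export
recon_config <- function(lambda = 0.01, n_iter = 7L, n_repeat = 3L, K = 6L,
                         K_background = 1L, block_grid = 10L,
                         block_overlap = 0.5) {
  check_number(lambda, "lambda", 0)
  structure(list(lambda = lambda,
                 n_iter = check_count(n_iter, "n_iter"),
                 n_repeat = check_count(n_repeat, "n_repeat"),
                 K = check_count(K, "K"),
                 K_background = check_count(K_background, "K_background"),
                 block_grid = check_count(block_grid, "block_grid"),
                 block_overlap = check_number(block_overlap, "block_overlap", 0, 0.999)),
            class = "recon_config")
}

#' Temporal finite-difference operator S
#'
#' Forward difference along the time dimension (length `T - 1`).
#' @param x array `H x W x T` (or a [dynamic_series])
#' @return array `H x W x (T-1)` of frame differences
#' @export
temporal_tv <- function(x) {
  if (inherits(x, "dynamic_series")) x <- x$data
  T <- dim(x)[3L]
  if (T < 2L) stop_invalid("temporal TV needs at least 2 frames")
  x[, , 2:T, drop = FALSE] - x[, , 1:(T - 1L), drop = FALSE]
}

#' Adjoint of the temporal finite-difference operator
#'
#' Negative backward difference with the boundary handling that makes
#' `<S x, y> = <x, S^H y>` exact.
#' @param d array `H x W x (T-1)`
#' @return array `H x W x T`
#' @export
temporal_tv_adjoint <- function(d) {
  dd <- dim(d)
  T <- dd[3L] + 1L
  out <- array(if (is.complex(d)) 0i else 0, c(dd[1L], dd[2L], T))
  out[, , 1L] <- -d[, , 1L]
  if (T > 2L)
    out[, , 2:(T - 1L)] <- d[, , 1:(T - 2L), drop = FALSE] - d[, , 2:(T - 1L), drop = FALSE]
  out[, , T] <- d[, , T - 1L]
  out
}

## sqrt(w)-weighted data array with unused (unbinned) spokes zeroed
weighted_data <- function(spec, ksp, weight_exp = 0.5) {
  y <- ksp$data
  C <- dim(y)[1L]
  flat <- aperm(y, c(1L, 3L, 2L))
  dim(flat) <- c(C, spec$traj$n_spokes * spec$traj$n_readout)
  out <- array(0i, dim(flat))
  for (f in seq_len(spec$n_frames)) {
    fd <- spec_frame_data(spec, f)
    out[, fd$rows] <- flat[, fd$rows, drop = FALSE] *
      matrix(fd$w ^ weight_exp, C, length(fd$rows), byrow = TRUE)
  }
  dim(out) <- c(C, spec$traj$n_readout, spec$traj$n_spokes)
  aperm(out, c(1L, 3L, 2L))
}

#' Density-compensated adjoint (gridding) reconstruction
#'
#' The conventional NUFFT baseline: per-frame adjoint with full ramp density
#' compensation and either sensitivity-weighted or root-sum-of-squares coil
#' combination.
#'
#' @param ksp raw [multicoil_kspace] (e.g. from [simulate_kspace])
#' @param spec matching [encoding_spec]
#' @param combine `"sens"` (conjugate-sensitivity combination, default) or
#'   `"rss"`
#' @param magnitude return magnitude (default TRUE) or the complex series
#' @return a [dynamic_series]
#' @export
nufft_recon <- function(ksp, spec, combine = c("sens", "rss"),
                        magnitude = TRUE) {
  combine <- match.arg(combine)
  scale <- attr(spec$weights, "scale")
  if (is.null(scale)) scale <- 1
  ## the ramp measure is built for the full spoke set; a frame holding only
  ## S_f of the S spokes integrates the same disk with Delta-theta = pi/S_f,
  ## so each frame's adjoint is rescaled by S / S_f
  frame_factor <- vapply(seq_len(spec$n_frames), function(f)
    spec$traj$n_spokes / sum(spec$frame_of_spoke == f, na.rm = TRUE),
    numeric(1))
  if (combine == "sens") {
    out <- decode_series(spec, ksp$data, weight_exp = 1) * scale
    out <- sweep(out, 3L, frame_factor, "*")
    ss <- apply(Mod(spec$coils)^2, c(2L, 3L), sum)
    ss <- pmax(ss, 1e-6 * max(ss))
    out <- sweep(out, c(1L, 2L), ss, "/")
  } else {
    C <- dim(spec$coils)[1L]
    H <- spec$img_dim[1L]; W <- spec$img_dim[2L]
    acc <- array(0, c(H, W, spec$n_frames))
    spec1 <- spec
    for (c in seq_len(C)) {
      ones <- array(1 + 0i, c(1L, H, W))
      spec1 <- encoding_spec(spec$img_dim, ones, spec$traj,
                             spec$frame_of_spoke, spec$weights, spec$frame_times)
      spec1$cache <- spec$cache   # reuse interpolation matrices
      xc <- decode_series(spec1, ksp$data[c, , , drop = FALSE], weight_exp = 1) * scale
      xc <- sweep(xc, 3L, frame_factor, "*")
      acc <- acc + Mod(xc)^2
    }
    out <- sqrt(acc)
  }
  if (magnitude && is.complex(out)) out <- Mod(out)
  dynamic_series(out, spec$frame_times)
}

## Nonlinear conjugate gradient (Fletcher-Reeves) with backtracking line
## search over a linear forward model. fwd(x) must return list(dc, tv) of
## complex vectors, both linear in x; adj(rdc, rtv) the corresponding adjoint
## into x-space. Because both maps are linear, each iteration costs exactly
## one forward and one adjoint application.
nlcg_solve <- function(x0, fwd, adj, y, lambda, eps, n_iter, n_repeat,
                       ls_beta = 0.5, ls_max = 20L, ls_c = 1e-4) {
  pen <- function(tv) sum(sqrt(Mod(tv)^2 + eps^2))
  x <- x0
  Fx <- fwd(x)
  obj <- function(dc, tv) 0.5 * sum(Mod(dc - y)^2) + lambda * pen(tv)
  f <- obj(Fx$dc, Fx$tv)
  trace <- numeric(0)
  t_prev <- 1
  for (rep in seq_len(n_repeat)) {
    d <- NULL; g_old_nrm <- NULL
    for (it in seq_len(n_iter)) {
      u <- Fx$tv / sqrt(Mod(Fx$tv)^2 + eps^2)
      g <- adj(Fx$dc - y, lambda * u)
      g_nrm <- sum(Mod(g)^2)
      if (g_nrm < 1e-30) break
      if (is.null(d)) d <- -g
      else d <- -g + (g_nrm / g_old_nrm) * d
      g_old_nrm <- g_nrm
      Fd <- fwd(d)
      slope <- cdot(g, d)
      if (slope >= 0) { d <- -g; Fd <- fwd(d); slope <- cdot(g, d) }
      ## quadratic data term coefficients in step size t
      r <- Fx$dc - y
      a2 <- 0.5 * sum(Mod(Fd$dc)^2)
      a1 <- cdot(r, Fd$dc)
      a0 <- 0.5 * sum(Mod(r)^2)
      t <- min(2 * t_prev, 10)
      ok <- FALSE
      for (ls in seq_len(ls_max)) {
        f_new <- a0 + a1 * t + a2 * t^2 + lambda * pen(Fx$tv + t * Fd$tv)
        if (f_new <= f + ls_c * t * slope) { ok <- TRUE; break }
        t <- t * ls_beta
      }
      if (!ok) break
      x <- x + t * d
      Fx <- list(dc = Fx$dc + t * Fd$dc, tv = Fx$tv + t * Fd$tv)
      f <- f_new
      t_prev <- t
      trace <- c(trace, f)
    }
  }
  list(x = x, objective = trace, final = f)
}

#' GRASP compressed-sensing reconstruction
#'
#' Solves the temporal-TV-regularized inverse problem by nonlinear conjugate
#' gradient (Fletcher-Reeves, backtracking line search), initialized at the
#' density-compensated adjoint. The accepted objective values are
#' non-increasing; the trace is returned as an attribute.
#'
#' @param ksp raw [multicoil_kspace]
#' @param spec matching [encoding_spec]
#' @param cfg a [recon_config]; `lambda`, `n_iter`, `n_repeat` are used
#' @param magnitude return magnitude series (default TRUE)
#' @return a [dynamic_series] with attribute `objective` (trace) and `config`
#' @export
grasp_recon <- function(ksp, spec, cfg = recon_config(), magnitude = TRUE) {
  if (any(!is.finite(Re(ksp$data))) || any(!is.finite(Im(ksp$data))))
    stop_invalid("k-space data contains non-finite values")
  H <- spec$img_dim[1L]; W <- spec$img_dim[2L]; T <- spec$n_frames
  yw <- weighted_data(spec, ksp)
  x0 <- nufft_recon(ksp, spec, magnitude = FALSE)$data
  scale0 <- max(Mod(x0))
  lambda <- cfg$lambda * scale0
  eps <- 1e-6 * scale0
  fwd <- function(xv) {
    xa <- array(xv, c(H, W, T))
    list(dc = as.vector(encode_series(spec, xa, 0.5)),
         tv = as.vector(temporal_tv(xa)))
  }
  adj <- function(rdc, rtv) {
    ra <- array(rdc, c(dim(spec$coils)[1L], spec$traj$n_spokes, spec$traj$n_readout))
    g <- decode_series(spec, ra, 0.5) +
      temporal_tv_adjoint(array(rtv, c(H, W, T - 1L)))
    as.vector(g)
  }
  sol <- nlcg_solve(as.vector(x0 + 0i), fwd, adj, as.vector(yw),
                    lambda, eps, cfg$n_iter, cfg$n_repeat)
  out <- array(sol$x, c(H, W, T))
  if (magnitude) out <- Mod(out)
  res <- dynamic_series(out, spec$frame_times)
  attr(res, "objective") <- sol$objective
  attr(res, "config") <- cfg
  res
}

## Casorati matrix (T x M) of a pixel index set
casorati <- function(series_data, idx) {
  d <- dim(series_data)
  m <- matrix(series_data, d[1L] * d[2L], d[3L])
  t(m[idx, , drop = FALSE])
}

#' Estimate per-region temporal bases by PCA
#'
#' For every region of the partition, forms the `T x M_i` Casorati matrix of
#' pixel time-courses from a (low-resolution) reconstruction and keeps the
#' `K` left singular vectors (no mean-centering), ordered by decreasing
#' singular value. A region named `"background"` gets `K_background`
#' components. The phase/sign of each basis vector is fixed so its
#' largest-magnitude entry is positive real.
#'
#' @param lowres a [dynamic_series] (complex or magnitude)
#' @param partition a [region_partition] on the same grid
#' @param cfg a [recon_config]; `K` and `K_background` are used
#' @return object of class `temporal_basis`: list of `T x K_i` matrices `U`,
#'   per-region `K`, singular values, region names
#' @export
estimate_basis <- function(lowres, partition, cfg = recon_config()) {
  x <- lowres$data
  d <- dim(x)
  if (!identical(as.integer(d[1:2]), as.integer(partition$dim)))
    stop_invalid("partition grid (%dx%d) does not match series (%dx%d)",
                 partition$dim[1], partition$dim[2], d[1], d[2])
  T <- d[3L]
  idx_sets <- partition_indices(partition)
  n <- length(idx_sets)
  U <- vector("list", n); Ks <- integer(n); sv <- vector("list", n)
  for (i in seq_len(n)) {
    K_i <- if (identical(partition$region_names[i], "background"))
      cfg$K_background else cfg$K
    M_i <- length(idx_sets[[i]])
    if (M_i == 0L) { U[[i]] <- matrix(0, T, 0); Ks[i] <- 0L; next }
    if (K_i > min(T, M_i)) {
      warning(sprintf("region '%s': K reduced from %d to %d (region size)",
                      partition$region_names[i], K_i, min(T, M_i)))
      K_i <- min(T, M_i)
    }
    X <- casorati(x, idx_sets[[i]])
    s <- svd(X, nu = K_i, nv = 0)
    Ui <- s$u[, seq_len(K_i), drop = FALSE]
    ## fix phase: largest-magnitude entry positive real
    for (k in seq_len(K_i)) {
      j <- which.max(Mod(Ui[, k]))
      ph <- Ui[j, k] / Mod(Ui[j, k])
      Ui[, k] <- Ui[, k] / ph
    }
    U[[i]] <- Ui; Ks[i] <- K_i; sv[[i]] <- s$d
  }
  structure(list(U = U, K = Ks, singular_values = sv,
                 region_names = partition$region_names, T = T),
            class = "temporal_basis")
}

#' @export
print.temporal_basis <- function(x, ...) {
  cat(sprintf("Temporal basis: %d regions, T = %d, K = [%s]\n",
              length(x$U), x$T, paste(x$K, collapse = ", ")))
  invisible(x)
}

## pixel coverage counts for a partition (overlapping blocks may exceed 1)
partition_coverage <- function(partition) {
  npix <- prod(partition$dim)
  cov <- numeric(npix)
  for (s in partition_indices(partition)) cov[s] <- cov[s] + 1
  cov
}

#' Compress a series onto per-region temporal subspaces
#'
#' `V_i = U_i^H X_i` for every region's Casorati matrix `X_i`.
#' @param series a [dynamic_series]
#' @param basis a [temporal_basis]
#' @param partition the matching [region_partition]
#' @return object of class `subspace_coefficients` (list of `K_i x M_i`)
#' @export
compress <- function(series, basis, partition) {
  idx_sets <- partition_indices(partition)
  if (length(idx_sets) != length(basis$U))
    stop_invalid("basis and partition disagree on region count")
  x <- series$data
  V <- lapply(seq_along(idx_sets), function(i) {
    X <- casorati(x, idx_sets[[i]])
    t(Conj(basis$U[[i]])) %*% X
  })
  structure(list(V = V), class = "subspace_coefficients")
}

#' Expand subspace coefficients back to a dynamic series
#'
#' `X_i = U_i V_i` reassembled into images; pixels covered by several
#' overlapping blocks are averaged over their covering blocks.
#' @param basis a [temporal_basis]
#' @param coeffs a `subspace_coefficients` object
#' @param partition the matching [region_partition]
#' @param frame_times frame times for the output series
#' @return a [dynamic_series] (complex)
#' @export
expand <- function(basis, coeffs, partition, frame_times = seq_len(basis$T)) {
  idx_sets <- partition_indices(partition)
  npix <- prod(partition$dim)
  T <- basis$T
  acc <- matrix(0i, npix, T)
  for (i in seq_along(idx_sets)) {
    if (basis$K[i] == 0L) next
    Xi <- basis$U[[i]] %*% coeffs$V[[i]]        # T x M
    acc[idx_sets[[i]], ] <- acc[idx_sets[[i]], ] + t(Xi)
  }
  cov <- partition_coverage(partition)
  acc <- acc / pmax(cov, 1)
  dynamic_series(array(acc, c(partition$dim, T)), frame_times)
}

## exact adjoint of expand (divides by coverage before the basis projection)
expand_adjoint <- function(series_data, basis, partition) {
  idx_sets <- partition_indices(partition)
  d <- dim(series_data)
  cov <- partition_coverage(partition)
  m <- matrix(series_data, d[1L] * d[2L], d[3L]) / pmax(cov, 1)
  V <- lapply(seq_along(idx_sets), function(i) {
    X <- t(m[idx_sets[[i]], , drop = FALSE])
    t(Conj(basis$U[[i]])) %*% X
  })
  structure(list(V = V), class = "subspace_coefficients")
}

## flatten / unflatten coefficient lists for the generic NLCG
coeffs_to_vec <- function(coeffs) {
  unlist(lapply(coeffs$V, as.vector), use.names = FALSE) + 0i
}
vec_to_coeffs <- function(v, basis, partition) {
  idx_sets <- partition_indices(partition)
  out <- vector("list", length(idx_sets))
  pos <- 0L
  for (i in seq_along(idx_sets)) {
    K <- basis$K[i]; M <- length(idx_sets[[i]])
    n <- K * M
    out[[i]] <- matrix(v[pos + seq_len(n)], K, M)
    pos <- pos + n
  }
  structure(list(V = out), class = "subspace_coefficients")
}

#' Subspace-constrained reconstruction (GLR / LLR / ELITE)
#'
#' Optimizes the data-consistency and temporal-TV objective over the
#' per-region subspace coefficients only, with the temporal bases fixed;
#' same nonlinear CG scheme as [grasp_recon], initialized at the compression
#' of the density-compensated adjoint. One whole-image region gives the
#' globally low-rank (GLR) reconstruction, overlapping blocks the locally
#' low-rank (LLR) one, and a tissue label map with a single-component
#' background the tissue-segment ('ELITE') one.
#'
#' @param ksp raw [multicoil_kspace]
#' @param spec matching [encoding_spec]
#' @param basis a [temporal_basis] from [estimate_basis]
#' @param partition the matching [region_partition] on the recon grid
#' @param cfg a [recon_config]
#' @param magnitude return magnitude series (default TRUE)
#' @return a [dynamic_series] with attributes `objective`, `config`,
#'   `coefficients` (the optimal `V`)
#' @export
subspace_recon <- function(ksp, spec, basis, partition, cfg = recon_config(),
                           magnitude = TRUE) {
  if (any(!is.finite(Re(ksp$data))) || any(!is.finite(Im(ksp$data))))
    stop_invalid("k-space data contains non-finite values")
  H <- spec$img_dim[1L]; W <- spec$img_dim[2L]; T <- spec$n_frames
  if (basis$T != T) stop_invalid("basis T (%d) != frame count (%d)", basis$T, T)
  yw <- weighted_data(spec, ksp)
  x0img <- nufft_recon(ksp, spec, magnitude = FALSE)$data
  scale0 <- max(Mod(x0img))
  lambda <- cfg$lambda * scale0
  eps <- 1e-6 * scale0
  v0 <- coeffs_to_vec(compress(dynamic_series(x0img, spec$frame_times),
                               basis, partition))
  fwd <- function(v) {
    xa <- expand(basis, vec_to_coeffs(v, basis, partition), partition,
                 spec$frame_times)$data
    list(dc = as.vector(encode_series(spec, xa, 0.5)),
         tv = as.vector(temporal_tv(xa)))
  }
  adj <- function(rdc, rtv) {
    ra <- array(rdc, c(dim(spec$coils)[1L], spec$traj$n_spokes, spec$traj$n_readout))
    g_img <- decode_series(spec, ra, 0.5) +
      temporal_tv_adjoint(array(rtv, c(H, W, T - 1L)))
    coeffs_to_vec(expand_adjoint(g_img, basis, partition))
  }
  sol <- nlcg_solve(v0, fwd, adj, as.vector(yw), lambda, eps,
                    cfg$n_iter, cfg$n_repeat)
  coeffs <- vec_to_coeffs(sol$x, basis, partition)
  out <- expand(basis, coeffs, partition, spec$frame_times)
  if (magnitude) out$data <- Mod(out$data)
  attr(out, "objective") <- sol$objective
  attr(out, "config") <- cfg
  attr(out, "coefficients") <- coeffs
  out
}

#' Overlapping block partition
#'
#' `block_grid^2` base blocks, each extended by `overlap_fraction` of the
#' block size on every side (clipped at the image border), so every pixel is
#' covered at least once and interior pixels by up to four blocks at 50%
#' overlap.
#'
#' @param height,width image dimensions
#' @param block_grid blocks per dimension
#' @param overlap_fraction fractional extension per side, in \[0, 1)
#' @return a `region_partition` in block mode
#' @export
partition_blocks <- function(height, width, block_grid, overlap_fraction = 0.5) {
  height <- check_count(height, "height"); width <- check_count(width, "width")
  block_grid <- check_count(block_grid, "block_grid")
  check_number(overlap_fraction, "overlap_fraction", 0, 0.999)
  bh <- height / block_grid; bw <- width / block_grid
  if (bh < 1 || bw < 1) stop_invalid("block larger than image")
  eh <- floor(overlap_fraction * bh); ew <- floor(overlap_fraction * bw)
  sets <- vector("list", block_grid^2)
  k <- 0L
  for (j in seq_len(block_grid)) {
    c0 <- max(1L, round((j - 1) * bw) + 1L - ew)
    c1 <- min(width, round(j * bw) + ew)
    for (i in seq_len(block_grid)) {
      r0 <- max(1L, round((i - 1) * bh) + 1L - eh)
      r1 <- min(height, round(i * bh) + eh)
      k <- k + 1L
      rows <- r0:r1
      cols <- c0:c1
      sets[[k]] <- as.vector(outer(rows, (cols - 1L) * height, "+"))
    }
  }
  region_partition(block_index_sets = sets, dim = c(height, width))
}

## k-means++ seeding
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i1 <- sample.int(n, 1L)
  centers[1L, ] <- X[i1, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    ij <- sample.int(n, 1L, prob = p)
    centers[j, ] <- X[ij, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

#' K-means partition of pixel time-courses
#'
#' Clusters the magnitude time-courses of a (low-resolution) series into
#' `n_clusters` regions with k-means (k-means++ seeding, fixed seed).
#'
#' @param lowres a [dynamic_series]
#' @param n_clusters number of segments (>= 2)
#' @param seed RNG seed
#' @return a `region_partition` in label-map mode (labels relabelled to
#'   `0..n-1` in order of first pixel occurrence)
#' @export
kmeans_partition <- function(lowres, n_clusters, seed = 0L) {
  n_clusters <- check_count(n_clusters, "n_clusters", lower = 2)
  x <- Mod(lowres$data)
  d <- dim(x)
  X <- matrix(x, d[1L] * d[2L], d[3L])
  if (n_clusters > nrow(X)) stop_invalid("more clusters than pixels")
  km <- with_seed(seed, {
    centers <- kmeanspp_centers(X, n_clusters)
    stats::kmeans(X, centers = centers, iter.max = 100L)
  })
  cl <- km$cluster
  ## contiguous labels in order of first pixel occurrence (deterministic)
  relab <- match(cl, unique(cl)) - 1L
  lab <- matrix(as.integer(relab), d[1L], d[2L])
  region_partition(lab, paste0("cluster", seq_len(length(unique(cl)))))
}

#' One-call reconstruction dispatcher
#'
#' Convenience wrapper running the full pipeline for a named method:
#' `nufft`, `grasp`, or the subspace methods `glr` (whole-image region),
#' `llr` (overlapping blocks) and `elite` (tissue label map, background
#' confined to `K_background` components). For subspace methods the temporal
#' bases are estimated by PCA from a GRASP reconstruction on the same grid
#' (pass `basis_series` to reuse an existing low-resolution series, e.g. a
#' denoised 2-spoke reconstruction).
#'
#' @param ksp raw [multicoil_kspace]
#' @param spec matching [encoding_spec]
#' @param method one of `"nufft"`, `"grasp"`, `"glr"`, `"llr"`, `"elite"`
#' @param cfg a [recon_config]
#' @param labels a [region_partition] label map (required for `"elite"`)
#' @param basis_series optional [dynamic_series] used for basis estimation
#' @return a magnitude [dynamic_series]
#' @export
reconstruct <- function(ksp, spec, method = c("nufft", "grasp", "glr", "llr", "elite"),
                        cfg = recon_config(), labels = NULL,
                        basis_series = NULL) {
  method <- match.arg(method)
  if (method == "nufft") return(nufft_recon(ksp, spec))
  if (method == "grasp") return(grasp_recon(ksp, spec, cfg))
  partition <- switch(method,
    glr = {
      lab <- matrix(0L, spec$img_dim[1L], spec$img_dim[2L])
      region_partition(lab, "whole")
    },
    llr = partition_blocks(spec$img_dim[1L], spec$img_dim[2L],
                           cfg$block_grid, cfg$block_overlap),
    elite = {
      if (is.null(labels)) stop_invalid("method 'elite' requires a tissue label map")
      labels
    })
  if (is.null(basis_series)) basis_series <- grasp_recon(ksp, spec, cfg)
  basis <- estimate_basis(basis_series, partition, cfg)
  subspace_recon(ksp, spec, basis, partition, cfg)
}
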