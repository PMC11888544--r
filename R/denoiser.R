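## Residual convolutional denoiser for 2-spokes-per-frame streak artifacts.
##
## A plain 2D residual network: n_conv_layers 3x3 convolutions with ReLU
## between them and a global residual connection (output = input + learned
## correction), trained with Adam on an L2 loss between undersampled 2-spoke
## reconstructions and fully sampled references. Convolutions are evaluated
## as im2col + BLAS matrix products with hand-written backpropagation, so
## training is deterministic under a fixed seed and runs on a single CPU.

#' Denoiser architecture specification
#'
#' @param n_conv_layers number of convolutional layers (>= 2, default 10)
#' @param channels feature channels in hidden layers (default 64)
#' @param kernel kernel size (odd, default 3)
#' @param residual global residual connection flag (default TRUE)
#' @param seed weight-initialization seed
#' @return object of class `denoiser_spec`
#' @export
denoiser_spec <- function(n_conv_layers = 10L, channels = 64L, kernel = 3L,
                          residual = TRUE, seed = 1L) {
  n_conv_layers <- check_count(n_conv_layers, "n_conv_layers", lower = 2)
  channels <- check_count(channels, "channels")
  kernel <- check_count(kernel, "kernel")
  if (kernel %% 2L == 0L) stop_invalid("kernel size must be odd")
  check_flag(residual, "residual")
  structure(list(n_conv_layers = n_conv_layers, channels = channels,
                 kernel = kernel, residual = residual, seed = as.integer(seed)),
            class = "denoiser_spec")
}

## im2col index table for an H x W image, k x k kernel, zero padding (k-1)/2.
## Returns an (H*W) x (k*k) matrix of source indices into the zero-padded
## image, computed once per image size and cached on the model.
im2col_index <- function(H, W, k) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  ctr <- as.vector(outer((p + seq_len(H)), (p + seq_len(W) - 1L) * Hp, "+"))
  offs <- as.vector(outer(seq_len(k) - 1L - p, (seq_len(k) - 1L - p) * Hp, "+"))
  outer(ctr, offs, "+")
}

pad_image <- function(x, p) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H + 2L * p, W + 2L * p)
  out[p + seq_len(H), p + seq_len(W)] <- x
  out
}

## x: H x W x Cin -> (H*W) x (k*k*Cin) patch matrix
im2col <- function(x, idx, k) {
  d <- dim(x)
  Cin <- if (length(d) == 3L) d[3L] else 1L
  p <- (k - 1L) %/% 2L
  cols <- matrix(0, nrow(idx), ncol(idx) * Cin)
  dim(x) <- c(d[1L], d[2L], Cin)
  for (c in seq_len(Cin)) {
    xp <- pad_image(x[, , c], p)
    cols[, (c - 1L) * ncol(idx) + seq_len(ncol(idx))] <- xp[idx]
  }
  cols
}

## adjoint of im2col: scatter-add patch-matrix gradients back to image
col2im <- function(cols, idx, k, H, W, Cin) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  out <- array(0, c(H, W, Cin))
  kk <- ncol(idx)
  for (c in seq_len(Cin)) {
    acc <- numeric(Hp * Wp)
    block <- cols[, (c - 1L) * kk + seq_len(kk), drop = FALSE]
    for (j in seq_len(kk)) {
      tj <- idx[, j]
      acc[tj] <- acc[tj] + block[, j]
    }
    dim(acc) <- c(Hp, Wp)
    out[, , c] <- acc[p + seq_len(H), p + seq_len(W)]
  }
  out
}

## He-initialized weights: list per layer of W ((k*k*Cin) x Cout) and bias
init_denoiser <- function(spec) {
  L <- spec$n_conv_layers; C <- spec$channels; k <- spec$kernel
  with_seed(spec$seed, {
    lapply(seq_len(L), function(l) {
      cin <- if (l == 1L) 1L else C
      cout <- if (l == L) 1L else C
      fan_in <- k * k * cin
      list(W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                      fan_in, cout),
           b = numeric(cout))
    })
  })
}

## forward pass; returns output H x W and per-layer caches for backprop
denoiser_forward <- function(x, weights, spec, idx, keep_cache = FALSE) {
  L <- spec$n_conv_layers; k <- spec$kernel
  H <- nrow(x); W <- ncol(x)
  a <- array(x, c(H, W, 1L))
  caches <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    cols <- im2col(a, idx, k)
    z <- cols %*% weights[[l]]$W
    z <- sweep(z, 2L, weights[[l]]$b, "+")
    if (l < L) {
      mask <- z > 0
      a_out <- z * mask
    } else {
      mask <- NULL
      a_out <- z
    }
    if (keep_cache) caches[[l]] <- list(cols = cols, mask = mask,
                                        cin = dim(a)[3L])
    a <- array(a_out, c(H, W, ncol(z)))
  }
  corr <- matrix(a, H, W)
  out <- if (spec$residual) x + corr else corr
  list(out = out, caches = caches)
}

## backprop of dLoss/dOut through the correction branch; returns gradients
denoiser_backward <- function(dout, weights, spec, idx, caches, H, W) {
  L <- spec$n_conv_layers; k <- spec$kernel
  grads <- vector("list", L)
  delta <- matrix(as.vector(dout), H * W, 1L)   # grad wrt final z
  for (l in rev(seq_len(L))) {
    cache <- caches[[l]]
    if (!is.null(cache$mask)) delta <- delta * cache$mask
    grads[[l]] <- list(W = crossprod(cache$cols, delta),
                       b = colSums(delta))
    if (l > 1L) {
      dcols <- tcrossprod(delta, weights[[l]]$W)      # (H*W) x (k*k*cin)
      dimg <- col2im(dcols, idx, k, H, W, cache$cin)
      delta <- matrix(dimg, H * W, cache$cin)
    }
  }
  grads
}

#' Augment a DRO case list by redrawing tissue rise times
#'
#' Per case, generates `n_aug_per_case` phantom variants whose tissue rise
#' times are re-drawn from the dictionary (deterministic under the seed);
#' the resulting dataset count is `length(cases) * n_aug_per_case`.
#'
#' @param cases list of [dro_phantom] objects
#' @param n_aug_per_case augmented variants per case (>= 1)
#' @param rise_dictionary per-tissue rise-time ranges
#' @param seed RNG seed
#' @return list of [dro_phantom] variants (length `n_cases * n_aug_per_case`)
#' @export
augment_training_set <- function(cases, n_aug_per_case,
                                 rise_dictionary = default_rise_dictionary(),
                                 seed = 0L) {
  if (length(cases) < 1L) stop_invalid("augment_training_set: empty case list")
  n_aug_per_case <- check_count(n_aug_per_case, "n_aug_per_case")
  out <- vector("list", length(cases) * n_aug_per_case)
  k <- 0L
  for (i in seq_along(cases)) {
    for (j in seq_len(n_aug_per_case)) {
      k <- k + 1L
      ph <- cases[[i]]
      sub_seed <- seed + 1000L * i + j
      rise <- sample_rise_times(DRO_TISSUES, rise_dictionary, seed = sub_seed)
      ph$kinetics <- default_tissue_kinetics(rise)
      ph$augment_seed <- sub_seed
      out[[k]] <- ph
    }
  }
  out
}

#' Build training pairs from a DRO phantom
#'
#' Simulates 2-spokes-per-frame radial k-space of the phantom's dynamic
#' series and reconstructs each frame with the density-compensated adjoint
#' (the streaked input). The target is the fully sampled reference frame: in
#' simulation the rendered object itself is the exact fully sampled image
#' (`reference = "truth"`, default); `reference = "nyquist"` instead
#' synthesizes it by reconstructing a Nyquist-rate spoke set of the same
#' frame, which adds the gridding operator's own discretization noise to the
#' targets. Frames are normalized jointly to the reference peak.
#'
#' @param phantom a [dro_phantom]
#' @param aif_in an [aif] covering the phantom grid
#' @param spokes_per_frame spokes per frame (default 2)
#' @param noise_sigma k-space noise SD (default 0)
#' @param seed RNG seed
#' @param reference `"nyquist"` or `"truth"`
#' @return list of pairs, each `list(input, target)` of H x W matrices
#' @export
make_training_pairs <- function(phantom, aif_in, spokes_per_frame = 2L,
                                noise_sigma = 0, seed = 0L,
                                reference = c("truth", "nyquist")) {
  reference <- match.arg(reference)
  truth <- generate_dynamic_phantom(phantom, aif_in)
  H <- dim(truth$data)[1L]; T <- dim(truth$data)[3L]
  n_spokes <- spokes_per_frame * T
  traj <- golden_angle_trajectory(n_spokes, 2L * H)
  fos <- bin_spokes(n_spokes, spokes_per_frame)
  spec <- encoding_spec(c(H, H), phantom$coils, traj, fos,
                        frame_times = truth$frame_times)
  ksp <- simulate_kspace(truth, spec, noise_sigma, seed)
  rec <- nufft_recon(ksp, spec)
  if (reference == "nyquist") {
    ## fully sampled reference: azimuthal Nyquist spokes for every frame
    s_ref <- as.integer(ceiling(pi / 2 * H))
    traj_r <- golden_angle_trajectory(s_ref * T, 2L * H)
    spec_r <- encoding_spec(c(H, H), phantom$coils, traj_r,
                            bin_spokes(s_ref * T, s_ref),
                            frame_times = truth$frame_times)
    ksp_r <- simulate_kspace(truth, spec_r, noise_sigma, seed + 1L)
    ref <- nufft_recon(ksp_r, spec_r)$data
  } else {
    ref <- truth$data
  }
  pk <- max(ref)
  lapply(seq_len(T), function(t)
    list(input = rec$data[, , t] / pk, target = ref[, , t] / pk))
}

#' Train the residual denoiser
#'
#' Minibatch Adam on the mean-squared error between network output and
#' reference frames. Deterministic under the spec seed with single-threaded
#' BLAS.
#'
#' @param pairs list of `list(input, target)` matrices of one common size
#' @param spec a [denoiser_spec]
#' @param epochs training epochs
#' @param lr Adam learning rate (default 1e-3)
#' @param batch_size minibatch size (default 4)
#' @return object of class `denoiser_model` with `weights`, `spec`,
#'   `loss_trace` (one mean loss per epoch)
#' @export
train_denoiser <- function(pairs, spec = denoiser_spec(), epochs = 50L,
                           lr = 1e-3, batch_size = 4L) {
  if (length(pairs) < 1L) stop_invalid("train_denoiser: need at least one pair")
  epochs <- check_count(epochs, "epochs")
  dims <- dim(pairs[[1L]]$input)
  for (p in pairs)
    if (!identical(dim(p$input), dims) || !identical(dim(p$target), dims))
      stop_invalid("train_denoiser: all pairs must share one shape")
  H <- dims[1L]; W <- dims[2L]
  idx <- im2col_index(H, W, spec$kernel)
  weights <- init_denoiser(spec)
  L <- spec$n_conv_layers
  mom <- lapply(weights, function(w) list(mW = 0 * w$W, vW = 0 * w$W,
                                          mb = 0 * w$b, vb = 0 * w$b))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  loss_trace <- numeric(epochs)
  order_draws <- with_seed(spec$seed + 1L,
                           replicate(epochs, sample(length(pairs)),
                                     simplify = FALSE))
  for (ep in seq_len(epochs)) {
    ord <- order_draws[[ep]]
    ep_loss <- 0
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (bt in batches) {
      gacc <- lapply(weights, function(w) list(W = 0 * w$W, b = 0 * w$b))
      bloss <- 0
      for (i in bt) {
        x <- pairs[[i]]$input; yref <- pairs[[i]]$target
        fw <- denoiser_forward(x, weights, spec, idx, keep_cache = TRUE)
        err <- fw$out - yref
        bloss <- bloss + mean(err^2)
        dout <- 2 * err / length(err)
        g <- denoiser_backward(dout, weights, spec, idx, fw$caches, H, W)
        for (l in seq_len(L)) {
          gacc[[l]]$W <- gacc[[l]]$W + g[[l]]$W
          gacc[[l]]$b <- gacc[[l]]$b + g[[l]]$b
        }
      }
      step <- step + 1L
      for (l in seq_len(L)) {
        gW <- gacc[[l]]$W / length(bt); gb <- gacc[[l]]$b / length(bt)
        mom[[l]]$mW <- b1 * mom[[l]]$mW + (1 - b1) * gW
        mom[[l]]$vW <- b2 * mom[[l]]$vW + (1 - b2) * gW^2
        mom[[l]]$mb <- b1 * mom[[l]]$mb + (1 - b1) * gb
        mom[[l]]$vb <- b2 * mom[[l]]$vb + (1 - b2) * gb^2
        mhW <- mom[[l]]$mW / (1 - b1^step); vhW <- mom[[l]]$vW / (1 - b2^step)
        mhb <- mom[[l]]$mb / (1 - b1^step); vhb <- mom[[l]]$vb / (1 - b2^step)
        weights[[l]]$W <- weights[[l]]$W - lr * mhW / (sqrt(vhW) + adam_eps)
        weights[[l]]$b <- weights[[l]]$b - lr * mhb / (sqrt(vhb) + adam_eps)
      }
      ep_loss <- ep_loss + bloss
    }
    loss_trace[ep] <- ep_loss / length(pairs)
  }
  structure(list(weights = weights, spec = spec, loss_trace = loss_trace,
                 img_dim = c(H, W)),
            class = "denoiser_model")
}

#' @export
print.denoiser_model <- function(x, ...) {
  cat(sprintf("Residual denoiser: %d conv layers, %d channels, trained %d epochs (final loss %.4g)\n",
              x$spec$n_conv_layers, x$spec$channels, length(x$loss_trace),
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Mean squared error of a model on a pair set
#' @param model a `denoiser_model`
#' @param pairs list of `list(input, target)`
#' @return mean over pairs of per-pair MSE
#' @export
denoiser_mse <- function(model, pairs) {
  idx <- im2col_index(model$img_dim[1L], model$img_dim[2L], model$spec$kernel)
  mean(vapply(pairs, function(p) {
    out <- denoiser_forward(p$input, model$weights, model$spec, idx)$out
    mean((out - p$target)^2)
  }, numeric(1)))
}

#' Apply the denoiser to a dynamic series
#'
#' Frame-wise application to the magnitude series; output has the input's
#' shape. With an all-zero correction branch the residual network is the
#' identity.
#'
#' @param model a `denoiser_model`
#' @param series a [dynamic_series]
#' @return a [dynamic_series] of denoised magnitude frames
#' @export
denoise <- function(model, series) {
  x <- Mod(series$data)
  d <- dim(x)
  if (!identical(as.integer(d[1:2]), as.integer(model$img_dim)))
    stop_invalid("series (%dx%d) does not match model input (%dx%d)",
                 d[1], d[2], model$img_dim[1], model$img_dim[2])
  idx <- im2col_index(d[1L], d[2L], model$spec$kernel)
  sc <- max(x)
  if (sc <= 0) sc <- 1
  out <- array(0, d)
  for (t in seq_len(d[3L]))
    out[, , t] <- denoiser_forward(x[, , t] / sc, model$weights, model$spec,
                                   idx)$out * sc
  dynamic_series(out, series$frame_times)
}
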