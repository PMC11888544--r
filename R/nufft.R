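## Gridding non-uniform FFT.
##
## Kaiser-Bessel interpolation on a 2x oversampled grid with analytic
## apodization (the standard convolution-gridding construction). The forward
## map samples the centred DFT of an H x W image at arbitrary normalized
## frequencies nu in [-0.5, 0.5)^2:
##     y(nu) = sum_n x[n] exp(-2i pi (nu_y (r - H/2) + nu_x (c - W/2)))
## The adjoint is the exact algebraic transpose (spread + unnormalized inverse
## FFT + crop + de-apodize), so <E x, y> = <x, E^H y> to machine precision.
## Interpolation is precomputed as a sparse matrix per spoke set and reused
## across coils and iterations; complex vectors are multiplied as two real
## matvecs since the kernel is real.

NUFFT_OS <- 2L       # grid oversampling
NUFFT_WIDTH <- 4L    # kernel taps per dimension

kb_beta <- function(width = NUFFT_WIDTH, os = NUFFT_OS) {
  ## Beatty et al. choice for minimal aliasing error
  pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
}

## kernel k(u) on |u| <= width/2 (grid units), unnormalized I0 form
kb_kernel <- function(u, width = NUFFT_WIDTH, beta = kb_beta(width)) {
  z <- 1 - (2 * u / width)^2
  out <- z * 0
  ok <- z > 0
  out[ok] <- besselI(beta * sqrt(z[ok]), 0)
  out
}

## continuous Fourier transform of the kernel at frequency f (cycles/grid-unit)
kb_kernel_ft <- function(f, width = NUFFT_WIDTH, beta = kb_beta(width)) {
  z2 <- beta^2 - (pi * width * f)^2
  out <- numeric(length(f))
  pos <- z2 > 0
  out[pos] <- width * sinh(sqrt(z2[pos])) / sqrt(z2[pos])
  out[!pos] <- width * sinc_safe(sqrt(-z2[!pos]))
  out
}

sinc_safe <- function(x) ifelse(abs(x) < 1e-8, 1, sin(x) / x)

## separable apodization for an N1 x N2 image on a G1 x G2 oversampled grid
nufft_apodization <- function(N1, N2, os = NUFFT_OS) {
  G1 <- os * N1; G2 <- os * N2
  a1 <- kb_kernel_ft((seq_len(N1) - 1 - N1 %/% 2) / G1)
  a2 <- kb_kernel_ft((seq_len(N2) - 1 - N2 %/% 2) / G2)
  outer(a1, a2)
}

## sparse interpolation matrix: (n_points) x (G1*G2), coords = 2-col matrix
## (nu_row, nu_col) in cycles/FOV
nufft_interp_matrix <- function(coords, N1, N2, os = NUFFT_OS,
                                width = NUFFT_WIDTH) {
  G1 <- os * N1; G2 <- os * N2
  beta <- kb_beta(width)
  np <- nrow(coords)
  u1 <- coords[, 1] * G1                # grid units relative to DC
  u2 <- coords[, 2] * G2
  ## DC sits at 0-based index G/2
  p1 <- u1 + G1 %/% 2
  p2 <- u2 + G2 %/% 2
  half <- width / 2
  offs <- seq_len(width) - 1L
  base1 <- ceiling(p1 - half)           # first tap (0-based)
  base2 <- ceiling(p2 - half)
  ## tap index matrices np x width
  t1 <- outer(base1, offs, "+")
  t2 <- outer(base2, offs, "+")
  w1 <- kb_kernel(t1 - p1, width, beta)
  w2 <- kb_kernel(t2 - p2, width, beta)
  t1 <- t1 %% G1; t2 <- t2 %% G2        # wrap (rarely triggered for |nu|<0.5)
  ## combine separable taps: width^2 entries per point
  ii <- rep(seq_len(np), times = width * width)
  jj <- integer(np * width * width)
  xx <- numeric(np * width * width)
  k <- 0L
  for (a in seq_len(width)) {
    for (b in seq_len(width)) {
      idx <- k * np + seq_len(np)
      jj[idx] <- t1[, a] + G1 * t2[, b] + 1L   # column-major 1-based
      xx[idx] <- w1[, a] * w2[, b]
      k <- k + 1L
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(np, G1 * G2))
}

## complex sparse matvec helpers (P real)
csp_mult <- function(P, z) {
  as.vector(P %*% Re(z)) + 1i * as.vector(P %*% Im(z))
}
csp_tmult <- function(P, z) {
  as.vector(Matrix::crossprod(P, Re(z))) +
    1i * as.vector(Matrix::crossprod(P, Im(z)))
}

## stacked NUFFT: imgs is N1 x N2 x B; returns np x B complex matrix.
## One batched FFT and one sparse x dense product serve all B slices.
nufft_apply_stack <- function(imgs, P, apod, os = NUFFT_OS) {
  d <- dim(imgs)
  N1 <- d[1L]; N2 <- d[2L]; B <- if (length(d) == 3L) d[3L] else 1L
  G1 <- os * N1; G2 <- os * N2
  pad <- array(0i, c(G1, G2, B))
  r0 <- G1 %/% 2 - N1 %/% 2
  c0 <- G2 %/% 2 - N2 %/% 2
  dim(imgs) <- c(N1, N2, B)
  for (b in seq_len(B))
    pad[r0 + seq_len(N1), c0 + seq_len(N2), b] <- imgs[, , b] / apod
  K <- fft2_stack(pad)
  dim(K) <- c(G1 * G2, B)
  out <- as.matrix(P %*% Re(K)) + 1i * as.matrix(P %*% Im(K))
  out
}

## stacked adjoint: y is np x B; returns N1 x N2 x B
nufft_adjoint_stack <- function(y, P, apod, N1, N2, os = NUFFT_OS) {
  y <- as.matrix(y)
  B <- ncol(y)
  G1 <- os * N1; G2 <- os * N2
  g <- as.matrix(Matrix::crossprod(P, Re(y))) +
    1i * as.matrix(Matrix::crossprod(P, Im(y)))
  dim(g) <- c(G1, G2, B)
  img <- fft2_stack(g, inverse = TRUE)
  r0 <- G1 %/% 2 - N1 %/% 2
  c0 <- G2 %/% 2 - N2 %/% 2
  out <- array(0i, c(N1, N2, B))
  for (b in seq_len(B))
    out[, , b] <- img[r0 + seq_len(N1), c0 + seq_len(N2), b] / apod
  out
}

## single-image NUFFT given precomputed structures
nufft_apply <- function(img, P, apod, os = NUFFT_OS) {
  N1 <- nrow(img); N2 <- ncol(img)
  G1 <- os * N1; G2 <- os * N2
  z <- img / apod
  pad <- matrix(0i, G1, G2)
  r0 <- G1 %/% 2 - N1 %/% 2
  c0 <- G2 %/% 2 - N2 %/% 2
  pad[r0 + seq_len(N1), c0 + seq_len(N2)] <- z
  K <- fft2_stack(pad)
  csp_mult(P, as.vector(K))
}

nufft_adjoint_apply <- function(y, P, apod, N1, N2, os = NUFFT_OS) {
  G1 <- os * N1; G2 <- os * N2
  g <- csp_tmult(P, y)
  dim(g) <- c(G1, G2)
  img <- fft2_stack(g, inverse = TRUE)
  r0 <- G1 %/% 2 - N1 %/% 2
  c0 <- G2 %/% 2 - N2 %/% 2
  img[r0 + seq_len(N1), c0 + seq_len(N2)] / apod
}
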