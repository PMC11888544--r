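#' @keywords internal
"_PACKAGE"

## Small shared helpers. Argument checking follows base-R stopifnot style but
## with readable messages, since most entry points are user-facing.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_invalid("'%s' must be TRUE or FALSE", name)
  invisible(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stop_invalid("'%s' must be in [%g, %g], got %g", name, lower, upper, x)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stop_invalid("'%s' must be an integer, got %g", name, x)
  invisible(as.integer(x))
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not disturb
#' the caller's random stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  code
}

#' Normalized root-mean-square error
#'
#' NRMSE between an estimate and a reference, normalized by the RMS of the
#' reference. Complex inputs are compared on their complex values; use
#' `Mod()` first to compare magnitudes.
#' @param x estimate (numeric or complex array)
#' @param ref reference of the same shape
#' @return scalar NRMSE (fraction, not percent)
#' @export
nrmse <- function(x, ref) {
  if (length(x) != length(ref)) stop_invalid("nrmse: inputs differ in length")
  sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))
}

## real inner product on complex vectors: Re<a, b>
cdot <- function(a, b) sum(Re(Conj(a) * b))

## 2D fftshift / ifftshift index vectors
shift_idx <- function(n, inverse = FALSE) {
  h <- if (inverse) ceiling(n / 2) else floor(n / 2)
  c(seq_len(n - h) + h, seq_len(h))
}

fftshift2 <- function(x) {
  d <- dim(x)
  x[shift_idx(d[1L]), shift_idx(d[2L]), drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  x[shift_idx(d[1L], inverse = TRUE), shift_idx(d[2L], inverse = TRUE), drop = FALSE]
}

## Batched centred 2D FFT of a stack (n x n x B). Computes
## fftshift(fft2(ifftshift(slice))) for every slice using two batched mvfft
## calls; inverse = TRUE gives the unnormalized (adjoint) inverse.
fft2_stack <- function(x, inverse = FALSE) {
  d <- dim(x)
  n1 <- d[1L]; n2 <- d[2L]
  B <- if (length(d) == 3L) d[3L] else 1L
  i1 <- shift_idx(n1, inverse = TRUE); s1 <- shift_idx(n1)
  i2 <- shift_idx(n2, inverse = TRUE); s2 <- shift_idx(n2)
  dim(x) <- c(n1, n2, B)
  x <- x[i1, i2, , drop = FALSE]
  dim(x) <- c(n1, n2 * B)
  x <- stats::mvfft(x, inverse = inverse)          # along dim 1
  dim(x) <- c(n1, n2, B)
  x <- aperm(x, c(2L, 1L, 3L))
  dim(x) <- c(n2, n1 * B)
  x <- stats::mvfft(x, inverse = inverse)          # along dim 2
  dim(x) <- c(n2, n1, B)
  x <- aperm(x, c(2L, 1L, 3L))
  x <- x[s1, s2, , drop = FALSE]
  if (length(d) == 2L) dim(x) <- d
  x
}

## centred 2D Fourier resize (crop or zero-pad in k-space), amplitude-preserving
## for smooth fields; used for coil-map and truth downsampling.
fourier_resize <- function(img, L) {
  N1 <- nrow(img); N2 <- ncol(img)
  K <- fft2_stack(img + 0i)
  out <- matrix(0i, L, L)
  take1 <- min(L, N1); take2 <- min(L, N2)
  src1 <- (N1 - take1) %/% 2L + seq_len(take1)
  src2 <- (N2 - take2) %/% 2L + seq_len(take2)
  dst1 <- (L - take1) %/% 2L + seq_len(take1)
  dst2 <- (L - take2) %/% 2L + seq_len(take2)
  out[dst1, dst2] <- K[src1, src2]
  fft2_stack(out, inverse = TRUE) / (N1 * N2)
}
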