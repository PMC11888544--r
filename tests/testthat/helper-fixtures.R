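# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small dynamic simulation: 48x48, 2 coils, 64 spokes binned 4/frame
small_sim <- function() fixture("small_sim", function() {
  N <- 48L; C <- 2L; S <- 64L; spf <- 4L
  nf <- S %/% spf
  tg <- (seq_len(nf) - 0.5) * 4.2
  ph <- dro_phantom(N, N, n_coils = C, time_grid = tg, seed = 0)
  a <- model_aif(seq(0, max(tg) + 5), onset = 15)
  truth <- generate_dynamic_phantom(ph, a)
  traj <- golden_angle_trajectory(S, 2L * N)
  spec <- encoding_spec(c(N, N), ph$coils, traj, bin_spokes(S, spf),
                        frame_times = tg)
  ksp <- simulate_kspace(truth, spec, noise_sigma = 0.5, seed = 1)
  list(N = N, phantom = ph, aif = a, truth = truth, traj = traj,
       spec = spec, ksp = ksp)
})

# direct (slow) non-uniform DFT oracles matching the package conventions:
# centred phase, coords in cycles/FOV
direct_nudft <- function(img, coords) {
  N1 <- nrow(img); N2 <- ncol(img)
  n1 <- (seq_len(N1) - 1) - N1 %/% 2
  n2 <- (seq_len(N2) - 1) - N2 %/% 2
  E1 <- exp(-2i * pi * outer(coords[, 1], n1))   # npts x N1
  E2 <- exp(-2i * pi * outer(coords[, 2], n2))
  rowSums((E1 %*% img) * E2)
}

direct_nudft_adjoint <- function(y, coords, N1, N2) {
  n1 <- (seq_len(N1) - 1) - N1 %/% 2
  n2 <- (seq_len(N2) - 1) - N2 %/% 2
  E1 <- exp(2i * pi * outer(n1, coords[, 1]))    # N1 x npts
  E2 <- exp(2i * pi * outer(n2, coords[, 2]))
  E1 %*% (y * t(E2))
}

rand_cplx <- function(n, seed) {
  set.seed(seed)
  complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
}

# closed-form biexponential impulse response of the 2CXM (per-second rates),
# independent of the package ODE path
tcxm_impulse <- function(params) {
  M <- rbind(c(-(params$Fp + params$PS) / params$vp, params$PS / params$vp),
             c(params$PS / params$ve, -params$PS / params$ve)) / 60
  b <- c(params$Fp / 60 / params$vp, 0)
  cvec <- c(params$vp, params$ve)
  eg <- eigen(M)
  coefs <- as.numeric(cvec %*% eg$vectors) * as.numeric(solve(eg$vectors) %*% b)
  function(t) coefs[1] * exp(eg$values[1] * t) + coefs[2] * exp(eg$values[2] * t)
}

# fine-step convolution of a sampled AIF with the impulse response
tcxm_oracle <- function(params, a, dt_fine = 0.002) {
  h <- tcxm_impulse(params)
  fine <- seq(0, max(a$t), by = dt_fine)
  caf <- stats::approx(a$t, a$Ca, xout = fine, rule = 2)$y
  hf <- Re(h(fine))
  conv <- stats::convolve(caf, rev(hf), type = "open")[seq_along(fine)] * dt_fine
  stats::approx(fine, conv, xout = a$t)$y
}
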