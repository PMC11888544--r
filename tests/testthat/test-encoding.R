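# Radial trajectory, frame binning, density compensation and the encoding
# operator pair.

test_that("golden-angle trajectory follows the 111.246-degree rule", {
  tr <- golden_angle_trajectory(5, 64)
  expect_equal(tr$angles[1], 0)
  expect_equal(tr$angles[2], 111.246 * pi / 180)
  expect_equal(tr$angles[4], ((3 * 111.246) %% 180) * pi / 180)
  # every spoke passes through k = 0 (sample at radius < half a cell)
  for (s in 1:5) {
    r <- sqrt(rowSums(tr$coords[(s - 1) * 64 + 1:64, ]^2))
    expect_lt(min(r), 0.5 / 64)
  }
  expect_error(golden_angle_trajectory(5, 63), "even")
})

test_that("golden-angle spokes are pairwise non-parallel over 100-spoke windows", {
  tr <- golden_angle_trajectory(150, 4)
  for (start in c(1, 51)) {
    win <- tr$angles[start:(start + 99)]
    d <- abs(outer(win, win, "-")) %% pi
    d <- pmin(d, pi - d)
    expect_gt(min(d[upper.tri(d)]), 1e-6)
  }
})

test_that("frame binning counts and remainder discard", {
  expect_equal(max(bin_spokes(288, 2), na.rm = TRUE), 144)
  expect_equal(max(bin_spokes(288, 8), na.rm = TRUE), 36)
  f <- bin_spokes(7, 2)
  expect_equal(max(f, na.rm = TRUE), 3)
  expect_true(is.na(f[7]))
  expect_error(bin_spokes(10, 0), "spokes_per_frame")
})

test_that("temporal resolution matches the acquisition arithmetic", {
  expect_equal(temporal_resolution(150, 288, 8), 150 * 8 / 288)
  expect_equal(round(temporal_resolution(150, 288, 8), 1), 4.2)
  expect_equal(round(temporal_resolution(150, 288, 2), 0), 1)
  expect_equal(round(temporal_resolution(150, 288, 13), 1), 6.8)
})

test_that("density weights are a positive mean-1 ramp", {
  tr <- golden_angle_trajectory(16, 64)
  w <- density_compensation(tr)
  expect_true(all(w > 0))
  expect_equal(mean(w), 1)
  r <- sqrt(rowSums(tr$coords^2))
  i1 <- which.min(abs(r - 0.1)); i2 <- which.min(abs(r - 0.2))
  expect_equal(w[i2] / w[i1], r[i2] / r[i1], tolerance = 1e-10)
})

test_that("point object PSF peaks at the correct pixel under dense sampling", {
  N <- 32L; S <- 100L
  tr <- golden_angle_trajectory(S, 2L * N)
  spec <- encoding_spec(c(N, N), array(1 + 0i, c(1, N, N)), tr,
                        bin_spokes(S, S), frame_times = 1)
  x <- array(0i, c(N, N, 1)); x[N / 2 + 5, N / 2 - 3, 1] <- 1
  ksp <- simulate_kspace(dynamic_series(x, 1), spec, 0, 0)
  rec <- nufft_recon(ksp, spec)
  peak <- which(rec$data[, , 1] == max(rec$data[, , 1]), arr.ind = TRUE)
  expect_equal(as.integer(peak), c(N / 2 + 5L, N / 2 - 3L))
  expect_gt(max(rec$data), 0.5)
})

test_that("forward operator matches the direct non-uniform DFT", {
  N <- 24L; S <- 6L
  tr <- golden_angle_trajectory(S, 2L * N)
  coils <- simulate_coils(N, N, 2)
  spec <- encoding_spec(c(N, N), coils, tr, bin_spokes(S, 3L),
                        frame_times = c(1, 2))
  set.seed(10)
  x <- array(rand_cplx(N * N * 2, 10), c(N, N, 2))
  ksp <- forward_op(spec, dynamic_series(x, c(1, 2)))
  # oracle: per coil/frame direct DFT of the coil-weighted image
  w <- spec$weights
  for (f in 1:2) {
    spokes <- which(spec$frame_of_spoke == f)
    rows <- as.vector(sapply(spokes, function(s) (s - 1) * 2 * N + 1:(2 * N)))
    for (cc in 1:2) {
      y0 <- direct_nudft(x[, , f] * coils[cc, , ], tr$coords[rows, ]) *
        sqrt(w[rows])
      got <- as.vector(t(ksp$data[cc, spokes, ]))
      expect_lt(sqrt(sum(Mod(got - y0)^2) / sum(Mod(y0)^2)), 1e-3)
    }
  }
})

test_that("E and E^H are exact adjoints and linear", {
  sim <- small_sim()
  spec <- sim$spec
  d <- dim(sim$truth$data)
  x <- array(rand_cplx(prod(d), 21), d)
  z <- array(rand_cplx(prod(d), 22), d)
  Ex <- forward_op(spec, dynamic_series(x, sim$truth$frame_times))
  y <- array(rand_cplx(length(Ex$data), 23), dim(Ex$data))
  # zero unused spokes of y (outside the range of E)
  unused <- is.na(spec$frame_of_spoke)
  y[, unused, ] <- 0i
  Ehy <- adjoint_op(spec, multicoil_kspace(y, sim$traj, spec$frame_of_spoke,
                                           spec$weights))
  ip1 <- sum(Conj(y) * Ex$data)
  ip2 <- sum(Conj(Ehy$data) * x)
  expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-10)
  # linearity
  Ez <- forward_op(spec, dynamic_series(z, sim$truth$frame_times))
  Exz <- forward_op(spec, dynamic_series(2 * x - 3i * z, sim$truth$frame_times))
  expect_lt(max(Mod(Exz$data - (2 * Ex$data - 3i * Ez$data))),
            1e-10 * max(Mod(Ex$data)))
  # zero maps to zero both ways
  E0 <- forward_op(spec, dynamic_series(array(0i, d), sim$truth$frame_times))
  expect_true(all(E0$data == 0))
})

test_that("simulated k-space is exact without noise and calibrated with it", {
  sim <- small_sim()
  y0 <- simulate_kspace(sim$truth, sim$spec, 0, seed = 9)
  y1 <- simulate_kspace(sim$truth, sim$spec, 0, seed = 99)
  expect_identical(y0$data, y1$data)
  sigma <- 0.37
  yn <- simulate_kspace(sim$truth, sim$spec, sigma, seed = 5)
  yn2 <- simulate_kspace(sim$truth, sim$spec, sigma, seed = 5)
  expect_identical(yn$data, yn2$data)
  noise <- yn$data - y0$data
  expect_equal(stats::sd(Re(noise)), sigma, tolerance = 0.02)
  expect_equal(stats::sd(Im(noise)), sigma, tolerance = 0.02)
})

test_that("low-resolution subset keeps the central half and rescales", {
  sim <- small_sim()
  N <- sim$N
  full <- lowres_subset(sim$ksp, 2L * N, N = 2L * N)  # readout-grid identity
  expect_equal(dim(full$data), dim(sim$ksp$data))
  low <- lowres_subset(sim$ksp, N / 2L, N = N)
  expect_equal(dim(low$data)[3], dim(sim$ksp$data)[3] / 2L)
  r_low <- sqrt(rowSums(low$trajectory$coords^2))
  expect_lt(max(r_low), 0.5 + 1e-9)       # rescaled to the L grid
  expect_gt(max(r_low), 0.45)             # and spanning it
  expect_error(lowres_subset(sim$ksp, 15L, N = N), "even")
})

test_that("low-resolution recon of a smooth object matches downsampled truth", {
  N <- 48L; L <- 24L; S <- 160L
  g <- outer(exp(-((1:N) - N / 2 - 1)^2 / 72), exp(-((1:N) - N / 2 - 1)^2 / 72))
  tr <- golden_angle_trajectory(S, 2L * N)
  spec <- encoding_spec(c(N, N), array(1 + 0i, c(1, N, N)), tr,
                        bin_spokes(S, S), frame_times = 1)
  ksp <- simulate_kspace(dynamic_series(array(g + 0i, c(N, N, 1)), 1), spec, 0, 0)
  klow <- lowres_subset(ksp, L, N = N)
  speclow <- lowres_spec(spec, klow, L)
  rec <- nufft_recon(klow, speclow)
  truth_low <- Mod(fourier_resize(g + 0i, L))
  expect_lt(nrmse(rec$data[, , 1], truth_low), 0.05)
})
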