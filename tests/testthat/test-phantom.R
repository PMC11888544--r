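# Digital reference object: geometry, kinetics, coils, rendering.

test_that("label map has six non-empty regions and is deterministic", {
  p1 <- make_label_map(160, 160, seed = 0)
  p2 <- make_label_map(160, 160, seed = 0)
  labs <- sort(unique(as.integer(p1$label_map)))
  expect_identical(labs, 0:5)
  counts <- table(p1$label_map)
  expect_true(all(counts > 0))
  expect_identical(p1$label_map, p2$label_map)
  expect_error(make_label_map(20, 160), "32")
})

test_that("lesion lies inside the fibroglandular bounding box", {
  p <- make_label_map(160, 160, seed = 3)
  les <- which(p$label_map == 1L, arr.ind = TRUE)
  fib <- which(p$label_map == 2L, arr.ind = TRUE)
  expect_gt(nrow(les), 0)
  expect_true(min(les[, 1]) >= min(fib[, 1]) && max(les[, 1]) <= max(fib[, 1]))
  expect_true(min(les[, 2]) >= min(fib[, 2]) && max(les[, 2]) <= max(fib[, 2]))
})

test_that("rise-time sampling respects ranges, degenerate ranges and seeds", {
  expect_equal(unname(sample_rise_times("lesion", list(lesion = c(30, 30)),
                                        seed = 1)), 30)
  draws <- vapply(1:200, function(s)
    sample_rise_times("lesion", list(lesion = c(20, 60)), seed = s)[["lesion"]],
    numeric(1))
  expect_true(all(draws >= 20 & draws <= 60))
  expect_gt(stats::sd(draws), 0)
  r1 <- sample_rise_times(c("lesion", "heart"), seed = 11)
  r2 <- sample_rise_times(c("lesion", "heart"), seed = 11)
  expect_identical(r1, r2)
  expect_error(sample_rise_times("lesion", list()), "empty")
  expect_error(sample_rise_times("lesion", list(lesion = c(60, 20))), "range")
})

test_that("coil maps: single-coil identity, positive RSS, smoothness", {
  c1 <- simulate_coils(64, 64, 1)
  expect_true(all(c1 == 1 + 0i))
  c8 <- simulate_coils(64, 64, 8)
  rss <- sqrt(apply(Mod(unclass(c8))^2, c(2, 3), sum))
  expect_true(all(rss > 0))
  # smoothness: magnitude finite differences bounded by the Gaussian lobe
  # slope (sigma = 0.55 in FOV units -> max gradient well under 5% per pixel)
  for (cc in 1:8) {
    m <- Mod(c8[cc, , ])
    expect_lt(max(abs(diff(m))), 0.05 * max(m))
  }
  expect_error(simulate_coils(64, 64, 0), "n_coils")
})

test_that("zero AIF leaves every frame at baseline; background is zero", {
  ph <- dro_phantom(48, 48, n_coils = 1, time_grid = c(2, 6, 10), seed = 0)
  a0 <- aif(seq(0, 20), rep(0, 21))
  ser <- generate_dynamic_phantom(ph, a0)
  expect_equal(ser$data[, , 1], ser$data[, , 3])
  bg <- ph$partition$label_map == 0L
  for (t in 1:3) expect_true(all(ser$data[, , t][bg] == 0))
})

test_that("time courses are bounded by baseline * (1 + amplitude)", {
  ph <- dro_phantom(48, 48, n_coils = 1,
                    time_grid = seq(5, 145, by = 10), seed = 2,
                    heterogeneity = 0)
  a <- model_aif(seq(0, 150), onset = 20)
  ser <- generate_dynamic_phantom(ph, a)
  for (j in seq_along(ph$kinetics)) {
    k <- ph$kinetics[[j]]
    idx <- ph$partition$label_map == (j - 1L)
    if (!any(idx)) next
    vals <- apply(ser$data, 3, function(fr) fr[idx])
    expect_true(all(vals >= -1e-12))
    expect_true(all(vals <= k$baseline * (1 + k$amplitude) + 1e-9))
  }
})

test_that("homogeneous regions give rank-1 Casorati matrices", {
  ph <- dro_phantom(48, 48, n_coils = 1, time_grid = seq(5, 95, by = 10),
                    seed = 0, heterogeneity = 0)
  a <- model_aif(seq(0, 100), onset = 20)
  ser <- generate_dynamic_phantom(ph, a)
  m <- matrix(ser$data, 48 * 48, 10)
  for (lab in 1:5) {
    idx <- which(ph$partition$label_map == lab)
    X <- t(m[idx, , drop = FALSE])
    sv <- svd(X, nu = 0, nv = 0)$d
    expect_lt(sv[2] / sv[1], 1e-10)
  }
})

test_that("embedded lesion curve matches a fine-step independent integration", {
  ph <- dro_phantom(48, 48, n_coils = 1, time_grid = seq(2, 290, by = 4),
                    seed = 0, heterogeneity = 0)
  a <- model_aif(seq(0, 295, by = 0.5), onset = 30)
  ser <- generate_dynamic_phantom(ph, a)
  k <- ph$kinetics$lesion
  idx <- which(ph$partition$label_map == 1L)[1]
  course <- apply(ser$data, 3, function(fr) fr[idx])
  emb <- course / k$baseline - 1            # amplitude * normalized curve
  # oracle: explicit RK4 at 1/100 the frame spacing
  p <- k$params
  Fp <- p$Fp / 60; PS <- p$PS / 60
  caf <- stats::approxfun(a$t, a$Ca, rule = 2)
  deriv <- function(t, y) c((Fp * caf(t) + PS * y[2] - (Fp + PS) * y[1]) / p$vp,
                            (PS * y[1] - PS * y[2]) / p$ve)
  dt <- 0.04; tt <- seq(0, 292, by = dt)
  y <- c(0, 0); ct <- numeric(length(tt))
  for (i in seq_along(tt)[-1]) {
    t0 <- tt[i - 1]
    k1 <- deriv(t0, y); k2 <- deriv(t0 + dt / 2, y + dt / 2 * k1)
    k3 <- deriv(t0 + dt / 2, y + dt / 2 * k2); k4 <- deriv(t0 + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ct[i] <- p$vp * y[1] + p$ve * y[2]
  }
  oracle <- stats::approx(tt, ct, xout = ph$time_grid)$y
  oracle <- k$amplitude * oracle / max(oracle)
  expect_lt(max(abs(emb - oracle)) / max(oracle), 0.005)
})

test_that("phantom bundle round-trips through the writer", {
  ph <- dro_phantom(48, 48, n_coils = 2, time_grid = c(2, 6), seed = 4)
  a0 <- aif(seq(0, 20), rep(0, 21))
  truth <- generate_dynamic_phantom(ph, a0)
  path <- tempfile(fileext = ".rds")
  write_phantom_bundle(ph, truth, path)
  back <- read_phantom_bundle(path)
  expect_identical(back$phantom$partition$label_map, ph$partition$label_map)
  expect_equal(back$truth$data, truth$data)
  expect_equal(back$phantom$kinetics$lesion$params$Fp, ph$kinetics$lesion$params$Fp)
})
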