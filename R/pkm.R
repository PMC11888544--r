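## Two-compartment exchange model (2CXM) for DCE-MRI pharmacokinetics.
##
## Tissue concentration: Ct(t) = vp*Cp(t) + ve*Ce(t)
##   vp dCp/dt = Fp*Ca(t) + PS*Ce(t) - (Fp + PS)*Cp(t)
##   ve dCe/dt = PS*Cp(t) - PS*Ce(t)
## with Fp (plasma flow) and PS (permeability-surface-area product) in 1/min,
## ve/vp unitless volume fractions and concentrations in mM. Time grids are in
## seconds throughout the package; rates are converted internally.

#' Pharmacokinetic parameter set for the two-compartment exchange model
#'
#' @param ve extracellular-extravascular volume fraction (unitless, in \[0,1\])
#' @param vp plasma volume fraction (unitless, in \[0,1\])
#' @param Fp plasma flow (1/min)
#' @param PS permeability-surface-area product (1/min)
#' @return an object of class `pkm_params` with the derived `Ktrans`
#' @export
pkm_params <- function(ve, vp, Fp, PS) {
  check_number(ve, "ve", 0, 1)
  check_number(vp, "vp", 0, 1)
  check_number(Fp, "Fp", 0)
  check_number(PS, "PS", 0)
  if (ve + vp > 1 + 1e-9)
    stop_invalid("ve + vp must be <= 1 (got %.3f)", ve + vp)
  structure(
    list(ve = ve, vp = vp, Fp = Fp, PS = PS, Ktrans = ktrans_from(Fp, PS)),
    class = "pkm_params"
  )
}

#' @export
print.pkm_params <- function(x, ...) {
  cat("2CXM parameters:\n")
  cat(sprintf("  ve = %.4f  vp = %.4f  Fp = %.4f /min  PS = %.4f /min  Ktrans = %.4f /min\n",
              x$ve, x$vp, x$Fp, x$PS, x$Ktrans))
  invisible(x)
}

#' Volume transfer constant from flow and permeability
#'
#' `Ktrans = Fp * (1 - exp(-PS / Fp))`, the effective contrast extraction
#' rate. Monotone increasing in both arguments, saturating at `Fp` for
#' `PS >> Fp`; returns 0 as `Fp -> 0`.
#'
#' @param Fp plasma flow (1/min), `>= 0`
#' @param PS permeability-surface-area product (1/min), `>= 0`
#' @return Ktrans in 1/min
#' @export
ktrans_from <- function(Fp, PS) {
  if (any(Fp < 0) || any(PS < 0))
    stop_invalid("Fp and PS must be non-negative")
  ifelse(Fp <= 0, 0, Fp * (1 - exp(-PS / pmax(Fp, .Machine$double.xmin))))
}

#' Arterial input function container
#'
#' @param t sample times in seconds, strictly increasing
#' @param Ca arterial plasma concentration in mM, non-negative
#' @return object of class `aif`
#' @export
aif <- function(t, Ca) {
  if (length(t) != length(Ca)) stop_invalid("aif: t and Ca differ in length")
  if (any(diff(t) <= 0)) stop_invalid("aif: t must be strictly increasing")
  if (any(Ca < -1e-12)) stop_invalid("aif: Ca must be non-negative")
  structure(list(t = as.numeric(t), Ca = pmax(as.numeric(Ca), 0)), class = "aif")
}

#' Population arterial input function model
#'
#' Analytic population AIF (mixture of two Gaussian bolus passes plus a
#' sigmoid-gated exponential washout, the standard population parameterization
#' for gadolinium bolus injection) shifted to a given onset time. Used to
#' drive the synthetic phantom and as a default AIF for fitting.
#'
#' @param t sample times (s)
#' @param onset bolus arrival time (s); `Ca = 0` before onset
#' @param scale multiplicative scale on the concentration (default 1)
#' @return an [aif] object
#' @export
model_aif <- function(t, onset = 30, scale = 1) {
  check_number(onset, "onset", 0)
  tm <- pmax(t - onset, 0) / 60  # minutes since arrival
  A1 <- 0.809; A2 <- 0.330; T1 <- 0.17046; T2 <- 0.365
  s1 <- 0.0563; s2 <- 0.132; alpha <- 1.050; beta <- 0.1685
  s <- 38.078; tau <- 0.483
  ca <- A1 / (s1 * sqrt(2 * pi)) * exp(-(tm - T1)^2 / (2 * s1^2)) +
    A2 / (s2 * sqrt(2 * pi)) * exp(-(tm - T2)^2 / (2 * s2^2)) +
    alpha * exp(-beta * tm) / (1 + exp(-s * (tm - tau)))
  ca[t < onset] <- 0
  aif(t, scale * ca)
}

#' Forward two-compartment exchange model
#'
#' Integrates the coupled plasma/EES ODEs from `Cp = Ce = 0` with an adaptive
#' stiff-capable solver (`deSolve::lsoda`, relative tolerance `1e-8`) and
#' returns the tissue, plasma and EES concentration curves on the AIF grid.
#' `vp = 0` falls back to a quasi-steady plasma compartment; `ve = 0` to a
#' plasma-only model; both zero is an error.
#'
#' @param params a [pkm_params] object
#' @param aif an [aif] object (times in seconds)
#' @return list of class `concentration_curve` with `t`, `Ct`, `Cp`, `Ce`
#' @export
tcxm_forward <- function(params, aif) {
  stopifnot(inherits(params, "pkm_params"), inherits(aif, "aif"))
  ve <- params$ve; vp <- params$vp
  Fp <- params$Fp / 60; PS <- params$PS / 60  # per-second rates
  if (vp <= 0 && ve <= 0)
    stop_invalid("tcxm_forward: ve and vp cannot both be zero")
  ca_fun <- stats::approxfun(aif$t, aif$Ca, rule = 2)
  tt <- aif$t
  t0 <- if (tt[1] > 0) c(0, tt) else tt

  if (Fp <= 0) {
    z <- rep(0, length(tt))
    return(structure(list(t = tt, Ct = z, Cp = z, Ce = z),
                     class = "concentration_curve"))
  }

  if (vp > 0 && ve > 0) {
    deriv <- function(t, y, p) {
      ca <- ca_fun(t)
      dCp <- (Fp * ca + PS * y[2] - (Fp + PS) * y[1]) / vp
      dCe <- (PS * y[1] - PS * y[2]) / ve
      list(c(dCp, dCe))
    }
    sol <- deSolve::lsoda(c(Cp = 0, Ce = 0), t0, deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    idx <- match(tt, sol[, 1])
    Cp <- sol[idx, 2]; Ce <- sol[idx, 3]
  } else if (vp > 0) {            # ve = 0: no EES exchange
    deriv <- function(t, y, p) {
      list((Fp * ca_fun(t) - Fp * y[1]) / vp)
    }
    sol <- deSolve::lsoda(c(Cp = 0), t0, deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    Cp <- sol[match(tt, sol[, 1]), 2]; Ce <- rep(0, length(tt))
  } else {                        # vp = 0: quasi-steady plasma
    deriv <- function(t, y, p) {
      cp <- (Fp * ca_fun(t) + PS * y[1]) / (Fp + PS)
      list(PS * (cp - y[1]) / ve)
    }
    sol <- deSolve::lsoda(c(Ce = 0), t0, deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    Ce <- sol[match(tt, sol[, 1]), 2]
    Cp <- (Fp * aif$Ca + PS * Ce) / (Fp + PS)
  }
  Ct <- params$vp * Cp + params$ve * Ce
  structure(list(t = tt, Ct = Ct, Cp = Cp, Ce = Ce),
            class = "concentration_curve")
}

#' Spoiled gradient-echo relaxation settings
#'
#' @param T10 pre-contrast T1 (s)
#' @param TR repetition time (s)
#' @param flip flip angle (degrees)
#' @param r1 contrast agent relaxivity (1/mM/s), default 4.5 (gadobutrol-class)
#' @return list of class `relaxation_settings`
#' @export
relaxation_settings <- function(T10 = 1.3, TR = 4.87e-3, flip = 10, r1 = 4.5) {
  check_number(T10, "T10", 1e-6); check_number(TR, "TR", 1e-9)
  check_number(flip, "flip", 1e-6, 90); check_number(r1, "r1", 1e-9)
  structure(list(T10 = T10, TR = TR, flip = flip * pi / 180, r1 = r1),
            class = "relaxation_settings")
}

## SPGR steady-state signal for longitudinal rate R1 (1/s)
spgr_signal <- function(M0, R1, rel) {
  E1 <- exp(-rel$TR * R1)
  M0 * sin(rel$flip) * (1 - E1) / (1 - E1 * cos(rel$flip))
}

#' Convert SPGR signal to contrast concentration
#'
#' Estimates the equilibrium magnetization from the pre-contrast baseline
#' window and the known `T10`, inverts the spoiled-gradient-echo steady-state
#' equation sample-by-sample to `R1(t)`, and maps to concentration via
#' `Ct = (R1 - 1/T10) / r1`. Samples implying `R1 < 1/T10` (noise below
#' baseline) are clipped to 0 and counted.
#'
#' @param signal numeric vector of signal intensities (a.u.)
#' @param t sample times (s)
#' @param baseline indices of the pre-contrast window
#' @param rel a [relaxation_settings] object
#' @return `concentration_curve` with `Ct` (and attribute `n_clipped`)
#' @export
signal_to_concentration <- function(signal, t, baseline, rel) {
  stopifnot(inherits(rel, "relaxation_settings"))
  if (length(baseline) < 1L) stop_invalid("baseline window is empty")
  if (length(signal) != length(t)) stop_invalid("signal and t differ in length")
  R10 <- 1 / rel$T10
  s0 <- mean(signal[baseline])
  E10 <- exp(-rel$TR * R10)
  M0 <- s0 * (1 - E10 * cos(rel$flip)) / (sin(rel$flip) * (1 - E10))
  b <- signal / (M0 * sin(rel$flip))
  E1 <- (1 - b) / (1 - b * cos(rel$flip))
  E1 <- pmin(pmax(E1, 1e-12), 1 - 1e-12)
  R1 <- -log(E1) / rel$TR
  Ct <- (R1 - R10) / rel$r1
  n_clipped <- sum(Ct < 0)
  Ct <- pmax(Ct, 0)
  structure(list(t = t, Ct = Ct, Cp = NULL, Ce = NULL),
            class = "concentration_curve", n_clipped = n_clipped)
}

#' Synthesize an SPGR signal from a concentration curve
#'
#' Forward counterpart of [signal_to_concentration], useful for round-trip
#' checks and phantom signal synthesis.
#' @param Ct concentration (mM)
#' @param baseline_signal pre-contrast signal level (a.u.)
#' @param rel a [relaxation_settings] object
#' @return numeric signal vector
#' @export
concentration_to_signal <- function(Ct, baseline_signal, rel) {
  R10 <- 1 / rel$T10
  M0 <- baseline_signal * (1 - exp(-rel$TR * R10) * cos(rel$flip)) /
    (sin(rel$flip) * (1 - exp(-rel$TR * R10)))
  spgr_signal(M0, R10 + rel$r1 * Ct, rel)
}

## onset = first sample exceeding `threshold` x peak
aif_onset_index <- function(ca, threshold = 0.1) {
  pk <- max(ca)
  if (pk <= 0) return(NA_integer_)
  which(ca > threshold * pk)[1L]
}

#' Population AIF by onset-aligned averaging
#'
#' Aligns each input AIF to its own bolus-arrival time (first sample above a
#' threshold fraction of its peak), averages the aligned curves on the common
#' grid, and places the averaged curve at a reference onset. AIFs with no
#' enhancement are excluded with a warning.
#'
#' @param aif_set list of [aif] objects on a common time grid
#' @param threshold onset threshold as a fraction of peak (default 0.1)
#' @return an [aif]: the onset-aligned population average, positioned at the
#'   median onset of the inputs
#' @export
population_aif <- function(aif_set, threshold = 0.1) {
  if (length(aif_set) < 1L) stop_invalid("population_aif: need at least one AIF")
  t <- aif_set[[1L]]$t
  onsets <- vapply(aif_set, function(a) {
    if (!isTRUE(all.equal(a$t, t))) stop_invalid("population_aif: AIFs must share a grid")
    as.integer(aif_onset_index(a$Ca, threshold))
  }, integer(1))
  keep <- !is.na(onsets)
  if (!all(keep)) warning(sprintf("excluding %d AIF(s) with no enhancement", sum(!keep)))
  if (!any(keep)) stop_invalid("population_aif: no enhancing AIF in the set")
  aifs <- aif_set[keep]; onsets <- onsets[keep]
  ref <- as.integer(round(stats::median(onsets)))
  n <- length(t)
  acc <- rep(0, n); cnt <- rep(0, n)
  for (j in seq_along(aifs)) {
    shift <- ref - onsets[j]
    src <- seq_len(n) - shift           # sample feeding position i
    ok <- src >= 1L & src <= n
    acc[ok] <- acc[ok] + aifs[[j]]$Ca[src[ok]]
    cnt[ok] <- cnt[ok] + 1
  }
  ca <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  aif(t, ca)
}

#' Shift a population AIF to a case-specific onset
#'
#' @param pop an [aif]
#' @param onset_time target bolus-arrival time (s)
#' @param threshold onset threshold fraction (default 0.1)
#' @return shifted [aif] on the same grid
#' @export
shift_aif <- function(pop, onset_time, threshold = 0.1) {
  i0 <- aif_onset_index(pop$Ca, threshold)
  if (is.na(i0)) stop_invalid("shift_aif: AIF has no enhancement")
  dt <- mean(diff(pop$t))
  shift <- as.integer(round((onset_time - pop$t[i0]) / dt))
  n <- length(pop$t)
  src <- seq_len(n) - shift
  ca <- ifelse(src >= 1L & src <= n, pop$Ca[pmin(pmax(src, 1L), n)], 0)
  ca[src < 1L] <- 0
  ca[src > n] <- pop$Ca[n]
  aif(pop$t, ca)
}

#' Fit the two-compartment exchange model to a tissue curve
#'
#' Bounded nonlinear least squares over `(ve, vp, Fp, PS)` with
#' Levenberg-Marquardt and multiple starting points to mitigate local minima.
#' `Ktrans` is derived from the fitted flow and permeability.
#'
#' @param ct `concentration_curve` (or numeric Ct on the AIF grid)
#' @param aif_in an [aif] on the same grid
#' @param init optional [pkm_params] initial guess
#' @param lower,upper bounds as named vectors over ve, vp, Fp, PS
#' @param n_starts number of multi-start restarts (default 5, fixed seeds)
#' @return object of class `pkm_fit`: fitted [pkm_params], residual norm,
#'   convergence flag and per-start diagnostics
#' @export
fit_pkm <- function(ct, aif_in, init = NULL,
                    lower = c(ve = 1e-4, vp = 1e-4, Fp = 1e-4, PS = 1e-4),
                    upper = c(ve = 1, vp = 1, Fp = 10, PS = 10),
                    n_starts = 5L) {
  y <- if (inherits(ct, "concentration_curve")) ct$Ct else as.numeric(ct)
  stopifnot(inherits(aif_in, "aif"))
  if (length(y) != length(aif_in$t))
    stop_invalid("fit_pkm: curve and AIF grids differ")
  resid_fun <- function(p) {
    pp <- pkm_params(min(p[["ve"]], 1 - min(p[["vp"]], 0.999)),
                     min(p[["vp"]], 0.999), p[["Fp"]], p[["PS"]])
    tcxm_forward(pp, aif_in)$Ct - y
  }
  starts <- list(c(ve = 0.3, vp = 0.05, Fp = 0.5, PS = 0.1))
  if (!is.null(init))
    starts[[1L]] <- c(ve = init$ve, vp = init$vp, Fp = init$Fp, PS = init$PS)
  if (n_starts > 1L) {
    extra <- with_seed(20260101L, lapply(seq_len(n_starts - 1L), function(i) {
      exp(log(pmax(starts[[1L]], lower)) + stats::rnorm(4, 0, 0.7))
    }))
    extra <- lapply(extra, function(s) pmin(pmax(s, lower), upper))
    starts <- c(starts, extra)
  }
  best <- NULL
  diag <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], lower = lower, upper = upper,
                         fn = resid_fun,
                         ## epsfcn >> ODE tolerance so finite-difference
                         ## Jacobians are not dominated by solver noise
                         control = minpack.lm::nls.lm.control(maxiter = 200,
                                                              epsfcn = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) { diag[[i]] <- list(ok = FALSE); next }
    rn <- sqrt(sum(fit$fvec^2))
    diag[[i]] <- list(ok = TRUE, resid_norm = rn, info = fit$info)
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, resid_norm = Inf, converged = FALSE,
                          starts = diag), class = "pkm_fit"))
  }
  p <- best$fit$par
  params <- pkm_params(min(p[["ve"]], 1 - min(p[["vp"]], 0.999)),
                       min(p[["vp"]], 0.999), p[["Fp"]], p[["PS"]])
  structure(list(params = params, resid_norm = best$rn,
                 converged = best$fit$info %in% 1:4, starts = diag),
            class = "pkm_fit")
}

#' @export
print.pkm_fit <- function(x, ...) {
  cat("2CXM fit", if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$params)) print(x$params)
  cat(sprintf("  residual norm: %.4g\n", x$resid_norm))
  invisible(x)
}

#' @export
coef.pkm_fit <- function(object, ...) {
  p <- object$params
  c(ve = p$ve, vp = p$vp, Fp = p$Fp, PS = p$PS, Ktrans = p$Ktrans)
}

#' Bootstrap pharmacokinetic fitting over voxel subsets
#'
#' Each replicate draws a fixed fraction of the voxels without replacement,
#' averages their concentration curves, and fits the 2CXM; the replicate
#' parameter sets establish the statistics of the region.
#'
#' @param voxel_curves matrix (voxels x time) of tissue concentration curves
#' @param aif_in an [aif] on the curve grid
#' @param fraction fraction of voxels per replicate, in (0, 1\] (default 0.10)
#' @param n_boot number of replicates (default 100)
#' @param seed RNG seed
#' @param n_starts multi-start count passed to [fit_pkm] (default 2 for speed)
#' @return object of class `pkm_bootstrap`: `replicates` (n_boot x 5 matrix of
#'   ve, vp, Fp, PS, Ktrans), `mean`, `sd`
#' @export
bootstrap_fit <- function(voxel_curves, aif_in, fraction = 0.10, n_boot = 100L,
                          seed = 1L, n_starts = 2L) {
  voxel_curves <- as.matrix(voxel_curves)
  nv <- nrow(voxel_curves)
  if (nv < 10L) stop_invalid("bootstrap_fit: need at least 10 voxels")
  if (!(fraction > 0 && fraction <= 1))
    stop_invalid("bootstrap_fit: fraction must be in (0, 1]")
  n_boot <- check_count(n_boot, "n_boot")
  k <- ceiling(fraction * nv)
  draws <- with_seed(seed, replicate(n_boot, sample.int(nv, k), simplify = FALSE))
  reps <- matrix(NA_real_, n_boot, 5,
                 dimnames = list(NULL, c("ve", "vp", "Fp", "PS", "Ktrans")))
  for (b in seq_len(n_boot)) {
    avg <- colMeans(voxel_curves[draws[[b]], , drop = FALSE])
    f <- fit_pkm(avg, aif_in, n_starts = n_starts)
    if (!is.null(f$params)) reps[b, ] <- coef(f)
  }
  structure(list(replicates = reps,
                 mean = colMeans(reps, na.rm = TRUE),
                 sd = apply(reps, 2, stats::sd, na.rm = TRUE),
                 fraction = fraction, n_boot = n_boot, seed = seed),
            class = "pkm_bootstrap")
}

#' @export
print.pkm_bootstrap <- function(x, ...) {
  cat(sprintf("2CXM bootstrap: %d replicates of %.0f%% voxel subsets\n",
              x$n_boot, 100 * x$fraction))
  print(round(rbind(mean = x$mean, sd = x$sd), 5))
  invisible(x)
}
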