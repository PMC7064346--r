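# Fluorescence correlation spectroscopy (FCS) calibration arithmetic:
# observation-volume geometry, the two-component 3D-diffusion + triplet
# autocorrelation model, curve fitting, concentration conversion and QC.

#' Observation volume of a confocal FCS setup
#'
#' The observation volume element (OVE) is approximated by a prolate
#' ellipsoid, `V = pi^(3/2) * wxy^2 * z0`, with `wxy` the lateral and
#' `z0` the axial 1/e^2 radius. With radii in micrometers the volume is
#' in cubic micrometers, i.e. femtoliters.
#'
#' @param wxy lateral 1/e^2 radius (um).
#' @param z0 axial 1/e^2 radius (um).
#' @return Volume in fL.
#' @export
#' @examples
#' ove_volume(0.2, 1) # ~0.223 fL
ove_volume <- function(wxy, z0) {
  if (wxy <= 0 || z0 <= 0) stop("radii must be > 0", call. = FALSE)
  pi^1.5 * wxy^2 * z0
}

#' FCS model parameters
#'
#' Parameters of the two-component 3D-diffusion autocorrelation model
#' with triplet correction.
#'
#' @param N mean particle number in the observation volume (> 0).
#' @param tauD1,tauD2 diffusion times of the fast and slow components
#'   (ms); `tauD1 <= tauD2` by convention.
#' @param y_frac fraction of the fast component (component 1) in \[0, 1\].
#' @param s structural parameter `wxy/wz` (dimensionless).
#' @param T_frac triplet fraction in \[0, 1).
#' @param tauT triplet time (ms).
#' @return A list of class `fcs_params`.
#' @export
fcs_params <- function(N, tauD1, tauD2 = tauD1, y_frac = 1, s = 0.2,
                       T_frac = 0, tauT = 0.005) {
  if (N <= 0) stop("N must be > 0", call. = FALSE)
  if (tauD1 <= 0 || tauD2 <= 0) stop("diffusion times must be > 0",
                                     call. = FALSE)
  if (tauD1 > tauD2) {
    stop("tauD1 must be <= tauD2 (component 1 is the fast component)",
         call. = FALSE)
  }
  if (y_frac < 0 || y_frac > 1) stop("y_frac must be in [0, 1]",
                                     call. = FALSE)
  if (T_frac < 0 || T_frac >= 1) stop("T_frac must be in [0, 1)",
                                      call. = FALSE)
  structure(list(N = N, tauD1 = tauD1, tauD2 = tauD2, y_frac = y_frac,
                 s = s, T_frac = T_frac, tauT = tauT),
            class = "fcs_params")
}

#' Two-component diffusion autocorrelation model
#'
#' Evaluates the normalized autocorrelation
#' `G(tau) = 1 + (1/N) * [y * g(tau; tauD1) + (1-y) * g(tau; tauD2)] *
#' (1 + T/(1-T) * exp(-tau/tauT))`
#' where each 3D-diffusion component is
#' `g(tau; tauD) = (1 + tau/tauD)^-1 * (1 + s^2 * tau/tauD)^-1/2`
#' and the structural parameter `s = wxy/wz` is shared by both
#' components.
#'
#' @param params an [fcs_params()] object.
#' @param lags lag times (ms, same unit as the tau parameters).
#' @return Vector of G values.
#' @export
#' @examples
#' p <- fcs_params(N = 1, tauD1 = 1)
#' model_acf(p, 0)  # zero-lag amplitude 1 + 1/N = 2
model_acf <- function(params, lags) {
  stopifnot(inherits(params, "fcs_params"))
  comp <- function(tauD) {
    (1 + lags / tauD)^(-1) * (1 + params$s^2 * lags / tauD)^(-0.5)
  }
  diff_term <- params$y_frac * comp(params$tauD1) +
    (1 - params$y_frac) * comp(params$tauD2)
  trip <- 1 + params$T_frac / (1 - params$T_frac) * exp(-lags / params$tauT)
  1 + diff_term * trip / params$N
}

#' Fit the FCS model to an autocorrelation curve
#'
#' Bounded nonlinear least squares of the two-component triplet model on
#' a measured (or synthetic) autocorrelation curve. Fractions are bounded
#' to \[0, 1\] and times/amplitudes kept positive. Parameters named in
#' `fixed` are held at their `init` values — the structural parameter `s`
#' is typically fixed from dye calibration.
#'
#' @param lags lag times (ms, increasing, >= 20 points spanning the
#'   decay).
#' @param G measured autocorrelation values.
#' @param init an [fcs_params()] object of starting values.
#' @param fixed character vector of parameter names to hold fixed
#'   (default `"s"`).
#' @return A list with `params` (fitted [fcs_params()]), `rss`,
#'   `converged`, `flagged` (degenerate or non-converged fits).
#' @export
fit_acf <- function(lags, G, init, fixed = "s") {
  stopifnot(inherits(init, "fcs_params"))
  if (length(lags) < 20) {
    stop("need >= 20 lag points spanning the decay", call. = FALSE)
  }
  if (stats::sd(G) < 1e-12) {
    return(list(params = init, rss = NA_real_, converged = FALSE,
                flagged = TRUE,
                reason = "flat curve: particle number unidentifiable"))
  }
  all_names <- c("N", "tauD1", "tauD2", "y_frac", "T_frac", "tauT", "s")
  free <- setdiff(all_names, fixed)
  lower <- c(N = 1e-6, tauD1 = 1e-6, tauD2 = 1e-6, y_frac = 0,
             T_frac = 0, tauT = 1e-6, s = 1e-6)
  upper <- c(N = Inf, tauD1 = Inf, tauD2 = Inf, y_frac = 1,
             T_frac = 0.999, tauT = Inf, s = Inf)
  make_par <- function(theta) {
    p <- init
    for (nm in free) p[[nm]] <- unname(theta[nm])
    class(p) <- "fcs_params"
    p
  }
  fn <- function(theta) {
    names(theta) <- free
    model_acf(make_par(theta), lags) - G
  }
  start <- unlist(init[free])
  fit <- try(minpack.lm::nls.lm(par = start, fn = fn,
                                lower = lower[free], upper = upper[free],
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(params = init, rss = NA_real_, converged = FALSE,
                flagged = TRUE, reason = "optimizer failure"))
  }
  theta <- fit$par
  names(theta) <- free
  pars <- make_par(theta)
  # keep the fast/slow labelling convention
  if (pars$tauD1 > pars$tauD2) {
    tmp <- pars$tauD1; pars$tauD1 <- pars$tauD2; pars$tauD2 <- tmp
    pars$y_frac <- 1 - pars$y_frac
  }
  converged <- fit$info %in% 1:4
  list(params = pars, rss = sum(fit$fvec^2), converged = converged,
       flagged = !converged)
}

#' Concentration from a fitted particle number
#'
#' Converts the mean particle number in the observation volume to a molar
#' concentration: `C = N / (V * Avogadro)`, reported in nM.
#'
#' @param N mean particle number (>= 0).
#' @param volume_fl observation volume in femtoliters (> 0), e.g. from
#'   [ove_volume()].
#' @return Concentration in nM.
#' @export
#' @examples
#' concentration_from_N(10, ove_volume(0.2, 1)) # ~74.6 nM
concentration_from_N <- function(N, volume_fl) {
  if (N < 0) stop("N must be >= 0", call. = FALSE)
  if (volume_fl <= 0) stop("volume must be > 0", call. = FALSE)
  N / (volume_fl * 1e-15 * 6.022e23) * 1e9
}

#' QC rule for FCS measurements
#'
#' A measurement is dropped when the molecular brightness is too low
#' (CPM below `cpm_min`, default 0.5 kHz per molecule) or when the
#' intensity trace shows marked photobleaching, quantified as a
#' (near-)monotonic decline from start to end exceeding `decline_frac`
#' (default 20%). If no QC inputs are available the measurement is kept
#' with a warning.
#'
#' @param cpm counts per molecule (kHz), or `NULL` if unavailable.
#' @param intensity_trace optional numeric intensity trace over the
#'   measurement.
#' @param cpm_min CPM threshold (default 0.5).
#' @param decline_frac photobleaching threshold as a fractional
#'   start-to-end decline (default 0.2).
#' @return A list with `keep` (logical) and `reason`.
#' @export
#' @examples
#' qc_exclude(cpm = 0.4)$keep # FALSE
qc_exclude <- function(cpm = NULL, intensity_trace = NULL,
                       cpm_min = 0.5, decline_frac = 0.2) {
  if (is.null(cpm) && is.null(intensity_trace)) {
    warning("no QC inputs available; keeping measurement")
    return(list(keep = TRUE, reason = "no QC inputs (kept with warning)"))
  }
  if (!is.null(cpm) && cpm < cpm_min) {
    return(list(keep = FALSE,
                reason = sprintf("low CPM (%.2f < %.2f kHz/molecule)",
                                 cpm, cpm_min)))
  }
  if (!is.null(intensity_trace) && length(intensity_trace) >= 3) {
    tr <- intensity_trace
    # coarse smoothing so shot noise does not hide a steady decline
    nb <- max(3, min(10, length(tr) %/% 5))
    sm <- tapply(tr, cut(seq_along(tr), nb), mean)
    decline <- 1 - sm[length(sm)] / sm[1]
    monotone <- all(diff(sm) <= 0)
    if (monotone && is.finite(decline) && decline > decline_frac) {
      return(list(keep = FALSE,
                  reason = sprintf(
                    "photobleaching (monotonic %.0f%% intensity decline)",
                    100 * decline)))
    }
  }
  list(keep = TRUE, reason = "passed QC")
}
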