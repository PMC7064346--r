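#' Intrinsic noise of a dual-reporter sample
#'
#' Computes the intrinsic (uncorrelated) component of expression noise
#' from two reporters measured in the same cells:
#' `eta2 = <(x - y)^2> / (2 <x> <y>)`.
#' This is the variance remaining after the covariance of the two
#' reporters is removed, normalised to the squared mean, and is
#' dimensionless.
#'
#' @param x,y per-cell outputs of the two reporters, in the same (scaled)
#'   units; equal length, length >= 2.
#' @return Intrinsic noise (dimensionless).
#' @export
#' @examples
#' intrinsic_noise(c(8, 12), c(12, 8)) # 0.08
intrinsic_noise <- function(x, y) {
  check_dual(x, y)
  mx <- mean(x); my <- mean(y)
  if (mx <= 0 || my <= 0) {
    stop("intrinsic noise undefined for non-positive channel means",
         call. = FALSE)
  }
  mean((x - y)^2) / (2 * mx * my)
}

#' Cumulative two-allele Fano factor
#'
#' The Fano factor expressed through intrinsic noise,
#' `Fano = eta2 * mu`, with `mu` the mean *total* output `mean(x + y)`.
#' Because the mean is the two-allele total, this is the cumulative Fano
#' factor: for independent alleles each with per-allele Fano `F`, it
#' equals `2F` in expectation.
#'
#' @inheritParams intrinsic_noise
#' @return Fano factor in the units of `x` and `y` (molecules or RFU).
#' @export
#' @examples
#' fano_factor(c(8, 12), c(12, 8)) # 1.6
fano_factor <- function(x, y) {
  intrinsic_noise(x, y) * mean(x + y)
}

#' Partition cells into log-spaced total-output bins
#'
#' Assigns each cell to a half-open bin `[low, high)` of constant width on
#' the log scale of its total output. Bins holding fewer than `min_cells`
#' cells are flagged as excluded (they remain in the table).
#'
#' @param totals per-cell total output; all values must be > 0.
#' @param bin_width bin width in log units (default 0.02).
#' @param log_base base of the log transform (default 10).
#' @param min_cells minimum cells for a bin to be retained (default 25;
#'   variance-type statistics are unstable below this).
#' @param n_bins if supplied, overrides `bin_width` with `n_bins`
#'   equal-width bins spanning the observed log range (the convention used
#'   for pooled simulation sweeps, typically 25-30 bins).
#'
#' @return A list with `assignment` (integer bin index per cell) and
#'   `bins`, a data.frame with `bin`, `bin_low`, `bin_high` (log units),
#'   `n_cells` and `retained`.
#' @export
bin_by_output <- function(totals, bin_width = 0.02, log_base = 10,
                          min_cells = 25, n_bins = NULL) {
  if (any(!is.finite(totals)) || any(totals <= 0)) {
    stop("all totals must be positive and finite; filter non-expressing",
         " cells upstream", call. = FALSE)
  }
  lt <- log(totals, base = log_base)
  if (!is.null(n_bins)) {
    rng <- range(lt)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * 1e-8
    bin_width <- diff(rng) / n_bins
    idx <- pmin(floor((lt - rng[1]) / bin_width), n_bins - 1L)
    origin <- rng[1]
  } else {
    idx <- floor(lt / bin_width)
    origin <- 0
  }
  levels <- sort(unique(idx))
  assignment <- match(idx, levels)
  n_cells <- tabulate(assignment, nbins = length(levels))
  bins <- data.frame(
    bin = seq_along(levels),
    bin_low = origin + levels * bin_width,
    bin_high = origin + (levels + 1) * bin_width,
    n_cells = n_cells,
    retained = n_cells >= min_cells
  )
  list(assignment = assignment, bins = bins,
       log_base = log_base, bin_width = bin_width)
}

#' Binned Fano-factor profile with bootstrap confidence intervals
#'
#' Partitions cells into log-spaced bins of total output `x + y`,
#' computes per-bin mean output, intrinsic noise and cumulative Fano
#' factor, and attaches a percentile-bootstrap 95% CI for each bin's Fano
#' factor from within-bin resampling with replacement.
#'
#' Cells with non-positive totals are dropped (with a message) before
#' binning; bins under `min_cells` are omitted from the profile.
#'
#' @inheritParams intrinsic_noise
#' @inheritParams bin_by_output
#' @param n_boot bootstrap resamples per bin (default 50000; a few
#'   thousand is adequate for exploratory work).
#' @param seed integer seed for the bootstrap, or `NULL`.
#' @param source_label identity label stored on the profile.
#'
#' @return A data.frame of class `noise_profile` with columns `bin_low`,
#'   `bin_high` (log units), `n_cells`, `mu`, `eta2`, `fano`, `ci_low`,
#'   `ci_high`; attributes `bin_width`, `log_base`, `n_boot`,
#'   `source_label`.
#' @export
noise_profile <- function(x, y, bin_width = 0.02, log_base = 10,
                          min_cells = 25, n_bins = NULL, n_boot = 50000,
                          seed = NULL, source_label = NA_character_) {
  check_dual(x, y)
  tot <- x + y
  keep <- is.finite(tot) & tot > 0
  if (!all(keep)) {
    message(sum(!keep), " cells with non-positive total dropped before",
            " binning")
    x <- x[keep]; y <- y[keep]; tot <- tot[keep]
  }
  if (length(tot) == 0) stop("no cells with positive total", call. = FALSE)
  b <- bin_by_output(tot, bin_width = bin_width, log_base = log_base,
                     min_cells = min_cells, n_bins = n_bins)
  retained <- b$bins$bin[b$bins$retained]
  with_seed(seed, {
    rows <- lapply(retained, function(k) {
      i <- which(b$assignment == k)
      xi <- x[i]; yi <- y[i]
      mu <- mean(xi + yi)
      eta2 <- intrinsic_noise(xi, yi)
      fan <- eta2 * mu
      boot <- replicate(n_boot, {
        j <- sample.int(length(i), replace = TRUE)
        xb <- xi[j]; yb <- yi[j]
        mxy <- mean(xb) * mean(yb)
        if (mxy <= 0) return(NA_real_)
        mean((xb - yb)^2) / (2 * mxy) * mean(xb + yb)
      })
      ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE)
      data.frame(
        bin_low = b$bins$bin_low[k], bin_high = b$bins$bin_high[k],
        n_cells = length(i), mu = mu, eta2 = eta2, fano = fan,
        ci_low = min(ci[1], fan), ci_high = max(ci[2], fan)
      )
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$bin_low), , drop = FALSE]
    rownames(out) <- NULL
    structure(out,
              class = c("noise_profile", "data.frame"),
              bin_width = b$bin_width, log_base = log_base,
              n_boot = n_boot, source_label = source_label)
  })
}

#' Lowess measurement-noise model from a tandem-tag Fano profile
#'
#' Fits a locally weighted (Lowess) regression of Fano factor on mean
#' output through the bins of a profile, typically one computed from
#' tandem-tagged control cells whose two channels read the same molecule
#' count, so that all decorrelation is measurement noise. The fitted
#' curve is evaluable at arbitrary output by linear interpolation;
#' outside the fitted support the prediction clamps to the nearest
#' endpoint value.
#'
#' @param profile a [noise_profile()].
#' @param span Lowess window fraction (default 0.3), kept constant across
#'   fits.
#' @return An object of class `measurement_noise_model` with elements
#'   `support`, `predicted_fano`, `span`.
#' @export
lowess_model <- function(profile, span = 0.3) {
  stopifnot(inherits(profile, "noise_profile") || is.data.frame(profile))
  if (nrow(profile) < 5) {
    stop("need >= 5 retained bins to fit a measurement-noise model",
         call. = FALSE)
  }
  fit <- stats::lowess(profile$mu, profile$fano, f = span)
  structure(
    list(support = fit$x, predicted_fano = fit$y, span = span),
    class = "measurement_noise_model"
  )
}

#' Evaluate a measurement-noise model
#'
#' @param object a `measurement_noise_model`.
#' @param mu mean outputs at which to predict.
#' @param ... unused.
#' @return Predicted Fano due to measurement noise at each `mu`; clamped
#'   to the endpoint values outside the fitted support.
#' @export
predict.measurement_noise_model <- function(object, mu, ...) {
  stats::approx(object$support, object$predicted_fano, xout = mu,
                rule = 2, ties = mean)$y
}

#' Subtract measurement noise from a Fano profile
#'
#' For each bin of a sample profile, subtracts the Fano factor predicted
#' by a tandem-tag measurement-noise model at the bin's mean output. The
#' bootstrap CI bounds are shifted by the same amount. Negative corrected
#' values are retained (the subtraction is unbiased) but flagged so that
#' summaries can mask them.
#'
#' @param profile a [noise_profile()] of the biological sample.
#' @param model a [lowess_model()] fitted to the tandem-tag control.
#' @return The profile with added columns `fano_measurement`,
#'   `corrected_fano`, `corrected_ci_low`, `corrected_ci_high`,
#'   `negative_flag`.
#' @export
subtract_measurement_noise <- function(profile, model) {
  stopifnot(inherits(model, "measurement_noise_model"))
  if (max(profile$mu) < min(model$support) ||
      min(profile$mu) > max(model$support)) {
    stop("measurement-noise model support does not overlap the profile;",
         " incompatible calibration", call. = FALSE)
  }
  pred <- predict(model, profile$mu)
  profile$fano_measurement <- pred
  profile$corrected_fano <- profile$fano - pred
  profile$corrected_ci_low <- profile$ci_low - pred
  profile$corrected_ci_high <- profile$ci_high - pred
  profile$negative_flag <- profile$corrected_fano < 0
  profile
}

check_dual <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 cells", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0)) {
    stop("channel values must be finite and >= 0 (after background",
         " subtraction)", call. = FALSE)
  }
  invisible(TRUE)
}
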