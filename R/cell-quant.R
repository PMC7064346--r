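# Per-disc preprocessing of segmented-cell fluorescence tables. Most cells
# in a disc image are non-expressing and form a roughly Gaussian background
# in each channel; expressing cells sit in the right tail. Everything here
# operates on plain data.frames with one row per segmented nucleus.

Z84 <- stats::qnorm(0.84) # 0.99446, the 84th-percentile normal deviate

#' Fit the per-disc, per-channel fluorescence background
#'
#' Estimates the background fluorescence distribution of one channel in
#' one disc by fitting a Gaussian to the (majority) non-expressing cell
#' population. The fit is iteratively trimmed: cells more than 3 sd above
#' the current location are dropped and the fit repeated until stable, so
#' the bright right tail of expressing cells does not bias the estimate.
#' The positive-cell threshold is the 84th percentile of the fitted
#' normal, `bg_mean + 0.99446 * bg_sd`.
#'
#' @param values raw RFU values of all cells in one disc and channel.
#' @param trim_sd trimming cutoff in sd units (default 3).
#' @param max_iter maximum trimming iterations (default 25).
#' @return A list of class `background_fit` with `bg_mean`, `bg_sd`,
#'   `threshold`, `n_used`.
#' @export
fit_background <- function(values, trim_sd = 3, max_iter = 25) {
  values <- values[is.finite(values)]
  if (length(values) < 100) {
    stop("need >= 100 cells to fit a background distribution", call. = FALSE)
  }
  # median/MAD initialisation: a moderate expressing fraction can shift the
  # plain mean/sd so far that trimming never engages
  m <- stats::median(values)
  s <- stats::mad(values)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate spread: background values are (near-)constant",
         call. = FALSE)
  }
  keep <- values[values <= m + trim_sd * s]
  for (i in seq_len(max_iter)) {
    m <- mean(keep); s <- stats::sd(keep)
    if (!is.finite(s) || s <= 0) {
      stop("degenerate spread: background values are (near-)constant",
           call. = FALSE)
    }
    new <- keep[keep <= m + trim_sd * s]
    if (length(new) == length(keep)) break
    if (length(new) < 50) break
    keep <- new
  }
  m <- mean(keep); s <- stats::sd(keep)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate spread: background values are (near-)constant",
         call. = FALSE)
  }
  structure(
    list(bg_mean = m, bg_sd = s, threshold = m + Z84 * s,
         n_used = length(keep)),
    class = "background_fit"
  )
}

#' Classify positive cells and subtract the background threshold
#'
#' A cell is expression-positive only if its *raw* fluorescence exceeds
#' the 84th-percentile background threshold in *both* channels. The
#' threshold value is then subtracted from every cell's raw value in that
#' disc and channel (negative subtracted values are retained but such
#' cells are never positive).
#'
#' @param disc data.frame with columns `green_rfu`, `red_rfu` (plus any
#'   id/position columns, preserved).
#' @param fit_green,fit_red [fit_background()] objects for the two
#'   channels of this disc.
#' @return `disc` with added columns `green_sub`, `red_sub`, `positive`.
#' @export
classify_and_subtract <- function(disc, fit_green, fit_red) {
  stopifnot(is.data.frame(disc),
            all(c("green_rfu", "red_rfu") %in% names(disc)))
  if (!inherits(fit_green, "background_fit") ||
      !inherits(fit_red, "background_fit")) {
    stop("background fits for both channels are required", call. = FALSE)
  }
  disc$green_sub <- disc$green_rfu - fit_green$threshold
  disc$red_sub <- disc$red_rfu - fit_red$threshold
  disc$positive <- disc$green_rfu > fit_green$threshold &
    disc$red_rfu > fit_red$threshold
  disc
}

#' Fit the per-disc channel scaling
#'
#' Ordinary least-squares fit of green on red fluorescence over the
#' positive cells of one disc, `green = slope * red + intercept`, used to
#' express the red channel in green-channel units. The linear correlation
#' coefficient is reported; discs with `r` outside the plausibility band
#' (default \[0.5, 1\]; well-behaved discs run ~0.85-0.95) are flagged.
#'
#' @param green,red background-subtracted channel values of the positive
#'   cells of one disc (>= 20 cells).
#' @param r_band plausibility band for the correlation coefficient.
#' @return A list of class `channel_scaling` with `slope`, `intercept`,
#'   `r`, `n_cells`, `flagged`.
#' @export
fit_channel_scaling <- function(green, red, r_band = c(0.5, 1)) {
  if (length(green) != length(red)) {
    stop("green and red must have equal length", call. = FALSE)
  }
  if (length(green) < 20) {
    stop("need >= 20 positive cells to fit channel scaling", call. = FALSE)
  }
  if (stats::var(red) == 0 || stats::var(green) == 0) {
    stop("degenerate channel variance: unusable disc", call. = FALSE)
  }
  fit <- stats::lm(green ~ red)
  r <- stats::cor(green, red)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = r, n_cells = length(green),
         flagged = r < r_band[1] | r > r_band[2]),
    class = "channel_scaling"
  )
}

#' Scale the red channel and total the two channels
#'
#' Applies the per-disc channel scaling to each cell's red value
#' (`scaled_red = slope * red + intercept`) and sums it with the green
#' value to obtain total output per cell in green-channel units.
#'
#' @param green,red background-subtracted channel values (positive cells).
#' @param scaling a [fit_channel_scaling()] object.
#' @return data.frame with `green`, `red`, `scaled_red`, `total_rfu`.
#' @export
scale_and_total <- function(green, red, scaling) {
  stopifnot(inherits(scaling, "channel_scaling"))
  scaled_red <- scaling$slope * red + scaling$intercept
  data.frame(green = green, red = red, scaled_red = scaled_red,
             total_rfu = green + scaled_red)
}

#' Fluorescence-to-molecule conversion calibration
#'
#' Stores the FCS-derived conversion between relative fluorescence units
#' and absolute numbers: by default 1 RFU corresponds to 10 nM, and with
#' a wing-disc nuclear volume of 23 fL that is ~138 molecules per RFU
#' (`10e-9 mol/L * 23e-15 L * Avogadro`).
#'
#' @param nM_per_rfu concentration per RFU (default 10 nM).
#' @param nuclear_volume nuclear volume in liters (default 23e-15).
#' @return A list of class `conversion_calibration` with `nM_per_rfu`,
#'   `nuclear_volume`, `molecules_per_rfu`.
#' @export
#' @examples
#' conversion_calibration()$molecules_per_rfu # ~138.5
conversion_calibration <- function(nM_per_rfu = 10, nuclear_volume = 23e-15) {
  stopifnot(nM_per_rfu > 0, nuclear_volume > 0)
  avogadro <- 6.022e23
  structure(
    list(nM_per_rfu = nM_per_rfu, nuclear_volume = nuclear_volume,
         avogadro = avogadro,
         molecules_per_rfu = nM_per_rfu * 1e-9 * nuclear_volume * avogadro),
    class = "conversion_calibration"
  )
}

#' Convert RFU to concentration and molecule numbers
#'
#' @param rfu non-negative fluorescence values.
#' @param calib a [conversion_calibration()] (default calibration if
#'   omitted).
#' @return data.frame with `rfu`, `nM`, `molecules` (unrounded; round only
#'   at presentation).
#' @export
#' @examples
#' rfu_to_molecules(1) # ~10 nM, ~138 molecules
rfu_to_molecules <- function(rfu, calib = conversion_calibration()) {
  stopifnot(inherits(calib, "conversion_calibration"))
  if (any(!is.finite(rfu)) || any(rfu < 0)) {
    stop("rfu must be finite and >= 0", call. = FALSE)
  }
  data.frame(rfu = rfu,
             nM = rfu * calib$nM_per_rfu,
             molecules = rfu * calib$molecules_per_rfu)
}

#' Fold change in protein output from per-disc channel slopes
#'
#' The microRNA de-repression assay: each disc of a genotype yields one
#' channel-scaling slope, and the fold difference in per-allele protein
#' output between two genotypes is the ratio of their mean slopes,
#' `fold = mean(slopes_a) / mean(slopes_b)`, with the standard error
#' propagated from the relative errors of the two means:
#' `SE_fold/fold = sqrt((SE_a/mean_a)^2 + (SE_b/mean_b)^2)`.
#'
#' @param slopes_a,slopes_b per-disc slopes for the two genotypes
#'   (>= 3 discs each).
#' @return A list with `fold`, `se`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
repression_fold <- function(slopes_a, slopes_b) {
  if (length(slopes_a) < 3 || length(slopes_b) < 3) {
    stop("need >= 3 discs per genotype", call. = FALSE)
  }
  ma <- mean(slopes_a); mb <- mean(slopes_b)
  if (ma == 0 || mb == 0) {
    stop("zero mean slope: fold change undefined", call. = FALSE)
  }
  se_a <- stats::sd(slopes_a) / sqrt(length(slopes_a))
  se_b <- stats::sd(slopes_b) / sqrt(length(slopes_b))
  fold <- ma / mb
  list(fold = fold,
       se = abs(fold) * sqrt((se_a / ma)^2 + (se_b / mb)^2),
       mean_a = ma, mean_b = mb,
       n_a = length(slopes_a), n_b = length(slopes_b))
}

#' Quantify one disc table end to end
#'
#' Convenience wrapper chaining [fit_background()] (per channel),
#' [classify_and_subtract()], [fit_channel_scaling()] and
#' [scale_and_total()] for a single disc, returning the augmented cell
#' table and the per-disc fits.
#'
#' @param disc data.frame with columns `green_rfu`, `red_rfu`.
#' @param calib optional [conversion_calibration()]; if supplied, a
#'   `total_molecules` column is added.
#' @return A list with `cells` (augmented table; positives carry
#'   `scaled_red` and `total_rfu`), `background` (per-channel fits),
#'   `scaling`.
#' @export
quantify_disc <- function(disc, calib = NULL) {
  fg <- fit_background(disc$green_rfu)
  fr <- fit_background(disc$red_rfu)
  cells <- classify_and_subtract(disc, fg, fr)
  pos <- cells$positive
  scaling <- fit_channel_scaling(cells$green_sub[pos], cells$red_sub[pos])
  cells$scaled_red <- NA_real_
  cells$total_rfu <- NA_real_
  st <- scale_and_total(cells$green_sub[pos], cells$red_sub[pos], scaling)
  cells$scaled_red[pos] <- st$scaled_red
  cells$total_rfu[pos] <- st$total_rfu
  if (!is.null(calib)) {
    cells$total_molecules <- NA_real_
    cells$total_molecules[pos] <-
      cells$total_rfu[pos] * calib$molecules_per_rfu
  }
  list(cells = cells, background = list(green = fg, red = fr),
       scaling = scaling)
}
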