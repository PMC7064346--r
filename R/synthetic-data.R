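# Seeded generators for every input the pipeline consumes, with the
# generating truth recorded, so all stages are testable without any
# external data. The disc generator emulates segmented-cell fluorescence
# tables from a wing imaginal disc: a Gaussian background population plus
# expression-positive cells laid out in two stripes flanking a boundary,
# whose two-allele protein counts come from the stochastic two-state model
# with the promoter activation rate graded by distance from the boundary
# (a stand-in for the Wg signaling gradient), read out through per-channel
# gains and multiplicative (log-normal) measurement noise.

#' Configuration for synthetic disc tables
#'
#' @param n_cells segmented cells per disc (default 1000).
#' @param positive_fraction fraction of expression-positive cells
#'   (default 0.30, the typical positive fraction of a quantified disc).
#' @param bg_green,bg_red background mean and sd per channel, RFU.
#' @param kinetic_base [kinetic_params()] providing all rates except
#'   `kon`, which is graded (its value in `kinetic_base` is ignored when
#'   a gradient is active).
#' @param kinetic_base_b optional second-allele parameters (defaults to
#'   `kinetic_base`; used e.g. for repression-assay genotypes where one
#'   allele translates faster).
#' @param kon_range `c(low, high)` of the promoter activation gradient
#'   (1/min), interpolated log-linearly from the stripe edge nearest the
#'   boundary (high) to the far edge (low). Use `c(v, v)` for a flat
#'   field.
#' @param measurement_cv per-channel multiplicative measurement noise CV
#'   (default 0.10, matched to the tandem-tag decorrelation scale).
#' @param channel_gain green-channel gain, RFU per molecule (default
#'   1/138.5, the inverse of the default molecules-per-RFU calibration).
#' @param true_slope,true_intercept generating channel scaling: a cell
#'   with equal allele outputs satisfies
#'   `green_signal = true_slope * red_signal + true_intercept`.
#' @param t_end simulated time per allele (min).
#' @param image_px image side length (pixels); `boundary_px` the boundary
#'   row; stripes of width `stripe_width_px` start `stripe_gap_px` from
#'   the boundary on both sides.
#' @param stripe_gap_px,stripe_width_px stripe layout, pixels.
#' @return A list of class `disc_sim_config`.
#' @export
disc_sim_config <- function(n_cells = 1000,
                            positive_fraction = 0.30,
                            bg_green = c(mean = 0.5, sd = 0.05),
                            bg_red = c(mean = 0.6, sd = 0.06),
                            kinetic_base = kinetic_params(
                              kon = 1, koff = 0.125, Sm = 0.5, Sp = 0.5,
                              Dm = 0.0462, Dp = 0.01),
                            kinetic_base_b = NULL,
                            kon_range = c(0.025, 10),
                            measurement_cv = 0.10,
                            channel_gain = 1 / 138.5,
                            true_slope = 1.2,
                            true_intercept = 0,
                            t_end = 300,
                            image_px = 512,
                            stripe_gap_px = 10,
                            stripe_width_px = 60) {
  if (positive_fraction < 0 || positive_fraction > 1) {
    stop("positive_fraction must be in [0, 1]", call. = FALSE)
  }
  if (channel_gain <= 0 || true_slope <= 0) {
    stop("gains and true_slope must be > 0", call. = FALSE)
  }
  if (measurement_cv < 0) stop("measurement_cv must be >= 0", call. = FALSE)
  stopifnot(inherits(kinetic_base, "kinetic_params"))
  if (is.null(kinetic_base_b)) kinetic_base_b <- kinetic_base
  stopifnot(inherits(kinetic_base_b, "kinetic_params"))
  structure(
    list(n_cells = n_cells, positive_fraction = positive_fraction,
         bg_green = bg_green, bg_red = bg_red,
         kinetic_base = kinetic_base, kinetic_base_b = kinetic_base_b,
         kon_range = kon_range, measurement_cv = measurement_cv,
         channel_gain = channel_gain, true_slope = true_slope,
         true_intercept = true_intercept, t_end = t_end,
         image_px = image_px, stripe_gap_px = stripe_gap_px,
         stripe_width_px = stripe_width_px),
    class = "disc_sim_config"
  )
}

# log-normal multiplicative noise with unit mean-log and given CV
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

# kon graded log-linearly by distance from the boundary
kon_at_distance <- function(d, config) {
  d0 <- config$stripe_gap_px
  d1 <- config$stripe_gap_px + config$stripe_width_px
  f <- pmin(pmax((d - d0) / (d1 - d0), 0), 1)
  exp(log(config$kon_range[2]) + f *
        (log(config$kon_range[1]) - log(config$kon_range[2])))
}

sim_one_count <- function(p, kon, t_end) {
  ssa_batch_cpp(kon, p$koff, p$Sm, p$Sp, p$Dm, p$Dp, p$nG_total,
                t_end, p$promoter_on, 1L)[1, "nP"]
}

#' Generate synthetic dual-allele disc tables
#'
#' Produces per-cell fluorescence tables mimicking segmented wing-disc
#' nuclei, together with the full generating truth. Background cells draw
#' Gaussian intensities in both channels; positive cells live in two
#' stripes flanking the boundary, their two allele protein counts are
#' simulated from the two-state model with `kon` graded by distance from
#' the boundary, converted to RFU through the channel gains and the true
#' channel scaling, degraded by log-normal measurement noise, and added
#' to a background draw.
#'
#' @param config a [disc_sim_config()].
#' @param n_discs number of discs (default 1).
#' @param seed integer seed; the same seed and config give identical
#'   tables.
#' @return A list with `cells` (data.frame: `cell_id`, `disc_id`, `x_px`,
#'   `y_px`, `green_rfu`, `red_rfu`) and `truth` (data.frame with
#'   per-cell `positive`, `kon`, `protein_a`, `protein_b`, plus the
#'   config and seed as attributes).
#' @export
make_disc_tables <- function(config, n_discs = 1, seed = NULL) {
  stopifnot(inherits(config, "disc_sim_config"))
  with_seed(seed, {
    discs <- lapply(seq_len(n_discs), function(d) make_one_disc(config, d))
    cells <- do.call(rbind, lapply(discs, `[[`, "cells"))
    truth <- do.call(rbind, lapply(discs, `[[`, "truth"))
    attr(truth, "config") <- config
    attr(truth, "seed") <- seed
    list(cells = cells, truth = truth)
  })
}

make_one_disc <- function(config, disc_id) {
  n_pos <- round(config$n_cells * config$positive_fraction)
  n_bg <- config$n_cells - n_pos
  half <- config$image_px / 2

  # background cells anywhere in the field
  bg <- data.frame(
    x_px = stats::runif(n_bg, 1, config$image_px),
    y_px = stats::runif(n_bg, 1, config$image_px),
    green_rfu = pmax(stats::rnorm(n_bg, config$bg_green["mean"],
                                  config$bg_green["sd"]), 0),
    red_rfu = pmax(stats::rnorm(n_bg, config$bg_red["mean"],
                                config$bg_red["sd"]), 0)
  )
  bg$positive <- FALSE
  bg$kon <- NA_real_
  bg$protein_a <- NA_real_
  bg$protein_b <- NA_real_

  # positive cells in two stripes flanking the boundary
  d <- stats::runif(n_pos, config$stripe_gap_px,
                    config$stripe_gap_px + config$stripe_width_px)
  side <- sample(c(-1, 1), n_pos, replace = TRUE)
  kon <- kon_at_distance(d, config)
  pa <- vapply(kon, function(k)
    sim_one_count(config$kinetic_base, k, config$t_end), numeric(1))
  pb <- vapply(kon, function(k)
    sim_one_count(config$kinetic_base_b, k, config$t_end), numeric(1))

  g_sig <- pa * config$channel_gain * ln_noise(n_pos, config$measurement_cv)
  r_sig <- pmax(pb * config$channel_gain - config$true_intercept, 0) /
    config$true_slope * ln_noise(n_pos, config$measurement_cv)

  pos <- data.frame(
    x_px = stats::runif(n_pos, 1, config$image_px),
    y_px = half + side * d,
    green_rfu = pmax(stats::rnorm(n_pos, config$bg_green["mean"],
                                  config$bg_green["sd"]), 0) + g_sig,
    red_rfu = pmax(stats::rnorm(n_pos, config$bg_red["mean"],
                                config$bg_red["sd"]), 0) + r_sig,
    positive = TRUE, kon = kon, protein_a = pa, protein_b = pb
  )

  all <- rbind(bg, pos)
  ord <- sample.int(nrow(all)) # shuffle so positives are not contiguous
  all <- all[ord, ]
  all$cell_id <- seq_len(nrow(all))
  all$disc_id <- disc_id
  list(
    cells = all[, c("cell_id", "disc_id", "x_px", "y_px",
                    "green_rfu", "red_rfu")],
    truth = all[, c("cell_id", "disc_id", "positive", "kon",
                    "protein_a", "protein_b")]
  )
}

#' Generate synthetic tandem-tag control tables
#'
#' Emulates the tandem-tagged control in which both fluorophores sit on
#' the same protein: each positive cell has one underlying molecule count
#' (by default the summed output of both alleles, i.e. a two-allele gene
#' dose, which doubles the per-channel median relative to the allelic
#' configuration) and both channels read that single count through
#' independent measurement noise. Any decorrelation between the channels
#' is therefore pure measurement noise.
#'
#' @inheritParams make_disc_tables
#' @param doubling logical; read the two-allele total (default `TRUE`).
#' @return As [make_disc_tables()]; `truth` carries the underlying count
#'   in both `protein_a` and `protein_b`.
#' @export
make_tandem_tables <- function(config, n_discs = 1, seed = NULL,
                               doubling = TRUE) {
  stopifnot(inherits(config, "disc_sim_config"))
  with_seed(seed, {
    discs <- lapply(seq_len(n_discs), function(d) {
      one <- make_one_disc(config, d)
      pos <- one$truth$positive
      total <- if (doubling) {
        one$truth$protein_a[pos] + one$truth$protein_b[pos]
      } else {
        one$truth$protein_a[pos]
      }
      n_pos <- sum(pos)
      g_sig <- total * config$channel_gain *
        ln_noise(n_pos, config$measurement_cv)
      r_sig <- pmax(total * config$channel_gain - config$true_intercept,
                    0) / config$true_slope *
        ln_noise(n_pos, config$measurement_cv)
      one$cells$green_rfu[pos] <-
        pmax(stats::rnorm(n_pos, config$bg_green["mean"],
                          config$bg_green["sd"]), 0) + g_sig
      one$cells$red_rfu[pos] <-
        pmax(stats::rnorm(n_pos, config$bg_red["mean"],
                          config$bg_red["sd"]), 0) + r_sig
      one$truth$protein_a[pos] <- total
      one$truth$protein_b[pos] <- total
      one
    })
    cells <- do.call(rbind, lapply(discs, `[[`, "cells"))
    truth <- do.call(rbind, lapply(discs, `[[`, "truth"))
    attr(truth, "config") <- config
    attr(truth, "seed") <- seed
    list(cells = cells, truth = truth)
  })
}

#' Generate synthetic decay time courses
#'
#' `level(t) = exp(-rate * t) * lognormal(cv)`, renormalized so the t = 0
#' point is exactly 1, as in a ratio-normalized qPCR or ELISA decay
#' assay.
#'
#' @param rate decay rate (> 0, 1/time-unit).
#' @param timepoints sampling times (default `c(0, 10, 20, 30)`).
#' @param noise_cv multiplicative noise CV (default 0.03).
#' @param n_replicates number of independent courses.
#' @param seed integer seed or `NULL`.
#' @return data.frame with `replicate`, `time`, `level`.
#' @export
make_decay_course <- function(rate, timepoints = c(0, 10, 20, 30),
                              noise_cv = 0.03, n_replicates = 1,
                              seed = NULL) {
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  with_seed(seed, {
    out <- lapply(seq_len(n_replicates), function(r) {
      lv <- exp(-rate * timepoints) * ln_noise(length(timepoints), noise_cv)
      data.frame(replicate = r, time = timepoints, level = lv / lv[1])
    })
    do.call(rbind, out)
  })
}

#' Generate a synthetic wing-count population
#'
#' Bernoulli wings: `n_mispatterned ~ Binomial(n_wings, p_error)`.
#'
#' @param p_error per-wing mispatterning probability.
#' @param n_wings wings scored.
#' @param seed integer seed or `NULL`.
#' @return A list with `n_wings`, `n_mispatterned`, `p_error`.
#' @export
make_wing_population <- function(p_error, n_wings, seed = NULL) {
  if (p_error < 0 || p_error > 1) stop("p_error must be in [0, 1]",
                                       call. = FALSE)
  with_seed(seed, {
    list(n_wings = n_wings,
         n_mispatterned = stats::rbinom(1, n_wings, p_error),
         p_error = p_error)
  })
}

#' Generate a synthetic FCS autocorrelation curve
#'
#' Evaluates the two-component diffusion model on a lag grid and applies
#' multiplicative noise; the CPM and an intensity trace can be attached
#' for QC-rule tests.
#'
#' @param params an [fcs_params()] object.
#' @param lags lag times (ms); default a log grid from 1e-3 to 1e3.
#' @param noise_cv multiplicative noise CV on G (default 0).
#' @param seed integer seed or `NULL`.
#' @param cpm optional counts-per-molecule value to attach.
#' @param intensity_trace optional intensity trace to attach.
#' @return A list with `lags`, `G`, `cpm`, `intensity_trace`, `params`.
#' @export
make_acf_curve <- function(params, lags = 10^seq(-3, 3, length.out = 120),
                           noise_cv = 0, seed = NULL, cpm = NULL,
                           intensity_trace = NULL) {
  stopifnot(inherits(params, "fcs_params"))
  with_seed(seed, {
    G <- model_acf(params, lags) * ln_noise(length(lags), noise_cv)
    list(lags = lags, G = G, cpm = cpm,
         intensity_trace = intensity_trace, params = params)
  })
}
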