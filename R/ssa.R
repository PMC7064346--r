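#' Simulate one allele of the two-state gene expression model
#'
#' Runs Gillespie's stochastic simulation algorithm for a single allele:
#' promoter activation/inactivation, transcription, mRNA decay,
#' translation and protein decay, starting from zero mRNA and protein
#' with the promoter state given by `params$promoter_on`. Identical seeds
#' give bit-identical trajectories.
#'
#' @param params a [kinetic_params()] object.
#' @param t_end simulated time (minutes); default 300 min, roughly five
#'   protein half-lives at the default `Dp = 0.01`/min.
#' @param seed integer seed, or `NULL` to use (and advance) the current
#'   RNG state.
#' @param record_trajectory logical; if `TRUE` the full event trajectory
#'   `(t, nG_on, nM, nP)` is returned as a matrix attribute-free component.
#'
#' @return A list with final counts `nG_on`, `nM`, `nP`, the end time `t`,
#'   and (optionally) `trajectory`.
#' @export
#' @examples
#' p <- constitutive_params(Sm = 0.5, Sp = 0.5, Dm = 0.0462, Dp = 0.01)
#' simulate_allele(p, t_end = 60, seed = 1)[c("nM", "nP")]
simulate_allele <- function(params, t_end = 300, seed = NULL,
                            record_trajectory = FALSE) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.finite(t_end) || t_end <= 0) {
    stop("t_end must be a positive, finite time", call. = FALSE)
  }
  with_seed(seed, {
    ssa_allele_cpp(params$kon, params$koff, params$Sm, params$Sp,
                   params$Dm, params$Dp, params$nG_total, t_end,
                   params$promoter_on, record_trajectory)
  })
}

#' Simulate independent allele pairs
#'
#' Simulates `n_pairs` alleles under `params_a` and `n_pairs` under
#' `params_b`, each as an independent realisation of the two-state model,
#' and pairs them by a seeded random permutation to mimic two independent
#' alleles in the same cell.
#'
#' @param params_a,params_b [kinetic_params()] for the two alleles. Pass
#'   the same object for identical alleles.
#' @param n_pairs number of simulated cells (default 5000).
#' @inheritParams simulate_allele
#' @param param_tag optional label stored in the `param_tag` column.
#'
#' @return A data.frame with columns `pair_id`, `protein_a`, `protein_b`,
#'   `mrna_a`, `mrna_b`, `param_tag`.
#' @export
#' @examples
#' p <- constitutive_params(0.5, 0.5, 0.0462, 0.01)
#' head(simulate_pairs(p, p, n_pairs = 5, t_end = 30, seed = 1))
simulate_pairs <- function(params_a, params_b = params_a, n_pairs = 5000,
                           t_end = 300, seed = NULL, param_tag = NA_character_) {
  stopifnot(inherits(params_a, "kinetic_params"),
            inherits(params_b, "kinetic_params"))
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) {
    stop("n_pairs must be >= 1", call. = FALSE)
  }
  if (!is.finite(t_end) || t_end <= 0) {
    stop("t_end must be a positive, finite time", call. = FALSE)
  }
  with_seed(seed, {
    a <- ssa_batch_cpp(params_a$kon, params_a$koff, params_a$Sm, params_a$Sp,
                       params_a$Dm, params_a$Dp, params_a$nG_total, t_end,
                       params_a$promoter_on, n_pairs)
    b <- ssa_batch_cpp(params_b$kon, params_b$koff, params_b$Sm, params_b$Sp,
                       params_b$Dm, params_b$Dp, params_b$nG_total, t_end,
                       params_b$promoter_on, n_pairs)
    perm <- sample.int(n_pairs) # random pairing wrt simulation order
    data.frame(
      pair_id = seq_len(n_pairs),
      protein_a = a[, "nP"],
      protein_b = b[perm, "nP"],
      mrna_a = a[, "nM"],
      mrna_b = b[perm, "nM"],
      param_tag = param_tag
    )
  })
}

#' Simulate trans-inhibited allele pairs
#'
#' Simulates each cell as one coupled Markov process over both alleles
#' (up to 12 propensities). While any gene copy of one allele is in the
#' 'on' state, the partner allele's activation propensity is reduced to
#' `kon * (1 - phi)`; the inhibition is mutual. The state dependence lives
#' in the propensity function, so the simulation remains exact.
#' `phi = 0` reduces to two independent alleles.
#'
#' @param params a [kinetic_params()] object shared by both alleles.
#' @param phi inhibition fraction in \[0, 1\].
#' @inheritParams simulate_pairs
#' @param keep_promoter logical; if `TRUE`, final promoter on-counts are
#'   attached as columns `gon_a`, `gon_b` (used by promoter-occupancy
#'   diagnostics).
#'
#' @return A data.frame as from [simulate_pairs()].
#' @export
simulate_trans_inhibited_pairs <- function(params, phi, n_pairs = 5000,
                                           t_end = 300, seed = NULL,
                                           param_tag = NA_character_,
                                           keep_promoter = FALSE) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.finite(phi) || phi < 0 || phi > 1) {
    stop("phi must lie in [0, 1]", call. = FALSE)
  }
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) {
    stop("n_pairs must be >= 1", call. = FALSE)
  }
  with_seed(seed, {
    res <- ssa_pair_coupled_cpp(params$kon, params$koff, params$Sm,
                                params$Sp, params$Dm, params$Dp,
                                params$nG_total, phi, t_end,
                                params$promoter_on, n_pairs)
    cnt <- res$counts
    out <- data.frame(
      pair_id = seq_len(n_pairs),
      protein_a = cnt[, "protein_a"],
      protein_b = cnt[, "protein_b"],
      mrna_a = cnt[, "mrna_a"],
      mrna_b = cnt[, "mrna_b"],
      param_tag = param_tag
    )
    if (keep_promoter) {
      out$gon_a <- res$promoter_on[, 1]
      out$gon_b <- res$promoter_on[, 2]
    }
    out
  })
}

#' Parameter sweep of paired simulations
#'
#' Varies one transcriptional parameter (`kon`, `koff` or `Sm`) across a
#' range of values, simulating paired alleles at each value (both alleles
#' of a pair always share the swept value) and pooling all pairs into one
#' population suitable for binned Fano profiling.
#'
#' Spacing defaults to logarithmic because the sweeps of interest span
#' orders of magnitude (e.g. `kon` from 0.025 to 10/min); linear spacing
#' leaves the low-activity regime nearly unsampled. The spacing used is
#' recorded in the output attributes.
#'
#' @param base a [kinetic_params()] object providing the fixed rates.
#' @param parameter one of `"kon"`, `"koff"`, `"Sm"`.
#' @param low,high sweep range (units of the swept rate).
#' @param n_values number of sweep values (default 20).
#' @param pairs_per_value simulated pairs per value (default 5000).
#' @param spacing `"log"` (default) or `"linear"`.
#' @param phi optional trans-inhibition fraction applied at every sweep
#'   value (default 0 = independent alleles).
#' @inheritParams simulate_allele
#'
#' @return A data.frame of pooled pairs with columns `pair_id`,
#'   `param_name`, `param_value`, `protein_a`, `protein_b`, `mrna_a`,
#'   `mrna_b`; attributes `spacing` and `values` record the sweep grid.
#' @export
sweep_pairs <- function(base, parameter = c("kon", "koff", "Sm"),
                        low, high, n_values = 20, pairs_per_value = 5000,
                        spacing = c("log", "linear"), t_end = 300,
                        seed = NULL, phi = 0) {
  stopifnot(inherits(base, "kinetic_params"))
  parameter <- match.arg(parameter)
  spacing <- match.arg(spacing)
  if (n_values < 2) stop("n_values must be >= 2", call. = FALSE)
  if (spacing == "log" && low <= 0) {
    stop("low must be > 0 for log spacing", call. = FALSE)
  }
  values <- if (spacing == "log") {
    exp(seq(log(low), log(high), length.out = n_values))
  } else {
    seq(low, high, length.out = n_values)
  }
  with_seed(seed, {
    chunks <- lapply(values, function(v) {
      p <- base
      p[[parameter]] <- v
      class(p) <- "kinetic_params"
      d <- if (phi > 0) {
        simulate_trans_inhibited_pairs(p, phi, n_pairs = pairs_per_value,
                                       t_end = t_end)
      } else {
        simulate_pairs(p, p, n_pairs = pairs_per_value, t_end = t_end)
      }
      d$param_name <- parameter
      d$param_value <- v
      d
    })
    out <- do.call(rbind, chunks)
    out$pair_id <- seq_len(nrow(out))
    out <- out[, c("pair_id", "param_name", "param_value",
                   "protein_a", "protein_b", "mrna_a", "mrna_b")]
    attr(out, "spacing") <- spacing
    attr(out, "values") <- values
    attr(out, "phi") <- phi
    out
  })
}

#' Steady-state diagnostic for a long trajectory
#'
#' Simulates one long trajectory and compares the time-average of mRNA
#' and protein over the last fraction of the run against the closed-form
#' constitutive means. Intended as a convergence diagnostic for choices
#' of `t_end`.
#'
#' @inheritParams simulate_allele
#' @param tail_fraction fraction of the trajectory to average over
#'   (default 0.1).
#' @return A data.frame with observed time-averaged and predicted means.
#' @export
steady_state_check <- function(params, t_end = 3000, seed = NULL,
                               tail_fraction = 0.1) {
  res <- simulate_allele(params, t_end = t_end, seed = seed,
                         record_trajectory = TRUE)
  traj <- res$trajectory
  t0 <- t_end * (1 - tail_fraction)
  keep <- which(traj[, "t"] >= t0)
  if (length(keep) < 2) stop("trajectory too short for diagnostic",
                             call. = FALSE)
  # time-weighted average over piecewise-constant segments
  idx <- keep[-length(keep)]
  dt <- diff(traj[keep, "t"])
  w <- dt / sum(dt)
  obs_m <- sum(traj[idx, "nM"] * w)
  obs_p <- sum(traj[idx, "nP"] * w)
  ss <- constitutive_steady_state(params)
  p_on <- promoter_on_fraction(params)
  data.frame(
    quantity = c("mrna", "protein"),
    observed = c(obs_m, obs_p),
    predicted = as.numeric(ss * p_on)
  )
}

# Run an expression under a temporary seed without disturbing the caller's
# RNG stream when seed is NULL.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
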