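# Kinetic rate-constant estimation: exponential decay fits for the mRNA
# and protein decay rates, and the algebra linking the translation burst
# size b = Sp/(Dm + Dp) to the constant-regime Fano factor 1 + b.

#' Fit an exponential decay to a normalized time course
#'
#' Nonlinear least-squares fit of `level = A * exp(-k * t)`. The amplitude
#' `A` is left free by default: time courses are ratio-normalized and the
#' t = 0 point need not be exactly 1. Starting values come from a
#' log-linear regression. A fixed-amplitude (`A = 1`) variant is available
#' via `fix_amplitude`.
#'
#' @param times time points (strictly increasing, >= 3).
#' @param levels normalized abundances (> 0, `level(0)` near 1).
#' @param fix_amplitude logical; fit with `A` fixed at 1.
#' @return A list of class `decay_fit` with `rate`, `half_life`
#'   (`log(2)/rate`), `amplitude`, `r_squared`, `flagged` (TRUE when the
#'   fitted rate is not positive).
#' @export
#' @examples
#' t <- c(0, 10, 20, 30)
#' fit_exponential(t, exp(-0.0462 * t))$rate # 0.0462
fit_exponential <- function(times, levels, fix_amplitude = FALSE) {
  if (length(times) != length(levels) || length(times) < 3) {
    stop("need >= 3 matched (time, level) points", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(levels <= 0)) stop("levels must be > 0", call. = FALSE)
  ll <- stats::lm(log(levels) ~ times)
  k0 <- -unname(stats::coef(ll)[2])
  a0 <- exp(unname(stats::coef(ll)[1]))
  dat <- data.frame(t = times, y = levels)
  fit <- if (fix_amplitude) {
    minpack.lm::nlsLM(y ~ exp(-k * t), data = dat,
                      start = list(k = max(k0, 1e-8)))
  } else {
    minpack.lm::nlsLM(y ~ A * exp(-k * t), data = dat,
                      start = list(A = a0, k = k0))
  }
  co <- stats::coef(fit)
  k <- unname(co["k"])
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((levels - mean(levels))^2)
  structure(
    list(rate = k,
         half_life = log(2) / k,
         amplitude = if (fix_amplitude) 1 else unname(co["A"]),
         r_squared = r2,
         flagged = !is.finite(k) || k <= 0),
    class = "decay_fit"
  )
}

#' Translation burst size from post-transcriptional rates
#'
#' Average number of proteins made per mRNA over its lifetime,
#' `b = Sp / (Dm + Dp)`.
#'
#' @param Sp translation rate (protein/mRNA/min).
#' @param Dm,Dp mRNA and protein decay rates (1/min); `Dm + Dp > 0`.
#' @return Burst size `b` (dimensionless).
#' @export
#' @examples
#' burst_size_post(Sp = 0.5, Dm = 0.0462, Dp = 0.002) # ~10.4
burst_size_post <- function(Sp, Dm, Dp) {
  if (Dm + Dp <= 0) stop("Dm + Dp must be > 0", call. = FALSE)
  if (Sp < 0) stop("Sp must be >= 0", call. = FALSE)
  Sp / (Dm + Dp)
}

#' Fano factors implied by a translation burst size
#'
#' In the constant (promoter non-limiting) regime the per-allele protein
#' Fano factor is `1 + b`; because variance is additive over independent
#' alleles, the cumulative two-allele statistic is `2 * (1 + b)`.
#'
#' @param b translation burst size (>= 0).
#' @return A list with `b`, `fano_single`, `fano_cumulative`.
#' @export
#' @examples
#' fano_from_burst(9)   # single 10, cumulative 20
fano_from_burst <- function(b) {
  if (b < 0) stop("b must be >= 0", call. = FALSE)
  list(b = b, fano_single = 1 + b, fano_cumulative = 2 * (1 + b))
}

#' Infer the translation rate from a constant-regime Fano factor
#'
#' Inverts `Fano = 1 + Sp/(Dm + Dp)`:
#' `Sp = (fano_single - 1) * (Dm + Dp)`.
#'
#' @param fano_single per-allele Fano factor (>= 1).
#' @inheritParams burst_size_post
#' @return Sp (protein/mRNA/min).
#' @export
#' @examples
#' infer_Sp(10, Dm = 0.0462, Dp = 0.002) # ~0.43, i.e. ~0.5
infer_Sp <- function(fano_single, Dm, Dp) {
  if (fano_single < 1) {
    stop("fano_single < 1 is sub-Poissonian and outside this model",
         call. = FALSE)
  }
  if (Dm + Dp <= 0) stop("Dm + Dp must be > 0", call. = FALSE)
  (fano_single - 1) * (Dm + Dp)
}
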