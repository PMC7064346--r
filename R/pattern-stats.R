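# Adult-wing pattern disorder statistics: mispatterning proportions,
# odds ratios on 2x2 tables with an exact test, and chemosensory bristle
# spacing/density with bootstrap confidence intervals.

#' Mispatterning frequency of a genotype
#'
#' Proportion of scored wings with at least one ectopic mechanosensory
#' bristle.
#'
#' @param n_mispatterned wings with >= 1 ectopic bristle.
#' @param n_wings total wings scored (> 0).
#' @return Proportion in \[0, 1\].
#' @export
#' @examples
#' mispattern_frequency(23, 79) # 0.291
mispattern_frequency <- function(n_mispatterned, n_wings) {
  if (any(n_wings <= 0)) stop("n_wings must be > 0", call. = FALSE)
  if (any(n_mispatterned < 0) || any(n_mispatterned > n_wings)) {
    stop("0 <= n_mispatterned <= n_wings required", call. = FALSE)
  }
  n_mispatterned / n_wings
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (a * d) / (b * c)` for the table
#' \preformatted{ mispatterned normal
#'   genotype 1       a        b
#'   genotype 2       c        d }
#' With any zero cell the OR is undefined; under the default
#' Haldane-Anscombe rule 0.5 is added to every cell and the result is
#' flagged, while `zero_rule = "strict"` signals an error instead.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param zero_rule `"haldane"` (default) or `"strict"`.
#' @return A list with `or`, `corrected` (logical), `cells`.
#' @export
#' @examples
#' odds_ratio(23, 56, 2, 60)$or # 12.3
odds_ratio <- function(a, b, c, d, zero_rule = c("haldane", "strict")) {
  zero_rule <- match.arg(zero_rule)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be >= 0", call. = FALSE)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (zero_rule == "strict") {
      stop("odds ratio undefined with a zero cell (zero_rule = 'strict')",
           call. = FALSE)
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  list(or = (cells["a"] * cells["d"]) / (cells["b"] * cells["c"]),
       corrected = corrected, cells = cells)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value conditional on the table margins: the sum of
#' hypergeometric probabilities of all tables with those margins whose
#' probability does not exceed that of the observed table (the
#' conventional "small-p" rule, as opposed to doubling the one-sided
#' value). Probabilities are compared with a small relative tolerance to
#' absorb floating-point ties.
#'
#' @inheritParams odds_ratio
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact(23, 56, 2, 60) # < 0.005
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  m <- a + b       # row 1 margin
  n <- c + d       # row 2 margin
  k <- a + c       # column 1 margin
  if (m + n == 0 || k == 0 || (b + d) == 0 || m == 0 || n == 0) {
    stop("all margins must be positive", call. = FALSE)
  }
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

#' Chemosensory bristle density with a bootstrap confidence interval
#'
#' Density is the inverse of the mean Euclidean distance between
#' successive bristles along the wing margin. A percentile bootstrap over
#' resampled distance sets gives the 95% CI.
#'
#' @param distances distances between successive bristles (> 0, >= 5).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed or `NULL`.
#' @return A list with `density`, `ci_low`, `ci_high`, `mean_spacing`,
#'   `n`.
#' @export
bristle_density <- function(distances, n_boot = 10000, seed = NULL) {
  if (length(distances) < 5) stop("need >= 5 distances", call. = FALSE)
  if (any(distances <= 0)) stop("distances must be > 0", call. = FALSE)
  dens <- 1 / mean(distances)
  with_seed(seed, {
    boot <- replicate(n_boot, {
      1 / mean(sample(distances, replace = TRUE))
    })
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
    list(density = dens,
         ci_low = min(ci[1], dens), ci_high = max(ci[2], dens),
         mean_spacing = mean(distances), n = length(distances))
  })
}
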