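#' Kinetic parameters of the two-state gene expression model
#'
#' Bundles the six rate constants of the telegraph (two-state promoter)
#' model of gene expression plus the gene copy number per allele. The
#' promoter toggles between an inactive and an active state with rates
#' `kon` and `koff`; active gene copies transcribe at `Sm`, mRNAs are
#' translated at `Sp` and decay at `Dm`, proteins decay at `Dp`.
#'
#' @param kon promoter activation rate (1/min).
#' @param koff promoter inactivation rate (1/min). `koff = 0` together with
#'   `promoter_on = TRUE` represents a permanently active (constitutive)
#'   promoter.
#' @param Sm transcription rate per active gene copy (mRNA/min).
#' @param Sp translation rate per mRNA (protein/mRNA/min).
#' @param Dm mRNA decay rate (1/min).
#' @param Dp protein decay rate (1/min).
#' @param nG_total gene copies per allele (default 1).
#' @param promoter_on logical; initial promoter state. Defaults to `FALSE`
#'   (simulations start silent), but is forced `TRUE` by
#'   [constitutive_params()].
#'
#' @return An object of class `kinetic_params` (a named list).
#' @seealso [constitutive_params()], [simulate_allele()], [burst_size()]
#' @export
#' @examples
#' kinetic_params(kon = 1, koff = 0.125, Sm = 0.5, Sp = 0.5,
#'                Dm = 0.0462, Dp = 0.01)
kinetic_params <- function(kon, koff, Sm, Sp, Dm, Dp, nG_total = 1L,
                           promoter_on = FALSE) {
  rates <- c(kon = kon, koff = koff, Sm = Sm, Sp = Sp, Dm = Dm, Dp = Dp)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  }
  nG_total <- as.integer(nG_total)
  if (is.na(nG_total) || nG_total < 1L) {
    stop("nG_total must be an integer >= 1", call. = FALSE)
  }
  if (koff == 0 && !promoter_on) {
    stop(
      "koff = 0 with an initially silent promoter is an absorbing dead end;",
      " use constitutive_params() for a permanently active promoter",
      call. = FALSE
    )
  }
  structure(
    list(kon = kon, koff = koff, Sm = Sm, Sp = Sp, Dm = Dm, Dp = Dp,
         nG_total = nG_total, promoter_on = isTRUE(promoter_on)),
    class = "kinetic_params"
  )
}

#' Constitutive (permanently active) promoter parameters
#'
#' Convenience constructor for the constitutive limit of the two-state
#' model: `koff = 0` and the promoter initialised in the active state, so
#' the gene transcribes continuously at `Sm`.
#'
#' @inheritParams kinetic_params
#' @return A `kinetic_params` object with `koff = 0` and `promoter_on = TRUE`.
#' @export
#' @examples
#' constitutive_params(Sm = 0.5, Sp = 0.5, Dm = 0.0462, Dp = 0.01)
constitutive_params <- function(Sm, Sp, Dm, Dp, nG_total = 1L) {
  kinetic_params(kon = 0, koff = 0, Sm = Sm, Sp = Sp, Dm = Dm, Dp = Dp,
                 nG_total = nG_total, promoter_on = TRUE)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Two-state gene expression parameters (per allele)\n")
  cat(sprintf("  kon  = %g /min   koff = %g /min\n", x$kon, x$koff))
  cat(sprintf("  Sm   = %g mRNA/min   Sp = %g protein/mRNA/min\n",
              x$Sm, x$Sp))
  cat(sprintf("  Dm   = %g /min   Dp = %g /min\n", x$Dm, x$Dp))
  cat(sprintf("  gene copies = %d, initial promoter %s\n",
              x$nG_total, if (x$promoter_on) "on" else "off"))
  invisible(x)
}

#' Transcriptional burst size
#'
#' Average number of mRNAs made per promoter 'on' period: `Sm / koff`.
#'
#' @param params a [kinetic_params()] object.
#' @return Burst size in mRNA per burst.
#' @export
#' @examples
#' p <- kinetic_params(1, 0.125, 0.5, 0.5, 0.0462, 0.01)
#' burst_size(p)  # 4 mRNA per burst
burst_size <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$koff == 0) {
    stop("burst size is undefined for koff = 0 (constitutive limit)",
         call. = FALSE)
  }
  params$Sm / params$koff
}

#' Transcriptional burst frequency
#'
#' Bursts per minute: the inverse of one full off + on promoter cycle,
#' `(1/kon + 1/koff)^-1`.
#'
#' @inheritParams burst_size
#' @return Burst frequency (1/min).
#' @export
burst_frequency <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$kon == 0 || params$koff == 0) {
    stop("burst frequency is undefined when kon or koff is 0", call. = FALSE)
  }
  1 / (1 / params$kon + 1 / params$koff)
}

#' Constitutive steady-state means
#'
#' Closed-form stationary means for a permanently active promoter:
#' mean mRNA `Sm/Dm` and mean protein `Sm*Sp/(Dm*Dp)` per allele
#' (per gene copy; multiplied by `nG_total`).
#'
#' @inheritParams burst_size
#' @return Named numeric vector `c(mrna = , protein = )`.
#' @export
#' @examples
#' constitutive_steady_state(constitutive_params(0.5, 0.5, 0.0462, 0.01))
constitutive_steady_state <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$Dm <= 0 || params$Dp <= 0) {
    stop("steady state undefined for zero decay rates", call. = FALSE)
  }
  m <- params$nG_total * params$Sm / params$Dm
  c(mrna = m, protein = m * params$Sp / params$Dp)
}

#' Predicted per-allele Fano factor for a constitutive promoter
#'
#' With the promoter permanently on, protein output is a birth-death
#' process with geometric translation bursts of mean size
#' `b = Sp/(Dm + Dp)` and the stationary protein Fano factor is `1 + b`.
#'
#' @inheritParams burst_size
#' @return Per-allele protein Fano factor (molecules).
#' @export
predicted_fano_constitutive <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$Dm + params$Dp <= 0) {
    stop("Dm + Dp must be positive", call. = FALSE)
  }
  1 + params$Sp / (params$Dm + params$Dp)
}

#' Mean active-promoter fraction of the telegraph model
#'
#' Stationary probability that a gene copy is in the 'on' state,
#' `kon/(kon + koff)`. Used mainly as a closed-form oracle for the
#' simulator.
#'
#' @inheritParams burst_size
#' @return Fraction in \[0, 1\].
#' @export
promoter_on_fraction <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$kon + params$koff == 0) {
    return(as.numeric(params$promoter_on))
  }
  if (params$koff == 0) return(1)
  params$kon / (params$kon + params$koff)
}
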