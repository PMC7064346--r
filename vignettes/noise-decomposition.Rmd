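---
title: "Dual-reporter noise decomposition with a two-state promoter model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-reporter noise decomposition with a two-state promoter model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensnoise)
```

## The problem

When the two alleles of a gene are tagged with different fluorophores
(say sfGFP on one, mCherry on the other), every cell carries two
independent reporters of the same regulatory state. Differences between
the two channels in the *same* cell cannot come from cell-to-cell
(extrinsic) variation — they measure the intrinsic stochasticity of
transcription and translation. `sensnoise` implements this
dual-reporter analysis for single-cell fluorescence tables from imaging
of tissues such as the *Drosophila* wing imaginal disc, where the
transcription factor Senseless (Sens) is expressed in two stripes
flanking the dorsoventral boundary under a Wingless (Wg) signalling
gradient, together with a stochastic simulator of the underlying gene
expression model so that every analysis step can be validated on data
with known ground truth.

## The gene expression model

Each allele is modelled as a two-state ("telegraph") promoter with six
first-order events and rate constants:

* promoter activation `kon` and inactivation `koff` (1/min),
* transcription `Sm` (mRNA/min per active gene copy),
* mRNA decay `Dm` (1/min),
* translation `Sp` (protein/mRNA/min),
* protein decay `Dp` (1/min).

`simulate_allele()` runs Gillespie's stochastic simulation algorithm
exactly: waiting times are exponential in the total propensity and the
event is chosen by cumulative-propensity inversion with a fixed event
ordering (activation, inactivation, transcription, mRNA decay,
translation, protein decay). The ordering is part of the
reproducibility contract: a fixed seed yields a bit-identical event
sequence. Simulations start with no mRNA, no protein and the promoter
off; the constitutive limit (`koff = 0`, promoter permanently on) is
only accepted through `constitutive_params()`, which also sets the
initial state to "on", because a silent start with `koff = 0` is an
absorbing dead end.

Useful closed forms (all exposed as functions and used as test
oracles):

* constitutive steady state: mean mRNA `Sm/Dm`, mean protein
  `Sm*Sp/(Dm*Dp)`;
* telegraph mean: the constitutive mean scaled by the active fraction
  `kon/(kon + koff)`;
* transcription burst size `Sm/koff` and burst frequency
  `(1/kon + 1/koff)^-1`;
* translation burst size `b = Sp/(Dm + Dp)` and the constant-regime
  per-allele protein Fano factor `1 + b`.

### Default rate constants

The defaults used throughout the package and its tests are the measured
values for *sens* in the wing disc: `Dm = 0.0462`/min (mRNA half-life
15 min), `Sp = 0.5` protein/mRNA/min (inferred from the constant-regime
Fano factor, below), and a transcription burst size of 4 mRNA
(`Sm = 0.5`, `koff = 0.125`). Protein decay was measured at 0.002/min
(half-life ~5 h), but simulations use `Dp = 0.01`/min: runs last
until steady state, about five times the slowest half-life, and the
noise trends are insensitive to this substitution while the run length
drops five-fold. The default horizon `t_end = 300` min reflects that
choice; `steady_state_check()` compares the time-average of a long
trajectory against the closed forms if you change the rates.

## Cells, pairs and sweeps

`simulate_pairs()` simulates two independent allele batches and pairs
them by a seeded random permutation, mimicking two independent alleles
per cell. `simulate_trans_inhibited_pairs()` instead couples the two
alleles into one Markov process of up to twelve propensities: while one
allele's promoter is on, the partner's activation rate is reduced to
`kon * (1 - phi)` (mutual inhibition, implemented in the propensity
function so the simulation stays exact). `phi = 0` reduces exactly to
independence; the promoter-pair occupancy at `phi > 0` is checked in
the test suite against the exact stationary solution of the four-state
promoter chain.

`sweep_pairs()` varies one of `kon`, `koff`, `Sm` over a grid (both
alleles of a pair always share the swept value) and pools all pairs
into one population — the *in silico* analogue of a signalling gradient
across a tissue. Spacing is logarithmic by default: the interesting
sweeps span two to three orders of magnitude (e.g. `kon` from 0.025 to
10/min), and even spacing on a linear scale leaves the low-activity
regime nearly unsampled. The spacing and grid are recorded as
attributes of the result.

## The noise statistics

For channel outputs `x` and `y` (same units), intrinsic noise is

    eta^2 = <(x - y)^2> / (2 <x> <y>)

and the Fano factor is reported as `eta^2 * mu` with `mu` the mean
*total* output `mean(x + y)` of the (sub)population. Because `mu` is
the two-allele total, this is the *cumulative* Fano factor: for
independent alleles with per-allele Fano `F` it equals `2F` in
expectation (variances add; the tests verify this additivity on
simulated pairs, as well as the scale laws — `eta^2` is scale-free,
Fano scales linearly).

`noise_profile()` bins cells by `log10` of total output and reports
per-bin `mu`, `eta^2`, Fano, and a percentile-bootstrap 95% CI from
within-bin resampling. Defaults follow the experimental convention: bin
width 0.02 log10 units, 50,000 bootstrap resamples (a few thousand is
fine for exploration; tests use hundreds and state so), and a minimum
of 25 cells per bin — variance-type statistics are unstable below
that, and under-populated bins are dropped rather than reported.
Pooled simulation sweeps are conventionally binned into 25–30
equal-width log bins instead; `n_bins` switches to that convention.
The log base (10) is recorded on the profile since bin counts depend
on it.

### Measurement-noise correction

A tandem-tagged control — both fluorophores fused to one protein, so
the two channels read the *same* molecule count — turns residual
channel decorrelation into a direct measurement of measurement noise.
`lowess_model()` fits a locally weighted regression (fixed span,
default 0.3) of Fano on mean output through the control profile;
`subtract_measurement_noise()` subtracts the model's prediction from
each bin of a biological profile, shifting the CI bounds by the same
amount. Outside the fitted support the prediction clamps to the nearest
endpoint. Negative corrected values are kept — the subtraction is
unbiased, and clipping would bias averages — but flagged so summaries
can mask them.

Two caveats the test suite makes explicit. First, the extreme bins of
any pooled binned profile carry selection bias: cells land in the
lowest and highest bins partly *because* their fluctuations pushed them
there, and the bias differs between allelic and tandem constructions.
Quantitative checks therefore run on fine (0.02 log) bins, where
within-bin selection is negligible, or restrict statements to the
central 5–95% of the output distribution. Second, a tandem control
driven by a two-allele gene dose has roughly double the per-channel
output of the allelic configuration (the generator reproduces the
observed ~2.1-fold median ratio); its profile therefore does not cover
the lowest octave of the allelic output range, where the clamped
prediction is an extrapolation.

## From fluorescence tables to molecule numbers

`quantify_disc()` chains the per-disc preprocessing steps:

1. **Background** (`fit_background()`): most segmented nuclei are
   non-expressing and form a near-Gaussian background per channel. The
   fit is iteratively trimmed (drop cells more than 3 sd above the
   location, refit) and initialised from the median and MAD — with a
   moderate expressing fraction, a plain mean/sd start can sit so high
   that trimming never engages. The positive-cell threshold is the 84th
   percentile of the fitted normal, `mean + 0.99446 * sd`, i.e. a
   percentile of the *fit*, not of the sample — the fit exists
   precisely to define this cutoff.
2. **Classification** (`classify_and_subtract()`): a cell is positive
   only if its raw value exceeds the threshold in *both* channels;
   the threshold value is then subtracted from every cell. Classifying
   on raw values against the threshold and then subtracting that same
   value keeps every positive cell's subtracted value positive, which
   downstream log-binning requires.
3. **Channel scaling** (`fit_channel_scaling()`): ordinary least
   squares of green on red over the positive cells gives a per-disc
   slope and intercept; the red channel is rescaled into green units
   and the two channels summed into a total. Discs whose green–red
   correlation falls outside [0.5, 1] are flagged (well-behaved discs
   run ~0.85–0.95).
4. **Absolute conversion** (`rfu_to_molecules()`): the
   FCS-anchored calibration of 10 nM per RFU and a nuclear volume of
   23 fL give `10e-9 * 23e-15 * 6.022e23 ≈ 138.5` molecules per RFU.

The per-disc slope is also the basis of the microRNA repression assay:
each disc yields one green-on-red slope, and the fold-difference in
per-allele output between two genotypes is the ratio of their mean
slopes with relative errors propagated (`repression_fold()`). Because
both genotypes share the same red-allele construct, regression
attenuation from noise in the red channel cancels in the ratio.

## Rate estimation and FCS arithmetic

`fit_exponential()` fits `A * exp(-k t)` by nonlinear least squares
with the amplitude free: decay courses are ratio-normalised and the
t = 0 point need not be exactly 1. (A fixed-amplitude variant is
available.) Reported half-lives are always `log(2)/k`; note that a
printed (rate, half-life) pair from an external source need not satisfy
that identity if it was produced under a different parameterisation, so
only the rate is treated as the quantity of record. Fits with
non-positive rates are flagged, not hidden.

The FCS module implements the standard two-component three-dimensional
diffusion autocorrelation with triplet correction,

    G(tau) = 1 + (1/N) [ y g(tau; tauD1) + (1 - y) g(tau; tauD2) ]
                     (1 + T/(1-T) exp(-tau/tauT))
    g(tau; tauD) = (1 + tau/tauD)^-1 (1 + s^2 tau/tauD)^-1/2

with one structural parameter `s = wxy/wz` shared by both components
(the calibration measures a single beam geometry, so a shared `s` is
the only self-consistent reading). The observation volume is the
prolate ellipsoid `pi^(3/2) wxy^2 z0`; `concentration_from_N()`
converts a fitted particle number to nM. Fitting uses bounded
Levenberg–Marquardt with `s` held fixed by default, as it comes from
dye calibration. QC follows two rules: drop measurements with
counts-per-molecule below 0.5 kHz, and drop traces showing a
(near-)monotonic intensity decline exceeding 20% start-to-end — the
photobleaching threshold is configurable since "marked photobleaching"
is a judgement call we quantify explicitly.

## Pattern statistics

Adult-wing disorder is summarised by the proportion of wings with at
least one ectopic mechanosensory bristle, compared between genotypes by
the odds ratio and a two-sided Fisher exact test. The two-sided p-value
is the conventional "small-p" sum — all tables with the observed
margins whose probability does not exceed the observed table's — which
differs from doubling the one-sided value; the suite checks it against
the reference implementation across exhaustive small-table grids. Zero
cells (parent genotypes show zero mispatterned wings) get the
Haldane–Anscombe 0.5 correction by default, flagged, with a strict mode
that refuses instead. Chemosensory spacing is summarised as density =
1/mean(successive distances) with a percentile bootstrap CI; comparing
genotypes is left to a t-test on the distance sets.

## The synthetic-data generator

`make_disc_tables()` emulates a segmented-disc fluorescence table:
30% of cells are expression-positive (the typical classified fraction)
and sit in two stripes flanking a boundary; their `kon` is interpolated
log-linearly from 10/min at the stripe edge nearest the boundary to
0.025/min at the far edge, standing in for the Wg gradient; two-allele
protein counts come from the exact simulator; channel readouts apply a
gain of 1/138.5 RFU per molecule (the inverse of the default
calibration), a true green-on-red scaling slope of 1.2, multiplicative
log-normal measurement noise (default CV 10%, the scale implied by the
tandem-tag decorrelation), and an additive Gaussian background. The
background means and sds (0.5 ± 0.05 and 0.6 ± 0.06 RFU) put the
brightest cells near 25 RFU, matching the observed dynamic range.
Measurement noise is multiplicative because the tandem-tag Fano grows
with output, which additive noise cannot reproduce. The stripe layout
exists to exercise spatial exports and the gradient, not to model Wg
biophysics. Every generated cell's true counts, `kon` and label are
recorded, and a seed plus config reproduces tables byte-identically.

What the generator does *not* emulate: segmentation errors, spatial
autocorrelation of background, FRET between tags, cell-cycle and
gene-replication effects, and any post-transcriptional rate gradient.
Passing tests on synthetic data therefore validate the statistical
machinery, not the imaging pipeline upstream of the tables.

## Numerical and design choices

* **Sweep defaults.** Grids default to 20 values and 5000 pairs per
  value; the suite and the acceptance script scale these down (12
  values, 400–800 pairs) — sizes at which every asserted shape was
  verified stable across seeds.
* **koff sweeps** are run at `Sm = 2` (burst sizes 80 down to 0.67) in
  the shape checks: the mid-range Fano peak produced by a `koff`
  gradient is a promoter-noise effect, and with `kon` = 1/min the
  switching is fast enough that at translation-limited transcription
  rates (`Sm` ≤ 0.5) the peak is smaller than realistic sampling
  error. The qualitative statement (interior peak) is what the package
  asserts.
* **Fano from a profile's edge bins** is not compared quantitatively
  anywhere, for the selection-bias reason above.
* **Bootstrap CIs** always contain the point estimate by construction
  (the bounds are clamped to it), are seeded, and use the percentile
  method.
* **Degenerate inputs** fail loudly: constant backgrounds, flat ACF
  curves, zero channel means, non-positive totals and zero-margin
  tables are all signalled rather than propagated as NaN.

## Reproducibility

All stochastic functions accept a `seed` argument and restore the
caller's RNG state afterwards; `NULL` uses (and advances) the current
stream. The acceptance script (`scripts/acceptance.R`) derives all of
its sub-seeds from one `--seed` and recomputes, from scratch: the
constant-regime cumulative Fano factor (~20 molecules), the burst-size
algebra (b = 9 at a single-allele Fano of 10), the 1.8-fold
slope-ratio recovery, and the decay-rate recovery at 0.0462/min.
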