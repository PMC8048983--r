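---
title: "Assessing sham blinding from online probe responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing sham blinding from online probe responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shamtrack)
```

## The problem

Transcranial direct current stimulation (tDCS) trials rely on a sham
(placebo) protocol that mimics the scalp sensations of active stimulation: a
brief fade-in, a few seconds of current, and a fade-out. Whether that
deception actually works is traditionally checked with a single end-of-study
question ("which session was sham?"). shamtrack implements a far more
informative assessment built on *online* probes: during the stimulation
period participants are asked every 30 s whether the stimulation is on and
how sure they are, yielding a 32-point perception time series per session
that can be compared against what a perfectly informed observer would
report.

## Weighted scores and group confidence bands

Each probe response is scored as sign x confidence: a "yes" (stimulation on)
carries +1, a "no" -1, multiplied by the 0-10 confidence rating, giving a
weighted score in [-10, +10] (`weighted_score()`). For each condition the
group curve is the per-probe *median* weighted score; uncertainty comes from
a participant-level bootstrap (`bootstrap_group_curve()`): participants are
resampled with replacement 5,000 times (one shared set of resamples across
probes), the median recomputed each time, and a 95% percentile interval
reported. We interpret the resampling as a bootstrap over participants
because the estimand is the group median at each probe; percentile intervals
are used because no other interval type is implied by the procedure.
Blinding failure shows up as probes where the active and sham bands separate
(`nonoverlap_probes()`); intervals are treated as closed, so curves that
merely touch still count as overlapping — the conservative choice when
claiming a failure. No multiplicity correction is applied across the 32
per-probe comparisons; this mirrors the standard practice for this display
and is deliberately left uncorrected (the band plot is descriptive, the
inferential battery is separate).

Missing probe responses (the fixed 4,500 ms response window can lapse) are
stored as missing and simply excluded from that probe's median: imputing
perception data would fabricate observations, and medians tolerate
missingness. A probe where *every* response is missing is flagged, never
silently zeroed.

## The sensitivity statistic

The core individual-level statistic asks: how well does this participant's
weighted-score series track the stimulation time course? The reference is
the **ideal response curve** (`build_ideal_curve()`): +10 at every probe at
which any current flows, -10 otherwise. Ramps count as "on" — any nonzero
current is detectable in principle, and the active on/off boundary at 660 s
(end of ramp-down) then coincides with the end of the third task block, as
the protocol intends. Probe k is timestamped at 30k s, the end of its
interval, and that convention is used everywhere. The ideal values sit at
the extremes of the weighted-score scale (+-10 rather than +-1) so both
series live on one scale; the cross-correlation normalization is
scale-invariant, so this cannot affect any coefficient (asserted in the test
suite).

Both series are detrended (ordinary least-squares line removed,
`detrend()`) and then cross-correlated over lags -31..+31 probes
(`xcorr_coeff()`):

$$ c(m) = \frac{\sum_n x(n)\, y(n+m)}{\sqrt{\sum_n x(n)^2 \sum_n y(n)^2}} $$

with zero padding outside the observed window. This is the classic signal-
processing "coeff" normalization: global, with no per-lag re-centering, so
coefficients at extreme lags shrink toward zero by construction and
|c(m)| <= 1 everywhere. A per-lag true Pearson variant (re-centred on the
overlap) is available behind `pearson = TRUE` for sensitivity analysis, but
the global normalization is the primary definition. Two deliberate
conventions:

* **Lag range.** A 32-sample series admits informative lags -31..+31 only;
  lags +-32 would have zero overlap and a coefficient of exactly 0, so
  `max_lag = 31` is the full range.
* **Peak extraction.** The *signed* maximum is taken (not the maximum
  absolute value), with ties broken toward the lag smallest in absolute
  value, then toward the negative lag. Positive lag means the participant's
  reports trail the ideal curve.

Missing probes are linearly interpolated from neighbours before detrending
(ends take the nearest valid value) because the lagged correlation needs
complete vectors; the interpolation count is carried through to the output.
The series detrended is the weighted-score series itself — the only series
the analysis constructs.

Each session is scored against the ideal curve of its own protocol
(*congruent*) and of the opposite protocol at the same current strength
(*incongruent*), giving four coefficients per participant
(`sensitivity_table()`). If response curves carry protocol-specific
information, congruent coefficients exceed incongruent ones.

One selection effect is worth knowing: maximizing over 63 lags biases the
peak upward, so even random responders score well above zero. A frozen
Monte Carlo regression test pins this level (mean peak r about 0.30
against the active ideal for sign-random, confidence-uniform series) — a
useful floor when interpreting individual coefficients.

## Classifier evaluation

`roc_auc()` computes the empirical ROC staircase and the AUC as the
Mann-Whitney probability that a positive-class score exceeds a
negative-class one (ties counted half) — identical to the trapezoidal area,
and the two routes are checked against each other and against pROC in the
tests. Three classifiers of the peak coefficients are evaluated per
condition (`run_classifiers()`): congruent-vs-incongruent reference,
1-vs-2 mA (congruent coefficients only), and correct-vs-incorrect
end-of-study guess (congruent only, strengths pooled, with a per-strength
breakdown). Positive classes (congruent / 2 mA / correct) are fixed a
priori; an AUC below 0.5 is reported as such, never flipped.

AUC inference uses the Hanley-McNeil standard error with a normal
approximation, the CI clipped to [0, 1], and the p-value against AUC = 0.5
computed with the null SE at 0.5. The original software behind published
CIs of this kind is rarely stated, so exact agreement with any particular
report is not expected; a stratified case bootstrap (2,000 seeded
resamples) is available via `auc_ci_method = "bootstrap"` as a check.

## The inferential battery

All remaining tests are standard and delegated to base R where possible
(`t.test`, `cor.test`, `aov`), wrapped to report effect sizes: Cohen's d
(paired: mean difference / SD of differences; independent: pooled SD) and
partial eta squared (SS_effect / (SS_effect + SS_error-of-its-stratum)).
Reaction-time trials are summarised as per-block medians over correct trials
only, and delta-RT subtracts the 100-trial baseline block's median. The
active-vs-sham delta-RT tests are one-tailed (active was expected to slow
responses) at a Bonferroni-adjusted alpha of 0.05/3 = 0.0167; because tail
bookkeeping differs between reports, every result carries both the
requested-tails and the two-sided p-value. The 2 (current strength) x 2
(stimulation type) mixed ANOVA uses the split-plot `Error(id/within)`
decomposition (Type I equals Type III in this balanced design); the 2 x 2
fully-within ANOVA (stimulation type x congruence) uses per-effect error
strata. Both are verified against hand-worked sums-of-squares fixtures.

The Wilcoxon signed-rank test for the five side-effect ratings is written
in-house because the analysis needs a Z statistic and exact tie-aware
p-values: zero differences are dropped (the classical procedure, chosen
because the data are coarse 1-5 ratings), tied absolute differences get
average ranks, and for up to 25 retained pairs the exact null distribution
of W is enumerated by convolution over the 2^n sign assignments; beyond
that a tie-corrected normal approximation with continuity correction is
used. It agrees with `stats::wilcox.test` in the no-ties regime by
construction (tested).

## The synthetic-study generator

No generative model for probe responses exists in the literature this
implements, so the generator (`simulate_study()`) is the package's own
minimal construction: noisy logistic detection of a habituating scalp
sensation.

Perceived intensity follows the current trapezoid (30 s linear ramps,
plateau at 1 or 2 mA) attenuated by exp(-t/tau): the scalp is most sensitive
in the first minutes of stimulation. From the end of the plateau the
sensation fades linearly, reaching zero at the end of the ramp-down plus a
short persistence window — sensation outlives the current slightly. (A
formulation where the post-offset decay starts from the amplitude *at*
offset would start from zero and make persistence inert, which is why the
fade is anchored at the plateau-end value.) At probe time t the probability
of a "yes" is `plogis(g (I(t) - threshold) + e)` with logit noise e;
confidence is `10 |2p - 1|` plus noise, clipped to [0, 10]; probes go
missing at the lapse rate.

Defaults (chosen once, as the study conditions the package emulates, and
calibrated so the full pipeline reproduces the magnitude of published
findings of this design — group mean peak r near 0.5 with SD near 0.25,
incongruent mean near 0.4, current strength a good classifier during active
stimulation, roughly 75% correct guesses at chance-level guess AUC):

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.4 mA | perceived intensity needed for 50% detection |
| `habituation_tau` | 1200 s | sensation decay under sustained current |
| `persistence_s` | 15 s | lingering sensation past the plateau + ramp-down |
| `response_noise` | 0.7 | SD of the per-probe logit noise |
| `confidence_noise` | 1.5 | SD of confidence rating noise (0-10 scale) |
| `lapse_rate` | 0.02 | probability a probe response is missing |
| `g` (population) | LogNormal(log 3.0 / log 4.2, sdlog 0.9) | gain at 1 / 2 mA |
| session jitter | sdlog 0.25 | within-participant gain stability |
| `guess_base`, `guess_coupling` | 0.75, 0 | P(correct) = clip(base + kappa(acc - 0.5)) |
| `distraction_coupling` | 6 ms | RT slowing per unit of gain-weighted intensity |
| `trials_per_block` | 110 | blocks 2-4 (baseline block is always 100) |

Two couplings are switches so each finding can be turned on or off in
tests. The end-of-study guess is correct with probability
`guess_base + kappa (accuracy - 0.5)`; with the default kappa = 0 the guess
is *independent* of sensitivity (while still 75% correct on average), the
regime in which guess accuracy classifies sensitivity at chance. The RT
distraction effect adds `distraction_coupling x g x mean perceived
intensity` to each stimulation-block trial in 2 mA active sessions only;
scaling by the participant's gain g is what lets individual sensitivity
correlate with block-3 slowing — a constant per-intensity shift would move
everyone equally and produce no correlation. Reaction times are ex-Gaussian
(mu 450 ms, sigma 50 ms, tau 100 ms), correct with probability 0.95; task
blocks 2 and 3 split the stimulation window at 330 s so block 3 ends with
the active ramp-down (660 s), and block 4 is entirely post-stimulation.
Side-effect ratings are latent-normal ordinals with itching rising most
under longer on-time.

**What the generator does and does not emulate.** It reproduces the data
layout, the perception dynamics that matter to the statistic (early onset
detection in both protocols, earlier perceived offset in sham, longer
tracking at higher current, wide inter-individual variability, positive
within-participant sensitivity correlation) and the couplings above. It
does not model electrode physics, montage, impedance, sequence/order
effects, learning across sessions, or response biases beyond a symmetric
logit. Synthetic active response curves are also *cleaner* step functions
than human ones; one visible consequence is that sliding the sham ideal to
align with the active offset step inflates incongruent coefficients for
active sessions, so the congruence classifier during active stimulation
runs nearer AUC 0.6 here than the ~0.7 seen with human data. Passing tests
therefore demonstrate correctness of the machinery and qualitative
reproduction of the findings, not quantitative equivalence to any human
dataset.

## Numerical choices and degenerate inputs

* Bootstrap bands and all simulations are seeded; the seed is part of the
  output metadata, and re-running with the same seed reproduces results
  byte-for-byte.
* Cross-correlation rejects all-zero inputs (undefined normalizer), series
  shorter than 2, and mismatched schedules, rather than returning NaN.
* Peak ties (possible with coarse +-10 data) resolve deterministically:
  smallest |lag|, then the negative lag.
* ANOVA sums of squares that are zero up to rounding (relative tolerance
  1e-10 within a stratum) are treated as exactly zero, so noiseless
  degenerate fixtures give F = 0 instead of ratios of rounding error.
* Zero-variance correlations, single-class classifier strata, all-zero
  Wilcoxon differences and RT blocks without correct trials are flagged in
  the output instead of erroring the whole pipeline.

## Problem sizes used by the test suite

The suite simulates at reduced but representative sizes chosen to exercise
every code path: full 64-participant studies where the property under test
concerns the population (parameter recovery, chance-level guessing over 200
replicate studies with 5 trials per RT block — the RT volume is irrelevant
to that property), 500 replications for bootstrap coverage at one probe
(n = 32, 1,000 resamples), 1,000-replicate null calibrations for the
type-I checks, and 2-6 participants per strength for layout round-trips.
`scripts/acceptance.R` runs the full default study (64 participants, 5,000
bootstrap resamples) end to end at the given seed.

## Known limitations

* The real deposited datasets use their own file layout; `read_study()`
  defines a documented long-format CSV schema instead of guessing it, and
  mapping a deposit onto the schema is a renaming exercise left to a thin
  adapter.
* Hanley-McNeil CIs are an approximation; with n = 32 per class they can
  differ from bootstrap or software-specific CIs in the second decimal.
* The peak statistic's selection bias (floor near 0.3) means absolute
  coefficient values should be compared against that floor, not against 0.
* Lag sign conventions differ across published analyses; ours is fixed,
  documented, and validated on shifted-series fixtures, but agreement with
  any specific original code cannot be guaranteed.
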