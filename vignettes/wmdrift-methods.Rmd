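---
title: "Methods: cross-session decoding and drift analysis for a delayed-association working-memory task"
author: "wmdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-session decoding and drift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and data model

The package analyses trial-aligned deconvolved calcium activity recorded
while head-fixed mice perform an olfactory delayed-association task: a first
odour (A or B, 1 s), a 5 s delay, a second odour (C or D, 1 s) and a 3 s
choice window. Licking after AC or BD is rewarded (hit); licking after AD or
BC is a false alarm; withholding produces a miss or a correct rejection.
Trial time zero is first-odour onset; all windows are half-open
`[start, end)` and frames and bins belong to the window containing their
start time.

A `Session` holds one day's ordered trial table, a nonnegative
`trials x neurons x frames` event-amplitude tensor, neuron identifiers and
centroid geometry (micrometres); a `Cohort` groups sessions by animal and
day. Analyses run on a `TrialTensor` obtained by summing event mass into
500 ms bins. Summation, not averaging, is used because deconvolved output is
event-like: summing preserves event mass and keeps all-zero bins
interpretable. A trailing partial bin is dropped so every trial shares one
shape.

Epoch windows default to: baseline `[-5, 0)`, first odour `[0, 1)`, early
delay `[1, 3)`, late delay `[4, 6)`, second odour `[6, 7)` and choice
`[7, 10)` seconds. The early/late delay spans are a declared package choice:
the task literature marks them graphically rather than numerically, and the
late-delay default covers delay seconds 4-5 — the portion whose optogenetic
inhibition impairs performance — leaving the middle delay second unassigned.
Both spans are configurable in `epochWindows()`.

Response maps (`zscoreResponseMap`) z-score the trial-averaged binned trace
against the mean and s.d. of the same averaged trace over the baseline
epoch, so maps read in units of spontaneous-activity s.d. A neuron silent
during the baseline (s.d. zero) is flagged and given an all-zero map rather
than raising an error, because silent neurons are expected in synthetic
nulls.

## Behavioural metrics

Performance is hits plus correct rejections over completed trials. Sessions
end early when the trailing ten-trial window contains more than three misses
(`applyAbortRule`); post-abort trials are excluded from all rates. Stage
labels are naive (`p < 0.65`), training (`0.65 <= p < 0.80`) and expert
(`p >= 0.80`), with the boundary inclusive, and novice marks training day
one. D-prime uses the standard signal-detection form
`qnorm(H) - qnorm(F)`; because no correction convention is given with the
task description, extreme rates are clamped by the common `1/(2N)` rule,
which keeps the statistic finite at perfect performance.

## Neuron-level statistics

**Activity fields.** A neuron has a significant activity field in an epoch
when its across-trial mean epoch activity exceeds a null built from 1,000
circular shuffles of the whole-session concatenated trace (one uniform
random offset per shuffle). Shifting the entire session preserves the
trace's autocorrelation; independent per-trial shifts were rejected as too
liberal. The test is one-sided (activation) with `alphaField = 0.05` by
default; both are configurable since neither is pinned down by convention.
`p = (1 + #{null >= observed})/(nShuffles + 1)`, so the p-value floor is
`1/(nShuffles + 1)`. The statistic is computed for all offsets at once via
an FFT cross-correlation with the epoch indicator, and the observed value is
read from the same profile (offset zero) so observed-versus-null
comparisons are numerically consistent. Note that offsets equal to
multiples of the trial length realign the trials exactly and tie the
observed value; the floor is attained exactly only when no such tie is
possible (e.g. single-trial traces with mass filling the epoch).

**Selectivity.** Odour and choice selectivity compares per-trial mean epoch
activity between label groups with the two-sided Wilcoxon rank-sum test at
`alpha = 0.01` (a 99% confidence level). The exact null distribution is used
for small untied samples (minimum group size 10 or less); otherwise the
normal approximation with tie and continuity correction. The effect size is
the rank-based AUC, the preferred label is the group with the larger mean
(ties broken toward the first label and flagged ambiguous). The standard
grid tests first-odour identity during the first-odour, early- and
late-delay epochs, second-odour identity during the second odour, and
lick/no-lick during the choice epoch. A neuron selective in exactly one grid
entry is *pure*, in two or more *mixed*. No multiple-testing correction is
applied across neurons: reported quantities are population fractions at a
fixed per-neuron level, as is conventional for this analysis. Choice
selectivity uses all completed trials rather than correct trials only.

**Associated-pair cells** are neurons selective for odour A during the first
odour and odour C during the second (or B and D) — the rewarded pairings.

**Movement correlation** compares the Pearson correlation between a
neuron's trace and the locomotion trace against 1,000 circularly shuffled
locomotion traces; a neuron is movement-correlated when its coefficient
lies at least two null s.d. from the null mean.

## Population decoding

The decoder is a linear max-margin classifier (libsvm via e1071) trained
per 500 ms bin on a stratified random 90% of trials and tested on the
held-out 10%, repeated 32 times with fresh splits; epoch accuracy is the
mean over the epoch's member bins. The protocol fixes choices that the task
description leaves open, and documents them as defaults: features are
standardized per neuron using training-split statistics only; the
inverse-regularization constant is fixed at C = 1; decoders are per-bin
(one per 500 ms bin) rather than per-epoch; class imbalance is handled by
stratified splits without subsampling. Multiclass (AC/AD/BC/BD) decoding
uses one-vs-one voting between binary linear decoders. Chance levels come
from label shuffles run through the identical protocol. All randomness
derives from one master seed fanned out per repeat through a counter-based
child-seed scheme, so results are bit-reproducible.

The top-N% curve re-runs the protocol on the `ceiling(N% x nNeurons)`
most selective neurons for N in {1, 2, 4, 8, 16, 32, 64, 100}; when N% of
the population is less than one neuron, one neuron is used and the point is
flagged. Depth-stratified decoding divides the bottom 420 um of the imaged
volume into seven 60 um intervals, equalizes neuron counts across intervals
by seeded random subsampling down to the smallest census, and decodes per
interval.

**Correct-versus-error decoding.** To test whether delay-period information
is present when the animal errs, decoders are trained on correct trials
(stratified 90% per repeat) and tested on all error trials. Error trials
are few and their label mix arbitrary, so accuracy here is *balanced*
(mean per-class recall), whose chance level is exactly 1/2 regardless of
label composition. The chance band permutes the correct-trial labels once
per shuffle and reruns the whole repeated protocol, so the null carries the
same repeat-to-repeat coherence as the observed statistic; re-permuting
inside every repeat would average the null's noise away and understate the
band.

## Cross-day generalization and crystallization

Neurons are matched across sessions from centroid geometry: all pairs
within 10 um are sorted by distance and accepted greedily while both
members are unmatched, yielding a one-to-one table (3-D distance when depth
is present). This deliberately replaces probabilistic footprint
registration with a transparent geometric rule whose correctness is
measurable against synthetic ground truth.

The cross-day matrix `acc[i, j]` trains per-bin decoders on all trials of
day i, restricted to the neurons matched between days i and j (the pairwise
intersection per pair, which maximizes neurons per pair; an across-all-days
intersection is available by precomputing a matching), and tests on all
trials of day j. The diagonal holds same-day cross-validated accuracy so
on- and off-diagonal entries are comparable.

Stability is quantified by the mean off-diagonal accuracy within an early
block versus a late block of days (defaults follow the two study designs:
days 1-3 vs 5-7 for seven-day series, 1-5 vs 6-10 for ten-day series). The
across-animal test is a one-sided unpaired two-sample t-test (the
stabilization hypothesis is directional), complemented by a day-identity
permutation test: rows and columns are permuted jointly (the same
permutation for every animal), the block difference recomputed, and
`p = (1 + #{perm >= obs})/(nPerm + 1)`. A single-day block has no
off-diagonal pairs; inside the permutation test its same-day entry
substitutes, which keeps two-day designs well defined, while the block
statistic itself requires two days per block and errors otherwise.

The crystallization day is estimated as the arg-max over candidate change
points c of the contrast [mean off-diagonal accuracy among days >= c] minus
[mean among days < c], requiring at least one off-diagonal pair per side;
if the best contrast is under a margin (default 0.1) no change point is
declared. An optional bootstrap over off-diagonal cells gives a confidence
band; a trial-level bootstrap (re-decoding resampled trials) would be more
faithful but orders of magnitude more expensive, and the cell-level band is
labelled as such.

## The synthetic-cohort generator

`generateCohort` plants everything the analyses are meant to recover.
Activity is compound Poisson: per-frame event counts are Poisson with a
tuning-dependent rate and each event carries an exponential(mean 1)
amplitude — sparse, nonnegative and continuous-valued like deconvolved
events (a pure Poisson model was rejected because it would not exercise
continuous-valued statistics). Rates are parameterized as expected event
mass per 500 ms bin: `noiseRate` (default 0.2) everywhere,
`effectRateHi`/`effectRateLo` (defaults 0.6/0.2) in a selective neuron's
informative epoch on preferred/non-preferred trials.

Day-one tuning plants `floor(frac x nNeurons)` neurons per primary epoch,
assigned deterministically by neuron index; a selective neuron becomes
mixed with probability `mixedProb` (default 0.4, reflecting the observed
predominance of mixed over pure coding) by gaining one or two extra epochs.
Choice coding is planted on lick/no-lick labels independently of odour
tuning so choice and odour decoders are separable in ground truth.
Associated-pair cells (default 1.2%) are selective for A-and-C or B-and-D
with consistent preferences. A `carryOverProb` fraction of odour-1 neurons
keep their elevated rate through the second-odour epoch — the persistent
trace that makes the four trial categories separable there. Under a planted
depth gradient, the probability that a selective neuron's epoch is late
delay rises logistically with depth (exact per-epoch counts then hold only
in expectation).

Between consecutive days a selective neuron keeps its tuning with
probability `retention` (default 0.5) and is otherwise redrawn from the
day-one marginal scheme, so neurons gain and lose responsiveness while
population fractions stay constant; from `crystallizationDay` (default 6 of
10) retention is 1 and the code is frozen. Behaviour presents trial types
uniformly at random, inverts the animal's response with probability
`errorRate` (default 0.06, matching expert performance around 94%), and
applies the miss-based abort rule. On error trials the late-delay effect is
multiplied by `1 - errorDegrade` (default: fully removed), emulating
degraded delay-period coding when the animal errs. Sessions hold 200 trials
by default (the task runs 150-250). Centroids are jittered day-to-day
(`centroidJitter`, default 1 um).

What the generator does **not** emulate: calcium indicator dynamics and
deconvolution artefacts, trial-to-trial response reliability below 100%
within a day, correlated noise across neurons, slow within-session drift,
and footprint shape. Passing recovery tests therefore demonstrates that the
analysis machinery measures what it claims on data with planted structure —
not that real recordings satisfy the generator's independence assumptions.

## Numerical and design notes

- Binning uses `floor(trialDuration/binWidth)` bins; frames map to bins by
  start time with a 1e-9 guard against floating-point boundary error.
- Degenerate inputs are flagged, not fatal: silent neurons in response maps
  and the field test (p = 1), zero-variance traces in movement and sequence
  correlations (recorded as missing), equal group means in selectivity
  (ambiguous preference, first label by convention).
- The abort rule is applied by default in simulated behaviour; experiments
  that need many error trials in full-length sessions (the correct-vs-error
  dissociation) disable it via `applyAbort = FALSE`, since with a high
  planted error rate the rule would truncate sessions and starve the error
  test set.
- `blockStabilityStat` returns t = 0, p = 1 for exactly constant matrices
  rather than failing in the t-test.
- Problem sizes in the test suite and in `scripts/acceptance.R` are scaled
  to desk hardware as a package choice (for example 40-500 neurons, 60-200
  trials, 4 animals x 10 days for drift recovery; the acceptance script
  runs 3 animals x 10 days x 100 neurons x 100 trials); every study
  condition that defines an experiment — retention schedules,
  crystallization day, error rates, 3:1 effect ratios, interval geometry —
  is kept as stated.

## Known limitations

The centroid matcher has no notion of footprint shape and will mismatch
neurons closer than the jitter scale; the generator's spacing makes this
measurable rather than hidden. The decoder family is linear by design;
nonlinear decoders are out of scope. The crystallization estimator assumes
a single change point and reports none when the contrast is weak; under
mild drift (retention near 1) the change point is only weakly identified
and the estimate can land a day or two late.
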