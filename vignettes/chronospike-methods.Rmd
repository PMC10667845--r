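---
title: "Methods: from broadband traces to functional coupling and task metrics"
author: "chronospike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from broadband traces to functional coupling and task metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronospike)
```

chronospike implements the analysis chain used with chronic multi-shank
extracellular recordings in behaving macaques: broadband preprocessing and
threshold detection, post-sorting unit curation, cross-session unit
tracking, visual (orientation / receptive-field) and motor (preferred
direction) tuning, functional-coupling inference from cross-correlograms,
and center-out brain-machine-interface task statistics. Because such
recordings are rarely shared, the package carries a synthetic-session
generator with known ground truth; every stage is validated by parameter
recovery against that ground truth.

## Preprocessing

Broadband voltage (20--30 kHz) is conditioned in the standard order:
per-sample common median referencing across channels, zero-phase
Butterworth filtering, high-voltage artifact blanking, and threshold
detection.

**Filtering.** All filters run forward--backward (zero phase), so detected
peaks are never lag-shifted by the filter. Designs are kept at the
zero-pole-gain stage and applied as cascaded biquad sections: collapsing a
4th-order design with a 0.3 Hz edge at 20 kHz into a single direct-form
polynomial is numerically unstable, while the biquad cascade is well
conditioned and realizes the same magnitude response. A band-pass is the
cascade of a high-pass and a low-pass of the stated order. Reflection
padding of about three time constants of the slowest pole absorbs start-up
transients; when that transient would outlast the record the padding is
skipped. The band edges are configuration values: 500--5000 Hz or 250--7500
Hz for the spike band (both in use depending on the recording rig; neither
is blessed as the default), 0.3--300 Hz for the LFP, a 50 Hz notch and a
>300 Hz 4th-order high-pass with a fixed -70 uV threshold for closed-loop
features. The notch's band-stop edges are placed geometrically symmetric
around the mains frequency so the transmission zero falls exactly on it.

**Robust background SD.** Wherever a threshold is stated in "standard
deviations of the background signal" the estimator is 1.4826 x MAD. Spikes
and artifacts inflate the naive SD; the robust estimator is insensitive to
them, and it also makes artifact blanking idempotent (after chunks are
zeroed, a naive SD shrinks and a second pass could blank more; the MAD
barely moves).

**Artifact blanking.** Samples outside +/- 6 robust SDs cause their
enclosing 0.1 s chunk to be zeroed; the blanked intervals are reported. For
a clean Gaussian record the expected false-blank count is about
2N &Phi;(-6), i.e. negligible.

**Detection.** Threshold crossing at 4.5 robust SDs in both polarities (or
at an absolute voltage), with the trace median-centered first so a DC
offset cannot change the event count. Each suprathreshold excursion
contributes its extremum; events closer than one snippet length (1.6 ms)
merge to the larger extremum -- a dead-time collision rule of our choosing,
as detection pipelines rarely state one. Snippets span 0.4 ms before to 1.2 ms after the peak (32
samples at 20 kHz); edge events are dropped and reported.

## Curation

Units are accepted when firing rate > 0.05 Hz (strict: 30 spikes in 600 s
fails), SNR > 1.5, and the fraction of spikes with inter-spike intervals
under 1.6 ms is at most 2%. Externally supplied sorter metrics gate only
when present (isolation > 0.95, noise overlap < 0.03); their definitions
live with the sorter and are treated as pass-through. Two readings of the
2% rule exist -- violations over spikes or over intervals; the default
divides by the spike count ("fraction of spikes"), and the alternative is a
configuration switch. No single SNR convention exists in the field; we use
peak-to-trough of the mean waveform over twice the residual SD, which
converges to template amplitude over noise. Before any waveform metric,
outlier snippets are removed by a generalized ESD (Rosner) test applied to
each snippet's L2 distance from the mean waveform (alpha 0.05, at most 10%
of snippets); the implementation is checked against a literal
iterative-max-deletion oracle. Duplicate clusters split across channels
within the 100 um adjacency radius are merged when their spike-time
coincidence within 0.5 ms exceeds half of the smaller train -- the window
and overlap fraction are our recorded choices, the radius is the stated
one.

## Cross-session tracking

Waveforms of a candidate unit pair from adjacent sessions are projected
onto a PCA basis fit on the pooled snippets (fitting on the earlier session
only is available as an option, as both conventions are in use).
The center-to-center distance is expressed in units of sigma of the earlier
session's score cloud, where sigma is the RMS of the per-component SDs --
"sigma of the PC distribution" is not otherwise defined, so this scalar
reading is recorded as ours. Pairs closer than 2 sigma match; a greedy
one-to-one assignment by smallest distance resolves conflicts (ties to the
lower unit id), which also guarantees chains never branch when matches are
chained across a session sequence. Candidates are restricted to shared or
adjacent (<= 100 um) primary channels when geometry is available.

## Visual tuning

Trial rates are spike counts in the stimulus window over its length.
Orientation curves report mean, SEM and rates normalized by the most active
orientation. OSI = (Rpref - Rorth)/(Rpref + Rorth) with Rorth the grid
condition nearest 90 degrees from the preferred one; the 0.3 gate is fixed
but several OSI formulas circulate, so this standard contrast form is our
recorded choice (1 - circular variance is the common alternative). The
preferred orientation is the half-angle of the rate-weighted doubled-angle
vector sum, which is equivariant under stimulus rotation and undefined
(NA) for flat or balanced curves.

Receptive fields are mapped as baseline-subtracted mean evoked rate per
stimulus grid location, with the baseline taken from an equal-length
pre-onset window (our choice among the usual baselines). A 2D elliptical
Gaussian is fit by Levenberg--Marquardt least squares with moment-based
starts; RF size is defined from the fit as 2 sqrt(sigma_x sigma_y) -- a
geometric-mean diameter at one sigma -- and eccentricity as the distance of
the fitted center from fixation at the origin. "RF size" has no canonical
definition; any monotone one preserves the depth trend the mixed model
tests. The size-versus-depth model is
`size ~ depth + (1 | shank) + (0 + depth | shank)`: a fixed slope with an
uncorrelated random intercept and random slope per shank, the fixed slope
tested against zero with Satterthwaite degrees of freedom and its 95% CI
using the t quantile at those df (with ~6 shanks the normal quantile
understates the interval). Singular random-slope fits fall back to the
random-intercept model and are flagged.

## Motor tuning

Per-direction rates come from the 0--300 ms epoch after movement onset.
The preferred direction is the angle of the max-normalized vector sum
FRx = sum_i (FR_i / max_j FR_j) cos theta_i (and sine for FRy) over the 8
directions; the preference strength is the vector length. Whether the max
normalization divides each term or the whole sum is a typographic
ambiguity in the usual presentation; the two readings give identical angle
and length, so the per-term form is implemented. Uniform rates cancel exactly over the
equispaced grid, giving strength 0 and an undefined direction; directions
with no trials raise an error rather than being imputed.

## Functional coupling

Cross-correlograms bin follower-minus-leader spike-time differences at 0.4
ms over lags -200..+200 ms (1001 bins; differences up to +/- 200.2 ms fall
in the end bins). The slow CCG structure is estimated by convolving the
observed CCG with a partially hollow Gaussian kernel -- SD 10 ms, truncated
at +/- 5 SD, central weight multiplied by 0.4 (60% hollow), renormalized --
with reflection padding at the lag edges so the baseline stays unbiased
there.

The acceptance rule is that the causal-window peak must exceed that
baseline and be significantly larger than the mirrored negative-lag peak;
no specific test is canonical, so our operationalization is: the peak count within (0, 10] ms
is referred to a one-sided Poisson tail at the baseline of its bin with
mid-p continuity correction, Bonferroni-adjusted by the number of bins
searched (25) because the peak is a maximum over the window; the causal
comparison is a one-sided conditional binomial test of the positive-lag
versus negative-lag peak counts. Both use alpha = 0.01 by default. The
adjustment is what makes the null honest: without it the maximum over 25
bins would be flagged about 20% of the time at alpha 0.01. On 1,000
independent 10 Hz, 600 s pairs the observed positive rate is far below
2 alpha, and power at the reference injected condition (excess probability
0.3, 2 ms lag, 0.5 ms jitter) is essentially 1 with the peak recovered at
+/- 1 bin. A symmetric zero-lag common-drive pair passes the exceedance
test but fails the causal comparison, as intended. Spikes are pooled over
the session (no trial-shuffled correction), and multiple-comparison
handling across the pair population is left to the caller.

## Center-out task metrics

Path efficiency is the straight-line distance from the start to the
acquisition point over the path length traveled to it; acquisition is the
first sample whose cursor center lies in the target disk (3.7 cm diameter,
7.5 cm from center, 8 directions at 45 degrees). No hold-time requirement
and a 10 s timeout are recorded choices; the task geometry is fixed but
the success rule is ours. Accuracy is successes over attempts per
direction. Hand-versus-brain comparisons follow the stated tests: a
two-tailed bootstrap (2000 resamples) of the per-direction success
proportion -- trials resampled with replacement within mode, two-tailed p
from the centered bootstrap difference with the add-one correction -- and
two-sided Mann--Whitney U for time cost and path efficiency, each metric
Benjamini--Hochberg adjusted across directions. The ridge velocity decoder
and the 50 ms closed-loop simulator are deliberately simple plumbing whose
only job is to produce brain-mode trials to compare; real closed-loop
decoders (e.g. subspace-identification methods) are out of scope.

## Synthetic data: what it emulates, and what it does not

Generators are pure functions of (parameters, seed); per-unit substreams
are derived as seed + unit index so growing a population never perturbs
existing units. Orientation tuning is a von Mises profile on the doubled
angle, lambda(theta) = b + a exp(kappa(cos 2(theta - theta_p) - 1)), with
defaults b = 2 Hz, a = 18 Hz, kappa = 2 -- firing ranges typical of V1
units under gratings. Direction tuning is a rectified cosine with b = 5 Hz
and modulation 15--20 Hz inside the 0--300 ms epoch. Coupling is
thinning-and-jitter injection: each leader spike begets a follower spike
with probability p at lag L plus Gaussian jitter, so the expected excess
count (p x leader count) is known exactly. Raw traces are template
insertions with exponential cross-channel decay plus white Gaussian noise
and rectangular artifact pulses; drift across sessions scales the template
amplitude. Cursor trials use a constant-speed heading-noise walk.

None of this reproduces bursting, refractory structure beyond what Poisson
gives, electrode drift within a session, correlated (1/f) noise, eye
movements, or behavioral learning. Passing the recovery suite therefore
shows the estimators are correct under their stated models at desk-scale
problem sizes -- sessions of tens of seconds to minutes, populations of a
handful of units, 50--1000 replicates -- not that they are robust to every
pathology of real tissue. Reproducing any specific laboratory's population
counts or significance values is out of scope: those derive from
unreleased recordings and are deliberately not targets.

## Numerical and degenerate-input choices

Strictly increasing spike times are enforced at the container; generators
deduplicate exact ties (probability-zero events under the continuous
models). Zero-noise SNR returns Inf as a sentinel. A zero-resultant
direction or orientation vector returns NA rather than an arbitrary angle.
GESD requires 10 snippets and otherwise warns and skips. The RF fit
declares failure when the grid peak is under twice the grid noise SD, when
the optimizer diverges, or when the center leaves the sampled grid. CCGs
require non-empty trains. Baselines that are non-positive at the tested
peak yield an undefined verdict with a warning rather than a division by
zero. The interchange format writes floats as "%.17g" so a load--save
cycle is byte-stable; waveforms and raw traces are float32 by design,
which is lossless from the second save onward.

## Problem sizes

The shipped tests run sessions of 30--600 s, populations of 1--30 units,
1,000-pair null suites, and 50--100-replicate recovery loops; these sizes
give 3-sigma-resolved checks for every stated property while keeping the
whole suite in tens of seconds on one core, and they are the sizes we
consider adequate for validating the estimators' correctness.
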