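---
title: "Detecting nonlocal spatial coding in entorhinal population activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nonlocal spatial coding in entorhinal population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the models and procedures implemented by
`mecnonlocal`, the assumptions behind them, the parameters a user might want
to change, and what the synthetic-data generator does and does not emulate.
Every empirical number quoted here is computed by the package's test suite or
the numbered scripts under `analysis/`; the vignette states no result those do
not themselves produce.

## The scientific problem

Medial entorhinal cortex (MEC) carries a population code for an animal's
position. During immobility - for instance while a mouse consumes a reward on
a maze - this code can transiently represent places far from the animal.
Detecting such *nonlocal coding* requires (i) decoding position from
population spiking at fine timescales, (ii) distinguishing a confident remote
representation from mere decoder uncertainty, and (iii) statistics that
compare what was represented against what chance geometry predicts. The
package implements that full chain for a figure-X maze ("X-maze") task in
which a mouse runs from one of two sample reward arms through a center arm to
one of two choice reward arms, in blocks of ten trials per sample arm, under a
match-to-sample or nonmatch-to-sample rule.

## Track model and chance geometry

The maze is a tree graph: four arms (each a 40-cm arm plus a 10-cm reward
zone ending at a port) joined to a 30-cm center arm at two junctions, 230 cm
of track. For decoding, the track is *linearized*: the five blocks are laid
end to end with a 15-cm buffer between consecutive blocks. Buffers are purely
a plotting/binning device - positions are never emitted inside them and
**every distance in the package is a shortest-path distance along the graph**
(`track_distance()`), never a difference of linearized coordinates. The
layout anchors the N sample reward at 0-10 cm and the S sample reward at
65-75 cm; the two sample ports are 100 cm apart on the track and a sample
port is 130 cm from either choice port.

Five task segments partition the track: sample reward (within 10 cm of a
sample port, port-inclusive, boundary half-open so a point exactly 10 cm from
the port belongs to the arm), sample arm, center, choice arm, choice reward.
`chance_level()` computes, for an animal paused at any position, the fraction
of the track at least 20 cm away (by track distance) that falls in a given
segment. At a sample port the denominator is 210 cm and the five segments'
chances are 10/210, 70/210, 30/210, 80/210 and 20/210; segment mode averages
the point values over a 1-cm grid of positions in the segment. These values
are exact under a 1-cm cell-center quadrature, which the tests verify against
the closed forms.

## The switching-dynamics decoder

Spikes from all units of one region are binned at 2 ms. The encoding model
is a per-unit rate map: mean firing rate in 2-cm linearized bins over
movement samples (speed > 2 cm/s), numerator and denominator each smoothed
with a 1-D Gaussian (sigma = 1 bin) *within* a track block so no rate bleeds
across a buffer, floored at 1e-3 Hz to avoid zero-likelihood lockout.

The latent state is the pair (movement dynamic, position bin) with three
dynamics:

* **stationary** - the position holds (identity kernel);
* **continuous** - a Gaussian random walk with sigma = 1.0 position bin per
  2-ms step (6.0 as the configurable alternative), the Gaussian evaluated in
  *track distance* so transition mass follows the graph topology, not the
  linear layout;
* **fragmented** - a uniform jump to any bin.

The dynamic switches with total probability 2% per step, split equally
between the two other dynamics (the maximum-entropy reading of a stated 2%
total). Emissions are independent Poisson per unit given the rate map, in
log domain throughout. A forward-backward smoother (C++ core) returns the
acausal posterior; the decoded (MAP) position is the argmax of the position
marginal summed over dynamics, ties broken to the lowest bin. On instances
small enough to enumerate every latent path, the smoother agrees with brute
force to 1e-12, and each time bin's posterior is normalized to 1e-9.

When the same time bins train and decode (movement decoding), the session is
split into five contiguous folds and each fold is decoded by a model trained
on the others; contiguous folds avoid temporal leakage. For immobility
analysis the model trains on all movement and decodes all time (`k = 1`).
A naive-Bayes decoder (100-ms bins, 1-s sliding window, uniform prior)
provides an independent check of decoded positions, and a control model
trained on temporally shuffled spikes (per-unit circular shifts) provides the
negative control; the control must itself be cross-validated when its
movement error is quoted, because a full-train control can partially memorize
its own shuffled spikes.

### Confidence masking

Low-confidence posterior bins are excluded before any nonlocal statistic.
The spread statistic is the posterior-weighted mean squared track distance
from the MAP bin (cm^2). Two threshold modes exist. The default is an
absolute spread of 400 cm^2 - a posterior SD of 20 cm, the same radius that
defines nonlocality, so a kept bin's position call is meaningful at the scale
of the question being asked. The alternative percentile mode excludes a fixed
fraction of the session (e.g. keeping 92.8%). We chose the absolute mode as
default after observing on synthetic sessions that diffuse-posterior bins -
whose MAP is essentially arbitrary - are exactly the bins that generate
spurious nonlocal labels, and that their spread separates cleanly (hundreds
to thousands of cm^2) from genuinely local or genuinely remote bins (tens of
cm^2).

## Nonlocal analysis

Immobility is speed < 2 cm/s, with neighboring bouts concatenated when the
gap is under 1 s *and* the net displacement under 2 cm. A 2-ms bin is
*nonlocal* when the track distance between MAP and actual position is at
least 20 cm, restricted to immobility and confidence-kept bins; remaining
kept immobile bins are *local*, and the three classes partition immobility
exactly. Consecutive nonlocal bins form bouts; by default a single
non-nonlocal bin splits a bout (a configurable gap is provided, default 0,
since no tolerance rule is otherwise defined).

Downstream statistics: per-bout percentage of nonlocal content and the
session summaries (percentage of bouts with any nonlocal content, percentage
of immobile time nonlocal, durations of local-only versus any-nonlocal
bouts); the decoded-versus-actual distance by speed histogram, column
normalized; the 5 x 5 mouse-segment by decoded-segment representation matrix
paired with segment-mode chance; the paired/unpaired reward analysis; and a
logistic regression predicting trial correctness from the percentage of
nonlocal content at the choice reward after the poke (classes balanced 50/50,
80/20 train/test, 1000 random splits, mean and SEM of test accuracy reported;
with several animals the animal identity enters as a covariate - both pooled
and per-animal use are possible since the package analyses one session at a
time and features carry an animal column).

The *paired* reward of a bout at a reward port is the opposite-end reward
associated with the animal's current arm under the task rule: match pairs
same-side rewards, nonmatch pairs opposite sides. Incorrect-trial bins are
duration-matched to the correct-trial total by seeded random subsampling of
time bins, averaged over 100 repetitions - the stated goal is duration
matching; subsampling is our mechanism choice.

## Single-unit statistics

All single-unit tests share one logic: the observed statistic must exceed the
95th percentile of the unit's own null distribution, built from 1000
shuffles. The shuffles are:

* **linear fields** - circular shift of the position series relative to the
  spikes (preserving both autocorrelations), per-bin 95th-percentile rate
  threshold, field = at least 8 consecutive 2-cm bins above threshold within
  one track block;
* **preferential recruitment** - circular spike-time shift, mean rate over
  all nonlocal periods;
* **tuning classification** - circular spike-time shift, recomputing spatial
  information, speed score (Pearson correlation of rate with speed over
  2-cm/s bins), head-direction score (resultant vector length over 10-degree
  bins), grid score (ratemap autocorrelogram correlation at 60/120 degrees
  minus 30/90/150, on an annulus excluding the central peak out to the map
  edge), border score ((longest wall span adjacent to one field minus the
  rate-weighted mean field distance from the nearest wall, half-box
  normalized) over their sum, with 2D fields = connected components of at
  least ten 2.5-cm bins above 0.25 Hz), and spatial stability (ratemap
  correlation between epoch halves). Spatial, grid, border and aperiodic
  flags additionally require the stability score to clear its own null;
  aperiodic = spatial and neither grid nor border.

Spatial information uses the rate-map (Skaggs) form of the mutual information
between firing rate and position, the standard reading; it equals log2 N
exactly for a unit firing in 1 of N equally occupied bins. Reward cells are
units whose per-poke firing rate during consumption is higher on rewarded
than unrewarded pokes by a one-sided Wilcoxon rank-sum test at alpha = 0.05.
The empirical type-I error of each shuffle rule is calibrated at 5% +/- 2%
in the acceptance tests over 200 seeded null runs (five independent null
units per run, 199-shuffle nulls, for which the strict greater-than-95th
percentile rule is exact at the 5% level for exchangeable continuous
statistics).

## LFP and sharp-wave ripples

The CA1 trace is bandpassed at 125-200 Hz with an equiripple FIR (5-Hz
transition bands; a long windowed-sinc design is the automatic fallback if
the Parks-McClellan iteration fails), applied zero-phase. Ripples are
detected where the Hilbert envelope, smoothed with a 4-ms Gaussian, exceeds
2 SD above baseline for at least 15 ms; boundaries extend outward to the
baseline-mean crossing and overlapping events merge. *Baseline* means the
mean/SD of the unsmoothed envelope (optionally over immobility only): with
smoothed-envelope statistics the same rule fires about 0.33 times/s on pure
stationary noise because smoothing stretches supra-threshold runs past the
15-ms rule, whereas the unsmoothed baseline keeps the null rate below 0.1/s
without losing injected 5-SD ripples - this is the one place where two
literal readings of the rule differ materially, so the choice is stated here.
The multi-unit variant applies the same rule to the population firing rate
smoothed with a 15-ms Gaussian (its own smoothed baseline; the z-scored
smoothed rate is the field's convention for population bursts).

SWR/nonlocal overlap is tested per session by moving each SWR to a random
time within a random immobility bout, 1000 times, one-sided at the 95th
percentile, reporting overlap in both directions. Spectral measures use
Welch averaging of Hanning-windowed 1-s segments for PSD and
magnitude-squared coherence (a multitaper estimator would be the classical
alternative; Welch with these window choices serves the same band summaries),
band power in type II theta (3-7 Hz), type I theta (7-11 Hz), fast gamma
(50-110 Hz) and ripple (125-200 Hz) bands, and instantaneous frequency via
bandpass, 15-sample Hanning smoothing and the Hilbert phase derivative.

## MEC-CA1 coordination

For each MEC-CA1 pair and each condition (local / nonlocal coding bouts),
the observed statistic is the CA1 firing rate inside the union of (1 ms,
10 ms] windows after every MEC spike in that condition, windows truncated at
bout edges and the rate normalized by actual window time. The null moves
each CA1 spike to a random time in a random immobility bout, 1000 times;
the window set stays fixed. A pair is significant in a condition when its
observed windowed rate exceeds the null's 95th percentile; pairs are
categorized local-only / nonlocal-only / both / neither. Spatial coherence
between regions is summarized as the fraction of confidence-kept 2-ms bins
in which the two decoders pick the identical position bin, split by the MEC
local/nonlocal condition; under independence this equals the sum of products
of the two marginal bin-occupancy distributions, which the tests verify under
permuted alignment.

## The synthetic-data generator

`simulate_session()` produces a complete session with known ground truth so
every stage above is testable without any recording:

* **Behavior**: trials in blocks of ten (southwest sample arm first), choice
  correct with probability `p_correct` under the rule; gamma dwells (mean
  4 s) at ports with sub-2-cm/s jitter; near-constant runs at ~25 cm/s;
  generated at 60 Hz, Hanning-smoothed (15 frames) and upsampled to 500 Hz,
  mirroring a camera-to-analysis pipeline.
* **Tuning**: per-region stratified Gaussian field centers tile the full
  track (sigma 5 cm, peaks ~10 Hz, baseline 0.5 Hz; 30% of units get a
  second field), so every bin is covered by several MEC fields; each MEC unit
  also carries a parametric 2D open-field class (grid / border /
  head-direction / speed / aperiodic) for the tuning-metric ground truth.
* **Events**: discrete constant-target episodes (not trajectories) injected
  into immobility as a Poisson process (0.5 events per immobile second,
  gamma durations with 250-ms mean), each with a single target at least
  20 cm of track distance away, drawn from a segment distribution enriched
  at rewards (or targeting the paired/unpaired opposite-end reward with a
  configurable probability). During an event, units with a field at the
  target fire at `event_gain` times their in-field rate while units with
  fields at the animal's position keep firing - local cells are *not*
  silenced (a config flag allows silencing for ablations). The within-event
  gain of remote-field cells is not an empirically constrained quantity, so
  it is a free parameter; the default of 2.0 was chosen a priori so the
  remote ensemble outvotes the still-active local ensemble in the population
  likelihood - with gain 1.0 the two ensembles are nearly symmetric
  and the decoded position flips between them.
* **CA1**: place-tuned to the *actual* position throughout (so MEC-remote
  bins show near-zero cross-region coincidence), with designated coupled
  pairs receiving lagged (1-10 ms) extra spikes after partner MEC spikes
  during non-event immobility only.
* **LFP** at 625 Hz: pink-noise background, movement theta at 8 Hz,
  immobility ripple bursts (165 Hz carrier, 70 ms, 5 SD) recorded as ground
  truth.

One master seed derives per-stage child seeds, making the entire session
bit-reproducible. What the generator does *not* emulate: theta phase
coding and sequences within movement, trajectory-like (sweeping) nonlocal
events, realistic spike waveforms and sorting artifacts, inter-animal
variability, slow nonstationarities (drift, satiety), and any LFP-spike
phase relationship. Tests passing on this generator therefore demonstrate
that the analysis chain recovers what it is defined to recover under its own
assumptions - not that real MEC data contain such events.

## Problem sizes and numerical choices

The test suite runs sessions of 8-12 trials with 30-40 MEC units for module
checks, and one 35-trial (~10-minute) session at the full task
conditions (100 MEC units) for the decoder-accuracy and event-recovery
checks; shuffle calibrations use 199-shuffle nulls over 200 seeded runs. The
`analysis/` scripts use a 30-trial session. These sizes were chosen so the
whole workflow runs on a single CPU at desk scale while leaving every rule
(thresholds, bin widths, shuffle logic) at its full-scale value. Other
numerical choices: emission math in log domain with per-bin max subtraction;
rate floor 1e-3 Hz; MAP ties to the lowest bin index; degenerate all-zero
emission rows renormalize to uniform rather than NaN; smoothing never
crosses track-block boundaries; the decoder's continuous kernel sigma is
interpreted in units of bins per time step and the "movement variance" of
the encoder-side training is treated as the same parameter (variance
1 bin^2), both configurable.

## Known limitations

* One session, one animal at a time; the group-level inferential statistics
  of a multi-animal study (paired tests, mixed-effects models) are out of
  scope by design.
* The 2D (non-linearized) decoder variant is not implemented.
* Ripple detection assumes a single representative CA1 channel; no
  multi-channel consensus.
* The duration-matching mechanism and the co-fire truncated-window
  normalization are reasonable choices where the procedure is otherwise
  underdetermined; both are seeded and documented above.
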