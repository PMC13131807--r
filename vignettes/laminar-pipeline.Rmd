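---
title: "Laminar dynamics of predictable attentional capture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar dynamics of predictable attentional capture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarpop)
```

# The scientific problem

In priming of pop-out (PoP) visual search, a monkey saccades to a color
oddball among uniform distractors. The target-defining color is fixed
within a block of trials and swaps between blocks, so the first trials
after a swap present an *unpredictable* sensory context while later
repetitions make the context *predictable*. Behaviorally, predictability
shortens reaction times and raises accuracy. Neurally, laminar recordings
in visual cortex let one ask where in the cortical column this benefit
arises: in the feedforward sweep through the granular input layer, or in
later, putatively recurrent, processing.

`laminarpop` implements the full analysis chain for such data as a
reusable package: multiunit activity (MUA) envelope extraction, current
source density (CSD) with functional laminar alignment, cluster-based
running nonparametric tests for the target selection time (TST),
predictable-minus-unpredictable contrasts of target enhancement
(&Delta;TE) and distractor suppression (&Delta;DS), reaction-time (RT)
quartile stratification and between-quartile variability, T-D-D-D-D
adaptation-sequence mining with Page's L trend test, and a synthetic
session generator with a complete ground-truth ledger that makes every
stage testable without any recorded data.

# Signal model and preprocessing

**MUA envelope.** Broadband voltage is band-passed 500--5000 Hz (4th-order
Butterworth), full-wave rectified, and low-passed at 250 Hz (half the
original high-pass edge), estimating the power of aggregate population
spiking. All filters run forward and backward (zero phase) over
reflection-padded data: latency estimates must not inherit a filter
delay, and reflection padding keeps startup transients out of the
pre-stimulus baseline. The 250 Hz stage doubles as the anti-alias filter
for decimation to the ~1 kHz analysis rate; with a 24414 Hz acquisition
rate the integer decimation factor 24 gives a realized rate of
1017.25 Hz, which all downstream windows handle through the explicit time
axis.

**CSD.** For interior contact `d` of a probe with uniform spacing `z`,

$$\mathrm{CSD}(t,d) = -\sigma\,\frac{x(t,d-z) + x(t,d+z) - 2x(t,d)}{z^2},$$

with conductivity `sigma` defaulting to 0.4 S/m. Under this convention
sinks (net inward current) are **negative**; published color maps often
flip the sign for display. The CSD is computed on the 1--100 Hz band of
the recording (the LFP range); the band edges are configurable.

**Normalization and smoothing.** Epochs of -300..+300 ms around array
onset are z-scored per trial and channel: divide by the SD of the 250 ms
pre-stimulus baseline, then subtract the (post-division) baseline mean.
Trials with a zero-variance baseline on any channel cannot be scaled and
are excluded and counted. A 15 ms "bidirectional" moving average is
applied; we read that phrase as a forward-then-backward boxcar (effective
triangular kernel, zero phase, unit DC gain) and also expose a centered
single-pass boxcar, since the wording admits both.

# Laminar alignment

The first stimulus-evoked sink appears in the granular input layer. The
trial-averaged, baseline-subtracted CSD map is searched 25--100 ms after
array onset for channels dropping below $-k$ baseline SDs ($k = 3$);
contiguous sink channels form regions, the region with the earliest
crossing wins, and the **bottom** (deepest channel) of that region is the
functional marker. Because ongoing noise occasionally dips below any SD
threshold, a crossing only counts if it persists for at least 10 ms --
evoked sinks last tens of milliseconds, noise excursions at 3 SD last a
couple. Compartments are then fixed spans of depth: *middle* (granular)
is the 0.5 mm up to and including the marker, *upper* the 0.5 mm above
that, *deep* the 0.5 mm below; with 0.1 mm spacing, five channels each,
truncated (and flagged) at the array edge. Whether the marker channel
itself belongs to middle or deep is not settled usage; we include it in
middle and provide a toggle. Sessions with no threshold crossing raise a
typed "no sink" condition and are excluded by the pipeline, and a marker
so close to the edge that fewer than three middle channels remain marks
the session unusable.

# Trial structure and behavior

Blocks are parsed from the target-feature sequence; `trial_in_block`
restarts at each swap. Trials 1--2 after a swap are *unpredictable*,
trials 3--15 *predictable*, later trials *excluded*. All neural analyses
use correct trials only; error trials are kept for the accuracy curve.
Within each session and context, correct trials are sorted by RT and
split into four contiguous quartile groups; when the count is not
divisible by four the extras go to the fastest groups, and ties are
broken stably by trial order (the quartile-remainder policy is not
dictated by anything in the data; it is simply fixed and documented).
Quartiling within context (rather than pooled) matches the four
behavioral groups per predictive context; a toggle selects the pooled
variant.

# Statistics

**Running cluster tests.** At each timepoint a two-sided Wilcoxon
rank-sum test (normal approximation with tie correction) or a
Kruskal-Wallis test compares the groups; samples with $p < 0.01$ and, for
the two-group test, a consistent direction form candidate clusters, and
clusters shorter than 25 ms (20 ms for the &Delta; contrasts) are
discarded. Minimum lengths convert to samples by rounding up at the
analysis rate. The TST is the onset of the earliest surviving cluster in
which the target response exceeds the distractor response; the paper
phrase "significantly higher" does not fix sidedness, so we use the
two-sided pointwise test plus an explicit direction requirement for
cluster membership. The suite calibrates the family-wise any-cluster rate
on smooth null data and documents a 5% bound.

**&Delta;TE / &Delta;DS.** Per session, the mean response waveform is
formed for each context x stimulus cell; &Delta;TE and &Delta;DS are the
predictable-minus-unpredictable differences for target and distractor
trials (negative &Delta;DS = suppression). Significance against baseline
is a running rank-sum between the per-session &Delta;(t) values and the
per-session mean of &Delta; over -250..0 ms -- the baseline-reference
construction is our choice, as the source only states that clusters
diverge from baseline -- with a 20 ms minimum cluster.

**Page's L.** For n subjects ranked over k ordered conditions,
$L = \sum_j j R_j$. The package computes the exact null by convolving the
single-subject distribution over all $k!$ permutations n times (default
for $k \le 8$; for n = 8, k = 4 the null has mean 200, variance 66.67 and
maximum 240) and the large-sample normal approximation; both are
reported. For predicted decreasing trends the column order is reversed so
the decline maps to the upper tail. With tied data, average ranks are
used and both references are approximations. In the adaptation analysis
the leading target position is displayed but excluded from the test
(k = 4 distractor positions).

**Repeated-measures ANOVA.** The accuracy-by-trial curve is tested with a
one-way within-subject ANOVA via direct sums-of-squares partitioning
(cross-checked against `aov` with an error stratum in the suite).

# Adaptation sequences

A qualifying sequence is a predictable-context target-in-RF trial
followed by four consecutive distractor-in-RF trials in the same block.
All five trials must be correct by default (the global correct-trial
restriction; toggleable), and sequences do not overlap (greedy from the
left; an overlap-allowed mode exists because the source is silent).
Sessions with fewer than 15 sequences are excluded. Early (58--78 ms) and
late (78 ms to saccade-minus-10 ms, hence trial-specific) windows are
averaged per compartment and sequence position, means are centered per
session across the five positions, and the four distractor positions
enter Page's L with a predicted decrease.

# The synthetic generator

`simulateSession()` emulates exactly the structure the analyses assume:

* block-structured trials with the feature swapping at boundaries and the
  target uniform over six positions;
* RT = 259 ms base - 15 ms in the predictable context +
  coupling x (-z-scored single-trial feedforward amplitude) + Gaussian
  noise (SD 30 ms), truncated at 150 ms -- the coupling (15 ms/SD) builds
  in the amplitude-to-RT link the quartile analyses must recover;
* accuracy rising as $\mathrm{plateau} - (\mathrm{plateau} -
  \mathrm{start})\,e^{-(t-1)/\tau}$ with start 0.70, plateau 0.92,
  $\tau = 1$ trial, which reproduces a roughly 20% relative improvement
  from trial 1 to 2 followed by a plateau;
* a gamma-shaped evoked transient (peak ~16 ms after the compartment
  latency; 50 ms in middle, 60 ms in upper/deep) plus a sustained plateau,
  350 ms long in total, with a shared lognormal-like trial-to-trial
  amplitude jitter (SD 0.15);
* target-in-RF responses scaled by 1 + 0.5 from the context's selection
  onset (134 ms unpredictable, 84 ms predictable);
* distractor-in-RF responses multiplied by $0.97^r$ after r consecutive
  distractor repetitions (reset by targets and block boundaries);
* an evoked LFP dipole (negative Gaussian trough across depth, width 1.5
  channels) whose second spatial derivative exhibits a granular sink; the
  generator records the *bottom of the injected sink region* -- which is
  what the functional marker estimates -- in its ground truth, not just
  the dipole center;
* ongoing Gaussian noise with per-context SD. The default is equal
  (1.15 a.u.) in both contexts: a context-asymmetric baseline SD feeds
  through single-trial z-normalization as a multiplicative gain on every
  normalized response and would confound the &Delta; contrasts, so
  asymmetry is something a user injects deliberately (as the variability
  tests do), not a default;
* one deterministic random stream per session keyed by the seed, so a
  configuration reproduces bit-for-bit.

Two fidelity modes exist because filter tests need full bandwidth and
analysis tests do not: envelope mode emits the MUA envelope and LFP at
1 kHz; broadband mode emits a 24414 Hz spike-band noise carrier
modulated by the injected envelope (plus the LFP), and returns the
injected envelope alongside for validation. The inter-trial interval is
uniform on 750--1250 ms by default, mirroring the task fore-period, but
the generator makes no fidelity claim about it and exposes it as
configuration.

**What the generator does not emulate:** biophysical spiking statistics,
eye-movement traces, oscillatory or 1/f structure in the LFP, cortical
curvature or non-uniform probe geometry, slow nonstationarities
(electrode drift, arousal), and feature-specific color processing.
Passing the suite therefore shows that the *procedures* recover what they
claim from data with the assumed structure -- not that real recordings
satisfy those assumptions.

# Numerical choices and degenerate inputs

* Zero-phase filtering everywhere a latency is later read off.
* Reflection padding for all smoothing/filtering edges.
* Minimum cluster lengths round *up* to samples.
* Sink crossings require 10 ms persistence (see above).
* Quartile extras to the fastest groups; stable ties.
* Zero-variance baselines exclude the trial, with a logged count.
* Empty compartments (a truncated map on a short probe) yield NA rows in
  window-mean matrices rather than errors.
* The exact Page null is used for inference when $k \le 8$; the normal
  approximation is always reported alongside. The two differ noticeably
  in the tails at n = 8 (e.g. at L = 215 the exact upper tail is 0.0376
  against 0.0331 from the normal curve), which is worth knowing when
  comparing against values computed by other software.

# Problem sizes used by the test suite

The suite validates parameter recovery at sizes chosen for a desk-scale
run: recovery of the selection onset uses 20 sessions of 400 trials on a
20-channel probe (with adaptation disabled so the selection stage is
isolated; recovered onsets sit a few ms early because the triangular
smoothing kernel leaks the step backwards, and the suite asserts a mean
absolute error under 10 ms); marker recovery uses full CSD alignment on
smaller sessions; the adaptation power check runs 100 replicates of 8
sessions x >= 15 sequences at adaptation factor 0.95 on an 8-channel
probe (only the middle-compartment channels matter for that test); the
false-positive calibration uses 1000 null replicates of 15-vs-15 trials
over 300 ms. Compressed inter-trial intervals (>= 450 ms) are used in
these runs; they stay long enough that one trial's 350 ms evoked response
can never reach the next trial's baseline window.

# Known limitations

* The pipeline pools trials across sessions at the compartment level for
  TST estimation; channel-level pooling across sessions (after alignment)
  is available per session but not across sessions.
* The paper-reported session-level quantities that depend on the recorded
  dataset (TST tables, onset latencies, ANOVA F values) are procedures
  here, validated on synthetic ground truth; the package does not claim
  to reproduce their numeric values.
* Page's exact null assumes tie-free rankings; heavy ties in small
  samples make both reported p-values approximate.
* The CSD condition comparison is descriptive (traces per condition), by
  design.
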