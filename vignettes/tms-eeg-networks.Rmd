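---
title: "Directed network analysis of TMS-evoked potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed network analysis of TMS-evoked potentials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepnet)
```

`tepnet` analyses how a transcranial magnetic stimulation (TMS) pulse
propagates through cortical networks measured with multichannel EEG, and how
that propagation differs between groups — the motivating application is the
comparison of healthy controls (HC) with alcohol-dependent participants in
early recovery (ALD) under single- and paired-pulse stimulation of the left
and right prefrontal cortex. This vignette describes the models, the choices
behind every tunable, and what the synthetic validation does and does not
establish.

## The measurement model

After each test pulse, every channel records an evoked potential: a damped
oscillation lasting a few hundred milliseconds. Analysis starts at +50 ms so
that the pulse artifact (and the conditioning-pulse window in paired trials)
never enters the data. Two derived windows matter:

* **50–150 ms** — the rectified area under the averaged evoked potential
  (ERP) quantifies the response strength entering the inhibition statistic;
* **50–350 ms** — the network analysis window, long enough to span
  cross-cortical conduction delays up to 150 ms.

**LICI.** In the paired-pulse paradigm (conditioning pulse, 100 ms
inter-stimulus interval, test pulse) the conditioning pulse suppresses the
test response. Inhibition is quantified as

$$\mathrm{LICI} = \left(1 - \frac{\mathrm{AUC}_{\text{conditioned}}}
{\mathrm{AUC}_{\text{unconditioned}}}\right) \times 100,$$

with the rectified AUC taken per channel (trapezoidal rule) and averaged
over channels before the ratio; positive values mean inhibition, 100 is
maximal, negative values facilitation. Because the statistic is a ratio it
is invariant to any common gain, so a noise-free suppression factor $s$ maps
exactly to $(1-s)\times 100$ — the property the test suite checks at
machine precision. The per-channel AUCs and their sum are also exposed,
since published pipelines do not always state the aggregation.

**Connectivity.** For channels $i, j$ the edge weight is the Pearson
cross-correlation $c(\tau)$ maximised over integer-sample delays
$\tau \in [0, 150]$ ms, computed on the overlapping segments with
overlap means and SDs, so every value stays in $[-1, 1]$ at every lag. A
positive maximising delay means the second signal is a delayed copy of the
first; the candidate edge points from the leading to the lagging channel.
Of the two ordered weights per pair only the larger is kept (an exact tie —
always the case at $\tau = 0$, where $c$ is symmetric — keeps the edge led
by the lower channel index), and edges below an absolute threshold of 0.6
are removed, non-strictly, so a weight of exactly 0.6 survives. The signed
maximum is used, not the absolute value: strongly anti-correlated pairs
cannot pass a positive threshold. Correlation is computed on the
condition-averaged ERP trace by default; a per-epoch mode that averages the
per-epoch weight matrices is available behind a flag.

**Graph metrics.** All four metrics are computed on the binarised directed
graph:

* *Mean degree* — per node, the number of distinct neighbours (an edge in
  either direction). On the pipeline's graphs, which carry at most one
  direction per pair, this equals $k_{in} + k_{out}$ and the mean equals
  $2|E|/N$; counting neighbours rather than arcs keeps the mean bounded by
  $N-1$ on any input and makes the complete graph a fixed point of all four
  metrics at $(N-1, 1, 1, 1)$.
* *Clustering* — $C_i = 2t_i / k_i(k_i-1)$ on the undirected projection,
  with $C_i = 0$ when $k_i < 2$; with one direction per pair the projection
  is lossless for triangle counting. Directed-cycle clustering variants
  (which halve these values on dense one-direction-per-pair graphs) are out
  of scope.
* *Path length* — breadth-first distance respecting edge direction, with
  $L_{ij} = \infty$ for unreachable ordered pairs.
* *Global efficiency* — $\mathrm{GE} = \frac{1}{N(N-1)}\sum_{i \ne j}
  L_{ij}^{-1}$ with $1/\infty := 0$; *local efficiency* — the global
  efficiency of the directed subgraph induced on each node's neighbourhood
  (the node removed), zero for fewer than two neighbours. Whether published
  efficiencies used directed or symmetrised distances is rarely stated;
  directed is the default here and `symmetrize = TRUE` provides the other
  reading.

**Group statistics.** The metric table feeds a 2×2×2 mixed ANOVA (between:
group; within: pulse, side) with listwise deletion of incomplete
participants, partial $\eta^2 = SS_{\text{effect}} / (SS_{\text{effect}} +
SS_{\text{error}})$ per stratum, and Sidak-adjusted simple effects on
request. Discrimination is assessed by binomial logistic regression on
z-scored predictors (sample-SD convention) — reported as inverted odds
ratios $e^{-B}$ with inverted Wald CIs, so a unit *decrease* of a predictor
maps to the reported odds multiplier, plus Nagelkerke $R^2$ and the
0.5-cutoff classification table — and by the ROC AUC computed as the
Mann–Whitney ranking probability with midrank ties and a Hanley–McNeil
95 % CI. Clinical associations use Pearson correlations within the patient
group.

## The synthetic cohort generator

No public TMS-EEG cohort accompanies the motivating study, so validation
rests on a generator that plants known structure:

* Each channel carries its own phase-locked damped-oscillation template.
  The classic evoked waveform exposed by `generate_evoked_template()` uses
  2–3 components at 4–40 Hz; the per-channel background templates use a
  richer mixture (8–12 components, 4–60 Hz, decays up to 300 ms). The
  richer family is deliberate: over a 300 ms window, two *independent*
  2–3-component traces already reach lag-maximised correlations near 0.6,
  which would saturate every graph at the threshold; with the richer
  mixture the chance correlation between uncoupled channels stays well
  below it.
* A planted coupling table (source, target, gain, lag) mixes lag-shifted
  source templates into target channels with unit-variance weights
  $\sqrt{1-g^2}\,\cdot\,$own $+\, g\,\cdot\,$shifted source, so a planted
  gain *is* the planted noise-free correlation and planted lags sit on the
  sample grid (the default hub uses lags on a 4 ms grid, exact at both
  1000 Hz and 250 Hz). The default is a hub: channel 1 drives the other 19
  with gains 0.70–0.99, which yields mean degrees around 16–18 of a possible
  19 at the 0.6 threshold — the density regime reported for TMS-evoked
  scalp networks.
* Paired-pulse trials are scaled by a suppression factor: 0.5 for HC
  (LICI ≈ 50) and 0.8 for ALD (LICI ≈ 20), i.e. reduced inhibition in the
  patient group. Suppression is a pure gain, so it moves the LICI statistic
  but not, in the noise-free limit, the correlation graph.
* The group effect: coupling gains are multiplied by `ald_coupling_factor`
  only for ALD participants in the paired-pulse left-PFC cell. The true
  effect size in this population is unknown, so it is a free parameter; the
  default 0.75 plants a degradation of roughly 2–3 within-cell standard
  deviations in mean degree, large enough that the replicate study design
  has its intended sensitivity while remaining confined to one cell.
* Between-participant variability comes from a log-normal coherence factor
  (`coherence_sd`, default 0.08) multiplying all of a participant's gains;
  within the ALD group the synthetic SADQ severity score decreases linearly
  in that coherence (plus noise), planting the negative
  severity–connectivity association. Only the sign of that link is treated
  as meaningful.
* Measurement noise is white (5 µV SD against a 10 µV RMS evoked response,
  per-trial SNR 2). Trial averaging shrinks it by $\sqrt{n}$; one real
  consequence survives averaging: cells with smaller evoked amplitude (a
  stronger suppression) retain relatively more residual ERP noise, which
  attenuates their correlations slightly. In the null configuration used
  for calibration checks the suppression factors are therefore equalised
  across groups — with `ald_coupling_factor = 1` that makes the two groups
  statistically exchangeable.

What the generator does **not** model: volume conduction and reference
leakage, non-stationary or trial-varying evoked responses, oscillatory
phase resetting, eye/muscle artifacts (rejection is exercised with planted
amplitude spikes instead), and any biophysical (neural-mass) dynamics.
Passing tests therefore certify the *pipeline* — recovery of planted lags,
gains, effects and associations through every processing stage — not the
neurophysiological validity of lagged correlation as a connectivity
measure on real EEG.

## Numerical choices and degenerate inputs

* Filtering is zero-phase (forward–backward FIR), preserving the evoked
  latencies the lag analysis depends on; bandpass order defaults to three
  periods of the lowest passband frequency, capped by the data length, and
  the notch is applied after the bandpass (linear filters commute; the
  order only matters for bit-exactness). The re-cut to 50–350 ms is taken
  from the wider epochs rather than re-filtering, avoiding double edge
  effects.
* The lag scan uses prefix sums for overlap means and variances and one
  cross-product per lag; a constant overlap segment has no defined
  correlation — such pairs are reported and their weight set to 0
  (`lagged_crosscorr()` on a single pair raises a typed error instead).
  Results are clipped to $[-1, 1]$ against rounding.
* Ties in the lag scan resolve to the smallest delay; direction ties to the
  lower-index leader. Thresholding keeps weights exactly at the cutoff.
* Shortest paths use simultaneous breadth-first search via boolean matrix
  powers — exact for graphs of this size and much faster in R than
  per-node queues.
* Degenerate statistics inputs raise typed errors: fewer than two
  participants per group (ANOVA), zero-variance predictors (z-scoring),
  single-class labels (AUC), fewer than three pairs (correlations).
  Quasi-separated logistic fits are flagged `converged = FALSE` but their
  coefficients are still reported.

## Problem sizes used in validation

The replicate studies in the test suite run the full design — 27
participants (16 HC, 11 ALD), 20 channels, both sites and pulse types —
at a 250 Hz analysis grid with 8 trials per condition cell, 200 replicates
for the planted-effect signature and 120 for the null calibration; these
sizes are the package's validation defaults and are deliberately smaller
than the acquisition-scale defaults of `sim_config()` (1000 Hz, 75 trials).
At 250 Hz the 4 ms default lags remain exactly on the sample grid, and with
8 trials the residual ERP noise is still an order of magnitude below the
evoked response. Lag-recovery checks run at 1000 Hz where the full
[0, 150] ms lag range is exercised sample by sample.

## Known limitations

* The hub-shaped default coupling creates feed-forward (near-acyclic)
  graphs; directed global efficiency is therefore dominated by forward
  reachability and sits below values typical of recurrent real networks.
  The metric code is validated on arbitrary digraphs regardless.
* The clustering convention is the undirected-projection formula; published
  toolboxes sometimes use directed-cycle variants that give systematically
  smaller values on dense one-direction-per-pair graphs.
* The absolute 0.6 threshold is taken as given (with monotonicity across
  0.5–0.9 verified); no attempt is made to optimise thresholding.
* ROC AUCs for the planted hypothesis are reported directionally (lower
  metric indicates the patient group); orientation-corrected AUCs are also
  available and never fall below 0.5 by construction.
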