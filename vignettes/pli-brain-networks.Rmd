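---
title: "Phase-lag-index connectivity and weighted brain networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag-index connectivity and weighted brain networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plinet)
```

## The analysis in one paragraph

`plinet` quantifies frequency-specific functional coupling between EEG
channels with the phase lag index (PLI), summarizes the resulting weighted
connectivity graphs with two weighted graph measures — the mean weighted
clustering coefficient $C_w$ and the mean weighted shortest path length
$L_w$ — normalizes both against edge-shuffled surrogate networks, and
compares groups of subjects with log-transformed pooled t-tests. Because
resting-state clinical EEG is rarely shareable, the package also contains a
seeded coupled-oscillator simulator that produces multichannel cohorts with
*known* band-specific phase-lag coupling, so that every stage of the
pipeline can be validated against ground truth.

## Phase lag index

For two channels with instantaneous phases $\phi_a(t), \phi_b(t)$ (argument
of the Hilbert-transform analytic signal of the band-filtered series), the
phase difference $\Delta\phi(t)$ is wrapped to $(-\pi, \pi]$ and

$$\mathrm{PLI} = \left| \langle \operatorname{sign} \Delta\phi(t) \rangle_t \right|
\in [0, 1].$$

PLI is 0 when phase differences are symmetric around 0 or $\pi$ — in
particular for *zero-lag* synchrony, which is what instantaneous volume
conduction produces — and 1 for perfect locking at any nonzero lag. The
directed variant replaces the sign with a Heaviside step ($H(0) = 0.5$):
$\mathrm{dPLI} = \langle H(\Delta\phi) \rangle_t$, with values above 0.5
meaning the first channel leads. With these conventions the identity
$|2\,\mathrm{dPLI} - 1| = \mathrm{PLI}$ holds exactly, which the test suite
asserts; choosing $\operatorname{sign}(0) = 0$ and $H(0) = 1/2$ is what
keeps it exact on degenerate zero-lag samples.

Connectivity is computed per epoch on all channel pairs and averaged
entrywise over epochs. Summaries follow the standard layout: the global
mean over all pairs, and means over a frontal cluster (Fp1, Fp2, F7, F3,
Fz, F4, F8), a posterior cluster (P3, Pz, P4, O1, Oz, O2) and the
fronto-posterior (long-range) cross pairs — 21, 15 and 42 pairs
respectively.

## Weighted graph measures and surrogate normalization

Electrodes are nodes; the PLI matrix supplies symmetric edge weights
$w_{ij} \in [0, 1]$. The weighted clustering coefficient of node $i$ is

$$C_i = \frac{\sum_{k \ne l} w_{ik} w_{kl} w_{li}}
             {\sum_{k \ne l} w_{ik} w_{il}},$$

with $C_i = 0$ for isolated vertices, and $C_w$ is the mean over nodes.
Path lengths use the inverse weights as edge lengths: the distance between
two nodes is the minimum of $\sum 1/w$ over connecting paths (Dijkstra's
algorithm), $L_i$ is the arithmetic mean of distances from $i$ to all
others (self-distances excluded), and $L_w$ the mean of $L_i$.

Raw $C_w$ and $L_w$ depend on the overall PLI level and its dispersion, so
both are divided by their means over `n_surrogates` (default 50) surrogate
networks obtained by uniformly permuting the upper-triangle weights
(preserving the weight multiset exactly). The small-world index is
$S = (C_w / C_w^{surr}) / (L_w / L_w^{surr})$; following the usual
convention the package reports the raw numbers rather than imposing a hard
small-world classification (values of $S$ above 1 with elevated normalized
clustering point to small-world organization).

Numerical choices: a zero-weight edge is treated as *absent* (infinite
length) and a disconnected graph is a hard error naming an unreachable pair
— never a silent large distance. Surrogates that happen to be disconnected
(only possible when exact zero weights are present) are resampled and the
event counted. The surrogate RNG stream is seeded independently of the
simulation stream, so connectivity results are unchanged by normalization
settings. Graph metrics are computed per epoch and then averaged
(`graph_on_epochs = TRUE`); computing them on the epoch-mean matrix instead
is available as a sensitivity switch. The subject-level $S$ is the mean of
per-epoch $S$, so it equals the ratio of the averaged normalized metrics
only approximately.

## Preprocessing

Band definitions are delta 0.5–4, theta 4–8, lower alpha 8–10, upper alpha
10–13, beta 13–30 and gamma 30–45 Hz. Filtering uses a 4th-order
Butterworth band-pass applied forward and backward (zero phase, no group
delay; the test suite checks that a symmetric pulse keeps its peak sample).
Continuous recordings are filtered first and then cut into six contiguous
4096-sample epochs from the start of the recording. Phases come from the
FFT-based analytic signal per epoch. The first and last few samples of an
epoch carry Hilbert edge effects; phase-slope examples in the tests
therefore evaluate the central 90% of the epoch, while the PLI itself uses
all samples — at 4096 samples the contamination is a handful of samples and
negligible against the tolerances used.

## The synthetic cohort generator

Each channel $c$ carries one oscillator per band $b$ whose phase evolves as

$$\theta_{cb}(t + 1) = \theta_{cb}(t) + 2\pi f_{cb} / f_s + \sigma_b\,\epsilon_t,$$

a phase-diffusion process around a per-channel center frequency
$f_{cb} = f_b + \delta_{cb}$. The signal is the sum of the band cosines
plus 1/f (spectrally shaped) background noise. A coupling pins the
follower's band phase to the leader's phase minus a lag via the circular
mixture $\arg[(1 - s) e^{i\theta_{free}} + s\,e^{i(\theta_{leader} - lag)}]$,
so tracking tightness — and hence downstream PLI — grows monotonically with
the strength $s$; at $s = 1$ with zero diffusion the lag is constant and
the PLI is exactly 1. Zero-lag mixing (volume conduction) is a separate
instantaneous matrix multiplication of the signal rows.

Two noise scales are deliberately distinct:

* **Phase diffusion** `sigma` (default 0.15 rad/$\sqrt{\text{sample}}$,
  about a 1.8 Hz Lorentzian linewidth at 500 Hz) keeps each component
  recognizably band-limited. Larger values would decorrelate uncoupled
  channels faster, but they broaden the components until adjacent bands
  interfere and band-specific coupling stops being recoverable.
* **Center-frequency jitter** `freq_jitter` (default
  $\min(\max(1.2, 0.1 f), 0.45 f)$ Hz, drawn once per channel) emulates
  individual peak-frequency variation. The resulting linear phase drift
  between uncoupled channels makes the sign of their phase difference
  cancel over an epoch, driving the uncoupled phase-level PLI below 0.1
  (about 0.09 averaged over seeds) while leaving couplings with
  $s > 0.5$ intact, since the pinned term then dominates the circular
  mixture at every sample.

### The PLI noise floor of band-limited epochs

A point worth knowing when interpreting any PLI analysis: after band-pass
filtering, the phase difference of two *independent* channels is smoothed
on the filter's time scale, so one epoch contains only roughly
$T \times BW$ independent sign samples and the expected PLI of uncoupled
channels is about $\sqrt{2 / (\pi\, T\, BW)}$ — about 0.10–0.13 for theta
(4 Hz wide) at 4096 samples and 500 Hz, and about 0.05–0.07 for beta (17 Hz
wide). This floor is a property of the epoch length and bandwidth, not of
the generator. Consequences adopted here: uncoupled-channel tests assert
the sub-0.1 level on the oscillator phases themselves, and the
volume-conduction property (mixed independent sources must stay PLI-silent
while being strongly coherent) is demonstrated in the beta band, where the
floor leaves room below the 0.1 criterion. Observed group-level PLI in
narrow bands should always be read relative to this floor.

### Cohort templates

The built-in templates emulate a fragile-X-like contrast over *identical*
coupling structures that differ only in strength: a theta-band hub (leader
Fz, followers P3, Pz, P4, O1, O2) strong in the FXS-like group (s = 0.6)
and weak in controls (0.15); upper-alpha and beta hubs (leaders Oz and Cz)
with the reverse pattern (0.15 vs 0.5). Followers are pinned to the same
leader with *distinct* lags (0.9, −0.9, 1.8, −1.8, 2.7 rad), so every pair
inside a block holds a constant nonzero phase difference and the realized
PLI matrix carries a dense synchronized block rather than scattered strong
edges. The geometry matters for the path-length direction: edge-shuffled
surrogates scatter strong weights uniformly, which shortens average
distances more effectively than a concentrated block does, so a dense block
drives normalized path length above 1 — disjoint strong pairs, by
contrast, look just like their own surrogates. The published group
contrasts report no usable effect magnitudes, so the templates are
calibrated by direction, not size: recovery tests assert signs, never
values.

Per-subject seeds are a deterministic hash of the master seed and subject
index, so cohorts are bit-reproducible and stable under subject reordering.

## Group statistics

Measures are natural-log transformed (they are positively skewed; the base
is irrelevant to t-statistics) and compared with pooled-variance two-tailed
independent t-tests, $df = n_1 + n_2 - 2$, with partial eta squared
$t^2 / (t^2 + df)$ as effect size. The pooled rather than Welch form
matches the conventional reporting for this design. No multiple-testing
correction is applied across bands — mirroring standard practice for this
analysis layout — and the group table reports every test performed so the
reader can count them. PLI–power confounds are screened by correlating,
within each group, subjects' global PLI with their band power (Pearson,
two-tailed p via the t transform). The a-priori power analysis inverts the
noncentral-t power curve (noncentrality $d\sqrt{n/2}$, $df = 2n - 2$): the
conventional large effect $d = 0.8$ at $\alpha = .05$ and power .80
requires 26 subjects per group.

A PLI of exactly zero would break the log transform; with full matrices the
global and cluster means are strictly positive in practice, and the
statistical layer raises an explicit error rather than silently dropping
such values.

## Validation strategy and problem sizes

Every operation with a closed form is tested against hand-computed values;
the two graph measures are additionally checked against independent
oracles: a naive triple-loop for the clustering equation (100 random graphs
up to 10 nodes, agreement to 1e−12) and exhaustive simple-path enumeration
(100 graphs up to 7 nodes) plus an independent graph library for shortest
paths. Surrogate normalization is calibrated on graphs with i.i.d. weights,
where all three normalized ratios must sit within 1 ± 0.05. Cohort-level
checks use 20 replicate cohorts at the full study geometry (8 vs 12
subjects, 26 channels, six 4096-sample epochs, 6 bands, 50 surrogates) for
direction-of-effect recovery, and 500 reduced null cohorts (3 channels, one
epoch, theta only — sized so the calibration runs in about a minute) for
the type-I error rate, which must lie in [0.03, 0.07] at $\alpha = .05$.

What passing these tests does *not* show: the generator contains no head
model or lead fields, no spatially correlated noise, no artifacts, and no
1/f slope differences between groups, so recovery on synthetic cohorts
demonstrates the pipeline's correctness and sensitivity, not robustness to
the full messiness of scalp EEG.

## Known limitations

* The montage ships with the asymmetric 26-electrode set as published
  (FC6 without FC5); it is overridable in the configuration.
* The frontal cluster interprets the published "PP2" electrode as Fp2,
  completing the 7-electrode frontal set.
* dPLI is computed and reported but not fed into graph metrics (PLI is the
  weight definition there).
* Laterality of cluster connectivity is not modelled.
* EDF support is a minimal 16-bit reader/writer (single-record layout on
  write) intended for interchange of synthetic cohorts, not a full
  implementation of the specification's annexes.
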