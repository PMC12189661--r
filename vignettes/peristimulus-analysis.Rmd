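---
title: "Peri-stimulus response analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-stimulus response analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(nigrastim)
```

# The measurement model

A cohort of substantia nigra neurons (SNc or SNr) is recorded around a
high-frequency stimulation train (100 Hz for 1 s) delivered to primary
motor cortex. Every spike train is aligned so that stimulation onset is
`t = 0`, and time is partitioned into three contiguous half-open
windows:

| window | default span | meaning |
|---|---|---|
| BE | `[-20, 0)` s | pre-stimulus baseline |
| TT | `[0, 1)` s | the tetanization train itself |
| PE | `[1, 21)` s | post-event period |

The defaults come from the recording span (20 s either side of the
event) and the 1 s train; all three are configurable through
`window_def()`. The primitive statistic is the mean window rate, count
over duration: `M_BE`, `M_TT`, `M_PE` in spikes/s. Bins and windows
are half-open on the right throughout, so a spike exactly on a
boundary belongs to the window to its right and no spike is ever
double-counted.

## Response classification

Each neuron receives a peri-stimulus half-label — tetanic depression
(TD) when `M_TT < M_BE(1 - eps)`, tetanic potentiation (TP) when
`M_TT > M_BE(1 + eps)` — and a post-stimulus half-label (PTD/PTP) by
the same rule on `M_PE`. The combined label is one of TD-PTD, TD-PTP,
TP-PTP, TP-PTD; if either half falls in the dead-band the neuron is
non-responsive (NR) and excluded from the four-type table.

The dead-band default is `eps = 0`, a strict sign rule under which
only exact ties are NR. This is a deliberate design choice: reported
four-type tables whose columns sum to 100% imply that the original
discrimination assigned every neuron a direction, and a nonzero
dead-band interacts badly with small genuine effects. Concretely, the
smallest published fold change (1.12 for the post-event window of
melanin-treated SNc TP-PTD neurons) corresponds to a rate shift of
about 1 Hz on a ~10 Hz baseline; with 20 s windows the sampling noise
of the rate estimate is ~0.45 Hz, so a 5% dead-band would misroute
roughly a fifth of those neurons into NR and visibly distort every
other type's share of the classified pool. Users analysing noisier
recordings can still set `epsilon > 0`; the trade-off is theirs to
make. Degenerate cases follow documented conventions: a zero baseline
with window activity is potentiation; an all-zero neuron is NR.

Classification is scale-invariant (multiplying all three rates by a
positive constant cannot change any label) and deterministic.

## Fold-change ratios

The reported per-type ratios `M_BE/M_TT` and `M_BE/M_PE` use the
magnitude convention `max/min`, so both excitatory and inhibitory
types report a ratio at or above 1; published ratio tables print
values > 1 on both sides, which a directional quotient cannot
reproduce coherently. This interpretation is the single most
consequential reading the package commits to. When one rate is zero
the ratio is capped (default `1e6`) and flagged rather than infinite;
when both are zero it is undefined and flagged.

Group-level ratios are computed from *pooled* window rates — counts
summed over the type's neurons before dividing by time — rather than
averaging per-neuron ratios. The pooled form matches summed peri-event
histograms and avoids the heavy small-sample bias of ratios formed
from 1-second single-neuron counts (a neuron contributing 2 spikes to
the TT window would otherwise dominate the mean ratio). With equal
window durations across neurons the pooled rate equals the mean of the
per-neuron rates exactly; the package tests assert that identity to
`1e-12`.

# The synthetic cohort generator

Because the recordings the analysis was designed around are not
deposited anywhere, the package ships a generator that emulates their
statistical structure, and every pipeline stage is validated by
closed-loop parameter recovery: plant known parameters, run the full
analysis, require the printed summaries to come back.

One neuron is generated as a piecewise-homogeneous Poisson process:
its window counts are Poisson with mean `rate x duration`, and spike
times are uniform within the window. Poisson is the simplest process
that carries the window-rate structure the analysis reads; real nigral
trains are burstier, so a `dispersion` knob (negative-binomial counts,
variance = dispersion x mean) is exposed for sensitivity analysis but
defaults to 1. What the generator deliberately does **not** emulate:
refractory periods, burst structure, inter-spike-interval shape,
adaptation within windows, or any correlation between neurons. Passing
recovery tests therefore demonstrates that the analysis inverts its
own generative assumptions — not that those assumptions exhaust real
data.

Per-cohort structure:

* **Type mixture.** Types are assigned by deterministic
  largest-remainder (Hamilton) quota allocation of the configured
  mixture over `n` neurons, not by independent multinomial draws, so
  realized counts match the mixture exactly and proportion-recovery
  tests are sharp. Ties in fractional remainders break by position
  order, keeping the allocation reproducible.
* **Baseline rates** are uniform on 8–12 Hz by default. Tonic nigral
  firing spans roughly 1–8 Hz; the default sits at the top of that
  range because the 1 s tetanization window must carry enough counts
  for a sign comparison (at 2 Hz the TT window of a 5-fold-depressed
  neuron would average 0.4 spikes). No per-neuron rate distribution is
  published, so the uniform choice is a modelling decision, made once
  and configurable via `baseline_rate_range`.
* **Fold changes.** For a depressed window the true rate is
  `r_be / fold`, for a potentiated one `r_be * fold`, with per-type
  folds taken from the published ratio tables in the six presets
  (`cohort_presets()`). Preset cohort sizes default to the recorded
  group sizes (107/135/105/184/95/141). The recorded per-group sizes
  sum to 767 although the source text also states a 622-neuron total;
  the per-group numbers are treated as authoritative.
* **Seeding.** All cohort randomness derives from `spec$seed`
  (default 20250528); the same spec reproduces byte-identical tables.
  `run_pipeline()` derives one sub-seed per cohort from its master
  seed so cohorts are independent streams, and logs the seed on every
  run.

## What recovery can and cannot promise

With the published fold scales, per-neuron misclassification
probability is below `1e-3` for the strongly-folded types (measured by
`misclassification_rate()` at n = 10 000). It is *not* uniformly below
that for near-unity folds: a fold of 1.12 on a 20 s window at ~10 Hz
sits about one standard error from the decision boundary, and no
dead-band choice fixes that — it is an information limit of the window
lengths, not an implementation defect. Consequently a 100-neuron
cohort recovers its planted integer percentages exactly at most seeds,
but a single 1-in-1000 count fluctuation among the dozens of neurons
of other types occasionally shifts one cell by a percentage point.
Exact-recovery checks should be read with that sampling caveat in
mind.

# Spike detection

The detector mirrors a hardware window discriminator: contiguous
supra-threshold excursions yield one candidate event at the extremum
sample, accepted only when the extremum amplitude lies inside the
configured window (`[a_min, a_max]`), with a refractory rule (default
1 ms) dropping events too close to the last accepted one. The
extremum-in-window rule (rather than amplitude-at-first-crossing) is
the behaviour of the analog discriminators such rigs emulate. The
original thresholds are not published; defaults (threshold 0.05 mV,
window 0.1–0.25 mV, positive polarity) are package choices scaled to
the synthetic template's 0.15 mV peak over 0.01 mV noise (amplitude
SNR 15).

Raw traces are synthesized as template copies (alpha-function
waveform, peak on the sample grid) plus Gaussian noise, with the true
spike times retained for scoring. Trace synthesis assumes the template
duration is small compared with the minimum inter-spike interval;
validation fixtures enforce a 3 ms refractory period on generated
trains before synthesis, since overlapping waveforms merge into single
threshold excursions and no single-channel amplitude discriminator can
separate them. Detection scoring (`score_detection()`) uses greedy
one-to-one matching within 1 ms; an empty detection set reports
precision 1 by convention, flagged.

# Statistics

The group-comparison battery follows common practice for proportion
tables and window-rate samples:

* `proportion_test()` — two-sided two-proportion z-test with pooled
  variance; when any expected cell of the 2x2 table is below 5 it
  falls back to Fisher's exact test and flags the result. Package
  tests verify the exact branch is identical to `fisher.test()` and
  that the z branch is anticonservative relative to the conditional
  exact test on all small tables, with type-I error near nominal
  (within [0.03, 0.07] at alpha = 0.05 over 10 000 null tables).
  Counts reconstructed from published percentages use
  `round(pct x n)`.
* `students_t()` / `cohens_d()` — pooled-variance t (Welch optional)
  with the df-weighted pooled-SD standardized mean difference
  attached.
* `one_way_anova()` / `tukey_hsd()` — base R `aov` and `TukeyHSD`;
  for two groups `F = t^2` exactly and Tukey reproduces the t-test.
* `assumption_checks()` — Shapiro–Wilk per group and mean-centered
  Levene (one-way ANOVA on absolute deviations from group means),
  cross-checked against `car::leveneTest(center = mean)`.

No multiplicity correction is applied across the type-by-region
comparison grid by default, matching the raw-p-starring convention of
the tables being emulated; results carry the raw p-values so any
correction can be applied downstream. Alpha is 0.05 throughout. Which
sample underlies the published region-contrast effect size is not
stated in the source material; `run_pipeline()` computes its SNc-vs-SNr
t/Cohen's d on per-neuron post-event rates and labels that assumption
in the report.

# Problem sizes and numerical choices

The validation suite uses cohorts of 100–500 neurons (recovery), a
10 000-neuron side simulation for misclassification rates, 10 000
simulated null tables for test calibration, and 2 000 s windows for
rate-consistency checks — sizes at which every recovered quantity's
Monte-Carlo error is several times smaller than the tolerance it is
checked against, while a full run stays interactive on a laptop.
Other numerical conventions: windows and bins half-open on the right;
PETH bin width 1 s by default (no bin width is published; the last bin
is truncated and flagged if the width does not divide the span);
difference curve defined as averaged bin rate minus pooled baseline
rate (the source names such a curve without defining it); fold-change
cap `1e6`; proportions reported both exact and integer-rounded, the
rounded form being what the published tables print.

# Known limitations

* The generator's Poisson independence assumptions (above) bound what
  recovery tests can claim about real recordings.
* NR neurons are excluded from the four-type table; with `eps = 0`
  NR is essentially ties-only, but with user-set dead-bands the
  reported proportions condition on responsiveness.
* The detector is single-channel and single-unit: no spike sorting,
  no overlap resolution, no drift handling.
* Raw traces are exchanged as in-memory objects and CSV; no HDF5
  container is provided.
* Fold-change recovery at the 1 s tetanization window needs pooled
  counts; per-neuron TT ratios at tonic rates are intentionally not
  reported.
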