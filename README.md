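# nigrastim

Peri-stimulus spike-train analysis of substantia nigra neurons under
high-frequency stimulation (HFS) of the primary motor cortex.

## The problem

Extracellular recordings from the substantia nigra pars compacta (SNc,
dopaminergic) and pars reticulata (SNr, GABAergic) are a standard way
to probe how cortical drive reaches the basal ganglia — in healthy
animals, in toxin-induced Parkinsonian models, and under candidate
neuroprotective treatments. A 100 Hz, 1 s stimulation train is
delivered to motor cortex (M1) while single-neuron spike trains are
recorded, aligned to stimulation onset. The analysis question is: how
does each neuron's firing rate change during and after the train, and
how do those changes distribute across experimental groups?

`nigrastim` implements that analysis end to end for anyone working
with event-aligned spike trains:

* **Windows.** Time is split into three half-open windows around the
  stimulation onset at `t = 0`: baseline `BE = [-20, 0)` s,
  tetanization `TT = [0, 1)` s, post-event `PE = [1, 21)` s. Mean
  rates M_BE, M_TT, M_PE (spikes/s) are counts over durations.
* **Classification.** Each neuron gets a peri-stimulus label —
  tetanic depression (TD) if M_TT < M_BE, tetanic potentiation
  (TP) if M_TT > M_BE — and a post-stimulus label (PTD / PTP) from
  M_PE vs M_BE, combining into the four response types TD-PTD,
  TD-PTP, TP-PTP, TP-PTD. An optional relative dead-band ε around
  the baseline declares near-ties non-responsive.
* **Group summaries.** Type proportions (percent of classified
  neurons) and magnitude fold-change ratios per type,

      M_BE/M_TT = max(M_BE, M_TT) / min(M_BE, M_TT)   (and likewise M_BE/M_PE),

  computed from *pooled* window rates (counts summed over neurons
  before dividing), so the 1 s tetanization window is never a ratio
  of tiny per-neuron counts. The magnitude convention reports a
  ratio ≥ 1 for both excitatory and inhibitory types.
* **PETH / raster.** Summed and averaged peri-event time histograms,
  a difference curve (averaged rate minus pooled baseline), and
  per-neuron raster export.
* **Synthetic cohorts.** A ground-truth generator producing
  piecewise-homogeneous Poisson spike trains with quota-allocated
  type mixtures and per-type fold changes, preconfigured with the six
  published group/region presets (`control`/`rotenone`/`rotenone+BM`
  × `SNc`/`SNr`). Optional raw-trace synthesis plus an
  amplitude-discrimination spike detector close the loop from
  voltage trace to classified cohort.
* **Statistics.** Two-proportion z-test with Fisher-exact fallback,
  Student's t with Cohen's d, one-way ANOVA with Tukey HSD, and
  Shapiro–Wilk / Levene assumption checks.

## Worked example

Simulate a control-SNc cohort of 100 neurons and fit the response
model:

```r
library(nigrastim)
co  <- generate_cohort(cohort_preset("control-SNc", n_neurons = 100, seed = 7))
fit <- hfs_response(co$spikes)
summary(fit)
```

```
Peri-stimulus response fit
  cohort: control / SNc, 100 neurons (100 classified, 0 NR)
  type proportions: TD-PTD 9%, TD-PTP 36%, TP-PTP 27%, TP-PTD 28%

Group summary: control / SNc  (100 neurons, 100 classified, 0 NR)
   type  n percent M_BE/M_TT M_BE/M_PE
 TD-PTD  9       9      8.08      2.93
 TD-PTP 36      36      4.06      2.16
 TP-PTP 27      27      3.21      1.72
 TP-PTD 28      28      2.15      1.33

Pooled baseline rate: 10.139 spikes/s; PETH bins: 41 x 1 s
```

The classifier recovers the planted mixture (9/36/27/28 percent)
exactly, and the pooled fold-change ratios sit near their configured
values (the TD-PTD M_BE/M_TT cell is noisy here because only 9
neurons contribute ~1.9 Hz each to a 1 s window; at the 500-neuron
recovery scale it converges to within a few percent). `coef(fit)`
returns the same estimates as a matrix, `plot(fit)` draws the summed
PETH and the window-rate bars, `simulate(fit)` draws new synthetic
cohorts from the fitted mixture, and `predict(fit, newdata)`
classifies further spike tables.

Group comparison, e.g. TD-PTP prevalence in SNc between a
rotenone-lesioned group (21 of 105 neurons) and a melanin-treated one
(34 of 95):

```r
proportion_test(21, 105, 34, 95)
#> two-proportion z-test: statistic = -2.497, p = 0.01251, d = -0.158
```

The full six-cohort pipeline — simulate, classify, summarise, compare
— is one call:

```r
report <- run_pipeline(run_config(seed = 1))
render_tables(report)   # proportions table + fold-change ratio table
```

A thin command-line wrapper with `simulate` / `classify` / `report`
subcommands is installed at `inst/scripts/hfs-pipeline.R`.

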