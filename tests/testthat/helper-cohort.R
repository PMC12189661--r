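# Shared fixtures: small cohorts and a deterministic single-type spec.

single_type_spec <- function(preset, type, n = 500, seed = 101L, ...) {
  cohort_preset(preset, n_neurons = n, type = type, seed = seed, ...)
}

# Enforce an absolute refractory period on a spike train (greedy
# thinning), so spike waveforms cannot overlap on a synthetic trace --
# the trace generator assumes template duration << min ISI.
refractory_train <- function(t, min_isi = 3e-3) {
  t <- sort(t)
  keep <- numeric(0)
  last <- -Inf
  for (s in t) {
    if (s - last >= min_isi) {
      keep <- c(keep, s)
      last <- s
    }
  }
  keep
}

# A tiny deterministic spike table: two neurons with hand-placed spikes.
toy_spikes <- function() {
  data.frame(
    neuron_id = c(rep(1L, 5), rep(2L, 3)),
    group = "control", region = "SNc",
    t = c(-19.5, -10.0, 0.5, 1.5, 20.5,
          -5.0, 0.2, 2.0))
}
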