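#' Extracellular spike waveform template
#'
#' An alpha-function waveform `A * (t/tau) * exp(1 - t/tau)` sampled on
#' the trace grid, peaking at exactly `A` at `t = tau` (tau is snapped
#' to the sample grid so the peak lies on a sample). Amplitudes are in
#' mV; the 0.15 mV default matches the recorded extracellular spike
#' amplitudes of 0.12-0.18 mV.
#'
#' @param sampling_rate Hz, >= 10000.
#' @param peak peak amplitude, mV (> 0).
#' @param rise_time time to peak, s.
#' @param duration total template length, s.
#' @return numeric vector of template samples; attribute `peak_index`
#'   marks the peak sample.
#' @export
spike_template <- function(sampling_rate = 20000, peak = 0.15,
                           rise_time = 3e-4, duration = 1.5e-3) {
  stopifnot(sampling_rate >= 10000, peak > 0, rise_time > 0,
            duration > rise_time)
  dt <- 1 / sampling_rate
  tau <- max(1L, round(rise_time / dt)) * dt
  t <- seq(0, duration, by = dt)
  w <- peak * (t / tau) * exp(1 - t / tau)
  structure(w, peak_index = which.max(w))
}

#' Synthesize a raw extracellular voltage trace
#'
#' Superimposes one spike-waveform template per spike time (template
#' peak aligned to the nearest sample of the spike time) on Gaussian
#' background noise. The true spike times are retained so detector
#' output can be scored against ground truth.
#'
#' @param spike_times numeric vector of spike times, s.
#' @param template waveform from [spike_template()] (must be sampled at
#'   `sampling_rate`).
#' @param noise_sd background noise SD, mV (>= 0).
#' @param sampling_rate Hz, >= 10000.
#' @param t_start,t_end trace span, s; defaults to the spike span
#'   padded by 50 ms (or [-1, 1] s for an empty train).
#' @return list of class `raw_trace`: `samples` (mV), `sampling_rate`,
#'   `t_start`, `noise_sd`, `true_spike_times`.
#' @export
generate_raw_trace <- function(spike_times, template = spike_template(),
                               noise_sd = 0.01, sampling_rate = 20000,
                               t_start = NULL, t_end = NULL) {
  if (sampling_rate < 10000)
    stop("sampling_rate too low to represent the spike template (need >= 10 kHz)")
  stopifnot(noise_sd >= 0)
  spike_times <- sort(as.numeric(spike_times))
  pad <- 0.05
  if (is.null(t_start))
    t_start <- if (length(spike_times)) min(spike_times) - pad else -1
  if (is.null(t_end))
    t_end <- if (length(spike_times)) max(spike_times) + pad else 1
  n <- ceiling((t_end - t_start) * sampling_rate) + 1L
  x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  pk <- attr(template, "peak_index")
  for (ts in spike_times) {
    centre <- round((ts - t_start) * sampling_rate) + 1L
    idx <- centre - pk + seq_along(template)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + template[ok]
  }
  structure(list(samples = x, sampling_rate = sampling_rate,
                 t_start = t_start, noise_sd = noise_sd,
                 true_spike_times = spike_times),
            class = "raw_trace")
}

#' Spike detection by threshold crossing and amplitude discrimination
#'
#' Emulates a hardware window discriminator: the trace is scanned for
#' excursions above `threshold` (below, for negative polarity); each
#' contiguous supra-threshold run yields one candidate event at its
#' extremum sample, accepted only if the extremum amplitude lies inside
#' `amplitude_window`. Accepted events closer than `refractory` to the
#' previously accepted event are dropped.
#'
#' @param trace a `raw_trace` (or plain numeric vector with
#'   `sampling_rate` supplied via attributes is not supported -- build
#'   one with [generate_raw_trace()]).
#' @param threshold crossing threshold, mV.
#' @param amplitude_window length-2 numeric `[a_min, a_max]`, mV; the
#'   acceptance band for the extremum amplitude.
#' @param refractory minimum separation of accepted events, s (> 0).
#' @param polarity `"positive"` (upward spikes) or `"negative"`.
#' @return numeric vector of event times (s, extremum samples, on the
#'   trace clock), strictly increasing.
#' @examples
#' tr <- generate_raw_trace(c(0.1, 0.2), noise_sd = 0)
#' detect_spikes(tr, threshold = 0.05, amplitude_window = c(0.1, 0.2))
#' @export
detect_spikes <- function(trace, threshold = 0.05,
                          amplitude_window = c(0.1, 0.25),
                          refractory = 1e-3,
                          polarity = c("positive", "negative")) {
  stopifnot(inherits(trace, "raw_trace"))
  polarity <- match.arg(polarity)
  if (anyNA(trace$samples)) stop("trace contains NaN/NA samples")
  stopifnot(length(amplitude_window) == 2L,
            amplitude_window[1] <= amplitude_window[2],
            refractory > 0)
  x <- trace$samples
  if (polarity == "negative") {
    x <- -x
    threshold <- -threshold
    amplitude_window <- rev(-amplitude_window)
  }
  above <- x >= threshold
  if (!any(above)) return(numeric(0))
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  times <- numeric(0)
  last <- -Inf
  dt <- 1 / trace$sampling_rate
  for (k in seq_along(starts)) {
    seg <- starts[k]:ends[k]
    i <- seg[which.max(x[seg])]
    amp <- x[i]
    if (amp < amplitude_window[1] || amp > amplitude_window[2]) next
    t_ev <- trace$t_start + (i - 1L) * dt
    if (t_ev - last < refractory) next
    times <- c(times, t_ev)
    last <- t_ev
  }
  times
}

#' Score detected spike times against ground truth
#'
#' Greedy one-to-one matching in time order: each true spike is matched
#' to the earliest unmatched detection within `tolerance`. Recall is
#' matched/true, precision matched/detected. When nothing was detected,
#' precision is reported as 1 by convention (no false positives) and
#' the result is flagged.
#'
#' @param detected,truth numeric vectors of spike times, s.
#' @param tolerance matching tolerance, s (> 0); default 1 ms.
#' @return list with `recall`, `precision`, `n_matched`, `n_true`,
#'   `n_detected`, and `empty_detection` flag.
#' @export
score_detection <- function(detected, truth, tolerance = 1e-3) {
  stopifnot(tolerance > 0)
  detected <- sort(as.numeric(detected))
  truth <- sort(as.numeric(truth))
  matched <- 0L
  j <- 1L
  for (tt in truth) {
    while (j <= length(detected) && detected[j] < tt - tolerance)
      j <- j + 1L
    if (j <= length(detected) && abs(detected[j] - tt) <= tolerance) {
      matched <- matched + 1L
      j <- j + 1L
    }
  }
  list(recall = if (length(truth)) matched / length(truth) else 1,
       precision = if (length(detected)) matched / length(detected) else 1,
       n_matched = matched, n_true = length(truth),
       n_detected = length(detected),
       empty_detection = length(detected) == 0L)
}
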