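#' Define the three peri-stimulus analysis windows
#'
#' The analysis partitions event-aligned time into three contiguous
#' half-open windows: `BE` (before event, the baseline), `TT`
#' (tetanization time, the stimulation train itself) and `PE`
#' (post-event). Time zero is stimulation onset, so `BE` must end and
#' `TT` must begin at `t = 0`. The defaults follow a 100 Hz / 1 s
#' stimulation protocol recorded from 20 s before to 20 s after the
#' train: `BE = [-20, 0)`, `TT = [0, 1)`, `PE = [1, 21)` seconds.
#'
#' @param be numeric length-2, baseline window `[t0, t1)` in seconds;
#'   `t1` must equal 0.
#' @param tt numeric length-2, tetanization window `[t1, t2)`.
#' @param pe numeric length-2, post-event window `[t2, t3)`.
#' @return An object of class `window_def`: a list with elements `be`,
#'   `tt`, `pe` (each `c(start, end)`) and `durations`.
#' @examples
#' window_def()
#' window_def(be = c(-10, 0), tt = c(0, 1), pe = c(1, 11))
#' @export
window_def <- function(be = c(-20, 0), tt = c(0, 1), pe = c(1, 21)) {
  stopifnot(length(be) == 2L, length(tt) == 2L, length(pe) == 2L)
  be <- as.numeric(be); tt <- as.numeric(tt); pe <- as.numeric(pe)
  if (be[2] != 0)
    stop("baseline window must end at t = 0 (stimulation onset)")
  if (be[1] >= be[2] || tt[1] >= tt[2] || pe[1] >= pe[2])
    stop("each window must have positive duration")
  if (be[2] != tt[1] || tt[2] != pe[1])
    stop("windows must be contiguous: BE|TT|PE")
  structure(
    list(be = be, tt = tt, pe = pe,
         durations = c(be = diff(be), tt = diff(tt), pe = diff(pe))),
    class = "window_def")
}

#' @export
print.window_def <- function(x, ...) {
  cat(sprintf("Peri-stimulus windows (s): BE [%g, %g)  TT [%g, %g)  PE [%g, %g)\n",
              x$be[1], x$be[2], x$tt[1], x$tt[2], x$pe[1], x$pe[2]))
  invisible(x)
}

as_window_def <- function(x) {
  if (inherits(x, "window_def")) return(x)
  if (is.list(x) && all(c("be", "tt", "pe") %in% names(x)))
    return(window_def(x$be, x$tt, x$pe))
  stop("cannot interpret 'windows' as a window definition")
}

#' Mean firing rates of one spike train in the BE/TT/PE windows
#'
#' Counts spikes falling in each half-open window and divides by the
#' window duration, giving the mean rates M_BE, M_TT and M_PE in
#' spikes/s. Spikes outside the BE..PE span are ignored.
#'
#' @param t numeric vector of spike times (s), aligned so stimulation
#'   onset is `t = 0`. May be unsorted; `NA` is not allowed.
#' @param windows a [window_def()].
#' @return An object of class `window_rates`: list with `m_be`, `m_tt`,
#'   `m_pe` (spikes/s), `counts` and `durations` (named length-3
#'   vectors).
#' @examples
#' w <- window_def()
#' window_rates(seq(-19.95, -0.05, by = 0.1), w)  # 200 baseline spikes -> 10 Hz
#' @export
window_rates <- function(t, windows = window_def()) {
  windows <- as_window_def(windows)
  t <- as.numeric(t)
  if (anyNA(t)) stop("spike times must not contain NA")
  cnt <- c(be = sum(t >= windows$be[1] & t < windows$be[2]),
           tt = sum(t >= windows$tt[1] & t < windows$tt[2]),
           pe = sum(t >= windows$pe[1] & t < windows$pe[2]))
  dur <- windows$durations
  structure(
    list(m_be = cnt[["be"]] / dur[["be"]],
         m_tt = cnt[["tt"]] / dur[["tt"]],
         m_pe = cnt[["pe"]] / dur[["pe"]],
         counts = cnt, durations = dur),
    class = "window_rates")
}

#' @export
print.window_rates <- function(x, ...) {
  cat(sprintf("M_BE = %.3f  M_TT = %.3f  M_PE = %.3f spikes/s\n",
              x$m_be, x$m_tt, x$m_pe))
  invisible(x)
}

#' Per-neuron window rates for a whole spike table
#'
#' Applies [window_rates()] to every neuron of a long-format spike table
#' and returns one row per neuron. Neurons present in `neuron_ids` but
#' absent from the table (zero spikes) get zero rates.
#'
#' @param spikes data.frame with columns `neuron_id` and `t`.
#' @param windows a [window_def()].
#' @param neuron_ids optional vector of ids defining the row set and
#'   order; defaults to the ids present in `spikes`.
#' @return data.frame with columns `neuron_id`, `m_be`, `m_tt`, `m_pe`,
#'   `n_be`, `n_tt`, `n_pe`.
#' @export
window_rates_table <- function(spikes, windows = window_def(),
                               neuron_ids = NULL) {
  windows <- as_window_def(windows)
  stopifnot(is.data.frame(spikes), all(c("neuron_id", "t") %in% names(spikes)))
  if (is.null(neuron_ids)) neuron_ids <- unique(spikes$neuron_id)
  idx <- split(spikes$t, factor(spikes$neuron_id, levels = neuron_ids))
  rows <- lapply(neuron_ids, function(id) {
    wr <- window_rates(idx[[as.character(id)]] %||% numeric(0), windows)
    data.frame(neuron_id = id,
               m_be = wr$m_be, m_tt = wr$m_tt, m_pe = wr$m_pe,
               n_be = wr$counts[["be"]], n_tt = wr$counts[["tt"]],
               n_pe = wr$counts[["pe"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled window rates across a group of neurons
#'
#' Pools spike counts over neurons before dividing by time, i.e.
#' `sum(counts) / (n_neurons * duration)` per window. This mirrors the
#' summed peri-event histograms: with equal recording durations it
#' equals the mean of the per-neuron rates, but it is the pooled form
#' that the group fold-change ratios are computed from, which avoids
#' ratio-of-small-counts bias in the 1 s tetanization window.
#'
#' @param trains list of numeric spike-time vectors, or a data.frame
#'   with columns `neuron_id` and `t`.
#' @param windows a [window_def()].
#' @return A `window_rates` object for the pooled group, with an
#'   `n_neurons` element.
#' @export
pooled_window_rates <- function(trains, windows = window_def()) {
  windows <- as_window_def(windows)
  if (is.data.frame(trains))
    trains <- split(trains$t, trains$neuron_id)
  if (!is.list(trains) || length(trains) == 0L)
    stop("'trains' must be a non-empty list of spike-time vectors")
  n <- length(trains)
  per <- lapply(trains, window_rates, windows = windows)
  cnt <- Reduce(`+`, lapply(per, `[[`, "counts"))
  dur <- windows$durations
  structure(
    list(m_be = cnt[["be"]] / (n * dur[["be"]]),
         m_tt = cnt[["tt"]] / (n * dur[["tt"]]),
         m_pe = cnt[["pe"]] / (n * dur[["pe"]]),
         counts = cnt, durations = dur, n_neurons = n),
    class = "window_rates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
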