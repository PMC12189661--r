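#' Summed and averaged peri-event time histograms
#'
#' Bins all spikes of a neuron group on a common event-aligned grid
#' spanning BE through PE. The summed histogram is the total spike
#' count per bin over all neurons; the averaged histogram normalizes
#' by neuron count and bin width to give spikes/s; the difference
#' curve subtracts the pooled baseline rate from the averaged rate, so
#' a flat zero curve means no departure from baseline.
#'
#' @param trains list of spike-time vectors, or a data.frame with
#'   columns `neuron_id` and `t`.
#' @param bin_width bin width, s; default 1 s.
#' @param windows a [window_def()] fixing the span (BE start to PE
#'   end). If `bin_width` does not divide the span evenly the last bin
#'   is truncated and the result is flagged.
#' @return object of class `peth`: list with `bin_edges`,
#'   `summed_counts`, `averaged_rate` (spikes/s), `difference_curve`,
#'   `baseline_rate`, `n_neurons`, `n_outside` (spikes outside the
#'   span) and `truncated_last_bin`.
#' @examples
#' co <- generate_cohort(cohort_preset("control-SNc", n_neurons = 10))
#' p <- build_peth(co$spikes)
#' plot(p)
#' @export
build_peth <- function(trains, bin_width = 1, windows = window_def()) {
  windows <- as_window_def(windows)
  if (is.data.frame(trains)) trains <- split(trains$t, trains$neuron_id)
  if (!is.list(trains) || length(trains) == 0L)
    stop("'trains' must be a non-empty list of spike trains")
  stopifnot(bin_width > 0)
  span <- c(windows$be[1], windows$pe[2])
  edges <- seq(span[1], span[2], by = bin_width)
  truncated <- FALSE
  if (edges[length(edges)] < span[2]) {
    edges <- c(edges, span[2])
    truncated <- TRUE
    warning("bin_width does not divide the span evenly; last bin truncated")
  }
  n <- length(trains)
  all_t <- unlist(trains, use.names = FALSE)
  inside <- all_t >= span[1] & all_t < span[2]
  # right-open bins: spike on a boundary belongs to the bin to its right
  counts <- hist(all_t[inside], breaks = edges, right = FALSE,
                 plot = FALSE)$counts
  widths <- diff(edges)
  base <- pooled_window_rates(trains, windows)$m_be
  avg <- counts / (n * widths)
  structure(
    list(bin_edges = edges, summed_counts = counts,
         averaged_rate = avg, difference_curve = avg - base,
         baseline_rate = base, n_neurons = n,
         n_outside = sum(!inside), truncated_last_bin = truncated,
         windows = windows),
    class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("PETH: %d neurons, %d bins over [%g, %g) s, pooled baseline %.3f spikes/s\n",
              x$n_neurons, length(x$summed_counts),
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              x$baseline_rate))
  invisible(x)
}

#' @export
plot.peth <- function(x, ...) {
  mids <- head(x$bin_edges, -1) + diff(x$bin_edges) / 2
  graphics::barplot(x$summed_counts, names.arg = round(mids, 1),
                    space = 0, col = "grey70", border = NA,
                    xlab = "time from stimulation onset (s)",
                    ylab = "summed spike count", ...)
  on_bin <- sum(x$bin_edges <= x$windows$tt[1])
  graphics::abline(v = on_bin, col = "red", lwd = 2)
  invisible(x)
}

#' Per-neuron raster of event-aligned spike times
#'
#' Losslessly restructures a spike table into one ordered spike-time
#' vector per neuron, the form used for raster displays and export.
#'
#' @param trains list of spike-time vectors or data.frame with
#'   `neuron_id` and `t`.
#' @return named list, one sorted numeric vector per neuron, input
#'   order preserved.
#' @export
raster <- function(trains) {
  if (is.data.frame(trains)) {
    if (nrow(trains) == 0L) return(list())
    trains <- split(trains$t,
                    factor(trains$neuron_id, levels = unique(trains$neuron_id)))
  }
  lapply(trains, function(t) sort(as.numeric(t)))
}

#' Export a PETH as a data.frame
#' @param peth a `peth` object.
#' @return data.frame with columns `bin_start`, `bin_end`,
#'   `summed_count`, `averaged_rate`, `difference`.
#' @export
peth_table <- function(peth) {
  stopifnot(inherits(peth, "peth"))
  data.frame(bin_start = head(peth$bin_edges, -1),
             bin_end = peth$bin_edges[-1],
             summed_count = peth$summed_counts,
             averaged_rate = peth$averaged_rate,
             difference = peth$difference_curve)
}
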