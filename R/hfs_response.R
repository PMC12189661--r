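#' Fit the peri-stimulus response model to a cohort of spike trains
#'
#' The central estimator of the package. Given event-aligned spike
#' trains for one group/region cohort, it estimates each neuron's mean
#' firing rate in the baseline (BE), tetanization (TT) and post-event
#' (PE) windows, classifies every neuron into one of the four
#' tetanic/post-tetanic response types (TD-PTD, TD-PTP, TP-PTP,
#' TP-PTD), and summarises the cohort by type proportions and pooled
#' magnitude fold-change ratios (M_BE/M_TT and M_BE/M_PE per type). A
#' summed/averaged PETH with difference curve is attached for
#' inspection and plotting.
#'
#' @param spikes long-format spike table: data.frame with columns
#'   `neuron_id` and `t` (s, stimulation onset at 0); optional `group`
#'   and `region` columns provide default labels.
#' @param windows a [window_def()].
#' @param epsilon relative dead-band for [classify_neuron()]; the
#'   default 0 is a strict sign rule (only exact ties are NR).
#' @param bin_width PETH bin width, s.
#' @param group,region cohort labels; default from the table.
#' @param neuron_ids optional id vector fixing the neuron set (so
#'   silent neurons are retained as zero-rate rows).
#' @return An object of class `hfs_response` with components `rates`
#'   (per-neuron rates + labels), `summary` (a `group_summary`),
#'   `peth`, `windows`, `epsilon`, `n_neurons` and `call`. Methods:
#'   [print()], [summary()], [coef()] (proportions and ratios),
#'   [predict()] (classify new spike tables), [plot()] (PETH +
#'   window-rate bars), [simulate()] (parametric cohorts drawn from
#'   the fitted type mixture and folds) and [residuals()].
#' @examples
#' co <- generate_cohort(cohort_preset("control-SNc", n_neurons = 50))
#' fit <- hfs_response(co$spikes)
#' fit
#' coef(fit)
#' @export
hfs_response <- function(spikes, windows = window_def(), epsilon = 0,
                         bin_width = 1, group = NULL, region = NULL,
                         neuron_ids = NULL) {
  stopifnot(is.data.frame(spikes), all(c("neuron_id", "t") %in% names(spikes)))
  if (nrow(spikes) == 0L) stop("empty spike table")
  windows <- as_window_def(windows)
  group <- group %||% (if ("group" %in% names(spikes)) as.character(spikes$group[1]) else "group")
  region <- region %||% (if ("region" %in% names(spikes)) as.character(spikes$region[1]) else "region")
  rates <- window_rates_table(spikes, windows, neuron_ids)
  labels <- classify_neuron(rates$m_be, rates$m_tt, rates$m_pe, epsilon)
  rates <- cbind(rates, labels)
  summ <- summarize_group(rates, labels, group = group, region = region,
                          epsilon = epsilon, windows = windows)
  peth <- build_peth(spikes, bin_width = bin_width, windows = windows)
  structure(
    list(rates = rates, summary = summ, peth = peth,
         windows = windows, epsilon = epsilon,
         n_neurons = nrow(rates), group = group, region = region,
         call = match.call()),
    class = "hfs_response")
}

#' @export
print.hfs_response <- function(x, ...) {
  cat("Peri-stimulus response fit\n")
  cat(sprintf("  cohort: %s / %s, %d neurons (%d classified, %d NR)\n",
              x$group, x$region, x$n_neurons,
              x$summary$n_classified, x$summary$n_nr))
  p <- x$summary$proportions_int
  cat("  type proportions: ",
      paste(sprintf("%s %d%%", names(p), p), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @describeIn hfs_response full summary: proportions, pooled rates
#'   and fold-change ratios per type.
#' @param object,x an `hfs_response` fit.
#' @param ... unused.
#' @export
summary.hfs_response <- function(object, ...) {
  structure(list(fit = object), class = "summary.hfs_response")
}

#' @export
print.summary.hfs_response <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\n")
  print(f$summary)
  cat(sprintf("\nPooled baseline rate: %.3f spikes/s; PETH bins: %d x %g s\n",
              f$peth$baseline_rate, length(f$peth$summed_counts),
              diff(f$peth$bin_edges[1:2])))
  invisible(x)
}

#' @describeIn hfs_response matrix of estimates: one row per response
#'   type, columns `percent`, `ratio_tt`, `ratio_pe`.
#' @export
coef.hfs_response <- function(object, ...) {
  s <- object$summary
  cbind(percent = s$proportions,
        ratio_tt = s$ratio_tt,
        ratio_pe = s$ratio_pe)
}

#' @describeIn hfs_response classify a new spike table with the fit's
#'   windows and dead-band.
#' @param newdata spike table (data.frame with `neuron_id`, `t`).
#' @export
predict.hfs_response <- function(object, newdata, ...) {
  rates <- window_rates_table(newdata, object$windows)
  cbind(rates["neuron_id"],
        classify_neuron(rates$m_be, rates$m_tt, rates$m_pe,
                        object$epsilon))
}

#' @describeIn hfs_response per-neuron deviations of the log2 window
#'   rate changes from their type means (NR neurons get `NA`).
#' @export
residuals.hfs_response <- function(object, ...) {
  r <- object$rates
  lf_tt <- log2((r$m_tt + .5 / object$windows$durations[["tt"]]) /
                (r$m_be + .5 / object$windows$durations[["be"]]))
  lf_pe <- log2((r$m_pe + .5 / object$windows$durations[["pe"]]) /
                (r$m_be + .5 / object$windows$durations[["be"]]))
  out <- matrix(NA_real_, nrow(r), 2,
                dimnames = list(r$neuron_id, c("tt", "pe")))
  for (ty in response_types) {
    i <- r$combined == ty
    if (!any(i)) next
    out[i, "tt"] <- lf_tt[i] - mean(lf_tt[i])
    out[i, "pe"] <- lf_pe[i] - mean(lf_pe[i])
  }
  out
}

#' @describeIn hfs_response plot the summed PETH (top) and the pooled
#'   BE/TT/PE rates (bottom).
#' @export
plot.hfs_response <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$peth, main = sprintf("%s / %s (n = %d)", x$group, x$region,
                              x$n_neurons))
  dur <- x$windows$durations
  n <- x$n_neurons
  pooled <- c(M_BE = sum(x$rates$n_be) / (n * dur[["be"]]),
              M_TT = sum(x$rates$n_tt) / (n * dur[["tt"]]),
              M_PE = sum(x$rates$n_pe) / (n * dur[["pe"]]))
  graphics::barplot(pooled, col = c("grey60", "indianred", "steelblue"),
                    ylab = "pooled rate (spikes/s)",
                    main = "window frequency")
  invisible(x)
}

#' @describeIn hfs_response draw `nsim` parametric synthetic cohorts
#'   from the fitted type mixture and per-type fold ratios.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param n_neurons neurons per simulated cohort; defaults to the
#'   fitted cohort size.
#' @export
simulate.hfs_response <- function(object, nsim = 1, seed = 20250528L,
                                  n_neurons = NULL, ...) {
  s <- object$summary
  mix <- s$proportions / 100
  mix <- mix[mix > 0]
  mix <- mix / sum(mix)
  ftt <- pmax(s$ratio_tt[names(mix)], 1)
  fpe <- pmax(s$ratio_pe[names(mix)], 1)
  lapply(seq_len(nsim), function(k) {
    spec <- cohort_spec(object$group, object$region,
                        n_neurons %||% object$n_neurons,
                        type_mix = mix, fold_tt = ftt, fold_pe = fpe,
                        windows = object$windows,
                        seed = as.integer(seed) + k - 1L)
    generate_cohort(spec)$spikes
  })
}
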