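#' Stimulation protocol description
#'
#' Records the high-frequency stimulation (HFS) parameters used to
#' align and annotate recordings. Defaults describe a 100 Hz train of
#' 0.05 ms rectangular pulses delivered for 1 s at 0.32 mA, the
#' motor-cortex protocol the default analysis windows assume.
#'
#' @param pulse_frequency pulse rate within the train, Hz.
#' @param train_duration train length, s.
#' @param pulse_width single pulse width, ms.
#' @param pulse_amplitude pulse amplitude, mV.
#' @param current current strength, mA.
#' @param onset_time alignment zero, s.
#' @return list of class `stim_protocol`.
#' @export
stim_protocol <- function(pulse_frequency = 100, train_duration = 1,
                          pulse_width = 0.05, pulse_amplitude = 0.15,
                          current = 0.32, onset_time = 0) {
  stopifnot(pulse_frequency > 0, train_duration > 0)
  structure(list(pulse_frequency = pulse_frequency,
                 train_duration = train_duration,
                 pulse_width = pulse_width,
                 pulse_amplitude = pulse_amplitude,
                 current = current, onset_time = onset_time),
            class = "stim_protocol")
}

response_types <- c("TD-PTD", "TD-PTP", "TP-PTP", "TP-PTD")

# Published group/region presets: response-type mixtures (percent of
# neurons per type), magnitude fold changes for the tetanization and
# post-event windows per type, and recorded cohort sizes.
.presets <- list(
  "control-SNc" = list(
    group = "control", region = "SNc", n_recorded = 107L,
    mix = c("TD-PTD" = 0.09, "TD-PTP" = 0.36, "TP-PTP" = 0.27, "TP-PTD" = 0.28),
    fold_tt = c("TD-PTD" = 5.36, "TD-PTP" = 4.24, "TP-PTP" = 3.21, "TP-PTD" = 2.18),
    fold_pe = c("TD-PTD" = 2.88, "TD-PTP" = 2.20, "TP-PTP" = 1.75, "TP-PTD" = 1.28)),
  "rotenone-SNc" = list(
    group = "rotenone", region = "SNc", n_recorded = 105L,
    mix = c("TD-PTD" = 0.27, "TD-PTP" = 0.20, "TP-PTP" = 0.11, "TP-PTD" = 0.42),
    fold_tt = c("TD-PTD" = 2.06, "TD-PTP" = 2.68, "TP-PTP" = 2.39, "TP-PTD" = 5.81),
    fold_pe = c("TD-PTD" = 1.74, "TD-PTP" = 2.33, "TP-PTP" = 1.48, "TP-PTD" = 4.24)),
  "bm-SNc" = list(
    group = "rotenone_bm", region = "SNc", n_recorded = 95L,
    mix = c("TD-PTD" = 0.12, "TD-PTP" = 0.36, "TP-PTP" = 0.25, "TP-PTD" = 0.27),
    fold_tt = c("TD-PTD" = 4.76, "TD-PTP" = 4.41, "TP-PTP" = 2.87, "TP-PTD" = 2.08),
    fold_pe = c("TD-PTD" = 1.92, "TD-PTP" = 1.98, "TP-PTP" = 1.80, "TP-PTD" = 1.12)),
  "control-SNr" = list(
    group = "control", region = "SNr", n_recorded = 135L,
    mix = c("TD-PTD" = 0.13, "TD-PTP" = 0.31, "TP-PTP" = 0.24, "TP-PTD" = 0.32),
    fold_tt = c("TD-PTD" = 6.04, "TD-PTP" = 4.84, "TP-PTP" = 3.86, "TP-PTD" = 2.79),
    fold_pe = c("TD-PTD" = 3.23, "TD-PTP" = 2.62, "TP-PTP" = 1.92, "TP-PTD" = 1.50)),
  "rotenone-SNr" = list(
    group = "rotenone", region = "SNr", n_recorded = 184L,
    mix = c("TD-PTD" = 0.32, "TD-PTP" = 0.17, "TP-PTP" = 0.15, "TP-PTD" = 0.36),
    fold_tt = c("TD-PTD" = 2.66, "TD-PTP" = 3.96, "TP-PTP" = 2.46, "TP-PTD" = 6.22),
    fold_pe = c("TD-PTD" = 1.86, "TD-PTP" = 3.14, "TP-PTP" = 2.16, "TP-PTD" = 4.97)),
  "bm-SNr" = list(
    group = "rotenone_bm", region = "SNr", n_recorded = 141L,
    mix = c("TD-PTD" = 0.16, "TD-PTP" = 0.39, "TP-PTP" = 0.28, "TP-PTD" = 0.17),
    fold_tt = c("TD-PTD" = 5.35, "TD-PTP" = 5.22, "TP-PTP" = 3.72, "TP-PTD" = 2.78),
    fold_pe = c("TD-PTD" = 2.07, "TD-PTP" = 2.58, "TP-PTP" = 2.23, "TP-PTD" = 1.42)))

#' Names of the built-in cohort presets
#' @return character vector of preset names usable with
#'   [cohort_preset()].
#' @export
cohort_presets <- function() names(.presets)

#' Cohort generator configuration
#'
#' A `cohort_spec` fully determines a synthetic cohort: how many
#' neurons, the mixture of the four response types, the tonic baseline
#' rate range, and the per-type magnitude fold changes applied to the
#' tetanization (TT) and post-event (PE) windows. Depressed windows
#' divide the baseline rate by the fold, potentiated windows multiply
#' by it; which half of the type name is depressed or potentiated
#' decides the direction.
#'
#' @param group group label, one of `"control"`, `"rotenone"`,
#'   `"rotenone_bm"` (free text allowed).
#' @param region recorded region label, `"SNc"` or `"SNr"`.
#' @param n_neurons number of neurons to simulate.
#' @param type_mix named numeric, proportions over the four response
#'   types (`TD-PTD`, `TD-PTP`, `TP-PTP`, `TP-PTD`); must sum to 1.
#' @param baseline_rate_range length-2 numeric, Hz; baseline rates are
#'   drawn uniformly from this interval. The default 8--12 Hz sits at
#'   the upper end of the tonic firing range so the 1 s tetanization
#'   window carries enough spikes for sign classification.
#' @param fold_tt,fold_pe named numeric (same names as `type_mix`),
#'   magnitude fold changes (>= 1) for the TT and PE windows.
#' @param windows a [window_def()].
#' @param dispersion variance-to-mean ratio of window spike counts;
#'   1 (default) gives Poisson counts, > 1 negative-binomial.
#' @param seed integer seed driving all randomness of the cohort.
#' @return list of class `cohort_spec`.
#' @seealso [cohort_preset()] for published presets, [generate_cohort()].
#' @export
cohort_spec <- function(group, region, n_neurons, type_mix,
                        baseline_rate_range = c(8, 12),
                        fold_tt, fold_pe,
                        windows = window_def(),
                        dispersion = 1,
                        seed = 20250528L) {
  if (length(type_mix) == 0L) stop("type_mix must not be empty")
  if (is.null(names(type_mix)) ||
      !all(names(type_mix) %in% response_types))
    stop("type_mix must be named with response types: ",
         paste(response_types, collapse = ", "))
  if (abs(sum(type_mix) - 1) > 1e-9)
    stop("type_mix proportions must sum to 1")
  if (any(type_mix < 0)) stop("type_mix proportions must be >= 0")
  n_neurons <- as.integer(n_neurons)
  if (is.na(n_neurons) || n_neurons < 1L) stop("n_neurons must be >= 1")
  stopifnot(length(baseline_rate_range) == 2L,
            baseline_rate_range[1] > 0,
            baseline_rate_range[1] <= baseline_rate_range[2])
  for (nm in names(type_mix)) {
    if (is.na(fold_tt[nm]) || is.na(fold_pe[nm]))
      stop("fold_tt and fold_pe must cover every type in type_mix")
    if (fold_tt[nm] < 1 || fold_pe[nm] < 1)
      stop("fold changes are magnitudes and must be >= 1")
  }
  if (dispersion < 1) stop("dispersion must be >= 1")
  structure(
    list(group = group, region = region, n_neurons = n_neurons,
         type_mix = type_mix,
         baseline_rate_range = as.numeric(baseline_rate_range),
         fold_tt = fold_tt[names(type_mix)],
         fold_pe = fold_pe[names(type_mix)],
         windows = as_window_def(windows),
         dispersion = dispersion,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Published cohort presets
#'
#' Returns a [cohort_spec()] preconfigured with the published
#' group/region response-type mixtures and fold-change ratios for one
#' of the six recorded cohorts (three groups x two regions).
#'
#' @param name preset name, see [cohort_presets()]: `"control-SNc"`,
#'   `"rotenone-SNc"`, `"bm-SNc"`, `"control-SNr"`, `"rotenone-SNr"`,
#'   `"bm-SNr"`.
#' @param n_neurons cohort size; defaults to the recorded cohort size
#'   for that group/region.
#' @param type restrict the cohort to a single response type (the
#'   mixture becomes 100% that type); useful for fold-change recovery
#'   runs.
#' @param seed integer seed.
#' @param ... further arguments passed to [cohort_spec()]
#'   (e.g. `windows`, `baseline_rate_range`).
#' @return a `cohort_spec`.
#' @examples
#' cohort_preset("control-SNc")            # 107 neurons, published mixture
#' cohort_preset("bm-SNr", n_neurons = 500, type = "TD-PTD")
#' @export
cohort_preset <- function(name, n_neurons = NULL, type = NULL,
                          seed = 20250528L, ...) {
  if (!name %in% names(.presets))
    stop("unknown preset '", name, "'; see cohort_presets()")
  p <- .presets[[name]]
  mix <- p$mix
  if (!is.null(type)) {
    type <- match.arg(type, response_types)
    mix <- stats::setNames(1, type)
  }
  cohort_spec(group = p$group, region = p$region,
              n_neurons = n_neurons %||% p$n_recorded,
              type_mix = mix, fold_tt = p$fold_tt, fold_pe = p$fold_pe,
              seed = seed, ...)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %s / %s, %d neurons, seed %d\n",
              x$group, x$region, x$n_neurons, x$seed))
  cat("  type mixture: ",
      paste(sprintf("%s %.0f%%", names(x$type_mix), 100 * x$type_mix),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  baseline %g-%g Hz; dispersion %g\n",
              x$baseline_rate_range[1], x$baseline_rate_range[2],
              x$dispersion))
  invisible(x)
}

# Largest-remainder (Hamilton) allocation of n items over proportions.
# Ties in the fractional remainders are broken by position order, so
# the allocation is deterministic.
largest_remainder <- function(p, n) {
  q <- p * n
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Ground-truth rate parameters for every neuron of a cohort
#'
#' Assigns response types by deterministic largest-remainder allocation
#' of the type mixture over the cohort size (so realized counts match
#' the mixture exactly, not just in expectation), draws each neuron's
#' baseline rate uniformly from the configured range, and derives the
#' tetanization and post-event rates from the per-type fold changes:
#' depressed windows get `r_be / fold`, potentiated windows
#' `r_be * fold`.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `neuron_id`, `true_type`, `r_be`,
#'   `r_tt`, `r_pe` (Hz).
#' @export
sample_neuron_params <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- largest_remainder(spec$type_mix, spec$n_neurons)
  types <- rep(names(spec$type_mix), counts)
  r_be <- stats::runif(spec$n_neurons,
                       spec$baseline_rate_range[1],
                       spec$baseline_rate_range[2])
  peri <- substr(types, 1, 2)   # TD or TP
  post <- substr(types, 4, 6)   # PTD or PTP
  f_tt <- spec$fold_tt[types]
  f_pe <- spec$fold_pe[types]
  r_tt <- ifelse(peri == "TD", r_be / f_tt, r_be * f_tt)
  r_pe <- ifelse(post == "PTD", r_be / f_pe, r_be * f_pe)
  data.frame(neuron_id = seq_len(spec$n_neurons),
             true_type = types,
             r_be = r_be, r_tt = unname(r_tt), r_pe = unname(r_pe),
             stringsAsFactors = FALSE)
}

#' Simulate one event-aligned spike train
#'
#' Draws a piecewise-homogeneous spike train over the BE/TT/PE
#' windows: the spike count of each window is Poisson with mean
#' `rate * duration` (negative binomial when `dispersion > 1`), and
#' spike times are uniform within the window, i.e. a homogeneous
#' Poisson process per window.
#'
#' @param r_be,r_tt,r_pe window firing rates, Hz (>= 0).
#' @param windows a [window_def()].
#' @param dispersion count variance-to-mean ratio, >= 1.
#' @return sorted numeric vector of spike times (s), stimulation onset
#'   at `t = 0`.
#' @export
generate_spike_train <- function(r_be, r_tt, r_pe,
                                 windows = window_def(),
                                 dispersion = 1) {
  windows <- as_window_def(windows)
  rates <- c(r_be, r_tt, r_pe)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("window rates must be finite and >= 0")
  draw <- function(rate, a, b) {
    mu <- rate * (b - a)
    n <- if (mu == 0) 0L
         else if (dispersion == 1) stats::rpois(1L, mu)
         else stats::rnbinom(1L, size = mu / (dispersion - 1), mu = mu)
    sort(stats::runif(n, a, b))
  }
  c(draw(r_be, windows$be[1], windows$be[2]),
    draw(r_tt, windows$tt[1], windows$tt[2]),
    draw(r_pe, windows$pe[1], windows$pe[2]))
}

# Evaluate expr with the RNG seeded locally; the caller's RNG state is
# left untouched.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a full synthetic cohort
#'
#' Samples ground-truth rate parameters for every neuron
#' ([sample_neuron_params()]), simulates each spike train
#' ([generate_spike_train()]), and returns the long-format spike table,
#' the ground-truth table and a manifest echoing the configuration.
#' All randomness derives from `spec$seed`, so the same spec yields
#' byte-identical output.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory; when given, writes
#'   `spikes.csv` (`neuron_id, group, region, t`), `truth.csv` and
#'   `manifest.json` there.
#' @return list of class `cohort` with elements `spikes` (data.frame),
#'   `truth` (data.frame), `manifest` (list) and `spec`.
#' @examples
#' co <- generate_cohort(cohort_preset("control-SNc", n_neurons = 20))
#' head(co$spikes)
#' table(co$truth$true_type)
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- with_local_seed(spec$seed, {
    truth <- sample_neuron_params(spec)
    trains <- lapply(seq_len(spec$n_neurons), function(i)
      generate_spike_train(truth$r_be[i], truth$r_tt[i], truth$r_pe[i],
                           spec$windows, spec$dispersion))
    list(truth = truth, trains = trains)
  })
  nsp <- lengths(out$trains)
  spikes <- data.frame(
    neuron_id = rep(out$truth$neuron_id, nsp),
    group = spec$group, region = spec$region,
    t = unlist(out$trains),
    stringsAsFactors = FALSE)
  manifest <- list(
    group = spec$group, region = spec$region,
    n_neurons = spec$n_neurons, seed = spec$seed,
    type_mix = as.list(spec$type_mix),
    fold_tt = as.list(spec$fold_tt), fold_pe = as.list(spec$fold_pe),
    baseline_rate_range = spec$baseline_rate_range,
    dispersion = spec$dispersion,
    windows = list(be = spec$windows$be, tt = spec$windows$tt,
                   pe = spec$windows$pe),
    n_spikes = sum(nsp),
    checksum = sprintf("%d:%.6f", sum(nsp), sum(spikes$t)))
  res <- structure(list(spikes = spikes, truth = out$truth,
                        manifest = manifest, spec = spec),
                   class = "cohort")
  if (!is.null(dir)) write_cohort(res, dir)
  res
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %s / %s, %d neurons, %d spikes (seed %d)\n",
              x$spec$group, x$spec$region, x$spec$n_neurons,
              x$manifest$n_spikes, x$spec$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- c(spikes = file.path(dir, "spikes.csv"),
             truth = file.path(dir, "truth.csv"),
             manifest = file.path(dir, "manifest.json"))
  tryCatch({
    utils::write.csv(cohort$spikes, paths[["spikes"]], row.names = FALSE)
    utils::write.csv(cohort$truth, paths[["truth"]], row.names = FALSE)
    jsonlite::write_json(cohort$manifest, paths[["manifest"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = function(e)
    stop("failed writing cohort to '", dir, "': ", conditionMessage(e)))
  invisible(paths)
}

#' Read a spike-time table written by [write_cohort()]
#' @param path path to a `spikes.csv` file.
#' @return data.frame with columns `neuron_id`, `group`, `region`, `t`.
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) stop("no such spike table: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
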