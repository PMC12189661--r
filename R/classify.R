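#' Classify a neuron's tetanic and post-tetanic response
#'
#' Compares the tetanization-window rate (M_TT) and post-event rate
#' (M_PE) against the baseline rate (M_BE). A window rate below
#' `m_be * (1 - epsilon)` is a depression (TD during the train, PTD
#' after it), above `m_be * (1 + epsilon)` a potentiation (TP / PTP),
#' and inside the band no response (NR). The combined label is the
#' concatenation of the two half-labels when both are responsive, else
#' NR. With the default `epsilon = 0` the rule is a strict sign
#' comparison and only exact ties give NR, which matches a four-type
#' report in which every neuron carries a label.
#'
#' Conventions for degenerate input: a zero baseline with nonzero
#' window rate is classified as potentiation; all-zero rates give NR.
#'
#' @param m_be,m_tt,m_pe window rates, spikes/s; vectors are accepted
#'   and recycled to a common length.
#' @param epsilon relative dead-band half-width (>= 0).
#' @return data.frame with character columns `peri` (`TD`/`TP`/`NR`),
#'   `post` (`PTD`/`PTP`/`NR`) and `combined` (one of `TD-PTD`,
#'   `TD-PTP`, `TP-PTP`, `TP-PTD`, `NR`).
#' @examples
#' classify_neuron(10, 2, 4)          # TD-PTD
#' classify_neuron(10, 32.1, 17.5)    # TP-PTP
#' classify_neuron(10, 10, 10)        # NR (exact tie)
#' @export
classify_neuron <- function(m_be, m_tt, m_pe, epsilon = 0) {
  stopifnot(epsilon >= 0)
  n <- max(length(m_be), length(m_tt), length(m_pe))
  m_be <- rep_len(as.numeric(m_be), n)
  m_tt <- rep_len(as.numeric(m_tt), n)
  m_pe <- rep_len(as.numeric(m_pe), n)
  if (any(!is.finite(c(m_be, m_tt, m_pe))))
    stop("window rates must be finite")
  half <- function(base, x, dn, up) {
    lab <- rep("NR", n)
    lab[x < base * (1 - epsilon)] <- dn
    lab[x > base * (1 + epsilon)] <- up
    lab[base == 0 & x > 0] <- up   # zero baseline, activity appears
    lab[base == 0 & x == 0] <- "NR"
    lab
  }
  peri <- half(m_be, m_tt, "TD", "TP")
  post <- half(m_be, m_pe, "PTD", "PTP")
  combined <- ifelse(peri == "NR" | post == "NR", "NR",
                     paste(peri, post, sep = "-"))
  data.frame(peri = peri, post = post, combined = combined,
             stringsAsFactors = FALSE)
}

#' Magnitude fold change between two window rates
#'
#' `max(a, b) / min(a, b)`: always >= 1, reporting the size of the
#' change regardless of direction. This is the convention behind the
#' reported M_BE/M_TT and M_BE/M_PE ratios, which exceed 1 for both
#' excitatory and inhibitory response types. When one rate is zero the
#' ratio is capped and flagged; when both are zero it is undefined
#' (`NaN`, flagged).
#'
#' @param m_be,m_x the two rates (spikes/s), typically baseline vs a
#'   response window. Vectorized.
#' @param cap value returned (with a flag) when the smaller rate is 0.
#' @return numeric vector of ratios; attribute `flag` is a character
#'   vector marking `"capped"`/`"undefined"` entries (`""` otherwise).
#' @examples
#' fold_change(10, 1.866)   # 5.36
#' fold_change(2, 10)       # 5: magnitude convention is symmetric
#' @export
fold_change <- function(m_be, m_x, cap = 1e6) {
  n <- max(length(m_be), length(m_x))
  a <- rep_len(as.numeric(m_be), n)
  b <- rep_len(as.numeric(m_x), n)
  hi <- pmax(a, b); lo <- pmin(a, b)
  out <- ifelse(lo > 0, hi / lo, ifelse(hi > 0, cap, NaN))
  flag <- ifelse(lo > 0, "", ifelse(hi > 0, "capped", "undefined"))
  structure(out, flag = flag)
}

#' Summarise a classified neuron group
#'
#' Tabulates the four response types over the classified (non-NR)
#' neurons, reporting exact and integer-rounded percentages, and
#' computes each type's group-level fold-change ratios M_BE/M_TT and
#' M_BE/M_PE from the pooled window rates of that type's neurons
#' (counts pooled before dividing, see [pooled_window_rates()]).
#'
#' @param rates data.frame from [window_rates_table()] (columns
#'   `neuron_id`, `m_be`, `m_tt`, `m_pe`, `n_be`, `n_tt`, `n_pe`).
#' @param labels data.frame from [classify_neuron()] with one row per
#'   row of `rates`; computed from `rates` when omitted.
#' @param group,region labels carried into the summary.
#' @param epsilon dead-band passed to [classify_neuron()] when
#'   `labels` is omitted.
#' @param windows the [window_def()] the rates were computed with
#'   (needed to pool counts).
#' @return object of class `group_summary`: list with `group`,
#'   `region`, `n_neurons`, `n_classified`, `n_nr`, `counts`,
#'   `proportions` (exact %), `proportions_int` (integer %),
#'   `ratio_tt`, `ratio_pe` (per type), `pooled` (per-type pooled
#'   rates).
#' @export
summarize_group <- function(rates, labels = NULL, group = "group",
                            region = "region", epsilon = 0,
                            windows = window_def()) {
  stopifnot(is.data.frame(rates), nrow(rates) >= 1L)
  windows <- as_window_def(windows)
  if (is.null(labels))
    labels <- classify_neuron(rates$m_be, rates$m_tt, rates$m_pe, epsilon)
  stopifnot(nrow(labels) == nrow(rates))
  cls <- labels$combined
  keep <- cls != "NR"
  if (!any(keep))
    stop("all neurons classified NR: no responsive neurons to summarise ",
         "(group ", group, ", region ", region, ")")
  counts <- table(factor(cls[keep], levels = response_types))
  prop <- 100 * as.numeric(counts) / sum(counts)
  names(prop) <- response_types
  dur <- windows$durations
  pool <- lapply(response_types, function(ty) {
    i <- keep & cls == ty
    if (!any(i)) return(c(be = NA_real_, tt = NA_real_, pe = NA_real_))
    c(be = sum(rates$n_be[i]) / (sum(i) * dur[["be"]]),
      tt = sum(rates$n_tt[i]) / (sum(i) * dur[["tt"]]),
      pe = sum(rates$n_pe[i]) / (sum(i) * dur[["pe"]]))
  })
  names(pool) <- response_types
  ratio_tt <- vapply(pool, function(p)
    if (anyNA(p)) NA_real_ else as.numeric(fold_change(p[["be"]], p[["tt"]])),
    numeric(1))
  ratio_pe <- vapply(pool, function(p)
    if (anyNA(p)) NA_real_ else as.numeric(fold_change(p[["be"]], p[["pe"]])),
    numeric(1))
  structure(
    list(group = group, region = region,
         n_neurons = nrow(rates), n_classified = sum(keep),
         n_nr = sum(!keep),
         counts = stats::setNames(as.integer(counts), response_types),
         proportions = prop,
         proportions_int = round(prop),
         ratio_tt = ratio_tt, ratio_pe = ratio_pe,
         pooled = pool, epsilon = epsilon),
    class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group summary: %s / %s  (%d neurons, %d classified, %d NR)\n",
              x$group, x$region, x$n_neurons, x$n_classified, x$n_nr))
  df <- data.frame(type = response_types,
                   n = x$counts,
                   percent = x$proportions_int,
                   `M_BE/M_TT` = round(x$ratio_tt, 2),
                   `M_BE/M_PE` = round(x$ratio_pe, 2),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Estimate the per-neuron misclassification probability by simulation
#'
#' Generates `n` ground-truth neurons of a single response type from a
#' cohort spec, classifies each from its simulated window rates, and
#' returns the fraction whose combined label differs from the truth.
#' Used to verify that a given fold-change structure is large enough,
#' relative to Poisson counting noise in the windows, for reliable
#' sign classification.
#'
#' @param spec a [cohort_spec()] whose mixture is a single type (see
#'   `type` argument of [cohort_preset()]).
#' @param n number of simulated neurons.
#' @param epsilon dead-band for [classify_neuron()].
#' @return list with `error_rate`, `n`, and the confusion `table`.
#' @export
misclassification_rate <- function(spec, n = 10000, epsilon = 0) {
  stopifnot(inherits(spec, "cohort_spec"), length(spec$type_mix) == 1L)
  truth_type <- names(spec$type_mix)
  res <- with_local_seed(spec$seed, {
    r_be <- stats::runif(n, spec$baseline_rate_range[1],
                         spec$baseline_rate_range[2])
    peri <- substr(truth_type, 1, 2)
    post <- substr(truth_type, 4, 6)
    f_tt <- spec$fold_tt[[truth_type]]
    f_pe <- spec$fold_pe[[truth_type]]
    r_tt <- if (peri == "TD") r_be / f_tt else r_be * f_tt
    r_pe <- if (post == "PTD") r_be / f_pe else r_be * f_pe
    dur <- spec$windows$durations
    m_be <- stats::rpois(n, r_be * dur[["be"]]) / dur[["be"]]
    m_tt <- stats::rpois(n, r_tt * dur[["tt"]]) / dur[["tt"]]
    m_pe <- stats::rpois(n, r_pe * dur[["pe"]]) / dur[["pe"]]
    classify_neuron(m_be, m_tt, m_pe, epsilon)$combined
  })
  list(error_rate = mean(res != truth_type), n = n,
       table = table(predicted = res))
}
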