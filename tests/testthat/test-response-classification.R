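test_that("classification follows the sign rule and its conventions", {
  expect_equal(classify_neuron(10, 2, 4)$combined, "TD-PTD")
  # fold changes 3.21 and 1.75 applied upward to a 10 Hz baseline
  expect_equal(classify_neuron(10, 32.1, 17.5)$combined, "TP-PTP")
  expect_equal(classify_neuron(10, 10, 10)$combined, "NR")

  # zero baseline with activity is potentiation; all-zero is NR
  expect_equal(classify_neuron(0, 5, 5)$combined, "TP-PTP")
  expect_equal(classify_neuron(0, 0, 0)$combined, "NR")

  # a dead-band widens the NR region
  expect_equal(classify_neuron(10, 9.8, 12, epsilon = 0.05)$combined, "NR")
  expect_equal(classify_neuron(10, 9.8, 12, epsilon = 0)$combined, "TD-PTP")

  # combined is NR whenever either half is NR
  lab <- classify_neuron(10, 10, 20)
  expect_equal(lab$peri, "NR")
  expect_equal(lab$combined, "NR")
  expect_error(classify_neuron(10, Inf, 3), "finite")
})

test_that("classification is scale-invariant and deterministic", {
  set.seed(14)
  for (i in 1:200) {
    m <- runif(3, 0, 30)
    c1 <- classify_neuron(m[1], m[2], m[3])$combined
    for (s in c(0.01, 0.5, 3, 1000)) {
      expect_identical(classify_neuron(s * m[1], s * m[2], s * m[3])$combined,
                       c1)
    }
  }
})

test_that("fold change uses the magnitude convention", {
  expect_equal(as.numeric(fold_change(10, 1.866)), 5.36, tolerance = 1e-3)
  expect_equal(as.numeric(fold_change(10, 10)), 1)
  expect_equal(as.numeric(fold_change(2, 10)), 5)
  expect_equal(as.numeric(fold_change(10, 2)), 5)

  # fold_change(x, x) = 1 over random rates
  set.seed(2)
  x <- runif(100, 0.1, 50)
  expect_true(all(as.numeric(fold_change(x, x)) == 1))

  # zero handling: capped with flag; both-zero undefined
  f <- fold_change(10, 0)
  expect_equal(as.numeric(f), 1e6)
  expect_equal(attr(f, "flag"), "capped")
  f2 <- fold_change(0, 0)
  expect_true(is.nan(as.numeric(f2)))
  expect_equal(attr(f2, "flag"), "undefined")
})

test_that("group summaries report proportions over classified neurons", {
  co <- generate_cohort(cohort_preset("control-SNc", n_neurons = 100,
                                      seed = 7))
  rates <- window_rates_table(co$spikes)
  s <- summarize_group(rates, group = "control", region = "SNc")
  expect_equal(unname(s$proportions_int),
               c(9, 36, 27, 28))
  expect_equal(sum(s$proportions), 100, tolerance = 1e-9)
  expect_equal(s$n_classified + s$n_nr, 100L)

  # a single classified neuron is 100% of its type
  one <- data.frame(neuron_id = 1, m_be = 10, m_tt = 2, m_pe = 4,
                    n_be = 200, n_tt = 2, n_pe = 80)
  s1 <- summarize_group(one)
  expect_equal(unname(s1$proportions[["TD-PTD"]]), 100)

  # all-NR input is an error with a diagnostic
  nr <- data.frame(neuron_id = 1:2, m_be = c(10, 5), m_tt = c(10, 5),
                   m_pe = c(10, 5), n_be = c(200, 100),
                   n_tt = c(10, 5), n_pe = c(200, 100))
  expect_error(summarize_group(nr), "NR")
})

test_that("group ratios come from pooled counts, not per-neuron ratios", {
  sp <- single_type_spec("control-SNc", "TD-PTD", n = 200, seed = 31)
  co <- generate_cohort(sp)
  rates <- window_rates_table(co$spikes)
  s <- summarize_group(rates, windows = window_def())
  pw <- pooled_window_rates(co$spikes)
  expect_equal(s$ratio_tt[["TD-PTD"]],
               as.numeric(fold_change(pw$m_be, pw$m_tt)),
               tolerance = 1e-12)
  expect_equal(s$ratio_pe[["TD-PTD"]],
               as.numeric(fold_change(pw$m_be, pw$m_pe)),
               tolerance = 1e-12)
})

test_that("misclassification is rare for the published fold scales", {
  # strong-fold type read by the proportion-recovery targets
  m <- misclassification_rate(
    single_type_spec("control-SNc", "TD-PTD", n = 1, seed = 3),
    n = 10000)
  expect_lt(m$error_rate, 1e-3)
})

test_that("every preset's summary proportions sum to 100 within rounding", {
  for (nm in cohort_presets()) {
    co <- generate_cohort(cohort_preset(nm, n_neurons = 100,
                                        seed = 50 + match(nm, cohort_presets())))
    fit <- hfs_response(co$spikes)
    expect_lte(abs(sum(fit$summary$proportions_int) - 100), 1)
  }
})
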