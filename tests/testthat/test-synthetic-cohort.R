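test_that("largest-remainder quota allocation realises type mixes exactly", {
  spec <- cohort_spec("control", "SNc", n_neurons = 100,
                      type_mix = c("TD-PTD" = 0.09, "TD-PTP" = 0.36,
                                   "TP-PTP" = 0.27, "TP-PTD" = 0.28),
                      fold_tt = c("TD-PTD" = 5.36, "TD-PTP" = 4.24,
                                  "TP-PTP" = 3.21, "TP-PTD" = 2.18),
                      fold_pe = c("TD-PTD" = 2.88, "TD-PTP" = 2.20,
                                  "TP-PTP" = 1.75, "TP-PTD" = 1.28),
                      seed = 1)
  truth <- sample_neuron_params(spec)
  cnt <- table(truth$true_type)
  expect_equal(unname(cnt[["TD-PTD"]]), 9L)
  expect_equal(unname(cnt[["TD-PTP"]]), 36L)
  expect_equal(unname(cnt[["TP-PTP"]]), 27L)
  expect_equal(unname(cnt[["TP-PTD"]]), 28L)

  # quota allocation is exact for every preset and several cohort sizes
  for (nm in cohort_presets()) {
    for (n in c(37L, 100L, 107L, 250L)) {
      sp <- cohort_preset(nm, n_neurons = n, seed = 2)
      got <- as.vector(table(factor(sample_neuron_params(sp)$true_type,
                                    levels = names(sp$type_mix))))
      q <- sp$type_mix * n
      base <- floor(q)
      rem <- n - sum(base)
      exp_counts <- base
      if (rem > 0) {
        extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
        exp_counts[extra] <- exp_counts[extra] + 1
      }
      expect_equal(got, unname(exp_counts), info = paste(nm, n))
      expect_equal(sum(got), n)
    }
  }
})

test_that("ground-truth rates follow the fold-change invariants", {
  # depressed tetanization window: r_tt = r_be / fold  (10 / 5.36 = 1.8657)
  sp <- single_type_spec("control-SNc", "TD-PTD", n = 50, seed = 5)
  truth <- generate_cohort(sp)$truth
  expect_equal(truth$r_tt, truth$r_be / 5.36, tolerance = 1e-12)
  expect_equal(truth$r_pe, truth$r_be / 2.88, tolerance = 1e-12)
  expect_true(all(truth$r_be >= 8 & truth$r_be <= 12))

  # potentiated windows multiply
  sp2 <- single_type_spec("rotenone-SNc", "TP-PTD", n = 20, seed = 5)
  truth2 <- generate_cohort(sp2)$truth
  expect_equal(truth2$r_tt, truth2$r_be * 5.81, tolerance = 1e-12)
  expect_equal(truth2$r_pe, truth2$r_be / 4.24, tolerance = 1e-12)

  # identity folds leave rates unchanged
  sp3 <- cohort_spec("g", "SNc", 10,
                     type_mix = c("TP-PTP" = 1),
                     fold_tt = c("TP-PTP" = 1), fold_pe = c("TP-PTP" = 1),
                     seed = 9)
  truth3 <- sample_neuron_params(sp3)
  expect_equal(truth3$r_tt, truth3$r_be)
  expect_equal(truth3$r_pe, truth3$r_be)
})

test_that("spike trains are Poisson with the configured window rates", {
  w <- window_def()
  set.seed(42)
  counts <- replicate(2000, {
    t <- generate_spike_train(10, 0, 5, w)
    sum(t < 0)
  })
  # mean BE count 200, CLT bound: 4 SE of the replicate mean
  expect_lt(abs(mean(counts) - 200), 4 * sqrt(200 / 2000))
  expect_lt(abs(var(counts) - 200), 30)  # Poisson: variance == mean

  # zero rate gives an empty window
  t <- generate_spike_train(5, 0, 5, w)
  expect_false(any(t >= 0 & t < 1))

  # strictly increasing times
  t2 <- generate_spike_train(20, 10, 20, w)
  expect_true(all(diff(t2) > 0))
})

test_that("long-window empirical rates converge to the true rates", {
  w <- window_def(be = c(-2000, 0), tt = c(0, 2000), pe = c(2000, 4000))
  set.seed(3)
  t <- generate_spike_train(10, 1.866, 5.2, w)
  wr <- window_rates(t, w)
  expect_lt(abs(wr$m_be - 10) / 10, 0.02)
  expect_lt(abs(wr$m_tt - 1.866) / 1.866, 0.02)
  expect_lt(abs(wr$m_pe - 5.2) / 5.2, 0.02)
})

test_that("cohort generation is seed-deterministic and validates input", {
  sp <- cohort_preset("control-SNc", n_neurons = 30, seed = 77)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$manifest$checksum, b$manifest$checksum)

  # a different seed changes the realisation
  c2 <- generate_cohort(cohort_preset("control-SNc", n_neurons = 30, seed = 78))
  expect_false(identical(a$spikes$t, c2$spikes$t))

  # written tables are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  expect_identical(readLines(file.path(d1, "spikes.csv")),
                   readLines(file.path(d2, "spikes.csv")))

  expect_error(cohort_preset("control-SNc", n_neurons = 0), "n_neurons")
  expect_error(cohort_spec("g", "SNc", 10, type_mix = numeric(0),
                           fold_tt = c(), fold_pe = c()),
               "empty")
  expect_error(cohort_spec("g", "SNc", 10,
                           type_mix = c("TD-PTD" = 0.5, "TD-PTP" = 0.4),
                           fold_tt = c("TD-PTD" = 2, "TD-PTP" = 2),
                           fold_pe = c("TD-PTD" = 2, "TD-PTP" = 2)),
               "sum to 1")
  expect_error(generate_spike_train(-1, 0, 0), "rates")
})

test_that("recorded cohort sizes back the preset defaults", {
  expect_equal(cohort_preset("control-SNc")$n_neurons, 107L)
  expect_equal(cohort_preset("rotenone-SNr")$n_neurons, 184L)
  man <- generate_cohort(cohort_preset("control-SNc", seed = 4))$manifest
  expect_equal(man$n_neurons, 107L)
})

test_that("dispersion knob inflates count variance beyond Poisson", {
  w <- window_def()
  set.seed(8)
  cnt <- function(disp) replicate(800, sum(
    generate_spike_train(10, 0, 0, w, dispersion = disp) < 0))
  v_pois <- var(cnt(1)); v_nb <- var(cnt(3))
  expect_gt(v_nb, 2 * v_pois)
})
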