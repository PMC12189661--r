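test_that("two-proportion z-test matches its closed form and trivial cases", {
  # equal proportions: z = 0, p = 1
  s <- proportion_test(20, 100, 10, 50)
  expect_equal(s$statistic, 0)
  expect_equal(s$p_value, 1)

  # hand-computed pooled z for the published-style counts
  k1 <- 21; n1 <- 105; k2 <- 34; n2 <- 95
  pp <- (k1 + k2) / (n1 + n2)
  z <- (k1 / n1 - k2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  s2 <- proportion_test(k1, n1, k2, n2)
  expect_equal(s2$statistic, z, tolerance = 1e-12)
  expect_equal(s2$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  # agrees with the uncorrected chi-square test (z^2 = X^2)
  pt <- prop.test(c(k1, k2), c(n1, n2), correct = FALSE)
  expect_equal(s2$statistic^2, unname(pt$statistic), tolerance = 1e-9)
  expect_equal(s2$p_value, pt$p.value, tolerance = 1e-9)

  # extreme split: both the test and the exact oracle are far below 0.001
  s3 <- proportion_test(0, 10, 10, 10)
  expect_lt(s3$p_value, 0.001)
  expect_lt(fisher.test(matrix(c(0, 10, 10, 0), 2, byrow = TRUE))$p.value,
            0.001)

  # small expected cells trigger the exact fallback, identical to Fisher
  s4 <- proportion_test(1, 8, 7, 8)
  expect_match(s4$flag, "exact")
  expect_equal(s4$p_value,
               fisher.test(matrix(c(1, 7, 7, 1), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
})

test_that("z-test p-values track the Fisher exact oracle on small tables", {
  # all 2x2 tables with n1 = n2 = 12: where the z-test applies (no
  # small expected cells) its p stays close to the exact p; where the
  # fallback triggers it must equal the oracle identically.
  n1 <- n2 <- 12L
  for (k1 in 0:12) for (k2 in 0:12) {
    res <- proportion_test(k1, n1, k2, n2)
    oracle <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2,
                                 byrow = TRUE))$p.value
    if (grepl("exact", res$flag)) {
      expect_equal(res$p_value, oracle, tolerance = 1e-12)
    } else {
      # the pooled z-test is anticonservative relative to the
      # conditional exact test (outside the deep tails, where both
      # p-values are negligible and the decision is the same), and
      # decisions agree wherever the oracle is decisive
      if (max(res$p_value, oracle) > 1e-4)
        expect_lte(res$p_value, oracle + 1e-9)
      if (oracle < 0.01) expect_lt(res$p_value, 0.05)
      if (oracle > 0.5) expect_gt(res$p_value, 0.05)
    }
  }
})

test_that("proportion-test type-I error is near nominal under the null", {
  set.seed(1234)
  n <- 100L
  reps <- 10000L
  k1 <- rbinom(reps, n, 0.3)
  k2 <- rbinom(reps, n, 0.3)
  p <- vapply(seq_len(reps), function(i)
    proportion_test(k1[i], n, k2[i], n)$p_value, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("Student's t matches the pooled closed form; F = t^2 for two groups", {
  x1 <- c(1, 2, 3); x2 <- c(11, 12, 13)
  s <- students_t(x1, x2)
  # pooled SD = 1, SE = sqrt(2/3), t = -10 / sqrt(2/3)
  expect_equal(s$statistic, -10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(s$df, 4)

  a <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(a$statistic, 0)
  expect_equal(a$p_value, 1)

  set.seed(6)
  g1 <- rnorm(20); g2 <- rnorm(25, 0.5)
  tt <- students_t(g1, g2)
  an <- one_way_anova(list(g1, g2))
  expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(an$p_value, tt$p_value, tolerance = 1e-9)
})

test_that("Cohen's d is the pooled standardized mean difference", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(11)
  x1 <- rnorm(4000, 0, 1); x2 <- rnorm(4000, 0.9, 1)
  expect_equal(cohens_d(x2, x1), 0.9, tolerance = 0.08)
  expect_equal(cohens_d(x1, x2), -cohens_d(x2, x1))
  expect_warning(d0 <- cohens_d(c(1, 1), c(2, 2)), "pooled SD")
  expect_true(is.nan(d0))
})

test_that("ANOVA and Tukey behave on degenerate and two-group input", {
  an <- one_way_anova(list(c(5, 5, 5), c(5, 5, 5)))
  expect_true(is.nan(an$statistic))
  expect_match(an$flag, "degenerate")

  set.seed(15)
  g1 <- rnorm(15); g2 <- rnorm(15, 0.4)
  th <- tukey_hsd(list(a = g1, b = g2))
  tt <- students_t(g1, g2)
  expect_equal(th$p_adj, tt$p_value, tolerance = 1e-6)
})

test_that("Tukey flags exactly the pairs involving a shifted group", {
  set.seed(20)
  reps <- 200
  hits <- matrix(FALSE, reps, 3)
  for (i in seq_len(reps)) {
    g <- list(a = rnorm(25), b = rnorm(25), c = rnorm(25, 1.2))
    th <- tukey_hsd(g)
    hits[i, ] <- th$p_adj < 0.05   # pairs: b-a, c-a, c-b
  }
  # the two pairs involving the shifted group are detected with high
  # power; the null pair keeps its error near the familywise level
  expect_gt(mean(hits[, 2]), 0.9)
  expect_gt(mean(hits[, 3]), 0.9)
  expect_lt(mean(hits[, 1]), 0.08)
})

test_that("assumption checks calibrate near the null and flag small samples", {
  set.seed(30)
  # Shapiro-Wilk p under normality is approximately uniform
  p_norm <- replicate(400, shapiro_p <- assumption_checks(
    list(rnorm(40)))$normality_p[[1]])
  ks <- ks.test(p_norm, "punif")
  expect_gt(ks$p.value, 0.01)

  # a contaminated sample is flagged as non-normal nearly always
  p_out <- replicate(200, assumption_checks(
    list(c(rnorm(38), 9, 10)))$normality_p[[1]])
  expect_gte(mean(p_out < 0.05), 0.95)

  # Levene type-I error near 0.05 for equal-variance groups
  lev <- replicate(500, assumption_checks(
    list(rnorm(20), rnorm(20), rnorm(20)))$levene_p)
  expect_gt(mean(lev < 0.05), 0.02)
  expect_lt(mean(lev < 0.05), 0.09)

  small <- assumption_checks(list(c(1, 2)))
  expect_true(is.na(small$normality_p[[1]]))
  expect_true(length(small$flags) > 0)
})

test_that("mean-centered Levene agrees with the reference implementation", {
  skip_if_not_installed("car")
  set.seed(40)
  g <- list(rnorm(20, sd = 1), rnorm(25, sd = 2), rnorm(30, sd = 1))
  ours <- assumption_checks(g)
  x <- unlist(g)
  f <- factor(rep(seq_along(g), lengths(g)))
  ref <- car::leveneTest(x, f, center = mean)
  expect_equal(ours$levene_F, ref[1, "F value"], tolerance = 1e-9)
  expect_equal(ours$levene_p, ref[1, "Pr(>F)"], tolerance = 1e-9)
})
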