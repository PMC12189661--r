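new_stat_result <- function(method, statistic = NA_real_, p_value,
                            df = NA_real_, effect_size = NA_real_,
                            flag = "") {
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, df = df,
                 effect_size = effect_size, flag = flag),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$method, x$statistic,
              x$p_value))
  if (!is.na(x$df[1])) cat(sprintf(", df = %s", paste(round(x$df, 2), collapse = ", ")))
  if (!is.na(x$effect_size)) cat(sprintf(", d = %.3f", x$effect_size))
  if (nzchar(x$flag)) cat(sprintf("  [%s]", x$flag))
  cat("\n")
  invisible(x)
}

#' Two-sample proportion comparison
#'
#' Two-sided two-proportion z-test with pooled variance,
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the pooled
#' proportion. When any expected cell count of the 2x2 table is below
#' 5 the normal approximation is unreliable; the test then falls back
#' to Fisher's exact test and flags the result. This is the stand-in
#' for the significance stars attached to the published type
#' proportions (rotenone vs melanin-treated comparisons).
#'
#' @param k1,n1 successes and size of sample 1.
#' @param k2,n2 successes and size of sample 2.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact test;
#'   `NULL` (default) decides by the expected-cell rule.
#' @return a `stat_result`; `statistic` is z (or the odds ratio for the
#'   exact fallback), `effect_size` is the difference in proportions.
#' @examples
#' proportion_test(21, 105, 34, 95)   # p < 0.05
#' @export
proportion_test <- function(k1, n1, k2, n2, exact = NULL) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  expected <- c(n1 * pp, n1 * (1 - pp), n2 * pp, n2 * (1 - pp))
  use_exact <- if (is.null(exact)) any(expected < 5) else isTRUE(exact)
  if (use_exact) {
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    return(new_stat_result("Fisher exact test (two-proportion fallback)",
                           statistic = unname(ft$estimate),
                           p_value = ft$p.value,
                           effect_size = p1 - p2,
                           flag = "exact"))
  }
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0)  # all successes or all failures in both arms
    return(new_stat_result("two-proportion z-test", statistic = 0,
                           p_value = 1, effect_size = 0,
                           flag = "degenerate"))
  z <- (p1 - p2) / se
  new_stat_result("two-proportion z-test", statistic = z,
                  p_value = 2 * stats::pnorm(-abs(z)),
                  effect_size = p1 - p2)
}

#' Cohen's d standardized mean difference
#'
#' `(mean(x1) - mean(x2)) / s_pooled`, with the pooled SD weighted by
#' degrees of freedom. Values around 0.2, 0.5 and 0.8 are
#' conventionally read as small, medium and large effects.
#'
#' @param x1,x2 numeric samples, each of length >= 2.
#' @return numeric; `NaN` with a warning when the pooled SD is 0.
#' @export
cohens_d <- function(x1, x2) {
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  if (sp2 == 0) {
    warning("pooled SD is zero: Cohen's d undefined")
    return(NaN)
  }
  (mean(x1) - mean(x2)) / sqrt(sp2)
}

#' Two-sample Student's t-test with effect size
#'
#' Two-sided t-test (equal-variance by default, Welch optional) with
#' Cohen's d attached. A degenerate case -- zero variance in both
#' samples with equal means -- is reported as p = 1 and flagged.
#'
#' @param x1,x2 numeric samples, each of length >= 2.
#' @param welch use the Welch unequal-variance form.
#' @return a `stat_result`.
#' @export
students_t <- function(x1, x2, welch = FALSE) {
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  if (stats::var(x1) == 0 && stats::var(x2) == 0) {
    if (mean(x1) == mean(x2))
      return(new_stat_result("Student's t-test", statistic = 0,
                             p_value = 1, df = length(x1) + length(x2) - 2,
                             effect_size = 0, flag = "zero variance"))
    return(new_stat_result("Student's t-test", statistic = Inf,
                           p_value = 0, df = length(x1) + length(x2) - 2,
                           effect_size = Inf, flag = "zero variance"))
  }
  tt <- stats::t.test(x1, x2, var.equal = !welch)
  d <- tryCatch(cohens_d(x1, x2), warning = function(w) NaN)
  new_stat_result(if (welch) "Welch t-test" else "Student's t-test",
                  statistic = unname(tt$statistic),
                  p_value = tt$p.value, df = unname(tt$parameter),
                  effect_size = d)
}

#' One-way analysis of variance
#'
#' Classic fixed-effects F decomposition across >= 2 groups.
#'
#' @param groups list of numeric samples, each of length >= 2.
#' @return a `stat_result` with `statistic` F and `df = c(df1, df2)`;
#'   flagged when the within-group variance is degenerate.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 2))
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(x) == 0)
    return(new_stat_result("one-way ANOVA", statistic = NaN, p_value = NA_real_,
                           df = c(length(groups) - 1, length(x) - length(groups)),
                           flag = "degenerate: zero total variance"))
  fit <- stats::aov(x ~ g)
  s <- summary(fit)[[1]]
  new_stat_result("one-way ANOVA", statistic = s[["F value"]][1],
                  p_value = s[["Pr(>F)"]][1],
                  df = s[["Df"]])
}

#' Tukey HSD pairwise comparisons after one-way ANOVA
#'
#' @param groups list of >= 2 numeric samples; names are used as group
#'   labels.
#' @return data.frame with columns `pair`, `diff`, `lwr`, `upr`,
#'   `p_adj` (studentized-range adjusted p-values).
#' @export
tukey_hsd <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 2))
  nm <- names(groups) %||% as.character(seq_along(groups))
  x <- unlist(groups)
  g <- factor(rep(nm, lengths(groups)), levels = nm)
  th <- stats::TukeyHSD(stats::aov(x ~ g))$g
  data.frame(pair = rownames(th), diff = th[, "diff"],
             lwr = th[, "lwr"], upr = th[, "upr"],
             p_adj = th[, "p adj"], row.names = NULL)
}

#' Normality and variance-homogeneity checks
#'
#' The screening battery run before parametric comparisons:
#' Shapiro-Wilk normality per group and a mean-centered Levene test of
#' variance homogeneity across groups (one-way ANOVA on absolute
#' deviations from the group means). Groups too small for a check are
#' skipped and flagged.
#'
#' @param samples list of numeric samples.
#' @return list with `normality_p` (named per group, `NA` when
#'   skipped), `levene_p`, `levene_F`, and `flags`.
#' @export
assumption_checks <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1)
  nm <- names(samples) %||% as.character(seq_along(samples))
  flags <- character(0)
  norm_p <- vapply(seq_along(samples), function(i) {
    x <- samples[[i]]
    if (length(x) < 3 || length(x) > 5000 || stats::var(x) == 0) {
      flags <<- c(flags, sprintf("normality check skipped for group %s", nm[i]))
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  names(norm_p) <- nm
  lev_p <- NA_real_; lev_F <- NA_real_
  if (length(samples) >= 2 && all(lengths(samples) >= 2)) {
    dev <- unlist(lapply(samples, function(x) abs(x - mean(x))))
    g <- factor(rep(nm, lengths(samples)), levels = nm)
    if (stats::var(dev) > 0) {
      s <- summary(stats::aov(dev ~ g))[[1]]
      lev_F <- s[["F value"]][1]
      lev_p <- s[["Pr(>F)"]][1]
    } else flags <- c(flags, "Levene test degenerate: zero deviation variance")
  } else flags <- c(flags, "Levene test skipped: need >= 2 groups of >= 2")
  list(normality_p = norm_p, levene_p = lev_p, levene_F = lev_F,
       flags = flags)
}
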