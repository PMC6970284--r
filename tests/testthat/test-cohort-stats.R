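grp_df <- function(...) {
  samples <- list(...)
  data.frame(g = rep(names(samples), lengths(samples)),
             v = unlist(samples, use.names = FALSE))
}

test_that("normality tests accept Gaussian and reject gross non-normality", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    d <- data.frame(v = rnorm(200))
    res <- normality_tests(d, v)
    if (all(res$p_value > 0.05)) hits <- hits + 1L
  }
  expect_gte(hits, 90)

  set.seed(1)
  two_point <- data.frame(v = sample(c(0, 1), 200, replace = TRUE))
  res <- normality_tests(two_point, v)
  expect_lt(res$p_value[res$method == "Shapiro-Wilk"], 0.01)

  expect_error(normality_tests(data.frame(v = rep(1, 10)), v), "constant")
  expect_error(normality_tests(data.frame(v = c(1, 2)), v), "n >= 3")
})

test_that("Levene's test detects unequal spreads and is calibrated under H0", {
  same <- grp_df(a = c(1, 2, 3, 4), b = c(11, 12, 13, 14))
  res <- variance_homogeneity(same, v, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(8)
  unequal <- grp_df(a = rnorm(50, sd = 4), b = rnorm(50, sd = 1))
  expect_lt(variance_homogeneity(unequal, v, g)$p_value, 0.01)

  # p-values uniform under the null (KS over 500 seeds)
  pvals <- vapply(1:500, function(s) {
    set.seed(s)
    d <- grp_df(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    variance_homogeneity(d, v, g)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)

  expect_error(variance_homogeneity(grp_df(a = 1, b = c(1, 2)), v, g), "n >= 2")
})

test_that("the omnibus switches between classic and Welch ANOVA", {
  set.seed(5)
  hom <- grp_df(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  res <- omnibus_anova(hom, v, g)
  expect_identical(res$method, "one-way ANOVA")
  expect_gte(res$levene_p, 0.05)

  het <- grp_df(a = rnorm(30, sd = 0.05), b = rnorm(30, sd = 0.05),
                c = rnorm(30, sd = 5))
  resw <- omnibus_anova(het, v, g)
  expect_identical(resw$method, "Welch's ANOVA")

  expect_identical(omnibus_anova(hom, v, g, mode = "welch")$method,
                   "Welch's ANOVA")

  # power: a 5-SD shifted group is detected decisively
  set.seed(6)
  shifted <- grp_df(a = rnorm(15), b = rnorm(15), c = rnorm(15, mean = 5))
  expect_lt(omnibus_anova(shifted, v, g)$p_value, 0.001)
})

test_that("with two groups the classic F equals the squared pooled t", {
  set.seed(7)
  d <- grp_df(a = rnorm(12, 10, 2), b = rnorm(15, 11, 2))
  f <- omnibus_anova(d, v, g, mode = "classic")
  tt <- independent_t_test(d, v, g, var_equal = TRUE)
  expect_equal(f$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(f$p_value, tt$p_value, tolerance = 1e-10)
})

test_that("Bonferroni post-hoc multiplies by the pair count and clamps at 1", {
  set.seed(9)
  d <- grp_df(a = rnorm(10), b = rnorm(10), c = rnorm(10), d = rnorm(10),
              e = rnorm(10))
  res <- bonferroni_pairwise(d, v, g)
  expect_identical(nrow(res), 10L)       # choose(5, 2)
  expect_true(all(res$n_pairs == 10))
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 10))
  expect_true(all(res$p_adjusted >= res$p_raw))

  m <- pairwise_p_matrix(res)
  expect_identical(m, t(m))
  expect_true(all(is.na(diag(m))))

  same <- grp_df(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_true(all(bonferroni_pairwise(same, v, g)$p_adjusted == 1))
})

test_that("independent t-tests have null identity, power, and symmetry", {
  same <- grp_df(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- independent_t_test(same, v, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(10)
  far <- grp_df(a = rnorm(25, 0), b = rnorm(25, 6))
  expect_lt(independent_t_test(far, v, g)$p_value, 0.001)

  swapped <- far; swapped$g <- ifelse(far$g == "a", "b", "a")
  r1 <- independent_t_test(far, v, g)
  r2 <- independent_t_test(swapped, v, g)
  expect_equal(r2$p_value, r1$p_value)
  expect_equal(r2$statistic, -r1$statistic)

  const <- grp_df(a = c(5, 5), b = c(5, 5))
  expect_warning(rc <- independent_t_test(const, v, g), "constant")
  expect_equal(rc$p_value, 1)
})

test_that("TOST concludes equivalence only inside the similarity region", {
  # epsilon -> 0+: equivalence can never be concluded
  set.seed(11)
  d <- grp_df(a = rnorm(16), b = rnorm(14))
  tiny <- tost_equivalence(d, v, g, epsilon = 1e-9)
  expect_gte(tiny$p_tost, 0.5)

  # identically distributed groups with a wide margin: nearly always concluded
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    ds <- grp_df(a = rnorm(16), b = rnorm(14))
    if (tost_equivalence(ds, v, g, epsilon = 3)$p_tost < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95)

  # clear non-equivalence: difference of 2 epsilon at large n
  set.seed(12)
  dn <- grp_df(a = rnorm(200, 0), b = rnorm(200, 1))
  res <- tost_equivalence(dn, v, g, epsilon = 0.5)
  expect_gt(res$p_tost, 0.99)
  expect_false(res$equivalent)

  # the standard TOST interval is the 90% CI; the 95% is also reportable
  r90 <- tost_equivalence(d, v, g, epsilon = 1)
  expect_equal(r90$ci_level, 0.90)
  r95 <- tost_equivalence(d, v, g, epsilon = 1, ci_level = 0.95)
  expect_gt(r95$ci_upper - r95$ci_lower, r90$ci_upper - r90$ci_lower)

  expect_error(tost_equivalence(d, v, g, epsilon = 0), "positive")
})

test_that("classification is strict at the boundary and unit-consistent", {
  out <- classify_subjects(data.frame(z = c(2.1, 2.0, -2.0001, 0)), z,
                           units = "z")
  expect_identical(out$label, c("abnormal", "normal", "abnormal", "normal"))

  ref <- build_reference_stats(c(970, 1000, 1030), test_key())
  ms <- classify_subjects(data.frame(t1 = 1061), t1, ref = ref)
  expect_identical(ms$label, "abnormal")  # |Z| = 61/30 = 2.033

  high_only <- classify_subjects(data.frame(z = c(-3, 3)), z, units = "z",
                                 sidedness = "high")
  expect_identical(high_only$label, c("normal", "abnormal"))

  # ms-space and Z-space thresholding agree on random cohorts
  for (s in 1:5) {
    set.seed(s)
    refr <- build_reference_stats(rnorm(15, 1000, 30), test_key())
    t1 <- rnorm(200, 1000, 60)
    in_ms <- classify_subjects(data.frame(t1 = t1), t1, ref = refr)$label
    in_z <- classify_subjects(data.frame(z = (t1 - refr$mean) / refr$sd), z,
                              units = "z")$label
    expect_identical(in_ms, in_z)
  }
})

test_that("diagnostic performance counts the confusion table correctly", {
  d <- data.frame(truth = c(rep("abnormal", 25), rep("normal", 14)),
                  pred = c(rep("abnormal", 24), "normal", rep("normal", 14)))
  res <- diagnostic_performance(d, truth, pred)
  expect_identical(c(res$tp, res$fn, res$tn, res$fp), c(24L, 1L, 14L, 0L))
  expect_equal(res$sensitivity, 0.96)
  expect_equal(res$specificity, 1.0)

  healthy_only <- data.frame(truth = rep("normal", 5),
                             pred = rep("normal", 5))
  expect_warning(res2 <- diagnostic_performance(healthy_only, truth, pred),
                 "sensitivity undefined")
  expect_true(is.na(res2$sensitivity))
  expect_equal(res2$specificity, 1)

  bad <- data.frame(truth = c("normal", "weird"), pred = c("normal", "normal"))
  expect_error(diagnostic_performance(bad, truth, pred), "binary")
})
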