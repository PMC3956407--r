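# Audic-Claverie probabilities and tails, the Dif ratio statistic,
# binned reporting, and the sage_test fit.

test_that("conditional probability matches closed forms and frozen exact values", {
  expect_equal(ac_probability(0, 0, 1000, 1000), 0.5, tolerance = 1e-12)
  expect_equal(ac_probability(1, 0, 500, 500), 0.25, tolerance = 1e-12)
  # frozen from exact rational arithmetic
  expect_equal(ac_probability(5, 15, 1894, 2670), 0.025476172304269233,
               tolerance = 1e-12)
  expect_error(ac_probability(-1, 0, 10, 10), "non-negative")
  expect_error(ac_probability(1, 1, 0, 10), ">= 1")
})

test_that("probabilities agree with the negative-binomial identity across totals", {
  # p(k|x) over k is the nbinom pmf with size x+1, prob N_A/(N_A+N_B);
  # independent route through R's C implementation
  for (tot in list(c(100, 100), c(1894, 2670), c(2670, 100))) {
    N_A <- tot[1]; N_B <- tot[2]
    x <- rep(0:30, each = 31)
    y <- rep(0:30, times = 31)
    mine <- ac_probability(x, y, N_A, N_B)
    ref <- dnbinom(y, size = x + 1, prob = N_A / (N_A + N_B))
    expect_lt(max(abs(mine / ref - 1)), 1e-12)
    tails <- ac_two_sided(x, y, N_A, N_B)
    expect_lt(max(abs(tails$p_left -
                        pnbinom(y, size = x + 1, prob = N_A / (N_A + N_B)))),
              1e-12)
  }
})

test_that("tails share the point mass and the two-sided rule is symmetric", {
  t1 <- ac_two_sided(10, 10, 1000, 1000)
  expect_equal(t1$p_left + t1$p_right - ac_probability(10, 10, 1000, 1000), 1,
               tolerance = 1e-9)
  expect_equal(t1$p_two_sided, 1, tolerance = 1e-9)  # x = y, equal totals
  # formula is symmetric in x, y when the library ratio is 1
  for (xy in list(c(3, 9), c(0, 5), c(17, 2))) {
    expect_equal(ac_probability(xy[1], xy[2], 800, 800),
                 ac_probability(xy[2], xy[1], 800, 800), tolerance = 1e-14)
  }
  # frozen from exact rational brute force: x=0, y=12, totals 1894/2670
  t2 <- ac_two_sided(0, 12, 1894, 2670)
  expect_equal(t2$p_left, 0.9990599452828307, tolerance = 1e-12)
  expect_equal(t2$p_right, 0.0016068950296482746, tolerance = 1e-9)
  expect_equal(t2$p_two_sided, 0.0032137900592965492, tolerance = 1e-9)
})

test_that("small right tails keep full relative accuracy", {
  # far right tail: complement evaluation would lose all digits
  t <- ac_two_sided(0, 40, 1894, 2670)
  exact_right <- (2670 / 4564)^40  # sum of the geometric tail for x = 0
  expect_equal(t$p_right / exact_right, 1, tolerance = 1e-10)
})

test_that("Dif statistic applies the rounded correction coefficient", {
  expect_identical(correction_coefficient(1894, 2670), 1.41)
  expect_equal(dif_statistic(100, 141, 1894, 2670), 1, tolerance = 1e-9)
  expect_equal(dif_statistic(1, 1, 1894, 2670), 1.41, tolerance = 1e-12)
  expect_identical(dif_statistic(3, 0, 1894, 2670), Inf)
  expect_identical(dif_statistic(0, 3, 1894, 2670), 0)
  expect_error(dif_statistic(0, 0, 1894, 2670), "at least one")
  # reciprocity up to coefficient rounding
  d_ab <- dif_statistic(7, 4, 1894, 2670)
  d_ba <- dif_statistic(4, 7, 2670, 1894)
  expect_equal(d_ab * d_ba, 1.41 * 0.71, tolerance = 1e-12)
})

test_that("Dif band classification flags values outside the band", {
  expect_false(classify_dif(1.0))
  expect_true(classify_dif(2.0))
  expect_true(classify_dif(Inf))
  expect_true(classify_dif(0))
  expect_false(classify_dif(0.6))
  expect_false(classify_dif(1.6))
})

test_that("binned report is exhaustive and sums to 100", {
  tags <- fixture_tags(5, seed = 41)
  res <- data.frame(dif = c(1.0, 1.0, 3.0, 0.4, 5.0),
                    count_A = c(10L, 20L, 5L, 3L, 2L))
  rep1 <- binned_report(res, weighting = "by_unique_tag")
  expect_equal(sum(rep1$percent), 100, tolerance = 0.1)
  expect_equal(rep1$percent[rep1$label == "0.6-1.6"], 40, tolerance = 1e-9)
  expect_equal(rep1$percent[rep1$label == "out_of_table"], 20, tolerance = 1e-9)
  expect_true(rep1$significant[rep1$label == "out_of_table"])
  expect_equal(attr(rep1, "total_significant_percent"), 60, tolerance = 1e-9)

  rep2 <- binned_report(res, weighting = "by_tag_count")
  expect_equal(rep2$percent[rep2$label == "0.6-1.6"], 75, tolerance = 1e-9)

  all_band <- data.frame(dif = rep(1, 4), count_A = c(1L, 2L, 3L, 4L))
  rep3 <- binned_report(all_band)
  expect_equal(rep3$percent[rep3$label == "0.6-1.6"], 100, tolerance = 1e-9)
  expect_equal(attr(rep3, "total_significant_percent"), 0, tolerance = 1e-9)

  expect_error(binned_report(res[0, ]), "at least one")
})

test_that("sage_test calls nothing significant under the exact null", {
  tags <- fixture_tags(6, seed = 43)
  counts <- c(2L, 5L, 9L, 14L, 20L, 40L)
  tab <- tag_count_table(tags, counts, counts)
  # equal totals and x = y: two-sided p is 1 for every tag
  fit <- sage_test(tab)
  expect_identical(sum(fit$results$significant_by_test), 0L)
  expect_equal(fit$results$p_two_sided, rep(1, nrow(tab)), tolerance = 1e-9)
})

test_that("sage_test detects strongly planted tags and supports BH correction", {
  cfg <- sim_config(n_transcripts = 200, de_fraction = 0.05,
                    fold_changes = c(20, 1 / 20), seed = 44)
  truth <- simulate_truth(cfg)
  tab <- sample_libraries(truth)
  fit <- sage_test(tab)
  res <- merge(fit$results, as.data.frame(truth), by = "tag")
  # planted 20-fold tags well-expressed in at least one library must be caught
  strong <- res$is_de & pmax(res$abundance_A * 1894, res$abundance_B * 2670) >= 10
  expect_true(sum(strong) > 0)
  expect_true(all(res$significant_by_test[strong]))
  expect_true(all(res$significant_by_dif[strong]))

  fit_bh <- sage_test(tab, correction = "benjamini_hochberg")
  expect_true(all(fit_bh$results$adjusted_p >= fit_bh$results$p_two_sided))
  expect_lte(sum(fit_bh$results$significant_by_test),
             sum(fit$results$significant_by_test))
})

test_that("detection power is monotone in fold change and expression level", {
  power_at <- function(p_expr, fold, n_rep = 400, seed) {
    set.seed(seed)
    x <- rbinom(n_rep, 1894, p_expr)
    y <- rbinom(n_rep, 2670, p_expr * fold)
    ok <- x + y > 0
    p <- ac_two_sided(x[ok], y[ok], 1894, 2670)$p_two_sided
    mean(p <= 0.05)
  }
  folds <- c(1.5, 3, 6)
  pw <- vapply(seq_along(folds), function(i) {
    power_at(0.004, folds[i], seed = 100 + i)
  }, 0)
  expect_true(all(diff(pw) >= 0))
  levels <- c(0.001, 0.004, 0.012)
  pw2 <- vapply(seq_along(levels), function(i) {
    power_at(levels[i], 4, seed = 200 + i)
  }, 0)
  expect_true(all(diff(pw2) >= 0))
})

test_that("threshold sensitivity reports a non-decreasing significant count", {
  tab <- fixture_table(30, seed = 45, totals_scale = 15L)
  fit <- sage_test(tab)
  sens <- threshold_sensitivity(fit)
  expect_true(all(diff(sens$n_significant) >= 0))
  expect_identical(sens$n_significant[sens$alpha == 0.05],
                   sum(fit$results$p_two_sided <= 0.05))
})
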