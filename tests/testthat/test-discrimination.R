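test_that("one-way ANOVA and Tukey comparisons match hand-computed values", {
  d <- data.frame(diagnosis = rep(c("CTL", "MCI", "AD"), each = 3),
                  value = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
  gt <- group_anova(d)
  expect_equal(gt$f_stat, 3.0)          # SSB = 6 on 2 df, MSW = 1
  expect_equal(gt$df_between, 2)
  expect_equal(gt$df_within, 6)
  expect_equal(nrow(gt$pairwise), 3)

  # identical groups: F = 0, p = 1
  same <- data.frame(diagnosis = rep(c("CTL", "MCI", "AD"), each = 3),
                     value = rep(c(1, 2, 3), 3))
  gt0 <- group_anova(same)
  expect_equal(gt0$f_stat, 0)
  expect_equal(gt0$p, 1)

  # overwhelming separation
  far <- data.frame(diagnosis = rep(c("CTL", "AD"), each = 10),
                    value = c(rnorm(10, 0, 1), rnorm(10, 100, 1)))
  gtf <- group_anova(far)
  expect_lt(gtf$p, 1e-10)
  expect_lt(gtf$pairwise$p_adj[1], 1e-6)

  expect_error(group_anova(data.frame(diagnosis = c("CTL", "AD"), value = 1:2)),
               class = "foldlaw_insufficient_data_error")
})

test_that("empirical AUC equals the Mann-Whitney pair-counting oracle", {
  # worked example: 3 of 4 pairs concordant
  r <- empirical_roc(c(-0.50, -0.53, -0.52, -0.56), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 0.75)

  # perfect separation
  expect_equal(empirical_roc(c(-0.5, -0.51, -0.6, -0.62),
                             c(FALSE, FALSE, TRUE, TRUE))$auc, 1.0)

  # randomized instances incl. ties, both directions, exact agreement
  set.seed(31)
  for (i in 1:60) {
    n <- sample(5:60, 1)
    scores <- round(rnorm(n), sample(0:2, 1))
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    for (dir in c("lower_is_positive", "higher_is_positive")) {
      expect_equal(empirical_roc(scores, labels, dir)$auc,
                   auc_pair_counting(scores, labels, dir),
                   tolerance = 1e-12)
    }
  }

  expect_error(empirical_roc(1:3, c(TRUE, TRUE, TRUE)),
               class = "foldlaw_validation_error")
})

test_that("reversing direction maps AUC to 1 - AUC", {
  set.seed(8)
  scores <- round(rnorm(40), 1)
  labels <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  a <- empirical_roc(scores, labels, "lower_is_positive")$auc
  b <- empirical_roc(scores, labels, "higher_is_positive")$auc
  expect_equal(a, 1 - b, tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(120)
  labels <- sample(c(TRUE, FALSE), 120, replace = TRUE)
  ours <- empirical_roc(scores, labels, "higher_is_positive")$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<", quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("labels independent of scores give AUC near one half", {
  set.seed(21)
  auc <- empirical_roc(rnorm(1000), sample(c(TRUE, FALSE), 1000, replace = TRUE))$auc
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("optimal cut-point matches the worked separations and tie-breaks", {
  # clean gap: midpoint of the separating interval, perfect metrics
  cp <- optimal_cutpoint(c(-0.50, -0.51, -0.52, -0.55, -0.56),
                         c(FALSE, FALSE, FALSE, TRUE, TRUE), bootstrap_n = 0)
  expect_equal(cp$cutpoint, -0.535)
  expect_equal(cp$sensitivity, 1)
  expect_equal(cp$specificity, 1)
  expect_equal(cp$auc, 1)
  expect_equal(cp$accuracy, 1)

  # two threshold regions tie at J = 0.5; max-sensitivity tie-break -> -0.51
  cp2 <- optimal_cutpoint(c(-0.50, -0.53, -0.52, -0.56),
                          c(FALSE, FALSE, TRUE, TRUE), bootstrap_n = 0)
  expect_equal(cp2$cutpoint, -0.51)
  expect_equal(cp2$sensitivity, 1)
  expect_equal(cp2$specificity, 0.5)

  expect_error(optimal_cutpoint(1:4, rep(TRUE, 4), bootstrap_n = 0),
               class = "foldlaw_validation_error")
  expect_error(optimal_cutpoint(1:4, c(TRUE, TRUE, FALSE, FALSE)),
               class = "foldlaw_validation_error")  # bootstrap without seed
})

test_that("cut-point search equals exhaustive threshold search on random instances", {
  set.seed(63)
  for (i in 1:300) {
    n <- sample(6:40, 1)
    scores <- round(rnorm(n), sample(0:2, 1))
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    dir <- sample(c("lower_is_positive", "higher_is_positive"), 1)
    got <- optimal_cutpoint(scores, labels, dir, bootstrap_n = 0)
    want <- cutpoint_exhaustive(scores, labels, dir)
    expect_identical(got$cutpoint, want$cutpoint)
    expect_identical(got$sensitivity, want$sensitivity)
    expect_identical(got$specificity, want$specificity)
  }
})

test_that("reported metrics are recomputable at the reported cut-point", {
  set.seed(77)
  scores <- rnorm(80)
  labels <- sample(c(TRUE, FALSE), 80, replace = TRUE)
  cp <- optimal_cutpoint(scores, labels, "lower_is_positive", bootstrap_n = 50,
                         seed = 4)
  sens <- mean(scores[labels] <= cp$cutpoint)
  spec <- mean(scores[!labels] > cp$cutpoint)
  expect_identical(cp$sensitivity, sens)
  expect_identical(cp$specificity, spec)
  acc <- (sens * sum(labels) + spec * sum(!labels)) / 80
  expect_equal(cp$accuracy, acc)
})

test_that("bootstrap intervals are reproducible under a fixed seed", {
  set.seed(5)
  scores <- rnorm(60)
  labels <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  a <- optimal_cutpoint(scores, labels, bootstrap_n = 200, seed = 11)
  b <- optimal_cutpoint(scores, labels, bootstrap_n = 200, seed = 11)
  expect_identical(a$cutpoint_ci, b$cutpoint_ci)
  c <- optimal_cutpoint(scores, labels, bootstrap_n = 200, seed = 12)
  expect_false(identical(a$cutpoint_ci, c$cutpoint_ci))
  # the bootstrap does not disturb the caller's RNG stream
  set.seed(3); before <- rnorm(1)
  set.seed(3)
  invisible(optimal_cutpoint(scores, labels, bootstrap_n = 20, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("contrast_table mirrors the lobe-by-contrast layout", {
  spec <- cohort_spec(n = c(CTL = 40, MCI = 15, AD = 10), seed = 2)
  cohort <- generate_cohort(spec)
  folded <- compute_folding(correct_lobes(cohort$morphometry))
  tab <- contrast_table(folded, "K", rois = c("hemisphere", "temporal"),
                        bootstrap_n = 20, seed = 6)
  expect_equal(nrow(tab), 4)  # 2 ROIs x 2 contrasts
  expect_setequal(unique(tab$contrast), c("CTL-AD", "CTL-MCI"))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))

  # absent disease group: warning, contrast skipped, others intact
  no_ad <- folded[folded$diagnosis != "AD", ]
  expect_warning(t2 <- contrast_table(no_ad, "K", rois = "hemisphere",
                                      bootstrap_n = 0, seed = 1),
                 "empty cell")
  expect_equal(nrow(t2), 1)
  expect_equal(t2$contrast, "CTL-MCI")
})

test_that("identical group distributions give chance-level discrimination", {
  set.seed(14)
  scores <- rnorm(400)
  labels <- rep(c(TRUE, FALSE), each = 200)
  cp <- optimal_cutpoint(scores, labels, bootstrap_n = 0)
  expect_lt(abs(cp$auc - 0.5), 0.08)
})
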