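# the published cohort counts: 13 cases (12 at or above cut-off 4),
# 19,372 controls (80 at or above)
paper_counts_cohort <- function() {
  data.frame(
    patient_id = sprintf("p%05d", 1:19385),
    risk_factor = c(rep(4L, 12), 3L, rep(4L, 80), rep(0L, 19292)),
    true_label = rep(c("FD-positive", "control"), c(13, 19372)),
    stringsAsFactors = FALSE)
}

test_that("confusion matrix and metrics reproduce the published cohort values", {
  prof <- paper_counts_cohort()
  cm <- confusion_at_cutoff(prof, 4L)
  expect_equal(cm$TP, 12L)
  expect_equal(cm$FN, 1L)
  expect_equal(cm$FP, 80L)
  expect_equal(cm$TN, 19292L)
  m <- screen_metrics(cm)
  expect_equal(round(m$accuracy, 3), 0.996)
  expect_equal(round(100 * m$recall, 1), 92.3)
  expect_equal(round(100 * m$specificity, 2), 99.59)
  expect_equal(round(m$precision, 4), 0.1304)
  expect_equal(round(m$f1, 4), 0.2286)
})

test_that("metrics handle degenerate confusion matrices", {
  m1 <- screen_metrics(list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  expect_equal(unlist(m1), c(accuracy = 1, precision = 1, recall = 1,
                             specificity = 1, f1 = 1))
  m0 <- screen_metrics(list(TP = 0L, TN = 5L, FP = 3L, FN = 0L))
  expect_equal(m0$precision, 0)
  expect_true(is.na(m0$f1) || m0$f1 == 0)
  expect_true(is.na(screen_metrics(list(TP = 0L, TN = 5L, FP = 0L, FN = 0L))$precision))
})

test_that("cut-off 0 predicts everyone positive", {
  prof <- random_cohort(5, 50)
  cm <- confusion_at_cutoff(prof, 0L)
  expect_equal(cm$FN, 0L)
  expect_equal(cm$TN, 0L)
  expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, nrow(prof))
  expect_error(confusion_at_cutoff(data.frame(risk_factor = 1), 0L), "label")
})

test_that("metrics agree with a per-patient recount on random cohorts", {
  set.seed(99)
  for (rep in 1:25) {
    prof <- random_cohort(sample(2:10, 1), sample(20:80, 1))
    co <- sample(0:10, 1)
    cm <- confusion_at_cutoff(prof, co)
    oracle <- recount_oracle(prof, co)
    expect_equal(cm$TP, oracle$TP)
    expect_equal(cm$FP, oracle$FP)
    expect_equal(cm$TN, oracle$TN)
    expect_equal(cm$FN, oracle$FN)
    expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, nrow(prof))
  }
})

test_that("the cut-off sweep is monotone and consistent with single cut-offs", {
  set.seed(123)
  for (rep in 1:15) {
    prof <- random_cohort(sample(2:8, 1), sample(30:100, 1))
    sw <- sweep_cutoffs(prof, 0:12)
    expect_true(all(diff(sw$sensitivity) <= 1e-12))
    expect_true(all(diff(sw$specificity) >= -1e-12))
  }
  prof <- random_cohort(5, 40)
  one <- sweep_cutoffs(prof, 4L)
  cm <- confusion_at_cutoff(prof, 4L)
  m <- screen_metrics(cm)
  expect_equal(nrow(one), 1)
  expect_equal(one$TP, cm$TP)
  expect_equal(one$sensitivity, m$recall)
  expect_equal(one$specificity, m$specificity)
  expect_error(sweep_cutoffs(prof, integer(0)), "empty")
})

test_that("ROC area equals the rank statistic and behaves at the extremes", {
  sep <- data.frame(risk_factor = c(10, 11, 12, 0, 1, 2),
                    true_label = rep(c("FD-positive", "control"), each = 3))
  expect_equal(roc_pr_curves(sep)$auc_roc, 1.0)

  set.seed(5)
  for (rep in 1:20) {
    prof <- random_cohort(sample(3:10, 1), sample(20:60, 1))
    auc <- roc_pr_curves(prof)$auc_roc
    oracle <- rank_auc_oracle(prof$risk_factor[prof$true_label == "FD-positive"],
                              prof$risk_factor[prof$true_label == "control"])
    expect_equal(auc, oracle, tolerance = 1e-12)
    # invariance under a strictly monotone transform of the scores
    prof2 <- prof
    prof2$risk_factor <- prof$risk_factor^3 + 2
    expect_equal(roc_pr_curves(prof2)$auc_roc, auc, tolerance = 1e-12)
  }

  # labels independent of scores: area near 1/2
  set.seed(31)
  big <- data.frame(risk_factor = sample(0:20, 10000, replace = TRUE),
                    true_label = sample(c("FD-positive", "control"), 10000,
                                        replace = TRUE))
  expect_equal(roc_pr_curves(big)$auc_roc, 0.5, tolerance = 0.02)

  single <- data.frame(risk_factor = 1:3, true_label = rep("control", 3))
  expect_error(roc_pr_curves(single), "both classes")
})

test_that("enrichment over the population rate matches the published ratio", {
  e <- enrichment_ratio(list(TP = 12L, FP = 80L), 40000)
  expect_equal(e$k, 7L)
  expect_equal(e$fold, 5714L)
  e2 <- enrichment_ratio(list(TP = 10L, FP = 10L), 40000)
  expect_equal(e2$k, 1L)
  expect_equal(e2$fold, 40000L)
  e3 <- enrichment_ratio(list(TP = 10L, FP = 0L), 40000)
  expect_true(e3$all_true_positive)
  expect_error(enrichment_ratio(list(TP = 0L, FP = 5L), 40000), "TP = 0")
})

test_that("group comparisons pick the right test and flag untestable traits", {
  set.seed(8)
  grp <- data.frame(age = rnorm(40, 50, 10),
                    sex = sample(c("female", "male"), 40, replace = TRUE),
                    cardio = sample(c(TRUE, FALSE), 40, replace = TRUE),
                    eye = FALSE)
  res <- compare_cohort_characteristics(grp, grp)
  expect_identical(res$test[res$attribute == "age"], "mann_whitney")
  expect_true(all(res$p_value[res$tested] > 0.99))
  expect_false(res$tested[res$attribute == "eye"])

  # a trait present in zero cases is reported untested
  cases <- data.frame(eye = rep(FALSE, 10))
  controls <- data.frame(eye = c(rep(TRUE, 3), rep(FALSE, 37)))
  r2 <- compare_cohort_characteristics(cases, controls)
  expect_false(r2$tested[1])

  expect_error(compare_cohort_characteristics(grp[0, ], grp), "non-empty")
})

test_that("small-table comparisons equal the exhaustive Fisher oracle", {
  cases <- data.frame(trait = c(rep(TRUE, 3), rep(FALSE, 7)))
  controls <- data.frame(trait = c(rep(TRUE, 9), rep(FALSE, 3)))
  res <- compare_cohort_characteristics(cases, controls)
  expect_identical(res$test, "fisher_exact")
  tab <- rbind(table(factor(cases$trait, levels = c(FALSE, TRUE))),
               table(factor(controls$trait, levels = c(FALSE, TRUE))))
  expect_equal(res$p_value, fisher_enum_oracle(tab), tolerance = 1e-9)
})
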