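test_that("roc_auc equals the all-pairs Mann-Whitney oracle", {
  set.seed(1)
  for (i in 1:60) {
    n <- sample(6:40, 1)
    labels <- c(1, 0, stats::rbinom(n - 2, 1, 0.4))
    scores <- if (i %% 3 == 0)
      sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
    else stats::rnorm(n)
    expect_lt(abs(roc_auc(labels, scores) - auc_oracle(labels, scores)),
              1e-12)
  }
  expect_equal(roc_auc(c(1, 1, 0, 0), c(5, 4, 3, 2)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(2, 4)), 0.5)     # all ties
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("roc_auc score-negation symmetry is exact", {
  set.seed(2)
  for (i in 1:20) {
    labels <- c(1, 0, stats::rbinom(18, 1, 0.3))
    scores <- round(stats::rnorm(20), 1)
    expect_identical(roc_auc(labels, scores) + roc_auc(labels, -scores), 1)
  }
})

test_that("confusion metrics follow the four formulas", {
  # TP=3, FP=1, TN=5, FN=1 at threshold 0.5
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.6, 0.2, 0.7, 0.1, 0.2, 0.3, 0.4, 0.45)
  cm <- confusion_metrics(labels, probs)
  expect_equal(cm$tp, 3); expect_equal(cm$fp, 1)
  expect_equal(cm$tn, 5); expect_equal(cm$fn, 1)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 5 / 6)
  expect_equal(cm$accuracy, 0.8)
  expect_equal(cm$f1, 0.75)
  # perfect classifier
  cmp <- confusion_metrics(c(1, 0), c(0.9, 0.1))
  expect_true(all(c(cmp$sensitivity, cmp$specificity, cmp$accuracy,
                    cmp$f1) == 1))
  # degenerate class: sensitivity undefined, specificity defined
  cm0 <- confusion_metrics(c(0, 0, 0), c(0.2, 0.6, 0.1))
  expect_true(is.na(cm0$sensitivity))
  expect_false(cm0$sensitivity_defined)
  expect_true(cm0$specificity_defined)
  # identity: accuracy = (sens*P + spec*N) / (P + N), over random tables
  set.seed(3)
  for (i in 1:25) {
    lab <- stats::rbinom(30, 1, 0.5)
    if (length(unique(lab)) < 2) next
    pr <- stats::runif(30)
    cmi <- confusion_metrics(lab, pr)
    P <- sum(lab); N <- sum(1 - lab)
    expect_equal(cmi$accuracy,
                 (cmi$sensitivity * P + cmi$specificity * N) / (P + N))
  }
})

test_that("DeLong self-comparison, antisymmetry and pROC agreement", {
  set.seed(4)
  labels <- stats::rbinom(80, 1, 0.3)
  labels[1:2] <- c(0, 1)
  a <- stats::rnorm(80) + labels
  b <- 0.6 * a + 0.8 * stats::rnorm(80)
  self <- delong_test(labels, a, a)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  ab <- delong_test(labels, a, b)
  ba <- delong_test(labels, b, a)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_true(ab$p > 0 && ab$p <= 1)
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                        pROC::roc(labels, b, quiet = TRUE),
                        method = "delong")
  expect_equal(ab$p, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_equal(abs(ab$z), abs(as.numeric(ref$statistic)), tolerance = 1e-8)
})

test_that("DeLong variance of the AUC difference matches a bootstrap", {
  set.seed(5)
  n <- 200
  labels <- rep(c(1, 0), c(60, 140))
  base <- stats::rnorm(n)
  a <- base + 0.9 * labels + 0.4 * stats::rnorm(n)
  b <- base + 0.5 * labels + 0.6 * stats::rnorm(n)
  dl <- delong_test(labels, a, b)
  boots <- vapply(1:2000, function(i) {
    idx <- c(sample(which(labels == 1), 60, replace = TRUE),
             sample(which(labels == 0), 140, replace = TRUE))
    roc_auc(labels[idx], a[idx]) - roc_auc(labels[idx], b[idx])
  }, numeric(1))
  expect_lt(abs(dl$var_diff - stats::var(boots)) / stats::var(boots), 0.15)
})

test_that("summarize_cv returns interpolated percentile intervals", {
  expect_equal(summarize_cv(rep(0.7, 5)),
               tibble::tibble(mean = 0.7, ci_low = 0.7, ci_high = 0.7,
                              n_estimates = 5L))
  x <- (1:100) / 100
  s <- summarize_cv(x)
  expect_equal(s$mean, mean(x))
  # type-7 interpolated percentiles of 0.01..1.00
  expect_equal(s$ci_low, 0.01 + 0.99 * 0.025)
  expect_equal(s$ci_high, 0.01 + 0.99 * 0.975)
  expect_equal(summarize_cv(sample(x))$mean, s$mean)   # permutation invariant
  expect_error(summarize_cv(0.5), "at least 2")
})

test_that("compare_models builds the comparison table and DeLong block", {
  set.seed(6)
  ids <- sprintf("P%02d", 1:30)
  labels <- stats::setNames(stats::rbinom(30, 1, 0.4), ids)
  labels[1:2] <- c(0, 1)
  mk <- function(model, fold, quality) tibble::tibble(
    model = model, repeat_index = 1L, fold_index = fold,
    patient_id = ids, label = as.numeric(labels),
    prob = stats::plogis(quality * (labels - 0.5) + stats::rnorm(30, 0, 0.8)))
  preds <- dplyr::bind_rows(mk("ITR", 1, 2), mk("ITR", 2, 2),
                            mk("Combined", 1, 4), mk("Combined", 2, 4))
  cmp <- compare_models(preds, reference = "Combined")
  expect_s3_class(cmp, "bcr_comparison")
  expect_setequal(unique(cmp$report$model), c("ITR", "Combined"))
  expect_setequal(unique(cmp$report$metric),
                  c("sensitivity", "specificity", "accuracy", "f1", "auc"))
  expect_true(all(cmp$report$ci_low <= cmp$report$mean + 1e-12))
  expect_true(all(cmp$report$mean <= cmp$report$ci_high + 1e-12))
  expect_equal(nrow(cmp$delong), 1)
  expect_true(cmp$delong$p > 0 && cmp$delong$p <= 1)
  # self-comparison through the same interface: identical scores
  preds_same <- dplyr::bind_rows(mk("A", 1, 3),
                                 dplyr::mutate(mk("A", 1, 3), model = "B"))
  preds_same$prob[preds_same$model == "B"] <-
    preds_same$prob[preds_same$model == "A"]
  cmp2 <- compare_models(preds_same, reference = "A")
  expect_equal(cmp2$delong$z, 0)
  expect_equal(cmp2$delong$p, 1)
  # mismatched patient sets are rejected
  bad <- dplyr::bind_rows(mk("A", 1, 2),
                          dplyr::filter(mk("B", 1, 2), patient_id != "P01"))
  expect_error(compare_models(bad), "identical patient sets")
  expect_s3_class(glance(cmp), "tbl_df")
  expect_s3_class(plot_roc(preds), "ggplot")
})
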