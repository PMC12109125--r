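#' Threshold-based confusion metrics
#'
#' Dichotomizes probabilities at `threshold` and computes sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/total and
#' F1 = 2TP/(2TP+FP+FN). Metrics whose denominator is empty (e.g.
#' sensitivity with no positive labels) are returned as `NA` with the
#' matching `*_defined` flag set to `FALSE`, never silently zero.
#'
#' @param labels 0/1 vector.
#' @param probs probabilities in \[0, 1\], same length.
#' @param threshold operating point (default 0.5).
#' @return One-row tibble: tp, tn, fp, fn, sensitivity, specificity,
#'   accuracy, f1, their `*_defined` flags, and the threshold.
#' @export
confusion_metrics <- function(labels, probs, threshold = 0.5) {
  stopifnot(length(labels) == length(probs),
            all(labels %in% c(0, 1)))
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  sens_def <- (tp + fn) > 0
  spec_def <- (tn + fp) > 0
  f1_def <- (2 * tp + fp + fn) > 0
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = if (sens_def) tp / (tp + fn) else NA_real_,
    specificity = if (spec_def) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(labels),
    f1 = if (f1_def) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    sensitivity_defined = sens_def, specificity_defined = spec_def,
    f1_defined = f1_def, threshold = threshold)
}

#' Youden-J optimal threshold
#'
#' Chooses the threshold maximizing sensitivity + specificity - 1 over
#' the observed scores. Intended to be fitted on training folds only.
#'
#' @param labels 0/1 vector (both classes present).
#' @param probs matching scores.
#' @return The optimal threshold (midpoint between adjacent scores).
#' @export
youden_threshold <- function(labels, probs) {
  stopifnot(length(unique(labels)) == 2)
  cuts <- sort(unique(probs))
  cand <- c(cuts[1] - 1e-9, (cuts[-1] + cuts[-length(cuts)]) / 2,
            cuts[length(cuts)] + 1e-9)
  j <- vapply(cand, function(th) {
    cm <- confusion_metrics(labels, probs, th)
    cm$sensitivity + cm$specificity - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Area under the ROC curve
#'
#' The tie-aware Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, counting ties as 1/2. Computed
#' from mid-ranks, which is exactly the all-pairs count.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`, one row per distinct
#'   score plus the two endpoints.
#' @export
roc_points <- function(labels, scores) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  purrr::map_dfr(ths, function(th) {
    pred <- scores >= th
    tibble::tibble(threshold = th,
                   fpr = sum(pred & labels == 0) / sum(labels == 0),
                   tpr = sum(pred & labels == 1) / sum(labels == 1))
  })
}

# placement values ("structural components"): for each positive, the
# fraction of negatives it beats (ties 1/2), and vice versa
placement_values <- function(labels, scores) {
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  v10 <- vapply(xs, function(x)
    mean((x > ys) + 0.5 * (x == ys)), numeric(1))
  v01 <- vapply(ys, function(y)
    mean((xs > y) + 0.5 * (xs == y)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong test for two correlated ROC curves
#'
#' Nonparametric comparison of the AUCs of two models evaluated on the
#' same patients. The AUC difference is standardized by the variance of
#' the difference estimated from placement-value covariances; the
#' two-sided p-value comes from the standard normal.
#'
#' @param labels shared 0/1 labels.
#' @param scores_a,scores_b score vectors of the two models.
#' @return List: `auc_a`, `auc_b`, `z`, `p` (two-sided), `var_diff`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  stopifnot(length(labels) == length(scores_a),
            length(labels) == length(scores_b))
  if (length(unique(labels)) < 2) stop("delong_test requires both classes")
  auc_a <- roc_auc(labels, scores_a)
  auc_b <- roc_auc(labels, scores_b)
  pa <- placement_values(labels, scores_a)
  pb <- placement_values(labels, scores_b)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- auc_a - auc_b
  if (d == 0) {
    z <- 0
  } else if (var_diff <= 0) {
    stop("DeLong variance degenerate (zero) with unequal AUCs")
  } else {
    z <- d / sqrt(var_diff)
  }
  list(auc_a = auc_a, auc_b = auc_b, z = z,
       p = 2 * stats::pnorm(-abs(z)), var_diff = var_diff)
}

#' Summarize per-fold metric estimates
#'
#' Mean plus a 95% percentile interval (2.5th and 97.5th percentiles,
#' linear interpolation) over fold-repeat estimates; a
#' normal-approximation interval is available by flag.
#'
#' @param estimates numeric vector of per-fold values (length >= 2).
#' @param ci `"percentile"` (default) or `"normal"`.
#' @return One-row tibble: `mean`, `ci_low`, `ci_high`, `n_estimates`.
#' @export
summarize_cv <- function(estimates, ci = c("percentile", "normal")) {
  ci <- match.arg(ci)
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) < 2)
    stop("summarize_cv needs at least 2 estimates")
  m <- mean(estimates)
  if (ci == "percentile") {
    q <- stats::quantile(estimates, c(0.025, 0.975), type = 7, names = FALSE)
  } else {
    se <- stats::sd(estimates) / sqrt(length(estimates))
    q <- m + c(-1, 1) * stats::qnorm(0.975) * se
  }
  tibble::tibble(mean = m, ci_low = q[1], ci_high = q[2],
                 n_estimates = length(estimates))
}

#' Per-model metric report over folds
#'
#' @param predictions tibble with columns `model`, `repeat_index`,
#'   `fold_index`, `patient_id`, `label`, `prob`.
#' @param threshold operating threshold for the confusion metrics.
#' @param ci interval type for [summarize_cv()].
#' @return A `bcr_metrics_report` tibble: one row per model x metric with
#'   mean and CI over fold-repeat estimates.
#' @export
metrics_report <- function(predictions, threshold = 0.5,
                           ci = "percentile") {
  per_fold <- predictions |>
    dplyr::group_by(.data$model, .data$repeat_index, .data$fold_index) |>
    dplyr::group_modify(function(df, key) {
      cm <- confusion_metrics(df$label, df$prob, threshold)
      auc <- if (length(unique(df$label)) == 2)
        roc_auc(df$label, df$prob) else NA_real_
      tibble::tibble(metric = c("sensitivity", "specificity", "accuracy",
                                "f1", "auc"),
                     value = c(cm$sensitivity, cm$specificity, cm$accuracy,
                               cm$f1, auc))
    }) |>
    dplyr::ungroup()
  rep <- per_fold |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::group_modify(function(df, key) {
      v <- df$value[!is.na(df$value)]
      if (length(v) < 2)   # single-fold runs: point estimate, no interval
        tibble::tibble(mean = mean(v), ci_low = NA_real_,
                       ci_high = NA_real_, n_estimates = length(v))
      else summarize_cv(v, ci)
    }) |>
    dplyr::ungroup()
  class(rep) <- c("bcr_metrics_report", class(rep))
  attr(rep, "per_fold") <- per_fold
  rep
}

delong_band <- function(p) {
  if (p >= 0.05) "ns" else if (p >= 0.01) "*" else "***"
}

#' Compare a set of models: metric table plus pairwise DeLong tests
#'
#' Produces the standard comparison layout: one metric row block per
#' model (sensitivity / specificity / accuracy / F1 / AUC with CIs over
#' fold-repeat estimates) and pairwise DeLong comparisons of pooled
#' per-patient scores. All models must be evaluated on identical
#' patients.
#'
#' @param predictions tibble with columns `model`, `repeat_index`,
#'   `fold_index`, `patient_id`, `label`, `prob`.
#' @param reference model name to which the others are DeLong-compared
#'   (default: first model); comparisons aggregate each patient's mean
#'   score over fold repeats.
#' @param threshold operating threshold.
#' @return A `bcr_comparison`: list with `report` (metrics table),
#'   `delong` (pairwise tests: model_a, model_b, auc_a, auc_b, z, p,
#'   band).
#' @export
compare_models <- function(predictions, reference = NULL, threshold = 0.5) {
  models <- unique(predictions$model)
  sets <- predictions |>
    dplyr::distinct(.data$model, .data$patient_id) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(ids = paste(sort(.data$patient_id), collapse = ","))
  if (length(unique(sets$ids)) != 1)
    stop("models were not evaluated on identical patient sets")
  if (is.null(reference)) reference <- models[1]
  report <- metrics_report(predictions, threshold)
  pooled <- predictions |>
    dplyr::group_by(.data$model, .data$patient_id) |>
    dplyr::summarise(label = .data$label[1], prob = mean(.data$prob),
                     .groups = "drop")
  ref <- pooled |> dplyr::filter(.data$model == reference) |>
    dplyr::arrange(.data$patient_id)
  delong <- purrr::map_dfr(setdiff(models, reference), function(mb) {
    other <- pooled |> dplyr::filter(.data$model == mb) |>
      dplyr::arrange(.data$patient_id)
    dl <- delong_test(ref$label, ref$prob, other$prob)
    tibble::tibble(model_a = reference, model_b = mb,
                   auc_a = dl$auc_a, auc_b = dl$auc_b, z = dl$z, p = dl$p,
                   band = delong_band(dl$p))
  })
  structure(list(report = report, delong = delong, reference = reference),
            class = "bcr_comparison")
}

#' @export
print.bcr_comparison <- function(x, ...) {
  cat("Model comparison (reference:", x$reference, ")\n\n")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$report,
                  cell = sprintf("%.3f (%.3f-%.3f)", .data$mean,
                                 .data$ci_low, .data$ci_high)),
    id_cols = "model", names_from = "metric", values_from = "cell")
  print(as.data.frame(wide), row.names = FALSE)
  if (nrow(x$delong)) {
    cat("\nDeLong tests vs", x$reference, "\n")
    print(as.data.frame(x$delong), row.names = FALSE)
  }
  invisible(x)
}

# ---- broom-style methods and plots ----------------------------------------

#' @export
tidy.bcr_metrics_report <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.bcr_comparison <- function(x, ...) tibble::as_tibble(x$report)

#' @export
glance.bcr_comparison <- function(x, ...) {
  aucs <- dplyr::filter(x$report, .data$metric == "auc")
  tibble::tibble(n_models = length(unique(x$report$model)),
                 best_model = aucs$model[which.max(aucs$mean)],
                 best_auc = max(aucs$mean),
                 reference = x$reference)
}

#' @export
tidy.bcr_prediction <- function(x, ...) {
  tibble::tibble(patient_id = x$patient_id,
                 slice_index = seq_along(x$slice_scores) - 1L,
                 slice_score = x$slice_scores,
                 patient_prob = x$patient_prob)
}

#' Generic tidier
#' @param x object to tidy.
#' @param ... unused.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic one-row summary
#' @param x object to summarize.
#' @param ... unused.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
autoplot.bcr_metrics_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$model, .data$mean,
                               ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "estimate (95% CI over folds)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @export
autoplot.bcr_comparison <- function(object, ...) {
  autoplot.bcr_metrics_report(object$report, ...)
}

#' Plot ROC curves for a prediction table
#'
#' @param predictions tibble with `model`, `patient_id`, `label`, `prob`
#'   (pooled over repeats by patient mean).
#' @return A ggplot object.
#' @export
plot_roc <- function(predictions) {
  pooled <- predictions |>
    dplyr::group_by(.data$model, .data$patient_id) |>
    dplyr::summarise(label = .data$label[1], prob = mean(.data$prob),
                     .groups = "drop")
  curves <- pooled |>
    dplyr::group_by(.data$model) |>
    dplyr::group_modify(function(df, key) roc_points(df$label, df$prob)) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param history tibble from [train_model()].
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  long <- tidyr::pivot_longer(history, c("train_loss", "val_metric"),
                              names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal()
}
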