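test_that("stratified split uses largest-remainder allocation", {
  labels <- c(rep(1, 38), rep(0, 144))
  names(labels) <- sprintf("P%03d", seq_along(labels))
  sp <- stratified_split(labels, 0.8, seed = 1)
  expect_length(sp$train, 146)
  expect_length(sp$validation, 36)
  expect_equal(sum(labels[sp$train]), 31)   # 31 positives + 115 negatives
  expect_equal(sum(labels[sp$validation]), 7)
  expect_length(intersect(sp$train, sp$validation), 0)

  lab10 <- stats::setNames(c(rep(1, 5), rep(0, 5)), letters[1:10])
  sp10 <- stratified_split(lab10, 0.8, seed = 2)
  expect_length(sp10$train, 8)
  expect_equal(sum(as.numeric(names(lab10)[lab10 == 1] %in% sp10$train)), 4)

  # boundary: a fraction leaving a class empty in validation errors
  expect_error(stratified_split(lab10, 0.999), "leaves a class empty")
  expect_error(stratified_split(rep(1, 6), 0.8), "both classes")
})

test_that("repeated stratified k-fold partitions with balanced classes", {
  set.seed(3)
  labels <- stats::rbinom(60, 1, 0.3)
  names(labels) <- sprintf("P%02d", 1:60)
  plan <- repeated_stratified_kfold(labels, k = 5, repeats = 20, seed = 4)
  expect_equal(nrow(plan), 100)
  for (r in unique(plan$repeat_index)) {
    vals <- unlist(plan$val_ids[plan$repeat_index == r])
    expect_setequal(vals, names(labels))   # partition
    expect_equal(anyDuplicated(vals), 0)
  }
  # per-fold class balance within one patient of the ideal proportion
  npos <- sum(labels)
  for (i in seq_len(nrow(plan))) {
    v <- plan$val_ids[[i]]
    ideal <- npos * length(v) / length(labels)
    expect_lte(abs(sum(labels[v]) - ideal), 1)
    expect_setequal(c(plan$train_ids[[i]], v), names(labels))
  }
  # exhaustive: k=2 on (1,1,0,0) gives one of each class per fold
  p2 <- repeated_stratified_kfold(c(a = 1, b = 1, c = 0, d = 0), 2, 1, 5)
  for (i in 1:2) {
    v <- p2$val_ids[[i]]
    expect_length(v, 2)
    expect_equal(sum(c(a = 1, b = 1, c = 0, d = 0)[v]), 1)
  }
  expect_error(repeated_stratified_kfold(c(a = 1, b = 0, c = 0), 2, 1, 1),
               "at least k")
})

test_that("cosine schedule hits its endpoints and midpoint", {
  expect_equal(cosine_lr(0, 100, 1e-4), 1e-4)
  expect_equal(cosine_lr(100, 100, 1e-4), 0)
  expect_equal(cosine_lr(50, 100, 1e-4), 5e-5)
  expect_error(cosine_lr(101, 100, 1e-4), "total_steps")
})

test_that("early stopping halts after patience non-improving epochs", {
  set.seed(6)
  pats <- c(lapply(1:6, function(i) make_patient(1, "ITR", 16L, 2L)),
            lapply(1:6, function(i) make_patient(0, "ITR", 16L, 2L)))
  m <- init_model(tiny_model_config(regions = "ITR", size = 16L,
                                    n_slices = 2L), seed = 7)
  tcfg <- train_config(lr0 = 1e-3, batch_size = 4, max_epochs = 40,
                       patience = 10, k = 2, repeats = 1, seed = 8,
                       augment = NULL)
  fit <- train_model(m, pats[c(1:4, 7:10)], pats[c(5, 6, 11, 12)], tcfg,
                     metric_fn = function(model, vp) 0.5)  # constant metric
  expect_equal(nrow(fit$history), 11)   # best at 1, then 10 bad epochs
  expect_equal(fit$best_epoch, 1)
  expect_true(all(fit$history$lr == cosine_lr(fit$history$epoch - 1, 40,
                                              1e-3)))
  expect_error(train_model(m, pats[1:4], pats[5:6], tcfg), "single class")
})

test_that("training histories are reproducible under a fixed seed", {
  set.seed(9)
  pats <- c(lapply(1:5, function(i) make_patient(1, "ITR", 16L, 2L,
                                                 signal = 2)),
            lapply(1:5, function(i) make_patient(0, "ITR", 16L, 2L)))
  tcfg <- train_config(lr0 = 2e-3, batch_size = 4, max_epochs = 3,
                       patience = 2, seed = 10,
                       augment = augment_opts(rotation_deg = 0))
  run <- function() {
    m <- init_model(tiny_model_config(regions = "ITR", size = 16L,
                                      n_slices = 2L, dropout = 0.1),
                    seed = 11)
    train_model(m, pats[c(1:4, 6:9)], pats[c(5, 10)], tcfg)$history
  }
  expect_identical(run(), run())
})

test_that("best-epoch weights are restored, never a later epoch's", {
  set.seed(12)
  pats <- c(lapply(1:6, function(i) make_patient(1, "ITR", 16L, 2L,
                                                 signal = 2)),
            lapply(1:6, function(i) make_patient(0, "ITR", 16L, 2L)))
  m <- init_model(tiny_model_config(regions = "ITR", size = 16L,
                                    n_slices = 2L), seed = 13)
  tcfg <- train_config(lr0 = 2e-3, batch_size = 4, max_epochs = 6,
                       patience = 5, seed = 14, augment = NULL)
  tr <- pats[c(1:4, 7:10)]; va <- pats[c(5, 6, 11, 12)]
  fit <- train_model(m, tr, va, tcfg)
  yv <- vapply(va, function(p) p$label, numeric(1))
  auc_now <- roc_auc(yv, bcrformer:::predict_probs(fit$model, va))
  expect_equal(auc_now, fit$history$val_metric[fit$best_epoch],
               tolerance = 1e-9)
  expect_equal(fit$history$val_metric[fit$best_epoch],
               max(fit$history$val_metric))
})
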