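#' Training configuration
#'
#' Defaults follow the standard protocol for this framework: AdamW with
#' initial learning rate 1e-4 and cosine annealing to zero, batch size 16,
#' up to 300 epochs with early stopping after 10 non-improving validation
#' epochs, and 5-fold cross-validation repeated 20 times.
#'
#' @param lr0 initial learning rate.
#' @param batch_size patients per optimization step.
#' @param max_epochs epoch cap.
#' @param patience consecutive non-improving validation epochs tolerated
#'   before stopping (ties count as non-improving).
#' @param weight_decay decoupled AdamW weight decay (applied to weight
#'   matrices and convolution kernels, not biases or normalization
#'   parameters).
#' @param k cross-validation folds.
#' @param repeats cross-validation repetitions.
#' @param train_fraction training share for a plain stratified split.
#' @param seed RNG seed for shuffling, augmentation draws and dropout.
#' @param augment an [augment_opts()] or `NULL` to disable augmentation.
#' @param pos_weight optional positive-class loss weight (default: none).
#' @return A `bcr_train_config`.
#' @export
train_config <- function(lr0 = 1e-4, batch_size = 16L, max_epochs = 300L,
                         patience = 10L, weight_decay = 0.01, k = 5L,
                         repeats = 20L, train_fraction = 0.8, seed = 1L,
                         augment = augment_opts(), pos_weight = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1, patience < max_epochs)
  structure(list(lr0 = lr0, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 weight_decay = weight_decay, k = as.integer(k),
                 repeats = as.integer(repeats),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 augment = augment, pos_weight = pos_weight),
            class = "bcr_train_config")
}

#' Stratified train/validation split with largest-remainder allocation
#'
#' The training set size is `round(train_fraction * N)`; per-class quotas
#' `train_fraction * n_class` are floored and the remaining seats go to
#' the largest fractional remainders, so e.g. a 182-patient cohort with
#' 38 positives at 0.8 yields 146 training patients (31 positive + 115
#' negative) and 36 validation patients.
#'
#' @param labels named 0/1 vector (names are patient ids; unnamed vectors
#'   get integer ids).
#' @param train_fraction training share in (0, 1).
#' @param seed RNG seed for the within-stratum assignment.
#' @param require_validation_classes error if any class would vanish from
#'   the validation set (default TRUE).
#' @return List with `train` and `validation` id vectors.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L,
                             require_validation_classes = TRUE) {
  if (is.null(names(labels))) names(labels) <- as.character(seq_along(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("both classes must be present")
  sizes <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  if (any(sizes < 2)) stop("a stratum has fewer than 2 patients")
  n <- length(labels)
  n_train <- round(train_fraction * n)
  quota <- train_fraction * sizes
  base <- floor(quota)
  rem <- quota - base
  extra <- n_train - sum(base)
  take <- base
  if (extra > 0) {
    ord <- order(rem, sizes, decreasing = TRUE)
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
  } else if (extra < 0) {
    ord <- order(rem, -sizes)
    take[ord[seq_len(-extra)]] <- take[ord[seq_len(-extra)]] - 1
  }
  if (require_validation_classes && any(sizes - take < 1))
    stop("train_fraction ", train_fraction,
         " leaves a class empty in the validation set")
  set.seed(seed)
  train <- character(0)
  for (i in seq_along(classes)) {
    ids <- names(labels)[labels == classes[i]]
    train <- c(train, sample(ids, take[i]))
  }
  list(train = sort(train),
       validation = sort(setdiff(names(labels), train)))
}

#' Repeated stratified k-fold plan
#'
#' Per repeat, each class is shuffled and dealt round-robin into k folds,
#' so per-fold class counts deviate from the ideal proportion by at most
#' one patient and the validation folds of one repeat partition the
#' cohort.
#'
#' @param labels named 0/1 vector.
#' @param k folds.
#' @param repeats repetitions (fresh shuffle each).
#' @param seed RNG seed.
#' @return Tibble with one row per (repeat, fold): columns `repeat_index`,
#'   `fold_index`, and list-columns `train_ids`, `val_ids`.
#' @export
repeated_stratified_kfold <- function(labels, k = 5L, repeats = 20L,
                                      seed = 1L) {
  if (is.null(names(labels))) names(labels) <- as.character(seq_along(labels))
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  if (any(counts < k))
    stop("each class must have at least k = ", k, " patients (smallest has ",
         min(counts), ")")
  set.seed(seed)
  rows <- list()
  all_ids <- names(labels)
  for (r in seq_len(repeats)) {
    fold_of <- stats::setNames(integer(length(labels)), all_ids)
    for (cl in classes) {
      ids <- sample(all_ids[labels == cl])
      fold_of[ids] <- rep_len(seq_len(k), length(ids))
    }
    for (f in seq_len(k)) {
      val <- all_ids[fold_of[all_ids] == f]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repeat_index = r, fold_index = f,
        train_ids = list(setdiff(all_ids, val)), val_ids = list(val))
    }
  }
  dplyr::bind_rows(rows)
}

#' Cosine annealing learning-rate schedule
#'
#' `lr = lr0 * 0.5 * (1 + cos(pi * step / total_steps))`: starts at `lr0`
#' and anneals to 0.
#'
#' @param step current step (0-based), `0 <= step <= total_steps`.
#' @param total_steps schedule length.
#' @param lr0 initial learning rate.
#' @return Learning rate.
#' @export
cosine_lr <- function(step, total_steps, lr0) {
  if (any(step < 0) || any(step > total_steps))
    stop("step must lie in [0, total_steps]")
  lr0 * 0.5 * (1 + cos(pi * step / total_steps))
}

# ---- AdamW -----------------------------------------------------------------

adamw_new <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adamw_step <- function(ps, grads, opt, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    if (any(startsWith(nm, ps$frozen))) next
    g <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- g * 0
      opt$v[[nm]] <- g * 0
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    p <- ps$params[[nm]]
    if (weight_decay > 0 && grepl("\\.(w|W)[0-9]*$", nm))
      p <- p - lr * weight_decay * p
    ps$params[[nm]] <- p - lr * upd
  }
  invisible(NULL)
}

# deep copies for best-epoch snapshots
snapshot_params <- function(ps) list(params = ps$params,
                                     state = lapply(ps$state, as.list))

restore_params <- function(ps, snap) {
  ps$params <- snap$params
  for (nm in names(snap$state)) {
    st <- new.env(parent = emptyenv())
    for (f in names(snap$state[[nm]])) assign(f, snap$state[[nm]][[f]], st)
    ps$state[[nm]] <- st
  }
  invisible(ps)
}

augment_patient <- function(patient, opts) {
  patient$slices <- lapply(patient$slices, function(stack)
    lapply(stack, augment, opts = opts))
  patient
}

# evaluation-mode probabilities for a patient list, in order
predict_probs <- function(model, patients, batch_size = 16L) {
  probs <- numeric(length(patients))
  idx <- seq_along(patients)
  for (chunk in split(idx, ceiling(idx / batch_size))) {
    fw <- model_forward_batch(model, patients[chunk], training = FALSE)
    probs[chunk] <- 1 / (1 + exp(-as.numeric(fw$logits$value)))
  }
  probs
}

#' Train a model
#'
#' AdamW updates with an epoch-granular cosine learning-rate schedule,
#' augmentation of training slices only, per-epoch validation AUC
#' monitoring, and early stopping: training halts once the validation
#' metric has not improved for `patience` consecutive epochs (a constant
#' metric therefore stops after epoch `patience + 1`). The returned model
#' carries the weights of the best-validation epoch.
#'
#' @param model a `bcr_model` or `bcr_clinical_model` (modified in place
#'   and returned).
#' @param train_patients,val_patients lists of preprocessed patients, each
#'   with a `label` element.
#' @param tcfg a [train_config()].
#' @param metric_fn validation metric: `function(model, val_patients)`
#'   returning a scalar to maximize. Default: validation AUC.
#' @param verbose print per-epoch progress.
#' @return List with `model`, `history` tibble (epoch, train_loss,
#'   val_metric, lr), `best_epoch`.
#' @export
train_model <- function(model, train_patients, val_patients,
                        tcfg = train_config(), metric_fn = NULL,
                        verbose = FALSE) {
  y_train <- vapply(train_patients, function(p) p$label, numeric(1))
  if (length(unique(y_train)) < 2)
    stop("training split contains a single class")
  if (is.null(metric_fn))
    metric_fn <- function(model, vp) {
      yv <- vapply(vp, function(p) p$label, numeric(1))
      roc_auc(yv, predict_probs(model, vp, tcfg$batch_size))
    }
  set.seed(tcfg$seed)
  opt <- adamw_new()
  n <- length(train_patients)
  best_metric <- -Inf
  best_epoch <- 0L
  best_snap <- NULL
  bad <- 0L
  hist <- vector("list", tcfg$max_epochs)
  w <- if (is.null(tcfg$pos_weight)) NULL else
    ifelse(y_train == 1, tcfg$pos_weight, 1)
  for (epoch in seq_len(tcfg$max_epochs)) {
    lr <- cosine_lr(epoch - 1, tcfg$max_epochs, tcfg$lr0)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (chunk in split(ord, ceiling(seq_along(ord) / tcfg$batch_size))) {
      pb <- train_patients[chunk]
      if (!is.null(tcfg$augment) && !inherits(model, "bcr_clinical_model"))
        pb <- lapply(pb, augment_patient, opts = tcfg$augment)
      fw <- model_forward_batch(model, pb, training = TRUE)
      yb <- vapply(pb, function(p) p$label, numeric(1))
      wb <- if (is.null(w)) NULL else w[chunk]
      loss <- op_sigmoid_bce(fw$tape, fw$logits, yb, weights = wb)
      backward_tape(fw$tape, loss)
      grads <- collect_grads(fw$tape, model$ps)
      adamw_step(model$ps, grads, opt, lr, tcfg$weight_decay)
      losses <- c(losses, loss$value)
    }
    metric <- metric_fn(model, val_patients)
    hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                    train_loss = mean(losses),
                                    val_metric = metric, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val %.4f  lr %.2e",
                      epoch, mean(losses), metric, lr))
    if (metric > best_metric + 1e-12) {
      best_metric <- metric
      best_epoch <- epoch
      best_snap <- snapshot_params(model$ps)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= tcfg$patience) break
    }
  }
  if (!is.null(best_snap)) restore_params(model$ps, best_snap)
  list(model = model, history = dplyr::bind_rows(hist),
       best_epoch = best_epoch)
}
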