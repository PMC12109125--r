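# End-to-end experiment orchestration: simulate -> regions -> preprocess ->
# repeated-CV training per model variant -> evaluation -> comparison.

log_line <- function(log_path, level, ...) {
  msg <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 level, paste0(...))
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE)
  message(msg)
  invisible(msg)
}

#' Default experiment configuration
#'
#' The desk-scale study: a synthetic cohort at the tiny-backbone
#' geometry, 3-fold cross-validation repeated twice, 15 epochs. Every
#' field can be overridden via the `config` argument of
#' [run_experiment()] or a YAML file with the same structure.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = file.path(tempdir(), "bcrformer_run"),
    variants = c("ITR", "PTR", "PPR", "Combined", "Clinical", "Integrated"),
    simulate = list(n_patients = 60L, prevalence = 0.2),
    preprocess = list(n_slices = 8L, input_size = 64L, margin_mm = 5,
                      bbox_pad_fraction = 0.1),
    model = list(backbone = "tiny", d_emb = 8L,
                 transformer = list(layers = 2L, heads = 4L, model_dim = 64L,
                                    dropout = 0.1, ffn_mult = 2L),
                 freeze_prefix = 0L),
    train = list(lr0 = 2e-3, batch_size = 16L, max_epochs = 15L,
                 patience = 10L, weight_decay = 0.01, k = 3L, repeats = 1L,
                 rotation_deg = 0, flip_prob = 0.5, brightness = 0.1,
                 contrast = 0.1),
    write_cohort = FALSE,
    strict_determinism = TRUE)
}

variant_spec <- function(variant) {
  switch(variant,
    ITR = list(regions = "ITR", clinical = FALSE),
    PTR = list(regions = "PTR", clinical = FALSE),
    PPR = list(regions = "PPR", clinical = FALSE),
    Combined = list(regions = c("ITR", "PTR", "PPR"), clinical = FALSE),
    Clinical = list(regions = character(0), clinical = TRUE),
    Integrated = list(regions = c("ITR", "PTR", "PPR"), clinical = TRUE),
    stop("unknown model variant: ", variant))
}

# derive a bounded sub-seed from run seed + context indices
sub_seed <- function(seed, ...) {
  ctx <- c(...)
  as.integer((as.numeric(seed) * 7919 + sum(ctx * 104729) +
                1) %% (.Machine$integer.max - 1)) + 1L
}

#' Preprocess an in-memory cohort into model-ready patients
#'
#' Builds the three regions and their slice stacks once per patient
#' (clinical vectors are attached per fold later, with training-fold
#' statistics only).
#'
#' @param cohort a `bcr_cohort`.
#' @param sopts a [slice_opts()].
#' @param margin_mm region margin.
#' @return Named list of patients, each with `slices`, `label`.
#' @export
preprocess_cohort <- function(cohort, sopts = slice_opts(input_size = 64L),
                              margin_mm = 5) {
  out <- lapply(names(cohort$patients), function(id) {
    p <- cohort$patients[[id]]
    pp <- preprocess_patient(p, regions = c("ITR", "PTR", "PPR"),
                             opts = sopts, margin_mm = margin_mm)
    list(slices = pp$slices, label = cohort$labels[[id]], patient_id = id)
  })
  names(out) <- names(cohort$patients)
  out
}

#' Cross-validated evaluation of model variants
#'
#' Runs repeated stratified k-fold cross-validation for each requested
#' variant (single-region, combined multi-region, clinical-only,
#' integrated). Within each fold, clinical min-max statistics come from
#' the training portion only; model weights and shuffling derive from
#' per-fold sub-seeds of the run seed.
#'
#' @param patients preprocessed patients ([preprocess_cohort()]).
#' @param clinical validated clinical tibble for the same patients.
#' @param variants subset of ITR, PTR, PPR, Combined, Clinical,
#'   Integrated.
#' @param tcfg a [train_config()] (its `k`, `repeats`, `seed` drive the
#'   fold plan).
#' @param model_opts list passed to [model_config()] /[desk_config()]
#'   style fields: `backbone`, `input_size`, `n_slices`, `d_emb`,
#'   `transformer`, `freeze_prefix`.
#' @param schema the clinical schema.
#' @param checkpoint_dir when given, the best-epoch weights of every
#'   variant/fold are saved there as `<variant>_<row>.rds`.
#' @param verbose log per-epoch progress.
#' @return List: `predictions` (tibble: model, repeat_index, fold_index,
#'   patient_id, label, prob), `histories`, `fold_plan`.
#' @export
evaluate_variants <- function(patients, clinical = NULL,
                              variants = c("ITR", "PTR", "PPR", "Combined"),
                              tcfg = train_config(), model_opts = list(),
                              schema = clinical_schema(),
                              checkpoint_dir = NULL, verbose = FALSE) {
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- vapply(patients, function(p) p$label, numeric(1))
  plan <- repeated_stratified_kfold(labels, tcfg$k, tcfg$repeats, tcfg$seed)
  need_clin <- any(vapply(variants,
                          function(v) variant_spec(v)$clinical, logical(1)))
  if (need_clin && is.null(clinical))
    stop("clinical table required for variants using covariates")
  if (need_clin) clinical <- validate_clinical(clinical, schema)
  preds <- list()
  hists <- list()
  for (variant in variants) {
    vs <- variant_spec(variant)
    for (i in seq_len(nrow(plan))) {
      tr_ids <- plan$train_ids[[i]]
      va_ids <- plan$val_ids[[i]]
      fold_patients <- patients
      if (vs$clinical) {
        cs <- clinical_stats(clinical, schema, train_ids = tr_ids)
        enc <- encode_clinical_table(clinical, cs)
        for (id in names(fold_patients))
          fold_patients[[id]]$clinical <- enc[id, ]
      }
      fseed <- sub_seed(tcfg$seed, i, match(variant, variants))
      if (length(vs$regions)) {
        margs <- utils::modifyList(
          list(backbone = "tiny", regions = vs$regions,
               use_clinical = vs$clinical,
               d_cli = if (vs$clinical) ncol(enc) else NULL,
               n_slices = dim_slices(fold_patients)),
          model_opts)
        cfg <- do.call(model_config, margs)
        model <- init_model(cfg, seed = fseed)
      } else {
        model <- init_clinical_model(ncol(enc), seed = fseed)
      }
      ftcfg <- tcfg
      ftcfg$seed <- fseed
      fit <- train_model(model, fold_patients[tr_ids],
                         fold_patients[va_ids], ftcfg, verbose = verbose)
      if (!is.null(checkpoint_dir))
        save_model(fit$model,
                   file.path(checkpoint_dir,
                             sprintf("%s_%02d.rds", variant, i)))
      probs <- predict_probs(fit$model, fold_patients[va_ids],
                             tcfg$batch_size)
      preds[[length(preds) + 1L]] <- tibble::tibble(
        model = variant, repeat_index = plan$repeat_index[i],
        fold_index = plan$fold_index[i], patient_id = va_ids,
        label = labels[va_ids], prob = probs)
      hists[[paste(variant, i, sep = "_")]] <- fit$history
    }
  }
  list(predictions = dplyr::bind_rows(preds), histories = hists,
       fold_plan = plan)
}

dim_slices <- function(patients) {
  length(patients[[1]]$slices[[1]])
}

#' Held-out AUC of a desk-scale model on one cohort
#'
#' The clean held-out protocol for separability checks: a stratified
#' 20-patient test split is set aside, a further stratified monitor split
#' inside the remaining patients drives early stopping, and the reported
#' AUC is computed on the untouched test patients. Used for the
#' null-separability study, where letting the test set drive epoch
#' selection would bias a chance-level AUC upward.
#'
#' @param patients preprocessed patients ([preprocess_cohort()]).
#' @param labels named 0/1 vector for the same patients.
#' @param run_seed seed for the splits, weight init and training.
#' @param test_n test-set size (default 20).
#' @param tcfg training configuration; default is the desk protocol
#'   (tiny backbone conditions: lr 2e-3, batch 16, 15 epochs, patience
#'   10, flips-only augmentation).
#' @return The test-set AUC.
#' @export
null_heldout_auc <- function(patients, labels, run_seed, test_n = 20L,
                             tcfg = NULL) {
  if (is.null(tcfg))
    tcfg <- train_config(lr0 = 2e-3, batch_size = 16, max_epochs = 15,
                         patience = 10, k = 3, repeats = 1,
                         seed = run_seed + 2,
                         augment = augment_opts(rotation_deg = 0))
  n <- length(labels)
  sp_test <- stratified_split(labels, train_fraction = (n - test_n) / n,
                              seed = run_seed)
  lab_dev <- labels[sp_test$train]
  sp_mon <- stratified_split(lab_dev, train_fraction = 0.8,
                             seed = run_seed + 1)
  model <- init_model(desk_config(regions = c("ITR", "PTR", "PPR"),
                                  freeze_prefix = 0L),
                      seed = run_seed + 2)
  fit <- train_model(model, patients[sp_mon$train],
                     patients[sp_mon$validation], tcfg)
  y_test <- vapply(patients[sp_test$validation], function(p) p$label,
                   numeric(1))
  roc_auc(y_test, predict_probs(fit$model, patients[sp_test$validation]))
}

#' Run a full experiment
#'
#' Executes simulate, region construction, preprocessing, repeated-CV
#' training of the configured model variants, evaluation and comparison,
#' writing all artifacts (config snapshot, fold plan, per-fold training
#' histories, predictions, metric report, DeLong table, log) under one
#' run directory.
#'
#' @param config nested list overriding [default_run_config()], or a
#'   YAML file path.
#' @param seed overrides `config$seed` when given.
#' @param out_dir overrides `config$out_dir` when given.
#' @return A `bcr_run_record`: config, seed, run id, output paths.
#' @export
run_experiment <- function(config = list(), seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  run_id <- sprintf("run-%s-seed%d", format(Sys.time(), "%Y%m%d%H%M%S"),
                    cfg$seed)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))
  stage <- "simulate"
  rec <- tryCatch({
    log_line(log_path, "INFO", "stage simulate: ",
             cfg$simulate$n_patients, " phantoms")
    pp <- do.call(phantom_params,
                  c(cfg$simulate, list(seed = sub_seed(cfg$seed, 1))))
    cohort <- generate_cohort(pp)
    if (isTRUE(cfg$write_cohort)) {
      stage <- "write-cohort"
      write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
    }
    stage <- "preprocess"
    log_line(log_path, "INFO", "stage preprocess: building regions + slices")
    sopts <- slice_opts(n_slices = cfg$preprocess$n_slices,
                        input_size = cfg$preprocess$input_size,
                        bbox_pad_fraction = cfg$preprocess$bbox_pad_fraction)
    patients <- preprocess_cohort(cohort, sopts, cfg$preprocess$margin_mm)
    stage <- "train"
    log_line(log_path, "INFO", "stage train: variants ",
             paste(cfg$variants, collapse = ", "))
    tcfg <- train_config(
      lr0 = cfg$train$lr0, batch_size = cfg$train$batch_size,
      max_epochs = cfg$train$max_epochs, patience = cfg$train$patience,
      weight_decay = cfg$train$weight_decay, k = cfg$train$k,
      repeats = cfg$train$repeats, seed = cfg$seed,
      augment = augment_opts(rotation_deg = cfg$train$rotation_deg,
                             flip_prob = cfg$train$flip_prob,
                             brightness = cfg$train$brightness,
                             contrast = cfg$train$contrast))
    mo <- cfg$model
    mo$input_size <- cfg$preprocess$input_size
    mo$n_slices <- cfg$preprocess$n_slices
    res <- evaluate_variants(patients, cohort$clinical, cfg$variants, tcfg,
                             model_opts = mo)
    stage <- "evaluate"
    log_line(log_path, "INFO", "stage evaluate")
    readr::write_csv(res$predictions,
                     file.path(cfg$out_dir, "predictions.csv"))
    plan_json <- res$fold_plan
    jsonlite::write_json(
      lapply(seq_len(nrow(plan_json)), function(i) list(
        repeat_index = plan_json$repeat_index[i],
        fold_index = plan_json$fold_index[i],
        train_ids = plan_json$train_ids[[i]],
        val_ids = plan_json$val_ids[[i]])),
      file.path(cfg$out_dir, "fold_plan.json"), auto_unbox = TRUE)
    hist_dir <- file.path(cfg$out_dir, "history")
    dir.create(hist_dir, showWarnings = FALSE)
    for (nm in names(res$histories))
      readr::write_csv(res$histories[[nm]],
                       file.path(hist_dir, paste0(nm, ".csv")))
    stage <- "compare"
    log_line(log_path, "INFO", "stage compare")
    report <- metrics_report(res$predictions)
    readr::write_csv(tibble::as_tibble(report),
                     file.path(cfg$out_dir, "report.csv"))
    cmp <- NULL
    if (length(cfg$variants) > 1) {
      ref <- if ("Combined" %in% cfg$variants) "Combined" else
        cfg$variants[1]
      cmp <- compare_models(res$predictions, reference = ref)
      readr::write_csv(cmp$delong, file.path(cfg$out_dir, "delong.csv"))
    }
    log_line(log_path, "INFO", "run complete")
    structure(list(config = cfg, seed = cfg$seed, run_id = run_id,
                   out_dir = cfg$out_dir,
                   outputs = list.files(cfg$out_dir, recursive = TRUE),
                   predictions = res$predictions, report = report,
                   comparison = cmp),
              class = "bcr_run_record")
  }, error = function(e) {
    log_line(log_path, "ERROR", "stage ", stage, " failed: ",
             conditionMessage(e))
    stop("experiment failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  rec
}

#' @export
print.bcr_run_record <- function(x, ...) {
  cat(sprintf("<bcr_run_record> %s\n  out: %s\n  %d output files\n",
              x$run_id, x$out_dir, length(x$outputs)))
  invisible(x)
}
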