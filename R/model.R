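#' Model configuration
#'
#' Describes one network variant: which backbone encodes the dual-channel
#' slices, which regions are fused, whether the clinical vector joins the
#' fusion, and the transformer feature-encoder geometry.
#'
#' @param backbone `"resnet18"` (224-pixel inputs, 7x7x512 features) or
#'   `"tiny"` (64-pixel inputs, 4x4x64 features).
#' @param input_size slice side length in pixels.
#' @param n_slices fixed per-patient slice budget.
#' @param regions subset of `c("ITR", "PTR", "PPR")`, fused in this order.
#' @param use_clinical concatenate the expanded clinical embedding.
#' @param d_cli clinical vector length (required if `use_clinical`).
#' @param d_emb clinical embedding width after the linear transform.
#' @param transformer list: `layers`, `heads`, `model_dim`, `dropout`,
#'   `ffn_mult`. Defaults: 4 layers, 8 heads, 256 dims, dropout 0.1,
#'   feed-forward expansion 4.
#' @param freeze_prefix number of leading backbone stages whose weights
#'   are frozen during fine-tuning (default 2: the stem plus the first
#'   residual stage).
#' @param pretrained flag recorded for bookkeeping; weights are loaded
#'   separately via [load_pretrained()].
#' @return A `bcr_model_config`.
#' @export
model_config <- function(backbone = c("resnet18", "tiny"),
                         input_size = NULL,
                         n_slices = 8L,
                         regions = c("ITR", "PTR", "PPR"),
                         use_clinical = FALSE,
                         d_cli = NULL,
                         d_emb = 16L,
                         transformer = list(),
                         freeze_prefix = 2L,
                         pretrained = FALSE) {
  backbone <- match.arg(backbone)
  if (is.null(input_size))
    input_size <- if (backbone == "resnet18") 224L else 64L
  tr <- utils::modifyList(
    list(layers = 4L, heads = 8L, model_dim = 256L, dropout = 0.1,
         ffn_mult = 4L), transformer)
  if (tr$model_dim %% tr$heads != 0)
    stop("transformer model_dim must be divisible by heads")
  regions <- match.arg(regions, c("ITR", "PTR", "PPR"), several.ok = TRUE)
  if (!length(regions)) stop("regions must be non-empty")
  if (use_clinical && is.null(d_cli))
    stop("d_cli is required when use_clinical = TRUE")
  spec <- backbone_spec(backbone)
  hw <- spec$out_hw(input_size)
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 n_slices = as.integer(n_slices), regions = regions,
                 use_clinical = use_clinical,
                 d_cli = if (is.null(d_cli)) 0L else as.integer(d_cli),
                 d_emb = as.integer(d_emb), transformer = tr,
                 freeze_prefix = as.integer(freeze_prefix),
                 pretrained = pretrained,
                 feat_hw = hw, feat_channels = spec$out_channels,
                 n_tokens = hw * hw,
                 c_total = length(regions) * spec$out_channels +
                   if (use_clinical) as.integer(d_emb) else 0L),
            class = "bcr_model_config")
}

#' Desk-scale configuration for CPU work
#'
#' The tiny backbone with 64-pixel inputs and a narrow transformer head
#' (2 layers, 4 heads, 64 dims, feed-forward expansion 2). This is the
#' documented entry point for tests and synthetic studies on one CPU.
#'
#' @inheritParams model_config
#' @param ... passed through to [model_config()].
#' @return A `bcr_model_config`.
#' @export
desk_config <- function(regions = c("ITR", "PTR", "PPR"),
                        use_clinical = FALSE, d_cli = NULL,
                        input_size = 64L, ...) {
  model_config(backbone = "tiny", input_size = input_size, regions = regions,
               use_clinical = use_clinical, d_cli = d_cli, d_emb = 8L,
               transformer = list(layers = 2L, heads = 4L, model_dim = 64L,
                                  dropout = 0.1, ffn_mult = 2L),
               ...)
}

#' Initialize a model
#'
#' Builds all parameter arrays: Kaiming-normal convolutions,
#' Xavier-uniform transformer and head weights (including the per-slice
#' recurrence head), a randomly initialized axial spatial embedding table
#' (one `W_I x H_I` plane per slice position), and the clinical linear
#' transform when configured. All draws come from the given seed.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for every weight draw.
#' @return A `bcr_model` (list with `cfg` and parameter store `ps`).
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "bcr_model_config"))
  set.seed(seed)
  ps <- param_store()
  build_encoder(ps, cfg$backbone)
  hw <- cfg$feat_hw
  ps_add(ps, "axial.table",
         array(stats::rnorm(cfg$n_slices * hw * hw, 0, 0.02),
               c(cfg$n_slices, hw, hw)))
  if (cfg$use_clinical) {
    ps_add(ps, "clin.W", init_xavier_uniform(cfg$d_cli, cfg$d_emb))
    ps_add(ps, "clin.b", numeric(cfg$d_emb))
  }
  d <- cfg$transformer$model_dim
  ps_add(ps, "tok.W", init_xavier_uniform(cfg$c_total, d))
  ps_add(ps, "tok.b", numeric(d))
  ps_add(ps, "pos.P",
         array(stats::rnorm(cfg$n_tokens * d, 0, 0.02), c(cfg$n_tokens, d)))
  f <- d * cfg$transformer$ffn_mult
  for (l in seq_len(cfg$transformer$layers)) {
    p <- function(...) paste0("tr", l, ".", ...)
    ps_add(ps, p("ln1.g"), rep(1, d)); ps_add(ps, p("ln1.b"), numeric(d))
    ps_add(ps, p("qkv.W"), init_xavier_uniform(d, 3 * d, c(d, 3 * d)))
    ps_add(ps, p("qkv.b"), numeric(3 * d))
    ps_add(ps, p("proj.W"), init_xavier_uniform(d, d))
    ps_add(ps, p("proj.b"), numeric(d))
    ps_add(ps, p("ln2.g"), rep(1, d)); ps_add(ps, p("ln2.b"), numeric(d))
    ps_add(ps, p("ffn1.W"), init_xavier_uniform(d, f, c(d, f)))
    ps_add(ps, p("ffn1.b"), numeric(f))
    ps_add(ps, p("ffn2.W"), init_xavier_uniform(f, d, c(f, d)))
    ps_add(ps, p("ffn2.b"), numeric(d))
  }
  ps_add(ps, "head.slice.W", init_xavier_uniform(d, 1, c(d, 1)))
  ps_add(ps, "head.slice.b", 0)
  ps_add(ps, "head.patient.W",
         init_xavier_uniform(cfg$n_slices, 1, c(cfg$n_slices, 1)))
  ps_add(ps, "head.patient.b", 0)
  stages <- backbone_spec(cfg$backbone)$stages
  if (cfg$freeze_prefix > 0)
    ps$frozen <- paste0("enc.", stages[seq_len(min(cfg$freeze_prefix,
                                                   length(stages)))], ".")
  structure(list(cfg = cfg, ps = ps), class = "bcr_model")
}

#' @export
print.bcr_model <- function(x, ...) {
  np <- sum(vapply(x$ps$params, length, numeric(1)))
  cat(sprintf(
    "<bcr_model> %s backbone, regions %s%s, transformer %dx%dh d%d, %d parameters\n",
    x$cfg$backbone, paste(x$cfg$regions, collapse = "+"),
    if (x$cfg$use_clinical) " + clinical" else "",
    x$cfg$transformer$layers, x$cfg$transformer$heads,
    x$cfg$transformer$model_dim, np))
  invisible(x)
}

# ---- spec-level array operations (tape-free, used directly and in tests) ---

#' Encode one dual-channel slice to its feature map
#'
#' Runs the shared CNN backbone in evaluation mode on one slice pair (or
#' an `(H, W, 2, N)` batch) and returns the `(W_I, H_I, C_I)` feature
#' map(s).
#'
#' @param pixels `(H, W, 2)` array or `(H, W, 2, N)` batch.
#' @param model a `bcr_model`.
#' @return `(W_I, H_I, C_I)` array, or `(W_I, H_I, C_I, N)` for a batch.
#' @export
slice_encode <- function(pixels, model) {
  d <- dim(pixels)
  single <- length(d) == 3L
  if (single) dim(pixels) <- c(d, 1L)
  if (dim(pixels)[1] != model$cfg$input_size ||
      dim(pixels)[3] != 2L)
    stop(sprintf("slice_encode expects (%d, %d, 2) input, got (%s)",
                 model$cfg$input_size, model$cfg$input_size,
                 paste(d, collapse = ", ")))
  tape <- tape_new(training = FALSE)
  x <- op_input(tape, pixels)
  f <- encoder_forward(tape, model$ps, model$cfg$backbone, x,
                       training = FALSE)
  if (single) array(f$value, dim(f$value)[1:3]) else f$value
}

#' Add the axial spatial embedding to a feature map
#'
#' The learned table holds one `W_I x H_I` plane per slice position; the
#' plane at `axial_index` is broadcast along the channel axis and added
#' element-wise.
#'
#' @param f `(W_I, H_I, C)` feature map.
#' @param axial_index 0-based slice position.
#' @param table `(n_slices, W_I, H_I)` embedding table.
#' @return Feature map of unchanged shape.
#' @export
add_axial_embedding <- function(f, axial_index, table) {
  if (axial_index < 0 || axial_index >= dim(table)[1])
    stop("axial_index out of range: ", axial_index)
  f + as.vector(table[axial_index + 1L, , ])
}

#' Expand a clinical vector to feature-map planes
#'
#' Applies the linear transform and replicates each resulting element
#' over the `W_I x H_I` plane.
#'
#' @param cv clinical vector (length `d_cli`).
#' @param w_i,h_i spatial extent of the image feature map.
#' @param W,b linear transform (`d_cli x d_emb` matrix and length-`d_emb`
#'   bias).
#' @return `(w_i, h_i, d_emb)` array of constant planes.
#' @export
expand_clinical <- function(cv, w_i, h_i, W, b = numeric(ncol(W))) {
  if (length(cv) != nrow(W))
    stop("clinical vector length ", length(cv), " does not match transform (",
         nrow(W), " rows)")
  z <- as.numeric(cv %*% W + b)
  array(rep(z, each = w_i * h_i), c(w_i, h_i, length(z)))
}

#' Fuse per-region feature maps and the clinical map
#'
#' Channel concatenation in fixed order ITR, PTR, PPR, clinical.
#'
#' @param region_maps named list of `(W_I, H_I, C_I)` maps (names from
#'   `c("ITR","PTR","PPR")`; fused in that canonical order).
#' @param clinical_map optional `(W_I, H_I, d_emb)` map appended last.
#' @return `(W_I, H_I, C_total)` fused map.
#' @export
fuse <- function(region_maps, clinical_map = NULL) {
  ord <- intersect(c("ITR", "PTR", "PPR"), names(region_maps))
  maps <- if (length(ord)) region_maps[ord] else region_maps
  if (!is.null(clinical_map)) maps <- c(maps, list(clinical = clinical_map))
  hw <- lapply(maps, function(m) dim(m)[1:2])
  if (length(unique(vapply(hw, paste, character(1), collapse = "x"))) != 1)
    stop("fuse: spatial extents differ across maps")
  d1 <- dim(maps[[1]])
  out <- array(0, c(d1[1], d1[2], sum(vapply(maps, function(m) dim(m)[3],
                                             numeric(1)))))
  off <- 0
  for (m in maps) {
    cm <- dim(m)[3]
    out[, , off + seq_len(cm)] <- m
    off <- off + cm
  }
  out
}

#' Per-slice recurrence value from a fused feature map
#'
#' Reshapes the fused map into S = W_I x H_I channel-dimension tokens
#' ("sequences of combination features"), linearly projects them to the
#' transformer width, adds learned positional embeddings, passes them
#' through the transformer encoder layers, mean-pools over tokens and
#' applies the final fully connected layer to yield the scalar slice
#' recurrence value r_i.
#'
#' @param f `(W_I, H_I, C_total)` fused feature map.
#' @param model a `bcr_model` whose `c_total` matches.
#' @return Scalar r_i.
#' @export
transformer_slice_head <- function(f, model) {
  d <- dim(f)
  if (d[3] != model$cfg$c_total)
    stop("fused map has ", d[3], " channels; model expects ",
         model$cfg$c_total)
  tape <- tape_new(training = FALSE)
  x <- op_input(tape, array(f, c(d[1], d[2], d[3], 1)))
  r <- transformer_head_forward(tape, model$ps, model$cfg, x,
                                S = d[1] * d[2], N = 1L)
  as.numeric(r$value)
}

# shared transformer trunk: fmap node (h, w, C_total, Nsl) -> scores (Nsl x 1)
transformer_head_forward <- function(tape, ps, cfg, fmap, S, N) {
  M <- op_tokens(tape, fmap)
  M <- op_linear(tape, M, pnode(tape, ps, "tok.W"), pnode(tape, ps, "tok.b"))
  M <- op_pos_add(tape, M, pnode(tape, ps, "pos.P"), S, N)
  for (l in seq_len(cfg$transformer$layers)) {
    p <- function(...) paste0("tr", l, ".", ...)
    a <- op_layernorm(tape, M, pnode(tape, ps, p("ln1.g")),
                      pnode(tape, ps, p("ln1.b")))
    a <- op_mha(tape, a, pnode(tape, ps, p("qkv.W")),
                pnode(tape, ps, p("qkv.b")), pnode(tape, ps, p("proj.W")),
                pnode(tape, ps, p("proj.b")), cfg$transformer$heads, S, N)
    M <- op_add(tape, M, a)
    ff <- op_layernorm(tape, M, pnode(tape, ps, p("ln2.g")),
                       pnode(tape, ps, p("ln2.b")))
    ff <- op_linear(tape, ff, pnode(tape, ps, p("ffn1.W")),
                    pnode(tape, ps, p("ffn1.b")))
    ff <- op_relu(tape, ff)
    ff <- op_linear(tape, ff, pnode(tape, ps, p("ffn2.W")),
                    pnode(tape, ps, p("ffn2.b")))
    M <- op_add(tape, M, ff)
    M <- op_dropout(tape, M, cfg$transformer$dropout)
  }
  pooled <- op_token_mean(tape, M, S, N)
  op_linear(tape, pooled, pnode(tape, ps, "head.slice.W"),
            pnode(tape, ps, "head.slice.b"))
}

#' Aggregate slice recurrence values into the patient probability
#'
#' Fully connected layer over the length-`n_slices` recurrence vector R
#' followed by a sigmoid. Entries flagged as padding are forced to zero
#' first.
#'
#' @param r numeric recurrence vector of length `n_slices`.
#' @param weights length-`n_slices` weight vector.
#' @param bias scalar bias.
#' @param is_padding logical vector marking padded positions.
#' @return Patient probability in (0, 1).
#' @export
aggregate_patient <- function(r, weights, bias = 0,
                              is_padding = rep(FALSE, length(r))) {
  if (length(r) != length(weights))
    stop("recurrence vector length ", length(r),
         " does not match weights (", length(weights), ")")
  r[is_padding] <- 0
  1 / (1 + exp(-(sum(r * weights) + bias)))
}

#' Binary cross-entropy loss
#'
#' `-(1/N) sum(y log p + (1-y) log(1-p))` with probabilities clamped at
#' `eps` for numerical safety.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 labels, same length.
#' @param eps clamp bound (default 1e-7).
#' @return Scalar loss.
#' @export
bce_loss <- function(probs, labels, eps = 1e-7) {
  if (length(probs) != length(labels))
    stop("probs and labels differ in length")
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# ---- batched forward pass --------------------------------------------------

# Assemble the encoder input array for a list of preprocessed patients.
# Image order: patient-major, then slice, then region
# (((p-1)*n_slices + (s-1)) * n_regions + r).
assemble_batch <- function(patients, cfg) {
  R <- length(cfg$regions)
  npat <- length(patients)
  ns <- cfg$n_slices
  sz <- cfg$input_size
  x <- array(0, c(sz, sz, 2, npat * ns * R))
  pad <- matrix(FALSE, ns, npat)
  for (p in seq_len(npat)) {
    for (s in seq_len(ns)) {
      for (r in seq_len(R)) {
        sp <- patients[[p]]$slices[[cfg$regions[r]]][[s]]
        x[, , , ((p - 1) * ns + (s - 1)) * R + r] <- sp$pixels
        if (r == 1) pad[s, p] <- isTRUE(sp$is_padding)
      }
    }
  }
  clin <- NULL
  if (cfg$use_clinical)
    clin <- t(vapply(patients, function(pp) as.numeric(pp$clinical),
                     numeric(cfg$d_cli)))
  list(x = x, pad = pad, clinical = clin, npat = npat)
}

# Full imaging-model forward on a patient batch. Returns list with
# `logits` node (npat x 1), `scores` node (n_slices x npat), and tape.
forward_imaging_batch <- function(model, batch, training = FALSE) {
  cfg <- model$cfg
  ps <- model$ps
  tape <- tape_new(training = training)
  R <- length(cfg$regions)
  ns <- cfg$n_slices
  npat <- batch$npat
  nsl <- npat * ns
  x <- op_input(tape, batch$x)
  feats <- encoder_forward(tape, ps, cfg$backbone, x, training)
  region_maps <- lapply(seq_len(R), function(r)
    op_index_images(tape, feats, seq(r, nsl * R, by = R)))
  fused <- if (R > 1) op_concat_channel(tape, region_maps) else
    region_maps[[1]]
  axial_idx <- rep(seq_len(ns), npat)
  fused <- op_axial_add(tape, fused, pnode(tape, ps, "axial.table"),
                        axial_idx)
  if (cfg$use_clinical) {
    Z <- op_linear(tape, op_input(tape, batch$clinical),
                   pnode(tape, ps, "clin.W"), pnode(tape, ps, "clin.b"))
    hw <- cfg$feat_hw
    cmap <- op_clinical_expand(tape, Z, hw, hw,
                               pat_of_slice = rep(seq_len(npat), each = ns))
    fused <- op_concat_channel(tape, list(fused, cmap))
  }
  scores <- transformer_head_forward(tape, ps, cfg, fused,
                                     S = cfg$n_tokens, N = nsl)
  smat <- op_reshape(tape, scores, c(ns, npat))
  smat <- op_mask(tape, smat, (!batch$pad) + 0)
  spat <- op_transpose(tape, smat)
  logits <- op_linear(tape, spat, pnode(tape, ps, "head.patient.W"),
                      pnode(tape, ps, "head.patient.b"))
  list(tape = tape, logits = logits, scores = smat)
}

#' Forward pass for one patient
#'
#' Composes the whole framework in evaluation mode: shared-encoder slice
#' features per region, axial embedding, clinical expansion and fusion,
#' the transformer slice head for each axial position, and patient-level
#' aggregation.
#'
#' @param model a `bcr_model`.
#' @param patient preprocessed patient ([preprocess_patient()]); must
#'   contain slices for every configured region, and a clinical vector if
#'   the model uses one.
#' @param patient_id identifier for the result.
#' @return A `bcr_prediction`: list with `slice_scores` (length
#'   `n_slices`), `patient_prob`, `patient_id`.
#' @export
forward_patient <- function(model, patient, patient_id = NA_character_) {
  cfg <- model$cfg
  missing_regions <- setdiff(cfg$regions, names(patient$slices))
  if (length(missing_regions))
    stop("patient lacks slices for configured region(s): ",
         paste(missing_regions, collapse = ", "))
  if (cfg$use_clinical && is.null(patient$clinical))
    stop("model uses clinical covariates but patient has none")
  batch <- assemble_batch(list(patient), cfg)
  fw <- forward_imaging_batch(model, batch, training = FALSE)
  structure(list(slice_scores = as.numeric(fw$scores$value),
                 patient_prob = 1 / (1 + exp(-as.numeric(fw$logits$value))),
                 patient_id = patient_id),
            class = "bcr_prediction")
}

#' @export
print.bcr_prediction <- function(x, ...) {
  cat(sprintf("<bcr_prediction> %s: p(BCR) = %.3f\n", x$patient_id,
              x$patient_prob))
  invisible(x)
}

# ---- checkpoints -----------------------------------------------------------

#' Save and load model checkpoints
#'
#' A checkpoint is a single file holding the exact configuration that
#' produced the weights, every parameter array, the batch-normalization
#' running statistics and the frozen-stage list, so a reloaded model
#' reproduces predictions bit-for-bit.
#'
#' @param model a `bcr_model` or `bcr_clinical_model`.
#' @param path checkpoint file path (`.rds`).
#' @return `save_model()`: `path`, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(class = class(model), cfg = model$cfg,
               params = model$ps$params,
               state = lapply(model$ps$state, as.list),
               frozen = model$ps$frozen),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  snap <- readRDS(path)
  ps <- param_store()
  ps$params <- snap$params
  ps$frozen <- snap$frozen
  for (nm in names(snap$state)) {
    st <- new.env(parent = emptyenv())
    for (f in names(snap$state[[nm]])) assign(f, snap$state[[nm]][[f]], st)
    ps$state[[nm]] <- st
  }
  structure(list(cfg = snap$cfg, ps = ps), class = snap$class)
}

# ---- clinical-only baseline ------------------------------------------------

#' Initialize the clinical-only baseline model
#'
#' A two-layer perceptron (`d_cli -> hidden -> 1`, sigmoid output) over
#' the encoded clinical vector.
#'
#' @param d_cli clinical vector length.
#' @param hidden hidden width (default 16).
#' @param seed weight seed.
#' @return A `bcr_clinical_model`.
#' @export
init_clinical_model <- function(d_cli, hidden = 16L, seed = 1L) {
  set.seed(seed)
  ps <- param_store()
  ps_add(ps, "mlp.W1", init_xavier_uniform(d_cli, hidden, c(d_cli, hidden)))
  ps_add(ps, "mlp.b1", numeric(hidden))
  ps_add(ps, "mlp.W2", init_xavier_uniform(hidden, 1, c(hidden, 1)))
  ps_add(ps, "mlp.b2", 0)
  structure(list(cfg = list(d_cli = d_cli, hidden = hidden,
                            use_clinical = TRUE, regions = character(0),
                            n_slices = 0L),
                 ps = ps),
            class = c("bcr_clinical_model", "bcr_model"))
}

forward_clinical_batch <- function(model, batch, training = FALSE) {
  tape <- tape_new(training = training)
  X <- op_input(tape, batch$clinical)
  h <- op_relu(tape, op_linear(tape, X, pnode(tape, model$ps, "mlp.W1"),
                               pnode(tape, model$ps, "mlp.b1")))
  logits <- op_linear(tape, h, pnode(tape, model$ps, "mlp.W2"),
                      pnode(tape, model$ps, "mlp.b2"))
  list(tape = tape, logits = logits, scores = NULL)
}

assemble_clinical_batch <- function(patients) {
  list(clinical = t(vapply(patients, function(p) as.numeric(p$clinical),
                           numeric(length(patients[[1]]$clinical)))),
       npat = length(patients))
}

model_forward_batch <- function(model, patients, training = FALSE) {
  if (inherits(model, "bcr_clinical_model")) {
    batch <- assemble_clinical_batch(patients)
    forward_clinical_batch(model, batch, training)
  } else {
    batch <- assemble_batch(patients, model$cfg)
    forward_imaging_batch(model, batch, training)
  }
}
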