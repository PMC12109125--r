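test_that("backbone output shapes follow the downsampling arithmetic", {
  m <- init_model(model_config(backbone = "resnet18"), seed = 1)
  f <- slice_encode(array(stats::rnorm(224 * 224 * 2), c(224, 224, 2)), m)
  expect_equal(dim(f), c(7L, 7L, 512L))
  mt <- init_model(tiny_model_config(size = 64L), seed = 1)
  ft <- slice_encode(array(stats::rnorm(64 * 64 * 2), c(64, 64, 2)), mt)
  expect_equal(dim(ft), c(4L, 4L, 64L))
  # deterministic in evaluation mode
  x <- array(stats::rnorm(64 * 64 * 2), c(64, 64, 2))
  expect_identical(slice_encode(x, mt), slice_encode(x, mt))
  expect_error(slice_encode(array(0, c(32, 32, 2)), mt), "expects")
})

test_that("token count and fused channel arithmetic match the config", {
  cfg <- model_config(backbone = "resnet18", use_clinical = TRUE,
                      d_cli = 6, d_emb = 16)
  expect_equal(cfg$n_tokens, 49L)          # S = W_I * H_I = 7 * 7
  expect_equal(cfg$c_total, 3L * 512L + 16L)  # = 1552
  cfg1 <- model_config(backbone = "resnet18", regions = "ITR")
  expect_equal(cfg1$c_total, 512L)
  cfgt <- tiny_model_config(regions = c("ITR", "PTR", "PPR"), size = 64L)
  expect_equal(cfgt$n_tokens, 16L)
  expect_equal(cfgt$c_total, 192L)
})

test_that("adapt_first_conv averages RGB kernels with the 2/3 response identity", {
  set.seed(4)
  w <- array(stats::rnorm(3 * 3 * 3 * 5), c(3, 3, 3, 5))
  b <- stats::rnorm(5)
  ad <- adapt_first_conv(w, b)
  expect_equal(dim(ad$weights), c(3L, 3L, 2L, 5L))
  expect_identical(ad$bias, b)
  # all three RGB kernels equal K -> both new channels equal K
  K <- array(stats::rnorm(3 * 3), c(3, 3))
  weq <- array(0, c(3, 3, 3, 1)); for (c in 1:3) weq[, , c, 1] <- K
  adeq <- adapt_first_conv(weq)
  expect_equal(adeq$weights[, , 1, 1], K)
  expect_equal(adeq$weights[, , 2, 1], K)
  # response identity: duplicated-channel response = (2/3) * response to the
  # RGB-replicated image (pre-bias)
  img <- array(stats::rnorm(12 * 12), c(12, 12))
  x3 <- array(0, c(12, 12, 3, 1)); for (c in 1:3) x3[, , c, 1] <- img
  x2 <- array(0, c(12, 12, 2, 1)); for (c in 1:2) x2[, , c, 1] <- img
  y3 <- bcrformer:::cpp_conv2d_fw(x3, dim(x3), w, dim(w), numeric(0), 1, 1)
  y2 <- bcrformer:::cpp_conv2d_fw(x2, dim(x2), ad$weights, dim(ad$weights),
                                  numeric(0), 1, 1)
  expect_lt(max(abs(y2 - (2 / 3) * y3)), 1e-5)
  expect_error(adapt_first_conv(array(0, c(3, 3, 2, 5))), "extent 3")
})

test_that("axial embedding adds the indexed plane across channels", {
  f <- array(stats::rnorm(4 * 4 * 6), c(4, 4, 6))
  tab <- array(0, c(8, 4, 4))
  expect_identical(add_axial_embedding(f, 3, tab), f)  # zero table
  tab[4, , ] <- 2.5
  out <- add_axial_embedding(f, 3, tab)
  expect_equal(out, f + 2.5)
  # distinct indices with a random table give distinct outputs
  set.seed(5)
  tabr <- array(stats::rnorm(8 * 4 * 4), c(8, 4, 4))
  expect_false(identical(add_axial_embedding(f, 0, tabr),
                         add_axial_embedding(f, 1, tabr)))
  expect_error(add_axial_embedding(f, 8, tab), "out of range")
})

test_that("clinical expansion replicates the transformed vector over space", {
  cv <- c(0.2, 0.8)
  out <- expand_clinical(cv, 4, 4, diag(2))
  expect_equal(dim(out), c(4L, 4L, 2L))
  expect_true(all(out[, , 1] == 0.2) && all(out[, , 2] == 0.8))
  set.seed(6)
  M <- matrix(stats::rnorm(2 * 5), 2, 5)
  out2 <- expand_clinical(cv, 3, 3, M)
  expect_equal(out2[2, 3, ], as.numeric(cv %*% M))
  expect_equal(out2[1, 1, ], out2[3, 2, ])  # spatially constant per channel
  expect_error(expand_clinical(c(1, 2, 3), 3, 3, M), "does not match")
})

test_that("fuse concatenates channels in canonical region order", {
  a <- array(1, c(4, 4, 3)); b <- array(2, c(4, 4, 3))
  cmap <- array(9, c(4, 4, 2))
  out <- fuse(list(PTR = b, ITR = a), clinical_map = cmap)
  expect_equal(dim(out), c(4L, 4L, 8L))
  expect_true(all(out[, , 1:3] == 1))   # ITR first despite list order
  expect_true(all(out[, , 4:6] == 2))
  expect_true(all(out[, , 7:8] == 9))
  expect_identical(fuse(list(ITR = a)), a)
  expect_error(fuse(list(ITR = a, PTR = array(0, c(5, 5, 3)))),
               "spatial extents")
})

test_that("transformer head is deterministic and permutation-equivariant", {
  m <- init_model(tiny_model_config(size = 64L), seed = 2)
  S <- m$cfg$n_tokens
  f <- array(stats::rnorm(m$cfg$feat_hw^2 * m$cfg$c_total),
             c(m$cfg$feat_hw, m$cfg$feat_hw, m$cfg$c_total))
  r1 <- transformer_slice_head(f, m)
  expect_length(r1, 1)
  expect_identical(r1, transformer_slice_head(f, m))
  # permuting tokens together with positional-embedding rows leaves r_i
  # unchanged (attention + mean pool are permutation-equivariant)
  set.seed(8)
  perm <- sample(S)
  fm <- matrix(array(f, c(S, m$cfg$c_total)), S)
  f_perm <- array(fm[perm, ], c(m$cfg$feat_hw, m$cfg$feat_hw,
                                m$cfg$c_total))
  m2 <- init_model(tiny_model_config(size = 64L), seed = 2)
  m2$ps$params[["pos.P"]] <- m2$ps$params[["pos.P"]][perm, , drop = FALSE]
  expect_equal(transformer_slice_head(f_perm, m2), r1, tolerance = 1e-9)
  # constant zero input: identical r_i across repeated calls/slices
  fz <- array(0, dim(f))
  expect_identical(transformer_slice_head(fz, m),
                   transformer_slice_head(fz, m))
})

test_that("patient aggregation and the loss follow their formulas", {
  r <- c(0.3, -1.2, 0.8, 0)
  w <- c(0.5, -0.1, 0.2, 0.9)
  expect_equal(aggregate_patient(r, w, 0.1),
               1 / (1 + exp(-(sum(r * w) + 0.1))))
  expect_equal(aggregate_patient(r, w * 0, 0), 0.5)  # sigmoid(0)
  p <- aggregate_patient(r, w, 5)
  expect_true(p > 0 && p < 1)
  # padding positions are zeroed before the FC
  expect_equal(aggregate_patient(r, w, 0, is_padding = c(F, T, T, F)),
               1 / (1 + exp(-(r[1] * w[1] + r[4] * w[4]))))
  expect_error(aggregate_patient(r, w[1:3]), "does not match")
  # loss worked values
  expect_equal(bce_loss(1, 1), 1e-7, tolerance = 1e-6)
  expect_equal(bce_loss(0.5, 0), log(2))
  ps <- c(0.2, 0.9, 0.4); ys <- c(0, 1, 1)
  expect_equal(bce_loss(ps, ys), bce_loss(1 - ps, 1 - ys))
  expect_error(bce_loss(c(0.1, 0.2), 1), "length")
})

test_that("forward_patient composes the framework end to end", {
  cfg <- tiny_model_config(regions = c("ITR", "PTR"), size = 16L,
                           n_slices = 3L, use_clinical = TRUE, d_cli = 4)
  m <- init_model(cfg, seed = 9)
  pat <- make_patient(1, c("ITR", "PTR"), 16L, 3L,
                      clinical = c(0.1, 0.5, 0.9, 0))
  pr <- forward_patient(m, pat, "P9")
  expect_s3_class(pr, "bcr_prediction")
  expect_length(pr$slice_scores, 3)
  expect_true(pr$patient_prob > 0 && pr$patient_prob < 1)
  # eval-mode double call is bit-identical
  pr2 <- forward_patient(m, pat, "P9")
  expect_identical(pr$slice_scores, pr2$slice_scores)
  expect_identical(pr$patient_prob, pr2$patient_prob)
  # clinical on/off changes the prediction on identical imaging
  cfg0 <- tiny_model_config(regions = c("ITR", "PTR"), size = 16L,
                            n_slices = 3L)
  m0 <- init_model(cfg0, seed = 9)
  pr0 <- forward_patient(m0, pat, "P9")
  expect_false(isTRUE(all.equal(pr0$patient_prob, pr$patient_prob)))
  # missing configured region is an error
  expect_error(forward_patient(m, make_patient(1, "ITR", 16L, 3L,
                                               clinical = rep(0, 4))),
               "lacks slices.*PTR")
  expect_s3_class(tidy(pr), "tbl_df")
})

test_that("checkpoints round-trip weights, config and running statistics", {
  dir <- withr::local_tempdir()
  cfg <- tiny_model_config(regions = c("ITR", "PTR"), size = 16L,
                           n_slices = 2L)
  m <- init_model(cfg, seed = 21)
  pat <- make_patient(1, c("ITR", "PTR"), 16L, 2L)
  # give batchnorm non-trivial running statistics before saving
  fw <- bcrformer:::model_forward_batch(m, list(pat), training = TRUE)
  p1 <- forward_patient(m, pat, "P1")
  f <- file.path(dir, "ckpt.rds")
  save_model(m, f)
  m2 <- load_model(f)
  p2 <- forward_patient(m2, pat, "P1")
  expect_identical(p2$patient_prob, p1$patient_prob)
  expect_identical(p2$slice_scores, p1$slice_scores)
  expect_identical(m2$cfg, m$cfg)
})

test_that("frozen backbone stages receive exactly zero gradient", {
  cfg <- tiny_model_config(regions = "ITR", size = 16L, n_slices = 2L,
                           freeze_prefix = 2L)
  m <- init_model(cfg, seed = 10)
  pats <- list(make_patient(1, "ITR", 16L, 2L),
               make_patient(0, "ITR", 16L, 2L))
  fw <- bcrformer:::model_forward_batch(m, pats, training = TRUE)
  loss <- bcrformer:::op_sigmoid_bce(fw$tape, fw$logits, c(1, 0))
  bcrformer:::backward_tape(fw$tape, loss)
  g <- bcrformer:::collect_grads(fw$tape, m$ps)
  frozen <- grep("^enc\\.(stem|b1)\\.", names(g), value = TRUE)
  thawed <- setdiff(names(g), frozen)
  expect_gt(length(frozen), 0)
  for (nm in frozen) expect_true(all(g[[nm]] == 0), label = nm)
  # every non-frozen parameter sees some gradient signal
  nonzero <- vapply(thawed, function(nm) any(g[[nm]] != 0), logical(1))
  expect_gt(mean(nonzero), 0.95)
})

test_that("20 optimization steps halve the loss on a separable toy batch", {
  set.seed(11)
  toy <- make_toy_batch(8, size = 16L)
  cfg <- tiny_model_config(regions = "ITR", size = 16L, n_slices = 2L)
  m <- init_model(cfg, seed = 12)
  opt <- bcrformer:::adamw_new()
  losses <- numeric(20)
  for (step in 1:20) {
    fw <- bcrformer:::model_forward_batch(m, toy$patients, training = TRUE)
    loss <- bcrformer:::op_sigmoid_bce(fw$tape, fw$logits, toy$labels)
    losses[step] <- loss$value
    bcrformer:::backward_tape(fw$tape, loss)
    g <- bcrformer:::collect_grads(fw$tape, m$ps)
    bcrformer:::adamw_step(m$ps, g, opt, lr = 5e-3, weight_decay = 0.01)
  }
  fw <- bcrformer:::model_forward_batch(m, toy$patients, training = FALSE)
  probs <- 1 / (1 + exp(-as.numeric(fw$logits$value)))
  expect_lt(bce_loss(probs, toy$labels), 0.5 * losses[1])
})
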