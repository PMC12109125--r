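test_that("z-score normalization is definitional and guards constants", {
  set.seed(1)
  v <- new_volume(array(rnorm(4 * 5 * 6, 50, 9), c(4, 5, 6)), c(3, 1, 1),
                  "T2WI_FS")
  z <- zscore_normalize(v)
  expect_lt(abs(mean(z$grid)), 1e-6)
  expect_lt(abs(stats::sd(z$grid) - 1), 1e-6)
  # idempotent on already-normalized input
  z2 <- zscore_normalize(z)
  expect_equal(z2$grid, z$grid, tolerance = 1e-12)
  expect_error(zscore_normalize(
    new_volume(array(3, c(2, 2, 2)), c(1, 1, 1), "DWI")), "constant")
})

test_that("extract_slices pads short spans and subsamples long ones", {
  shp <- c(20L, 30L, 30L)
  g <- array(0, shp)
  g[11:15, 10:20, 10:20] <- 1  # spans axial indices 11..15 (5 slices)
  sp <- c(3, 1, 1)
  set.seed(2)
  t2 <- zscore_normalize(new_volume(array(rnorm(prod(shp)), shp), sp,
                                    "T2WI_FS"))
  dwi <- zscore_normalize(new_volume(array(rnorm(prod(shp)), shp), sp,
                                     "DWI"))
  m <- new_mask(g, sp, "ITR")
  out <- extract_slices(t2, dwi, m, slice_opts(n_slices = 8, input_size = 32))
  expect_length(out, 8)
  expect_equal(sum(vapply(out, function(s) !s$is_padding, logical(1))), 5)
  expect_equal(vapply(out, function(s) s$axial_index, integer(1)), 0:7)
  expect_true(all(vapply(out[6:8], function(s) all(s$pixels == 0),
                         logical(1))))
  # masking contract: outside-region pixels exactly zero, channels aligned
  for (s in out[1:5]) {
    expect_true(all(s$pixels[, , 1][s$mask == 0] == 0))
    expect_identical(s$pixels[, , 1] == 0 | s$mask > 0,
                     s$pixels[, , 2] == 0 | s$mask > 0)
    expect_equal(dim(s$pixels), c(32L, 32L, 2L))
  }

  # 16-slice span subsampled to 8 evenly spaced positions
  g2 <- array(0, shp); g2[3:18, 10:20, 10:20] <- 1
  out2 <- extract_slices(t2, dwi, new_mask(g2, sp, "ITR"),
                         slice_opts(n_slices = 8, input_size = 32))
  src <- vapply(out2, function(s) s$source_slice, integer(1))
  expect_identical(src, as.integer(round(seq(3, 18, length.out = 8))))
  expect_error(extract_slices(t2, dwi, new_mask(g * 0, sp, "ITR"),
                              slice_opts()), "empty region")
})

test_that("clinical encoding scales with training statistics only", {
  sch <- clinical_schema(numeric = c("age", "psa"),
                         categorical = list(isup_grade = 1:5))
  clin <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4"),
    age = c(60, 70, 80, 95), psa = c(4, 10, 20, 45),
    isup_grade = c(1L, 3L, 5L, 3L), bcr_label = c(0L, 1L, 0L, 1L))
  stats <- clinical_stats(clin, sch, train_ids = c("P1", "P2", "P3"))
  e1 <- encode_clinical(clin[1, ], stats)
  e3 <- encode_clinical(clin[3, ], stats)
  expect_equal(unname(e1[["age"]]), 0)   # training min
  expect_equal(unname(e3[["age"]]), 1)   # training max
  expect_equal(unname(encode_clinical(clin[2, ], stats)[["isup_grade"]]),
               0.5)                      # (3-1)/(5-1)
  # held-out value above the training max clips to 1
  e4 <- encode_clinical(clin[4, ], stats)
  expect_equal(unname(e4[["age"]]), 1)
  expect_equal(unname(e4[["psa"]]), 1)
  # perturbing a held-out record never changes training encodings
  clin2 <- clin; clin2$age[4] <- 120
  stats2 <- clinical_stats(clin2, sch, train_ids = c("P1", "P2", "P3"))
  expect_identical(encode_clinical(clin2[2, ], stats2),
                   encode_clinical(clin[2, ], stats))
  # degenerate field errors with its name
  cd <- clin; cd$psa <- 7
  expect_error(encode_clinical(cd[1, ], clinical_stats(cd, sch)),
               "degenerate clinical field 'psa'")
})

test_that("augmentation honours identity, involution and the value formula", {
  set.seed(3)
  sp <- make_slice(24, value = c(0.7, -0.4))
  # identity parameters return the input exactly
  same <- augment(sp, angle = 0, flip = FALSE, gain = 1, shift = 0)
  expect_identical(same$pixels, sp$pixels)
  # horizontal flip applied twice is the identity
  f1 <- augment(sp, angle = 0, flip = TRUE, gain = 1, shift = 0)
  f2 <- augment(f1, angle = 0, flip = TRUE, gain = 1, shift = 0)
  expect_equal(f2$pixels, sp$pixels, tolerance = 1e-12)
  # background zeros stay exactly zero under flips and right angles
  r90 <- augment(sp, angle = 90, flip = FALSE, gain = 1, shift = 0)
  expect_true(all(r90$pixels[, , 1][r90$mask == 0] == 0))
  expect_equal(sum(r90$mask), sum(sp$mask))
  # gain g and shift b about the foreground mean: constant-c foreground
  g <- 1.3; b <- 0.2
  out <- augment(sp, angle = 0, flip = FALSE, gain = g, shift = b)
  c0 <- 0.7; mu <- c0  # constant foreground -> mean is c0
  expect_equal(unique(out$pixels[, , 1][out$mask > 0]),
               g * (c0 - mu) + mu + b, tolerance = 1e-12)
  # padding slices pass through untouched
  pad <- make_slice(24, is_padding = TRUE)
  expect_identical(augment(pad), pad)
  # arbitrary-angle rotation keeps both channels' zero sets aligned
  rr <- augment(sp, angle = 17, flip = FALSE, gain = 1, shift = 0)
  expect_true(all(rr$pixels[, , 1][rr$mask == 0] == 0))
  expect_true(all(rr$pixels[, , 2][rr$mask == 0] == 0))
})
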