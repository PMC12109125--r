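test_that("phantom generation is deterministic and respects geometry", {
  pp <- tiny_phantom_params(2, seed = 5)
  a <- generate_phantom(pp, 1, seed = 99, patient_id = "P1")
  b <- generate_phantom(pp, 1, seed = 99, patient_id = "P1")
  expect_identical(a$t2$grid, b$t2$grid)
  expect_identical(a$dwi$grid, b$dwi$grid)
  expect_identical(a$tumor$grid, b$tumor$grid)
  expect_identical(a$clinical, b$clinical)
  # nesting invariants: tumor inside prostate, exclusion outside it
  expect_true(all(a$prostate$grid[a$tumor$grid > 0] == 1))
  expect_equal(sum(a$exclusion$grid * a$prostate$grid), 0)
  # T2 contrast: prostate brighter than background, tumor hypointense
  pro_only <- a$prostate$grid > 0 & a$tumor$grid == 0
  expect_gt(mean(a$t2$grid[pro_only]), mean(a$t2$grid[a$prostate$grid == 0]))
  expect_lt(mean(a$t2$grid[a$tumor$grid > 0]), mean(a$t2$grid[pro_only]))
  # DWI: tumor hyperintense
  expect_gt(mean(a$dwi$grid[a$tumor$grid > 0]), mean(a$dwi$grid[pro_only]))
})

test_that("tumor DWI shift follows the generative rule (Monte Carlo)", {
  ndraw <- 50
  shift <- 5 * 15  # 5 * noise_sd
  pp1 <- tiny_phantom_params(2, seed = 1, tumor_dwi_shift = shift)
  diffs <- vapply(seq_len(ndraw), function(i) {
    p1 <- generate_phantom(pp1, 1, seed = 1000 + i)
    p0 <- generate_phantom(pp1, 0, seed = 1000 + i)
    mean(p1$dwi$grid[p1$tumor$grid > 0]) -
      mean(p0$dwi$grid[p0$tumor$grid > 0])
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(ndraw)
  expect_lt(abs(mean(diffs) - shift), 2 * se + 1e-9)
})

test_that("all-zero effect sizes make the label distributions identical", {
  pp <- tiny_phantom_params(2, seed = 2, tumor_dwi_shift = 0,
                            ptr_texture_gain = 0, ppr_gradient_gain = 0,
                            clinical_shift = 0)
  m1 <- m0 <- numeric(50)
  for (i in 1:50) {
    p1 <- generate_phantom(pp, 1, seed = 2000 + i)
    p0 <- generate_phantom(pp, 0, seed = 3000 + i)
    m1[i] <- mean(p1$dwi$grid[p1$tumor$grid > 0])
    m0[i] <- mean(p0$dwi$grid[p0$tumor$grid > 0])
  }
  expect_gt(stats::t.test(m1, m0)$p.value, 0.01)
  # and with the same sub-seed the volumes are bit-identical
  p1 <- generate_phantom(pp, 1, seed = 7)
  p0 <- generate_phantom(pp, 0, seed = 7)
  expect_identical(p1$t2$grid, p0$t2$grid)
  expect_identical(p1$dwi$grid, p0$dwi$grid)
})

test_that("cohort labels follow the prevalence and are reproducible", {
  pp <- tiny_phantom_params(10, seed = 31)
  co <- generate_cohort(pp)
  co2 <- generate_cohort(pp)
  expect_identical(co$labels, co2$labels)
  expect_identical(co$patients$P003$dwi$grid, co2$patients$P003$dwi$grid)
  # cohort-size worked example: 232 patients at prevalence 46/232; the
  # positive count must fall within binomial sampling error of 46
  pp232 <- tiny_phantom_params(232, seed = 77, prevalence = 46 / 232)
  co232 <- generate_cohort(pp232)
  expect_equal(length(co232$patients), 232)
  sd_binom <- sqrt(232 * (46 / 232) * (1 - 46 / 232))
  expect_lt(abs(sum(co232$labels) - 46), 3 * sd_binom)
  # every phantom respects the nesting invariants
  for (p in co$patients) {
    expect_true(all(p$prostate$grid[p$tumor$grid > 0] == 1))
    expect_equal(sum(p$exclusion$grid * p$prostate$grid), 0)
  }
})

test_that("degenerate prevalence yields a single-class warning", {
  pp <- tiny_phantom_params(4, seed = 3, prevalence = 1)
  expect_warning(co <- generate_cohort(pp), "single class")
  expect_true(all(co$labels == 1))
  expect_true(co$single_class)
})

test_that("infeasible tumor geometry is rejected", {
  expect_error(
    phantom_params(n_patients = 2, grid_shape = c(12L, 32L, 32L),
                   spacing = c(3, 1.2, 1.2),
                   prostate_semi_mm = list(axial = c(6, 7), row = c(8, 9),
                                           col = c(8, 9)),
                   tumor_radius_mm = c(7, 8), seed = 1),
    "infeasible")
})

test_that("write_cohort round-trips through the ingestion functions", {
  dir <- withr::local_tempdir()
  pp <- tiny_phantom_params(3, seed = 13)
  co <- suppressWarnings(generate_cohort(pp))  # tiny cohort may be one-class
  manifest <- write_cohort(co, dir)
  expect_equal(nrow(manifest), 3)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  m2 <- read_manifest(file.path(dir, "manifest.csv"))
  p2 <- load_patient(m2[2, ])
  expect_identical(p2$t2$grid, co$patients$P002$t2$grid)
  expect_identical(p2$tumor$grid, co$patients$P002$tumor$grid)
  expect_equal(p2$dwi$spacing, pp$spacing, tolerance = 1e-6)
  # clinical CSV column order matches the schema
  clin <- readr::read_csv(file.path(dir, "clinical.csv"),
                          show_col_types = FALSE)
  sch <- clinical_schema()
  expect_equal(names(clin),
               c(sch$id, sch$numeric, names(sch$categorical), sch$label))
  tab <- read_clinical_table(file.path(dir, "clinical.csv"), sch)
  expect_equal(tab$patient_id, c("P001", "P002", "P003"))
})
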