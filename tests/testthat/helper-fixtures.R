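# Shared fixtures: small phantom geometries for fast tests, brute-force
# oracles for dilation and AUC, and tiny model/patient builders.

# phantom parameters on a small grid so per-patient generation stays cheap
tiny_phantom_params <- function(n_patients, seed, ...) {
  phantom_params(
    n_patients = n_patients,
    grid_shape = c(12L, 32L, 32L),
    spacing = c(3, 1.2, 1.2),
    prostate_semi_mm = list(axial = c(8, 10), row = c(10, 13),
                            col = c(10, 13)),
    tumor_radius_mm = c(4, 5.5),
    seed = seed, ...)
}

# O(n * m) physical-distance dilation oracle: a voxel is set iff its centre
# lies within radius_mm of some foreground voxel centre
dilate_oracle <- function(grid, spacing, radius_mm) {
  idx <- which(grid > 0, arr.ind = TRUE)
  out <- array(0, dim(grid))
  if (nrow(idx) == 0) return(out)
  co <- list(
    z = (seq_len(dim(grid)[1]) - 1) * spacing[1],
    y = (seq_len(dim(grid)[2]) - 1) * spacing[2],
    x = (seq_len(dim(grid)[3]) - 1) * spacing[3])
  d2min <- array(Inf, dim(grid))
  for (r in seq_len(nrow(idx))) {
    dz <- (co$z - co$z[idx[r, 1]])^2
    dy <- (co$y - co$y[idx[r, 2]])^2
    dx <- (co$x - co$x[idx[r, 3]])^2
    d2 <- outer(outer(dz, dy, "+"), dx, "+")
    d2min <- pmin(d2min, d2)
  }
  (d2min <= radius_mm^2 + 1e-9) + 0
}

# all-pairs tie-aware Mann-Whitney AUC oracle
auc_oracle <- function(labels, scores) {
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  tot <- 0
  for (x in xs) tot <- tot + sum(x > ys) + 0.5 * sum(x == ys)
  tot / (length(xs) * length(ys))
}

# one synthetic region-masked slice pair with constant foreground values
make_slice <- function(size = 16L, axial_index = 0L, value = NULL,
                       is_padding = FALSE, region = "ITR") {
  if (is_padding)
    return(list(pixels = array(0, c(size, size, 2)),
                mask = matrix(0, size, size),
                axial_index = axial_index, source_slice = NA_integer_,
                region = region, is_padding = TRUE))
  mask <- matrix(0, size, size)
  ctr <- (size %/% 4):(3 * size %/% 4)
  mask[ctr, ctr] <- 1
  if (is.null(value)) value <- stats::rnorm(2)
  px <- array(0, c(size, size, 2))
  px[, , 1] <- mask * value[1]
  px[, , 2] <- mask * value[2]
  list(pixels = px, mask = mask, axial_index = axial_index,
       source_slice = axial_index + 1L, region = region,
       is_padding = FALSE)
}

# a minimal preprocessed patient for the tiny backbone
make_patient <- function(label, regions = "ITR", size = 16L, n_slices = 2L,
                         signal = 0, clinical = NULL) {
  slices <- lapply(regions, function(rg)
    lapply(seq_len(n_slices) - 1L, function(k)
      make_slice(size, k, value = stats::rnorm(2) + label * signal,
                 region = rg)))
  names(slices) <- regions
  list(slices = slices, clinical = clinical, label = label)
}

# small separable batch: positives bright, negatives dark
make_toy_batch <- function(n = 8, size = 16L, regions = "ITR") {
  labels <- rep(c(1, 0), length.out = n)
  pats <- lapply(labels, function(y)
    make_patient(y, regions, size, n_slices = 2L, signal = 3))
  list(patients = pats, labels = labels)
}

tiny_model_config <- function(regions = "ITR", size = 16L, n_slices = 2L,
                              use_clinical = FALSE, d_cli = NULL,
                              freeze_prefix = 0L, dropout = 0) {
  cfg <- desk_config(regions = regions, use_clinical = use_clinical,
                     d_cli = d_cli, input_size = size, n_slices = n_slices,
                     freeze_prefix = freeze_prefix)
  cfg$transformer$dropout <- dropout
  cfg
}
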