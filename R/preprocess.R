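#' Z-score normalize a volume
#'
#' Centres and scales voxel intensities so the whole volume has mean 0 and
#' standard deviation 1 (population SD is not used; the sample SD over all
#' voxels is, which is immaterial at volume size).
#'
#' @param v a `bcr_volume`.
#' @return The normalized `bcr_volume`.
#' @export
zscore_normalize <- function(v) {
  stopifnot(inherits(v, "bcr_volume"))
  s <- stats::sd(v$grid)
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a constant volume (zero intensity variance)")
  v$grid <- (v$grid - mean(v$grid)) / s
  v
}

#' Preprocessing options for slice extraction
#'
#' @param n_slices fixed per-patient slice budget; shorter spans are
#'   zero-padded, longer spans uniformly subsampled (default 8).
#' @param input_size output side length in pixels (slices are resized to
#'   `input_size x input_size` per channel; default 224, the standard
#'   input of an 18-layer residual backbone; 64 for the tiny backbone).
#' @param bbox_pad_fraction fractional padding added around the region's
#'   in-plane bounding box before cropping (default 0.1).
#' @return A `bcr_slice_opts` list.
#' @export
slice_opts <- function(n_slices = 8L, input_size = 224L,
                       bbox_pad_fraction = 0.1) {
  stopifnot(n_slices >= 1, input_size >= 8, bbox_pad_fraction >= 0)
  structure(list(n_slices = as.integer(n_slices),
                 input_size = as.integer(input_size),
                 bbox_pad_fraction = bbox_pad_fraction),
            class = "bcr_slice_opts")
}

strip_image <- function(m) {
  if (methods::is(m, "Image")) m <- EBImage::imageData(m)
  m
}

resize_bilinear <- function(m, size) {
  if (all(dim(m) == c(size, size))) return(m)
  strip_image(EBImage::resize(m, w = size, h = size))
}

#' Extract the dual-channel region-masked slice stack of one region
#'
#' Axial slices intersecting the region form a contiguous span. Each slice
#' of the span is cropped to the region's in-plane bounding box (union
#' over the span, padded by `bbox_pad_fraction`), multiplied by the
#' slice's region mask so non-region pixels are exactly zero, resized to
#' `input_size` per channel, and stacked as (H, W, 2) with channel 1 =
#' T2WI-FS, channel 2 = DWI. Spans shorter than `n_slices` are completed
#' with all-zero padding slices (`is_padding = TRUE`); longer spans are
#' uniformly subsampled down to `n_slices`.
#'
#' @param t2,dwi normalized `bcr_volume`s on a shared grid.
#' @param region_mask non-empty `bcr_mask` for one region.
#' @param opts a [slice_opts()].
#' @return List of `n_slices` slice pairs; each has `pixels` (H, W, 2),
#'   `mask` (H, W), `axial_index` (0-based position in the stack),
#'   `source_slice` (original axial index, NA for padding), `region`,
#'   `is_padding`.
#' @export
extract_slices <- function(t2, dwi, region_mask, opts = slice_opts()) {
  stopifnot(inherits(t2, "bcr_volume"), inherits(dwi, "bcr_volume"),
            inherits(region_mask, "bcr_mask"))
  stop_if_grid_mismatch(dwi, t2, "DWI volume")
  stop_if_grid_mismatch(region_mask, t2, "region mask")
  if (region_mask$empty)
    stop("cannot extract slices from an empty region mask (",
         region_mask$label, ")")
  g <- region_mask$grid
  ax <- which(apply(g > 0, 1, any))
  span <- seq(min(ax), max(ax))
  # union in-plane bounding box over the span, padded fractionally
  rows <- which(apply(g[span, , , drop = FALSE] > 0, 2, any))
  cols <- which(apply(g[span, , , drop = FALSE] > 0, 3, any))
  pad_r <- ceiling(opts$bbox_pad_fraction * length(rows))
  pad_c <- ceiling(opts$bbox_pad_fraction * length(cols))
  r0 <- max(1, min(rows) - pad_r); r1 <- min(dim(g)[2], max(rows) + pad_r)
  c0 <- max(1, min(cols) - pad_c); c1 <- min(dim(g)[3], max(cols) + pad_c)

  if (length(span) > opts$n_slices) {
    sel <- round(seq(span[1], span[length(span)],
                     length.out = opts$n_slices))
  } else {
    sel <- span
  }
  n_real <- length(sel)
  sz <- opts$input_size
  out <- vector("list", opts$n_slices)
  for (k in seq_len(opts$n_slices)) {
    if (k <= n_real) {
      s <- sel[k]
      msl <- resize_bilinear(g[s, r0:r1, c0:c1], sz)
      msl <- (msl >= 0.5) + 0
      ch1 <- resize_bilinear(t2$grid[s, r0:r1, c0:c1], sz) * msl
      ch2 <- resize_bilinear(dwi$grid[s, r0:r1, c0:c1], sz) * msl
      px <- array(c(ch1, ch2), c(sz, sz, 2))
      out[[k]] <- list(pixels = px, mask = msl, axial_index = k - 1L,
                       source_slice = as.integer(s),
                       region = region_mask$label, is_padding = FALSE)
    } else {
      out[[k]] <- list(pixels = array(0, c(sz, sz, 2)),
                       mask = matrix(0, sz, sz), axial_index = k - 1L,
                       source_slice = NA_integer_,
                       region = region_mask$label, is_padding = TRUE)
    }
  }
  out
}

#' Augmentation options
#'
#' @param rotation_deg maximum absolute random rotation (degrees); right
#'   angles and 0 keep background zeros exact, other angles interpolate
#'   with zero background.
#' @param flip_prob probability of a horizontal flip.
#' @param brightness additive-shift range (drawn uniformly from
#'   `[-brightness, brightness]`), in normalized intensity units.
#' @param contrast multiplicative-gain range: gain drawn from
#'   `[1 - contrast, 1 + contrast]`, applied about the slice's foreground
#'   mean.
#' @return A `bcr_augment_opts` list.
#' @export
augment_opts <- function(rotation_deg = 10, flip_prob = 0.5,
                         brightness = 0.1, contrast = 0.1) {
  structure(list(rotation_deg = rotation_deg, flip_prob = flip_prob,
                 brightness = brightness, contrast = contrast),
            class = "bcr_augment_opts")
}

apply_geometric <- function(m, angle, flip, bilinear = TRUE) {
  if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (angle != 0) {
    if (abs(angle %% 90) < 1e-9) {
      turns <- (round(angle / 90)) %% 4
      for (i in seq_len(turns)) m <- t(m[rev(seq_len(nrow(m))), ])
    } else {
      m <- strip_image(EBImage::rotate(m, angle, bg.col = 0,
                                       output.dim = dim(m)))
    }
  }
  m
}

#' Augment one slice pair
#'
#' Applies one identical geometric transform (flip and/or rotation) to
#' both channels and the mask, then a brightness shift and a contrast
#' gain about the foreground mean of each channel. Padding slices pass
#' through untouched. With `angle = 0`, `flip = FALSE`, `gain = 1`,
#' `shift = 0` the slice is returned unchanged.
#'
#' @param sp a slice pair from [extract_slices()].
#' @param opts an [augment_opts()].
#' @param angle,flip,gain,shift optional fixed transform parameters; when
#'   `NULL` they are drawn from `opts` using the current RNG state.
#' @return The augmented slice pair.
#' @export
augment <- function(sp, opts = augment_opts(), angle = NULL, flip = NULL,
                    gain = NULL, shift = NULL) {
  if (isTRUE(sp$is_padding)) return(sp)
  if (is.null(flip)) flip <- stats::runif(1) < opts$flip_prob
  if (is.null(angle))
    angle <- stats::runif(1, -opts$rotation_deg, opts$rotation_deg)
  if (is.null(gain))
    gain <- stats::runif(1, 1 - opts$contrast, 1 + opts$contrast)
  if (is.null(shift))
    shift <- stats::runif(1, -opts$brightness, opts$brightness)
  mask <- apply_geometric(sp$mask, angle, flip)
  mask <- (mask >= 0.5) + 0
  px <- sp$pixels
  for (ch in 1:2) {
    m <- apply_geometric(px[, , ch], angle, flip)
    m <- m * mask
    fg <- mask > 0
    if (any(fg) && (gain != 1 || shift != 0)) {
      mu <- mean(m[fg])
      m[fg] <- gain * (m[fg] - mu) + mu + shift
    }
    px[, , ch] <- m
  }
  sp$pixels <- px
  sp$mask <- mask
  sp
}

#' Preprocess a whole patient into model-ready tensors
#'
#' Convenience wrapper: z-scores both volumes, builds the configured
#' regions' slice stacks and returns them with the patient's encoded
#' clinical vector.
#'
#' @param patient list with `t2`, `dwi`, `tumor`, `prostate`, optional
#'   `exclusion` (as from [generate_phantom()] or [load_patient()]).
#' @param regions character subset of `c("ITR", "PTR", "PPR")`.
#' @param opts a [slice_opts()].
#' @param margin_mm region margin in mm.
#' @param clinical_vec optional encoded clinical vector to attach.
#' @return List with `slices` (named per region), `clinical`, `n_slices`.
#' @export
preprocess_patient <- function(patient, regions = c("ITR", "PTR", "PPR"),
                               opts = slice_opts(), margin_mm = 5,
                               clinical_vec = NULL) {
  t2 <- zscore_normalize(patient$t2)
  dwi <- zscore_normalize(patient$dwi)
  rs <- build_regions(patient$tumor, patient$prostate, patient$exclusion,
                      margin_mm)
  region_masks <- list(ITR = rs$itr, PTR = rs$ptr, PPR = rs$ppr)
  slices <- lapply(region_masks[regions], function(m)
    extract_slices(t2, dwi, m, opts))
  list(slices = slices, clinical = clinical_vec, n_slices = opts$n_slices,
       regions = regions)
}
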