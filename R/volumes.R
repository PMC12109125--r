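#' Imaging containers
#'
#' A `bcr_volume` holds one 3D MRI sequence as a voxel grid in a fixed
#' canonical frame: axis 1 is axial (slice), axes 2-3 are in-plane row and
#' column. `spacing` is millimetres per axis in the same order. A
#' `bcr_mask` is a binary segmentation on the same grid.
#'
#' @param grid rank-3 numeric array, axes (axial, row, column).
#' @param spacing numeric length-3, mm per axis, strictly positive.
#' @param sequence one of `"T2WI_FS"`, `"DWI"`.
#' @param patient_id character scalar.
#' @return A `bcr_volume` object.
#' @export
new_volume <- function(grid, spacing, sequence = c("T2WI_FS", "DWI"),
                       patient_id = NA_character_) {
  sequence <- match.arg(sequence)
  if (length(dim(grid)) != 3L)
    stop("volume grid must be rank-3 (axial, row, column), got rank ",
         length(dim(grid)))
  if (!all(is.finite(grid)))
    stop("volume grid contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  structure(
    list(grid = grid, spacing = spacing, sequence = sequence,
         patient_id = patient_id),
    class = "bcr_volume")
}

#' @param label one of `"TUMOR"`, `"PROSTATE"`, `"ORGAN_EXCLUSION"`,
#'   `"ITR"`, `"PTR"`, `"PPR"`.
#' @rdname new_volume
#' @export
new_mask <- function(grid, spacing,
                     label = c("TUMOR", "PROSTATE", "ORGAN_EXCLUSION",
                               "ITR", "PTR", "PPR"),
                     patient_id = NA_character_) {
  label <- match.arg(label)
  if (length(dim(grid)) != 3L)
    stop("mask grid must be rank-3, got rank ", length(dim(grid)))
  grid <- (grid > 0) + 0
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  structure(
    list(grid = grid, spacing = spacing, label = label,
         patient_id = patient_id, empty = !any(grid > 0)),
    class = "bcr_mask")
}

#' @export
print.bcr_volume <- function(x, ...) {
  cat(sprintf("<bcr_volume %s> %s grid %s, spacing %s mm\n",
              x$sequence, x$patient_id,
              paste(dim(x$grid), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.bcr_mask <- function(x, ...) {
  cat(sprintf("<bcr_mask %s> grid %s, %d voxels%s\n", x$label,
              paste(dim(x$grid), collapse = "x"), sum(x$grid),
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

stop_if_grid_mismatch <- function(a, b, what = "mask") {
  if (!identical(dim(a$grid), dim(b$grid)))
    stop(sprintf("grid mismatch: %s shape (%s) vs reference shape (%s)",
                 what, paste(dim(a$grid), collapse = ","),
                 paste(dim(b$grid), collapse = ",")))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop(sprintf("grid mismatch: %s spacing (%s) vs reference spacing (%s)",
                 what, paste(signif(a$spacing, 6), collapse = ","),
                 paste(signif(b$spacing, 6), collapse = ",")))
  invisible(TRUE)
}

# Reorient an RNifti image to RAS when its xform permits, then permute so
# the superior-inferior axis leads: canonical grid axes (axial, row, column)
# with spacing reordered to match.
canonicalize_nifti <- function(img) {
  # files we write ourselves carry no xform; reorientation is a no-op there
  suppressWarnings(try(RNifti::orientation(img) <- "RAS", silent = TRUE))
  arr <- as.array(img)
  pixdim <- RNifti::pixdim(img)
  if (length(pixdim) < 3) pixdim <- c(pixdim, rep(1, 3 - length(pixdim)))
  list(grid = aperm(arr, c(3L, 2L, 1L)),
       spacing = abs(pixdim[c(3L, 2L, 1L)]))
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file, reorients it to the package's canonical frame
#' (axial axis first) and extracts voxel spacing in mm from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param sequence sequence tag, `"T2WI_FS"` or `"DWI"`.
#' @param patient_id optional patient identifier to attach.
#' @return A [new_volume()] object.
#' @export
read_volume <- function(path, sequence = c("T2WI_FS", "DWI"),
                        patient_id = NA_character_) {
  sequence <- match.arg(sequence)
  if (!file.exists(path))
    stop("cannot read volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("cannot read volume: non-3D image (rank ",
         length(d), ") at ", path)
  can <- canonicalize_nifti(img)
  if (any(!is.finite(can$spacing)) || any(can$spacing <= 0))
    stop("cannot read volume: degenerate header spacing at ", path)
  new_volume(can$grid, can$spacing, sequence, patient_id)
}

#' Write a volume or mask as NIfTI
#'
#' Inverse of [read_volume()]: the canonical (axial, row, column) grid is
#' permuted back to NIfTI (x, y, z) order and spacing stored in the header.
#' Volumes are written as float64 so a write/read round trip is
#' bit-identical.
#'
#' @param x a `bcr_volume` or `bcr_mask`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- aperm(x$grid, c(3L, 2L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing[c(3L, 2L, 1L)]
  dtype <- if (inherits(x, "bcr_mask")) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Read a segmentation mask on a reference grid
#'
#' Values are binarized (`> 0` becomes 1). The file must live on the same
#' grid (shape and spacing) as the reference volume; mismatches are an
#' error, never silently resampled.
#'
#' @param path NIfTI file path.
#' @param label mask label (see [new_mask()]).
#' @param reference a `bcr_volume` defining the expected grid.
#' @return A [new_mask()] object; `$empty` flags an all-zero mask.
#' @export
read_mask <- function(path, label, reference) {
  if (!file.exists(path))
    stop("cannot read mask: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("cannot read mask: non-3D image at ", path)
  can <- canonicalize_nifti(img)
  m <- new_mask(can$grid, can$spacing, label,
                patient_id = reference$patient_id)
  stop_if_grid_mismatch(m, reference, what = paste0(label, " mask"))
  m
}
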