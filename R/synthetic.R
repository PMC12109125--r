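#' Parameters of the synthetic dual-sequence prostate phantom
#'
#' The generator emulates the structure the pipeline consumes: a prostate
#' ellipsoid with an interior tumor ball on a shared anisotropic grid, a
#' T2WI-FS channel (prostate brighter than background, tumor hypointense),
#' a DWI channel (tumor hyperintense), label-dependent effects planted per
#' region, an adjacent-organ exclusion body, and label-correlated clinical
#' covariates. Each effect size is an independent knob so single-region
#' versus combined ablations have a known ground truth.
#'
#' @param n_patients cohort size.
#' @param prevalence positive-label (recurrence) fraction, in (0, 1);
#'   default 0.2, matching a roughly one-in-five recurrence rate.
#' @param grid_shape voxel grid (axial, row, column).
#' @param spacing mm per axis (axial, row, column); anisotropic by default.
#' @param prostate_semi_mm ranges (min, max) of the ellipsoid semi-axes in
#'   mm, per axis.
#' @param tumor_radius_mm range of the tumor ball radius in mm; must fit
#'   strictly inside the smallest prostate semi-axis.
#' @param tumor_dwi_shift DWI intensity added inside the tumor for
#'   label-1 patients (intensity units).
#' @param ptr_texture_gain multiplier on `noise_sd` for extra label-1
#'   texture noise in the 5 mm peritumoral shell (unitless).
#' @param ppr_gradient_gain peak T2 intensity of the label-1 radial
#'   gradient in the periprostatic shell (intensity units).
#' @param clinical_shift label-1 shift of numeric covariates in standard
#'   deviations, and tilt strength of categorical covariates.
#' @param noise_sd additive Gaussian noise SD, both channels (intensity
#'   units).
#' @param margin_mm width of the peri-tumoral / peri-prostatic effect
#'   shells (mm).
#' @param seed integer seed; mandatory, drives every random draw.
#' @return A `bcr_phantom_params` list.
#' @export
phantom_params <- function(n_patients = 120,
                           prevalence = 0.2,
                           grid_shape = c(24L, 96L, 96L),
                           spacing = c(3, 0.6, 0.6),
                           prostate_semi_mm = list(axial = c(12, 16),
                                                   row = c(16, 22),
                                                   col = c(16, 22)),
                           tumor_radius_mm = c(5, 8),
                           tumor_dwi_shift = 40,
                           ptr_texture_gain = 1.5,
                           ppr_gradient_gain = 25,
                           clinical_shift = 1.2,
                           noise_sd = 15,
                           margin_mm = 5,
                           seed) {
  if (missing(seed) || is.null(seed)) stop("phantom_params: seed is mandatory")
  if (prevalence <= 0 || prevalence >= 1)
    if (!(prevalence %in% c(0, 1)))  # 0/1 admitted only for degenerate tests
      stop("prevalence must be in (0, 1)")
  semi_min <- min(vapply(prostate_semi_mm, min, numeric(1)))
  if (max(tumor_radius_mm) >= semi_min)
    stop(sprintf(
      "infeasible geometry: tumor radius up to %g mm cannot fit inside the smallest prostate semi-axis (%g mm)",
      max(tumor_radius_mm), semi_min))
  structure(list(n_patients = n_patients, prevalence = prevalence,
                 grid_shape = as.integer(grid_shape), spacing = spacing,
                 prostate_semi_mm = prostate_semi_mm,
                 tumor_radius_mm = tumor_radius_mm,
                 tumor_dwi_shift = tumor_dwi_shift,
                 ptr_texture_gain = ptr_texture_gain,
                 ppr_gradient_gain = ppr_gradient_gain,
                 clinical_shift = clinical_shift,
                 noise_sd = noise_sd, margin_mm = margin_mm,
                 seed = as.integer(seed)),
            class = "bcr_phantom_params")
}

# physical voxel-centre coordinate arrays for a grid
voxel_coords <- function(shape, spacing) {
  list(z = (seq_len(shape[1]) - 1) * spacing[1],
       y = (seq_len(shape[2]) - 1) * spacing[2],
       x = (seq_len(shape[3]) - 1) * spacing[3])
}

# baseline tissue intensities (arbitrary units, identical for every patient)
.phantom_base <- list(t2_bg = 100, t2_prostate = 160, t2_tumor = 120,
                      dwi_bg = 60, dwi_prostate = 70, dwi_tumor = 140)

# categorical covariate base distributions for label-0 patients
.clinical_base <- list(
  gleason_sum = c(0.20, 0.40, 0.40),
  isup_grade = c(0.20, 0.26, 0.14, 0.19, 0.21),
  clinical_stage = c(0.86, 0.14),
  capra = c(0.49, 0.51))

#' Generate one synthetic patient phantom
#'
#' @param params a [phantom_params()].
#' @param label 0/1 recurrence label controlling all planted effects.
#' @param seed per-patient seed (defaults to `params$seed`).
#' @param patient_id identifier attached to all outputs.
#' @return List with `t2`, `dwi` (`bcr_volume`), `tumor`, `prostate`,
#'   `exclusion` (`bcr_mask`), `clinical` (one-row tibble) and `label`.
#' @export
generate_phantom <- function(params, label, seed = params$seed,
                             patient_id = "P001") {
  stopifnot(inherits(params, "bcr_phantom_params"), label %in% c(0, 1))
  set.seed(seed)
  shp <- params$grid_shape; sp <- params$spacing
  co <- voxel_coords(shp, sp)
  extent <- c(max(co$z), max(co$y), max(co$x))
  centre <- extent / 2 + stats::runif(3, -0.04, 0.04) * extent
  semi <- vapply(params$prostate_semi_mm,
                 function(r) stats::runif(1, r[1], r[2]), numeric(1))
  r_tum <- stats::runif(1, params$tumor_radius_mm[1], params$tumor_radius_mm[2])
  if (r_tum >= min(semi))
    stop("infeasible geometry: tumor cannot fit inside prostate")
  # tumor centre: uniform direction, pulled inward so the ball stays strictly
  # inside the ellipsoid (1 mm safety margin)
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  u <- stats::runif(1, 0, 0.9)
  t_centre <- centre + u * dir * (semi - r_tum - 1)

  # normalized ellipsoid field, built axis-wise to stay vectorized
  ez <- ((co$z - centre[1]) / semi[1])^2
  ey <- ((co$y - centre[2]) / semi[2])^2
  ex <- ((co$x - centre[3]) / semi[3])^2
  efield <- outer(outer(ez, ey, "+"), ex, "+")
  prostate_grid <- (efield <= 1) + 0
  tz <- (co$z - t_centre[1])^2
  ty <- (co$y - t_centre[2])^2
  tx <- (co$x - t_centre[3])^2
  tfield <- outer(outer(tz, ty, "+"), tx, "+")
  tumor_grid <- ((tfield <= r_tum^2) & (prostate_grid > 0)) + 0
  if (!any(tumor_grid > 0)) stop("infeasible geometry: empty tumor on grid")

  # adjacent organ (rectum-like body) posterior along the row axis
  o_centre <- centre + c(0, semi[2] + 9, 0)
  oz <- ((co$z - o_centre[1]) / 12)^2
  oy <- ((co$y - o_centre[2]) / 9)^2
  ox <- ((co$x - o_centre[3]) / 9)^2
  ofield <- outer(outer(oz, oy, "+"), ox, "+")
  exclusion_grid <- ((ofield <= 1) & (prostate_grid == 0)) + 0

  # effect shells from true geometry (physical distances)
  d_tum <- sqrt(cpp_edt_sq(tumor_grid, shp, sp))
  ptr_shell <- (d_tum > 0 & d_tum <= params$margin_mm) & (prostate_grid > 0)
  d_pro <- sqrt(cpp_edt_sq(prostate_grid, shp, sp))
  ppr_shell <- (d_pro > 0 & d_pro <= params$margin_mm) & (exclusion_grid == 0)

  b <- .phantom_base
  t2 <- array(b$t2_bg, shp)
  t2[prostate_grid > 0] <- b$t2_prostate
  t2[tumor_grid > 0] <- b$t2_tumor
  dwi <- array(b$dwi_bg, shp)
  dwi[prostate_grid > 0] <- b$dwi_prostate
  dwi[tumor_grid > 0] <- b$dwi_tumor + label * params$tumor_dwi_shift
  if (any(ppr_shell)) {
    grad <- label * params$ppr_gradient_gain *
      (1 - d_pro[ppr_shell] / params$margin_mm)
    t2[ppr_shell] <- t2[ppr_shell] + grad
  }
  if (any(ptr_shell)) {
    n_sh <- sum(ptr_shell)
    tex_sd <- label * params$ptr_texture_gain * params$noise_sd
    if (tex_sd > 0) {
      t2[ptr_shell] <- t2[ptr_shell] + stats::rnorm(n_sh, 0, tex_sd)
      dwi[ptr_shell] <- dwi[ptr_shell] + stats::rnorm(n_sh, 0, tex_sd)
    }
  }
  if (params$noise_sd > 0) {
    t2 <- t2 + array(stats::rnorm(prod(shp), 0, params$noise_sd), shp)
    dwi <- dwi + array(stats::rnorm(prod(shp), 0, params$noise_sd), shp)
  }

  cs <- params$clinical_shift
  age <- stats::rnorm(1, 70 + label * cs * 6, 6)
  psa <- max(0.5, stats::rnorm(1, 12 + label * cs * 6, 6))
  draw_cat <- function(p0) {
    k <- length(p0)
    tilt <- exp(label * cs * (seq_len(k) - 1) / (k - 1))
    p <- p0 * tilt; p <- p / sum(p)
    sample.int(k, 1, prob = p)
  }
  cats <- lapply(.clinical_base, draw_cat)
  sch <- clinical_schema()
  clinical <- tibble::tibble(
    patient_id = patient_id,
    age = round(age, 1), psa = round(psa, 2),
    gleason_sum = sch$categorical$gleason_sum[cats$gleason_sum],
    isup_grade = as.character(sch$categorical$isup_grade[cats$isup_grade]),
    clinical_stage = sch$categorical$clinical_stage[cats$clinical_stage],
    capra = sch$categorical$capra[cats$capra],
    bcr_label = as.integer(label))

  list(t2 = new_volume(t2, sp, "T2WI_FS", patient_id),
       dwi = new_volume(dwi, sp, "DWI", patient_id),
       tumor = new_mask(tumor_grid, sp, "TUMOR", patient_id),
       prostate = new_mask(prostate_grid, sp, "PROSTATE", patient_id),
       exclusion = new_mask(exclusion_grid, sp, "ORGAN_EXCLUSION", patient_id),
       clinical = clinical, label = as.integer(label))
}

#' Generate a synthetic cohort
#'
#' Labels are drawn Bernoulli(`prevalence`) under `params$seed`; each
#' patient's phantom is generated from an independent sub-seed so the
#' cohort is reproducible patient-by-patient.
#'
#' @param params a [phantom_params()].
#' @return A `bcr_cohort`: list of patient phantoms plus a `clinical`
#'   tibble and `labels` vector. If only one class was drawn, the cohort
#'   carries `single_class = TRUE` and a warning is raised.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "bcr_phantom_params"), params$n_patients >= 2)
  set.seed(params$seed)
  labels <- stats::rbinom(params$n_patients, 1, params$prevalence)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, params$n_patients)
  ids <- sprintf("P%03d", seq_len(params$n_patients))
  patients <- vector("list", params$n_patients)
  for (i in seq_len(params$n_patients)) {
    patients[[i]] <- generate_phantom(params, labels[i], seed = sub_seeds[i],
                                      patient_id = ids[i])
  }
  names(patients) <- ids
  clinical <- dplyr::bind_rows(lapply(patients, `[[`, "clinical"))
  single_class <- length(unique(labels)) == 1L
  if (single_class)
    warning("synthetic cohort contains a single class (all labels ",
            labels[1], ")")
  structure(list(patients = patients, clinical = clinical,
                 labels = stats::setNames(labels, ids),
                 params = params, single_class = single_class),
            class = "bcr_cohort")
}

#' @export
print.bcr_cohort <- function(x, ...) {
  cat(sprintf("<bcr_cohort> %d patients (%d positive), grid %s\n",
              length(x$patients), sum(x$labels),
              paste(x$params$grid_shape, collapse = "x")))
  invisible(x)
}

#' Write a cohort to disk and return its manifest
#'
#' Writes per-patient NIfTI volumes and masks plus `clinical.csv` and
#' `manifest.csv` under `dir`, in exactly the formats the ingestion
#' functions read back.
#'
#' @param cohort a `bcr_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest tibble (one row per patient with file paths),
#'   also persisted as `manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bcr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(cohort$patients), function(id) {
    p <- cohort$patients[[id]]
    paths <- list(
      path_t2 = file.path(dir, paste0(id, "_t2.nii.gz")),
      path_dwi = file.path(dir, paste0(id, "_dwi.nii.gz")),
      path_tumor_mask = file.path(dir, paste0(id, "_tumor.nii.gz")),
      path_prostate_mask = file.path(dir, paste0(id, "_prostate.nii.gz")),
      path_exclusion_mask = file.path(dir, paste0(id, "_exclusion.nii.gz")))
    write_volume(p$t2, paths$path_t2)
    write_volume(p$dwi, paths$path_dwi)
    write_volume(p$tumor, paths$path_tumor_mask)
    write_volume(p$prostate, paths$path_prostate_mask)
    write_volume(p$exclusion, paths$path_exclusion_mask)
    tibble::tibble(patient_id = id, !!!paths)
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Read and validate a dataset manifest
#'
#' @param path `manifest.csv` path (columns `patient_id`, `path_t2`,
#'   `path_dwi`, `path_tumor_mask`, `path_prostate_mask`, optionally
#'   `path_exclusion_mask`).
#' @return Manifest tibble; errors if referenced files are missing or ids
#'   are duplicated.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("patient_id", "path_t2", "path_dwi", "path_tumor_mask",
            "path_prostate_mask")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(m$patient_id))
    stop("duplicate patient_id in manifest: ",
         m$patient_id[duplicated(m$patient_id)][1])
  path_cols <- grep("^path_", names(m), value = TRUE)
  for (col in path_cols) {
    gone <- !file.exists(m[[col]])
    if (any(gone))
      stop(sprintf("manifest file missing for patient %s (%s): %s",
                   m$patient_id[gone][1], col, m[[col]][gone][1]))
  }
  m
}

#' Load one manifest row back into memory
#'
#' @param row one manifest row (list or one-row tibble).
#' @return The same structure [generate_phantom()] returns, minus clinical.
#' @export
load_patient <- function(row) {
  t2 <- read_volume(row$path_t2, "T2WI_FS", row$patient_id)
  dwi <- read_volume(row$path_dwi, "DWI", row$patient_id)
  stop_if_grid_mismatch(dwi, t2, "DWI volume")
  tumor <- read_mask(row$path_tumor_mask, "TUMOR", t2)
  prostate <- read_mask(row$path_prostate_mask, "PROSTATE", t2)
  exclusion <- NULL
  if (!is.null(row$path_exclusion_mask) && !is.na(row$path_exclusion_mask))
    exclusion <- read_mask(row$path_exclusion_mask, "ORGAN_EXCLUSION", t2)
  list(t2 = t2, dwi = dwi, tumor = tumor, prostate = prostate,
       exclusion = exclusion)
}
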