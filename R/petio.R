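#' @importFrom stats rnorm runif rexp rgamma rlnorm rpois pnorm
#' @importFrom utils read.csv write.csv
NULL

PET_UNITS <- c("SUV", "ACTIVITY_KBQ_PER_ML")

#' PET volume with world-space geometry
#'
#' A `pet_volume` couples a 3D non-negative scalar grid with its physical
#' geometry: per-axis voxel spacing (mm), the world position of voxel
#' `(0,0,0)` (mm), an orthonormal 3x3 direction matrix, and a unit tag.
#' Voxel indices are 0-based throughout; world coordinates are physical mm
#' in the scanner frame; reported distances are cm.
#'
#' @param data 3D numeric array of non-negative, finite voxel values.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, world coordinate (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix mapping voxel axes to world axes.
#' @param unit `"SUV"` or `"ACTIVITY_KBQ_PER_ML"`. Operations that require
#'   SUV input (segmentation, feature extraction) reject activity volumes.
#' @return An object of class `pet_volume`.
#' @seealso [mask_volume()], [read_volume()], [activity_to_suv()]
#' @export
pet_volume <- function(data, spacing, origin = c(0, 0, 0), direction = diag(3),
                       unit = c("SUV", "ACTIVITY_KBQ_PER_ML")) {
  unit <- match.arg(unit)
  check_grid(data, allow_labels = FALSE)
  geom <- check_geometry(spacing, origin, direction)
  structure(list(data = data, spacing = geom$spacing, origin = geom$origin,
                 direction = geom$direction, unit = unit),
            class = "pet_volume")
}

#' Label/mask volume sharing PET geometry
#'
#' Carrier for binary masks (prostate, body) and integer lesion label maps.
#' Geometry fields and conventions are identical to [pet_volume()]; voxel
#' values must be non-negative integers (0 = background).
#'
#' @inheritParams pet_volume
#' @param data 3D array of integer labels in `{0, 1, ...}`.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  check_grid(data, allow_labels = TRUE)
  geom <- check_geometry(spacing, origin, direction)
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = geom$spacing, origin = geom$origin,
                 direction = geom$direction),
            class = "mask_volume")
}

check_grid <- function(data, allow_labels) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("voxel values must be finite", call. = FALSE)
  if (any(data < 0))
    stop("voxel values must be non-negative", call. = FALSE)
  if (allow_labels && any(data != round(data)))
    stop("mask values must be integer labels", call. = FALSE)
  invisible(TRUE)
}

check_geometry <- function(spacing, origin, direction) {
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(3L, 3L)) || any(!is.finite(direction)))
    stop("`direction` must be a finite 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6 ||
      abs(abs(det(direction)) - 1) > 1e-6)
    stop("`direction` must be orthonormal (|det| = 1)", call. = FALSE)
  list(spacing = spacing, origin = origin, direction = direction)
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("PET volume [%s]: %s voxels, spacing %s mm\n", x$unit,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  cat(sprintf("  origin (%s) mm, value range [%.3g, %.3g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  lab <- sort(unique(as.integer(x$data)))
  cat(sprintf("Mask volume: %s voxels, labels {%s}, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(utils::head(lab, 8), collapse = ","),
              sum(x$data > 0)))
  invisible(x)
}

#' Voxel-to-world affine of a volume
#'
#' @param vol a `pet_volume` or `mask_volume`.
#' @return 4x4 affine mapping homogeneous 0-based voxel indices to world mm.
#' @export
vol_affine <- function(vol) {
  aff <- diag(4)
  aff[1:3, 1:3] <- vol$direction %*% diag(vol$spacing)
  aff[1:3, 4] <- vol$origin
  aff
}

#' Map voxel indices to world coordinates
#'
#' World position of a (possibly fractional) 0-based voxel index:
#' `world = origin + direction %*% (spacing * index)`. Fractional indices
#' are the natural representation of centroids.
#'
#' @param vol a `pet_volume` or `mask_volume`.
#' @param index numeric length-3 index or an n x 3 matrix of indices (0-based).
#' @param integer_mode if `TRUE`, indices must be whole numbers within the
#'   grid bounds; out-of-bounds indices are an error.
#' @return world coordinates in mm: length-3 vector or n x 3 matrix.
#' @export
voxel_to_world <- function(vol, index, integer_mode = FALSE) {
  idx <- if (is.matrix(index)) index else matrix(as.numeric(index), ncol = 3)
  if (ncol(idx) != 3L) stop("`index` must have 3 columns", call. = FALSE)
  if (integer_mode) {
    dm <- dim(vol$data)
    if (any(idx != round(idx)) ||
        any(idx < 0) || any(sweep(idx, 2, dm - 1L) > 0))
      stop("integer index out of grid bounds", call. = FALSE)
  }
  w <- idx %*% t(vol$direction %*% diag(vol$spacing))
  w <- sweep(w, 2, vol$origin, "+")
  if (is.matrix(index)) w else drop(w)
}

#' Map world coordinates to (fractional) voxel indices
#'
#' Exact inverse of [voxel_to_world()] for the volume's geometry.
#'
#' @inheritParams voxel_to_world
#' @param world length-3 world point (mm) or an n x 3 matrix of points.
#' @return 0-based fractional indices, same shape convention as the input.
#' @export
world_to_voxel <- function(vol, world) {
  w <- if (is.matrix(world)) world else matrix(as.numeric(world), ncol = 3)
  if (ncol(w) != 3L) stop("`world` must have 3 columns", call. = FALSE)
  w <- sweep(w, 2, vol$origin, "-")
  idx <- w %*% t(solve(vol$direction %*% diag(vol$spacing)))
  if (is.matrix(world)) idx else drop(idx)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 image (`.nii` / `.nii.gz`) and decodes its geometry from
#' the stored affine. The image must be 3D, or 4D with a singleton fourth
#' axis (squeezed); true dynamic series are rejected. The affine must be an
#' orthonormal frame scaled by positive spacings; shear or a degenerate
#' (zero) column is rejected.
#'
#' @param path file path to a readable NIfTI image.
#' @param expected_unit unit tag to attach: the file format does not record
#'   whether voxels are activity concentration (kBq/mL) or SUV, so the caller
#'   must declare it.
#' @return a [pet_volume()].
#' @export
read_volume <- function(path, expected_unit = c("SUV", "ACTIVITY_KBQ_PER_ML")) {
  expected_unit <- match.arg(expected_unit)
  raw <- read_nifti_array(path)
  pet_volume(raw$data, spacing = raw$spacing, origin = raw$origin,
             direction = raw$direction, unit = expected_unit)
}

#' Read a NIfTI label mask
#'
#' @inheritParams read_volume
#' @return a [mask_volume()].
#' @export
read_mask <- function(path) {
  raw <- read_nifti_array(path)
  mask_volume(raw$data, spacing = raw$spacing, origin = raw$origin,
              direction = raw$direction)
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  dm <- dim(a)
  if (length(dm) == 4L && dm[4] == 1L) {
    dm <- dm[1:3]                          # singleton time axis squeezed
  } else if (length(dm) != 3L) {
    stop("image must be 3D (or 4D with a singleton last axis), got ",
         paste(dm, collapse = "x"), call. = FALSE)
  }
  a <- array(as.vector(a, mode = "double"), dim = dm)
  if (!all(is.finite(a))) stop("image contains non-finite voxels", call. = FALSE)
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  lin <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  if (any(spacing < 1e-8) || abs(det(lin)) < 1e-12)
    stop("degenerate geometry: affine has a zero or dependent column", call. = FALSE)
  direction <- sweep(lin, 2, spacing, "/")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-4)
    stop("affine contains shear; only orthonormal frames are supported", call. = FALSE)
  # re-orthonormalize to kill float32 header noise
  sv <- svd(direction)
  direction <- sv$u %*% t(sv$v)
  list(data = a, spacing = spacing, origin = aff[1:3, 4], direction = direction)
}

#' Write a volume as NIfTI
#'
#' Voxel data are stored as float64 so that [read_volume()] round-trips the
#' array bit-exactly; the affine is written to both sform and qform (the
#' NIfTI header holds it in float32, so geometry round-trips to roughly
#' 1e-4 mm at scanner-scale coordinates).
#'
#' @param vol a `pet_volume` or `mask_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, datatype = "double")
  RNifti::sform(img) <- structure(vol_affine(vol), code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Patient metadata needed for SUV normalization
#'
#' @param patient_id character scalar.
#' @param weight_kg body weight in kg; values outside (20, 300) are rejected
#'   as probable unit errors.
#' @param injected_dose_MBq injected activity, decay-corrected to scan start,
#'   in MBq; values outside (10, 1000) are rejected as probable unit errors.
#' @param uptake_time_min optional tracer uptake time (min); recorded but not
#'   used in normalization.
#' @return an object of class `patient_meta`.
#' @export
patient_meta <- function(patient_id, weight_kg, injected_dose_MBq,
                         uptake_time_min = NA_real_) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  weight_kg <- as.numeric(weight_kg)
  injected_dose_MBq <- as.numeric(injected_dose_MBq)
  if (!is.finite(weight_kg) || weight_kg <= 20 || weight_kg >= 300)
    stop("weight_kg = ", weight_kg, " outside (20, 300): probable unit error",
         call. = FALSE)
  if (!is.finite(injected_dose_MBq) || injected_dose_MBq <= 10 ||
      injected_dose_MBq >= 1000)
    stop("injected_dose_MBq = ", injected_dose_MBq,
         " outside (10, 1000): probable unit error", call. = FALSE)
  if (!is.na(uptake_time_min) && uptake_time_min <= 0)
    stop("uptake_time_min must be positive", call. = FALSE)
  structure(list(patient_id = patient_id, weight_kg = weight_kg,
                 injected_dose_MBq = injected_dose_MBq,
                 uptake_time_min = uptake_time_min),
            class = "patient_meta")
}

#' Read a patient metadata table
#'
#' CSV with columns `patient_id`, `weight_kg`, `injected_dose_MBq` and
#' optionally `uptake_time_min`; each row is validated by [patient_meta()].
#'
#' @param path CSV file path.
#' @return named list of `patient_meta`, keyed by patient id.
#' @export
read_patient_meta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "weight_kg", "injected_dose_MBq")
  if (!all(need %in% names(df)))
    stop("metadata CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ut <- if ("uptake_time_min" %in% names(df)) df$uptake_time_min else
    rep(NA_real_, nrow(df))
  out <- lapply(seq_len(nrow(df)), function(i)
    patient_meta(as.character(df$patient_id[i]), df$weight_kg[i],
                 df$injected_dose_MBq[i], ut[i]))
  names(out) <- as.character(df$patient_id)
  out
}

#' Convert an activity-concentration volume to SUV
#'
#' Body-weight SUV with unit tissue density:
#' `SUV = concentration[kBq/mL] * weight[kg] / dose[MBq]`.
#' The injected dose is assumed decay-corrected to scan start; no uptake-time
#' correction is applied. Geometry is untouched.
#'
#' @param vol a `pet_volume` with unit `"ACTIVITY_KBQ_PER_ML"`.
#' @param meta a [patient_meta()].
#' @return a `pet_volume` with unit `"SUV"`.
#' @export
activity_to_suv <- function(vol, meta) {
  stopifnot(inherits(vol, "pet_volume"), inherits(meta, "patient_meta"))
  if (vol$unit != "ACTIVITY_KBQ_PER_ML")
    stop("input volume must be in ACTIVITY_KBQ_PER_ML units, got ", vol$unit,
         call. = FALSE)
  out <- vol
  out$data <- vol$data * meta$weight_kg / meta$injected_dose_MBq
  out$unit <- "SUV"
  out
}

require_suv <- function(vol) {
  if (!inherits(vol, "pet_volume") || vol$unit != "SUV")
    stop("an SUV volume is required (convert with activity_to_suv())",
         call. = FALSE)
  invisible(vol)
}

#' Check that two volumes share a voxel grid
#'
#' Pairings (PET + prostate mask, PET + lesion labels) require identical
#' shapes, spacings within 1e-4 mm, and origins/directions within 1e-3 mm.
#'
#' @param a,b volumes to compare.
#' @return `TRUE` invisibly, or an error describing the mismatch.
#' @export
check_paired_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("geometry mismatch: grid shapes differ", call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > 1e-4)
    stop("geometry mismatch: spacings differ beyond 1e-4 mm", call. = FALSE)
  if (max(abs(a$origin - b$origin)) > 1e-3)
    stop("geometry mismatch: origins differ beyond 1e-3 mm", call. = FALSE)
  ext <- max(abs(dim(a$data) * a$spacing))
  if (max(abs(a$direction - b$direction)) * ext > 1e-3)
    stop("geometry mismatch: direction matrices differ", call. = FALSE)
  invisible(TRUE)
}

# world coordinates (n x 3 mm) of a set of linear voxel indices
linear_index_world <- function(vol, lin_idx) {
  idx <- arrayInd(lin_idx, dim(vol$data)) - 1L
  w <- idx %*% t(vol$direction %*% diag(vol$spacing))
  sweep(w, 2, vol$origin, "+")
}
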