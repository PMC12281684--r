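#' Euclidean lesion-to-prostate distances
#'
#' Distance from each lesion centroid to the geometric center of the
#' prostate, in cm (world-space mm / 10). Order follows the lesion table.
#'
#' @param lesions a `lesion_table` from [lesion_stats()].
#' @param center length-3 world point (mm), typically [prostate_center()].
#' @return numeric vector of distances in cm.
#' @export
lesion_distances <- function(lesions, center) {
  if (NROW(lesions) == 0L) stop("empty lesion list", call. = FALSE)
  d <- sweep(lesion_centroids(lesions), 2, center, "-")
  sqrt(rowSums(d^2)) / 10
}

#' Maximum lesion dissemination distance (Dmax)
#'
#' @param distances nonempty numeric vector of lesion-to-prostate distances (cm).
#' @return max of the distances, cm.
#' @export
dmax <- function(distances) {
  if (length(distances) == 0L) stop("empty distance list", call. = FALSE)
  max(distances)
}

#' Total lesion dissemination distance (Dtotal)
#'
#' @inheritParams dmax
#' @return sum of the distances, cm. Equals [dmax()] for a single lesion.
#' @export
dtotal <- function(distances) {
  if (length(distances) == 0L) stop("empty distance list", call. = FALSE)
  sum(distances)
}

#' Identify the primary (intraprostatic) lesion
#'
#' The primary lesion is the one with the largest fraction of its voxels
#' inside the prostate mask (requires the label map). If no lesion overlaps
#' the prostate at all, the lesion whose centroid is nearest the prostate
#' center is returned with a warning. Ties go to the larger lesion, then the
#' lower label id.
#'
#' @param lesions a `lesion_table`.
#' @param prostate the prostate `mask_volume`.
#' @param labels the `lesion_label_map` the table was computed from; if
#'   omitted, overlap is approximated by whether each centroid falls inside
#'   the mask.
#' @return single-row `lesion_table` of the primary lesion, with an
#'   `overlap_fraction` column appended.
#' @export
primary_lesion <- function(lesions, prostate, labels = NULL) {
  if (NROW(lesions) == 0L) stop("empty lesion list", call. = FALSE)
  stopifnot(inherits(prostate, "mask_volume"))
  if (!is.null(labels)) {
    lab <- if (inherits(labels, "lesion_label_map")) labels$labels else labels
    check_paired_geometry(lab, prostate)
    ov <- vapply(lesions$label_id, function(id) {
      lin <- which(lab$data == id)
      mean(prostate$data[lin] > 0L)
    }, numeric(1))
  } else {
    ov <- as.numeric(centroid_in_mask(lesions, prostate))
  }
  if (all(ov == 0)) {
    d <- lesion_distances(lesions, prostate_center(prostate))
    pick <- order(d, -lesions$voxel_count, lesions$label_id)[1]
    warning("no lesion overlaps the prostate mask; using nearest centroid ",
            "as primary", call. = FALSE)
  } else {
    pick <- order(-ov, -lesions$voxel_count, lesions$label_id)[1]
  }
  out <- lesions[pick, , drop = FALSE]
  out$overlap_fraction <- ov[pick]
  out
}

# logical: does each lesion centroid fall on a prostate voxel?
centroid_in_mask <- function(lesions, prostate) {
  idx <- round(world_to_voxel(prostate, lesion_centroids(lesions)))
  if (!is.matrix(idx)) idx <- matrix(idx, ncol = 3)
  dm <- dim(prostate$data)
  inside <- idx[, 1] >= 0 & idx[, 1] < dm[1] & idx[, 2] >= 0 & idx[, 2] < dm[2] &
            idx[, 3] >= 0 & idx[, 3] < dm[3]
  out <- logical(nrow(idx))
  if (any(inside))
    out[inside] <- prostate$data[idx[inside, , drop = FALSE] + 1L] > 0L
  out
}

#' Classify metastatic status from the lesion set
#'
#' Two selectable rules:
#' * `"outside_prostate"` (default): metastatic iff any lesion centroid lies
#'   outside the prostate mask.
#' * `"count_gt2"`: metastatic iff more than two lesions are present.
#'
#' @param lesions a `lesion_table`.
#' @param prostate the prostate `mask_volume` (used by the default rule).
#' @param rule `"outside_prostate"` or `"count_gt2"`.
#' @return logical scalar.
#' @export
classify_metastasis <- function(lesions, prostate,
                                rule = c("outside_prostate", "count_gt2")) {
  rule <- match.arg(rule)
  if (NROW(lesions) == 0L) stop("empty lesion list", call. = FALSE)
  if (rule == "count_gt2") return(NROW(lesions) > 2L)
  any(!centroid_in_mask(lesions, prostate))
}

#' Per-patient imaging feature record
#'
#' Composes the per-patient features used by the survival stage: SUVmax and
#' metabolic volume (PMTV, cm^3) of the primary lesion, and Dmax / Dtotal
#' (cm) over all lesions (primary included).
#'
#' @param labels a `lesion_label_map`.
#' @param vol the paired SUV `pet_volume`.
#' @param prostate the prostate `mask_volume`.
#' @param patient_id character id for the output row.
#' @param metastasis_rule passed to [classify_metastasis()].
#' @param clinical optional named list of clinical covariates to append
#'   (`psa_ng_ml`, `gleason`, `age_y`, `weight_kg`).
#' @return one-row data frame: `patient_id`, `suvmax`, `pmtv_cm3`,
#'   `dmax_cm`, `dtotal_cm`, `n_lesions`, `metastasis`, plus any clinical
#'   columns supplied.
#' @export
compute_features <- function(labels, vol, prostate, patient_id = "P1",
                             metastasis_rule = c("outside_prostate", "count_gt2"),
                             clinical = NULL) {
  metastasis_rule <- match.arg(metastasis_rule)
  check_paired_geometry(vol, prostate)
  lesions <- lesion_stats(labels, vol)
  prim <- primary_lesion(lesions, prostate, labels)
  dists <- lesion_distances(lesions, prostate_center(prostate))
  rec <- data.frame(patient_id = patient_id,
                    suvmax = prim$suvmax,
                    pmtv_cm3 = prim$volume_cm3,
                    dmax_cm = dmax(dists),
                    dtotal_cm = dtotal(dists),
                    n_lesions = NROW(lesions),
                    metastasis = classify_metastasis(lesions, prostate,
                                                     metastasis_rule),
                    stringsAsFactors = FALSE)
  for (nm in c("psa_ng_ml", "gleason", "age_y", "weight_kg"))
    if (!is.null(clinical[[nm]])) rec[[nm]] <- clinical[[nm]]
  rec
}

#' Dichotomization cutoffs for the PET features
#'
#' Defaults are the reported prognostic cutoffs: SUVmax 17.06, PMTV
#' 41.59 cm^3, Dmax 9.69 cm, Dtotal 11.95 cm, PSA 68.38 ng/mL.
#'
#' @param suvmax,pmtv_cm3,dmax_cm,dtotal_cm,psa_ng_ml positive cutoffs.
#' @return named list of class `cutoff_set`.
#' @export
cutoff_set <- function(suvmax = 17.06, pmtv_cm3 = 41.59, dmax_cm = 9.69,
                       dtotal_cm = 11.95, psa_ng_ml = 68.38) {
  cuts <- list(suvmax = suvmax, pmtv_cm3 = pmtv_cm3, dmax_cm = dmax_cm,
               dtotal_cm = dtotal_cm, psa_ng_ml = psa_ng_ml)
  if (any(!vapply(cuts, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                  logical(1))))
    stop("all cutoffs must be positive scalars", call. = FALSE)
  structure(cuts, class = "cutoff_set")
}

#' Dichotomize feature records at fixed cutoffs
#'
#' Each feature is coded 1 if strictly greater than its cutoff, else 0
#' (matching the "feature > cutoff" convention of the reported tables; a
#' value exactly at the cutoff codes 0).
#'
#' @param records data frame of feature records (rows = patients).
#' @param cuts a [cutoff_set()].
#' @param features which features to code; default: all cutoff features
#'   present in `records`.
#' @return data frame of 0/1 columns named `<feature>_high`.
#' @export
dichotomize <- function(records, cuts = cutoff_set(), features = NULL) {
  stopifnot(inherits(cuts, "cutoff_set"))
  if (is.null(features)) features <- intersect(names(cuts), names(records))
  miss <- setdiff(features, names(records))
  if (length(miss) > 0)
    stop("features absent from records: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(features, function(f) as.integer(records[[f]] > cuts[[f]]))
  names(out) <- paste0(features, "_high")
  as.data.frame(out)
}

#' Three-tier risk stratification from PMTV and Dmax
#'
#' Group 1 (low risk): PMTV and Dmax both strictly below their cutoffs.
#' Group 3 (high risk): both at or above. Group 2 (intermediate): exactly
#' one at or above. The three groups partition any cohort.
#'
#' @param records data frame with `pmtv_cm3` and `dmax_cm` columns (or two
#'   numeric vectors via `pmtv_cm3` / `dmax_cm`).
#' @param pmtv_cut,dmax_cut cutoffs (defaults: 41.59 cm^3, 9.69 cm).
#' @return integer vector of group codes 1/2/3, with levels attribute
#'   `c("low", "intermediate", "high")`.
#' @export
stratify_risk <- function(records, pmtv_cut = 41.59, dmax_cut = 9.69) {
  if (is.data.frame(records)) {
    if (!all(c("pmtv_cm3", "dmax_cm") %in% names(records)))
      stop("records must contain pmtv_cm3 and dmax_cm", call. = FALSE)
    pmtv <- records$pmtv_cm3; dm <- records$dmax_cm
  } else stop("`records` must be a data frame of feature records", call. = FALSE)
  if (any(!is.finite(pmtv)) || any(!is.finite(dm)))
    stop("missing feature: pmtv_cm3/dmax_cm must be finite", call. = FALSE)
  high <- (pmtv >= pmtv_cut) + (dm >= dmax_cut)
  grp <- ifelse(high == 0L, 1L, ifelse(high == 2L, 3L, 2L))
  structure(as.integer(grp), levels = c("low", "intermediate", "high"))
}
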