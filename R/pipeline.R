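#' Validated pipeline configuration
#'
#' Schema-checks a configuration list before any computation; unknown keys
#' (top level or within the option blocks) are rejected.
#'
#' @param images data frame with columns `patient_id`, `pet`,
#'   `prostate_mask`, and optionally `seeds` (path to a per-patient seed CSV
#'   with columns x_mm, y_mm, z_mm) and `unit` (`"SUV"` default or
#'   `"ACTIVITY_KBQ_PER_ML"`).
#' @param metadata_csv optional patient metadata CSV (see
#'   [read_patient_meta()]); required for any activity-unit image.
#' @param segmentation list of [segment_lesions()] options: `fraction`,
#'   `mode`, `min_voxels`.
#' @param features list of feature options: `metastasis_rule`.
#' @param cutoffs a [cutoff_set()].
#' @param out_dir optional output directory for CSV/JSON artifacts and the
#'   reproducibility manifest.
#' @param seed integer seed recorded in the manifest and used for any
#'   randomized step.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(images, metadata_csv = NULL,
                            segmentation = list(), features = list(),
                            cutoffs = cutoff_set(), out_dir = NULL,
                            seed = 1L) {
  images <- as.data.frame(images)
  need <- c("patient_id", "pet", "prostate_mask")
  if (!all(need %in% names(images)))
    stop("`images` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(images), c(need, "seeds", "unit"))
  if (length(extra) > 0)
    stop("unknown image-table column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(images$patient_id))
    stop("duplicate patient_id in image table", call. = FALSE)
  check_keys(segmentation, c("fraction", "mode", "min_voxels"), "segmentation")
  check_keys(features, c("metastasis_rule"), "features")
  stopifnot(inherits(cutoffs, "cutoff_set"))
  structure(list(images = images, metadata_csv = metadata_csv,
                 segmentation = segmentation, features = features,
                 cutoffs = cutoffs, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

check_keys <- function(x, allowed, what) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0)
    stop("unknown ", what, " option(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Extract per-patient features for a cohort of images
#'
#' Runs read -> (SUV conversion) -> segmentation -> feature computation for
#' every patient in the configuration. Per-patient failures are logged
#' (via `message`) and skipped rather than aborting the cohort; the number
#' of skips is attached as attribute `n_skipped`, and the run errors only
#' if no patient succeeds.
#'
#' @param config a [pipeline_config()].
#' @return data frame of feature records (one row per successful patient),
#'   with attributes `n_skipped` and `skipped` (ids). Written to
#'   `out_dir/features.csv` (plus a manifest) when `out_dir` is set.
#' @export
run_extract <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  img <- config$images
  if (nrow(img) == 0L) stop("empty cohort", call. = FALSE)
  meta <- if (!is.null(config$metadata_csv))
    read_patient_meta(config$metadata_csv) else list()
  seg <- config$segmentation
  rule <- config$features$metastasis_rule %||% "outside_prostate"
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(img))) {
    pid <- as.character(img$patient_id[i])
    rec <- tryCatch({
      unit <- if (!is.null(img$unit)) img$unit[i] else "SUV"
      vol <- read_volume(img$pet[i], expected_unit = unit)
      if (vol$unit != "SUV") {
        if (is.null(meta[[pid]]))
          stop("activity volume but no metadata for ", pid)
        vol <- activity_to_suv(vol, meta[[pid]])
      }
      prost <- read_mask(img$prostate_mask[i])
      check_paired_geometry(vol, prost)
      seeds <- NULL
      if (!is.null(img$seeds) && !is.na(img$seeds[i]) && nzchar(img$seeds[i])) {
        sdf <- read.csv(img$seeds[i])
        seeds <- as.matrix(sdf[, c("x_mm", "y_mm", "z_mm")])
      }
      labels <- segment_lesions(
        vol,
        fraction = seg$fraction %||% 0.4,
        mode = seg$mode %||% (if (is.null(seeds)) "global_threshold" else "per_seed"),
        seeds = seeds,
        min_voxels = seg$min_voxels %||% 2L)
      compute_features(labels, vol, prost, patient_id = pid,
                       metastasis_rule = rule)
    }, error = function(e) {
      message("skipping patient ", pid, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) skipped <- c(skipped, pid) else rows[[pid]] <- rec
  }
  if (length(rows) == 0L) stop("no patient could be processed", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- length(skipped)
  attr(out, "skipped") <- skipped
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
    write_manifest(config$out_dir, config)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full survival analysis on a feature table
#'
#' Joins features and outcomes on `patient_id` and reproduces the study's
#' reporting layout:
#' * a univariable Cox sweep, one model per dichotomized feature;
#' * three multivariable Cox models -- model 0: PSA + PMTV; model 1:
#'   PSA + PMTV + Dmax; model 2: PSA + PMTV + Dtotal -- each with its
#'   in-sample C-index;
#' * per-feature Kaplan-Meier curves (high vs low) with log-rank p;
#' * the three-tier PMTV/Dmax risk stratification with per-group KM curves,
#'   the overall log-rank test, and all pairwise log-rank tests;
#' * a Pearson correlation matrix over the continuous features and Kendall
#'   tau of the distance features against Gleason score (when present).
#'
#' @param features feature data frame (as from [run_extract()] or
#'   [generate_cohort()]).
#' @param outcomes data frame with `patient_id`, `time_months`, `event`.
#' @param cuts a [cutoff_set()].
#' @param out_dir optional directory: writes `survival_report.json`,
#'   per-group KM curves as CSV, and a manifest.
#' @param seed recorded in the manifest (no randomness is used unless a
#'   permutation option is added by the caller).
#' @return list of class `survival_report`.
#' @export
run_survival <- function(features, outcomes, cuts = cutoff_set(),
                         out_dir = NULL, seed = 1L) {
  if (anyDuplicated(features$patient_id) || anyDuplicated(outcomes$patient_id))
    stop("duplicate patient_id", call. = FALSE)
  dat <- merge(features, outcomes, by = "patient_id")
  if (nrow(dat) < 10L)
    stop("fewer than 10 usable patients after join", call. = FALSE)
  tm <- dat$time_months; ev <- dat$event
  bin <- dichotomize(dat, cuts)

  uni <- do.call(rbind, lapply(names(bin), function(v) {
    fit <- fit_cox(bin[v], tm, ev)
    cbind(fit$table, c_index = fit$c_index)
  }))

  model_terms <- list(model0 = c("psa_ng_ml_high", "pmtv_cm3_high"),
                      model1 = c("psa_ng_ml_high", "pmtv_cm3_high", "dmax_cm_high"),
                      model2 = c("psa_ng_ml_high", "pmtv_cm3_high", "dtotal_cm_high"))
  model_terms <- lapply(model_terms, intersect, names(bin))
  multi <- lapply(model_terms, function(tr) fit_cox(bin[tr], tm, ev))

  km_by_feature <- lapply(names(bin), function(v) {
    g <- bin[[v]]
    list(feature = v,
         km_low = km_estimate(tm[g == 0], ev[g == 0]),
         km_high = km_estimate(tm[g == 1], ev[g == 1]),
         logrank = logrank_test(tm, ev, g))
  })
  names(km_by_feature) <- names(bin)

  grp <- stratify_risk(dat, pmtv_cut = cuts$pmtv_cm3, dmax_cut = cuts$dmax_cm)
  km_by_group <- lapply(1:3, function(g)
    if (any(grp == g)) km_estimate(tm[grp == g], ev[grp == g]) else NULL)
  names(km_by_group) <- c("low", "intermediate", "high")
  pairwise <- list()
  for (a in 1:2) for (b in (a + 1):3)
    if (any(grp == a) && any(grp == b)) {
      sel <- grp %in% c(a, b)
      pairwise[[sprintf("g%d_vs_g%d", a, b)]] <-
        logrank_test(tm[sel], ev[sel], grp[sel])
    }
  overall <- if (length(unique(grp)) > 1)
    logrank_test(tm, ev, grp) else NULL

  cont <- intersect(c("suvmax", "pmtv_cm3", "dmax_cm", "dtotal_cm",
                      "psa_ng_ml"), names(dat))
  pearson <- stats::cor(dat[cont], method = "pearson")
  kendall_gleason <- if ("gleason" %in% names(dat))
    vapply(c("dmax_cm", "dtotal_cm"), function(v)
      kendall_tau(dat[[v]], dat$gleason), numeric(1)) else NULL

  report <- structure(list(n = nrow(dat), n_event = sum(ev),
                           univariable = uni, multivariable = multi,
                           km_by_feature = km_by_feature,
                           risk_groups = list(group = grp,
                                              counts = tabulate(grp, 3),
                                              km = km_by_group,
                                              logrank_overall = overall,
                                              logrank_pairwise = pairwise),
                           pearson = pearson,
                           kendall_gleason = kendall_gleason,
                           cuts = cuts),
                      class = "survival_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(out_dir, "survival_report.json"))
    for (g in names(km_by_group)) {
      km <- km_by_group[[g]]
      if (!is.null(km))
        write.csv(data.frame(time = km$time, survival = km$survival,
                             at_risk = km$n_risk, events = km$n_event),
                  file.path(out_dir, sprintf("km_group_%s.csv", g)),
                  row.names = FALSE)
    }
    write_manifest(out_dir, list(cuts = unclass(cuts), seed = seed,
                                 n = nrow(dat)))
  }
  report
}

#' @export
print.survival_report <- function(x, ...) {
  cat(sprintf("Survival report: n = %d, events = %d\n", x$n, x$n_event))
  cat("\nUnivariable Cox (dichotomized features):\n")
  u <- x$univariable
  print(data.frame(term = u$term,
                   `HR [95% CI]` = sprintf("%.2f [%.2f, %.2f]",
                                           u$hr, u$hr_lo, u$hr_hi),
                   p = signif(u$p, 2), check.names = FALSE),
        row.names = FALSE)
  for (m in names(x$multivariable)) {
    cat("\n", m, " (C-index ", sprintf("%.2f", x$multivariable[[m]]$c_index),
        ")\n", sep = "")
    print(x$multivariable[[m]])
  }
  cat("\nRisk groups (low/intermediate/high): ",
      paste(x$risk_groups$counts, collapse = " / "), "\n")
  if (!is.null(x$risk_groups$logrank_overall))
    cat(sprintf("Overall log-rank: chi2 = %.2f, p = %.2g\n",
                x$risk_groups$logrank_overall$chi2,
                x$risk_groups$logrank_overall$p))
  invisible(x)
}

write_report_json <- function(report, path) {
  slim <- list(
    n = report$n, n_event = report$n_event,
    univariable = report$univariable,
    multivariable = lapply(report$multivariable, function(m)
      list(table = m$table, c_index = m$c_index, converged = m$converged)),
    logrank_by_feature = lapply(report$km_by_feature, function(k) k$logrank),
    risk_group_counts = report$risk_groups$counts,
    risk_logrank_overall = report$risk_groups$logrank_overall,
    risk_logrank_pairwise = report$risk_groups$logrank_pairwise,
    pearson = report$pearson,
    kendall_gleason = report$kendall_gleason,
    cuts = unclass(report$cuts))
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# reproducibility manifest: config hash, seed, versions
write_manifest <- function(out_dir, config) {
  cfg_path <- file.path(out_dir, "config.json")
  cfg <- config
  if (inherits(cfg, "pipeline_config")) cfg <- unclass(cfg)
  cfg$cutoffs <- if (!is.null(cfg$cutoffs)) unclass(cfg$cutoffs)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = config$seed %||% NA,
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("petdist")),
                   created = "see file mtime")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
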