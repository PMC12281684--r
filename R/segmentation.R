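# 26-connected component labeling on a logical 3D array.
# Builds the half-neighbourhood voxel graph over foreground voxels and labels
# components with igraph; returns an integer array (0 = background) with
# arbitrary (but deterministic) component ids.
label_components_26 <- function(fg) {
  dm <- dim(fg)
  lin <- which(fg)
  out <- array(0L, dim = dm)
  if (length(lin) == 0L) return(out)
  vid <- array(0L, dim = dm)
  vid[lin] <- seq_along(lin)
  coords <- arrayInd(lin, dm)
  # 13 half-space offsets cover all 26 neighbours once
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + dm[1] * (nb[ok, 2] - 1L) + dm[1] * dm[2] * (nb[ok, 3] - 1L)
    tgt <- vid[nb_lin]
    hit <- tgt > 0L
    if (any(hit))
      edges[[k]] <- cbind(vid[lin[ok]][hit], tgt[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  out[lin] <- as.integer(memb)
  out
}

# steepest-ascent hill climb over the 26-neighbourhood from a voxel index
# (1-based row vector); ties broken by the first neighbour in array order.
hill_climb <- function(data, start) {
  dm <- dim(data)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cur <- start
  repeat {
    nb <- sweep(offs, 2, cur, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nb <- nb[ok, , drop = FALSE]
    vals <- data[nb]
    best <- which.max(vals)     # first maximum in fixed order: deterministic
    if (vals[best] > data[cur[1], cur[2], cur[3]]) cur <- nb[best, ]
    else return(cur)
  }
}

#' Segment PSMA-avid lesions at a fractional-SUVmax threshold
#'
#' Thresholds an SUV volume at `fraction` of a reference SUVmax and labels
#' 26-connected components. Two readings of "40% SUVmax" are provided:
#'
#' * `"per_seed"` (default): for each seed point, a hill climb over the
#'   26-neighbourhood finds the local uptake maximum, the threshold is
#'   `fraction` times that local max, and the lesion is the connected
#'   super-threshold region containing the peak. Seeds whose regions touch
#'   are merged into one lesion. This per-lesion reading preserves
#'   low-uptake metastases next to a hot primary.
#' * `"global_threshold"`: one threshold at `fraction` times the global
#'   SUVmax (optionally restricted to `body_mask`), then component labeling.
#'
#' Components smaller than `min_voxels` are discarded. Labels are renumbered
#' 1..K by descending voxel count, ties broken by ascending world x, y, z of
#' the component centroid, so labeling is deterministic.
#'
#' @param vol a `pet_volume` in SUV units.
#' @param fraction threshold as a fraction of the reference SUVmax, in (0,1);
#'   default 0.4.
#' @param mode `"per_seed"` or `"global_threshold"`.
#' @param seeds n x 3 matrix of world points (mm), required in per-seed mode.
#' @param min_voxels minimum component size kept (default 2; suppresses
#'   single-voxel noise).
#' @param body_mask optional `mask_volume` restricting the global-mode
#'   reference maximum and the thresholded foreground.
#' @return an object of class `lesion_label_map`: list with `labels` (a
#'   `mask_volume` of 1..K lesion labels), `mode`, `fraction`, and
#'   `thresholds` (the governing SUV threshold per label).
#' @export
segment_lesions <- function(vol, fraction = 0.4,
                            mode = c("per_seed", "global_threshold"),
                            seeds = NULL, min_voxels = 2L, body_mask = NULL) {
  require_suv(vol)
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  if (max(vol$data) <= 0) stop("all-zero volume: nothing to segment", call. = FALSE)
  if (!is.null(body_mask)) check_paired_geometry(vol, body_mask)
  dm <- dim(vol$data)

  if (mode == "global_threshold") {
    ref_data <- vol$data
    if (!is.null(body_mask)) ref_data[body_mask$data == 0L] <- 0
    gmax <- max(ref_data)
    if (gmax <= 0) stop("all-zero volume within body mask", call. = FALSE)
    thr <- fraction * gmax
    comp <- label_components_26(ref_data >= thr)
    thr_by_comp <- rep(thr, max(comp))
  } else {
    if (is.null(seeds)) stop("per-seed mode requires `seeds`", call. = FALSE)
    seeds <- if (is.matrix(seeds)) seeds else matrix(as.numeric(seeds), ncol = 3)
    sidx <- round(world_to_voxel(vol, seeds)) + 1L   # to 1-based voxel
    if (any(sidx < 1L) || any(sweep(sidx, 2, dm) > 0))
      stop("seed outside grid", call. = FALSE)
    comp <- array(0L, dim = dm)
    thr_by_comp <- numeric(0)
    next_id <- 0L
    for (s in seq_len(nrow(sidx))) {
      peak <- hill_climb(vol$data, sidx[s, ])
      local_max <- vol$data[peak[1], peak[2], peak[3]]
      if (local_max <= 0) next
      thr <- fraction * local_max
      cc <- label_components_26(vol$data >= thr)
      region <- cc == cc[peak[1], peak[2], peak[3]] & cc > 0L
      hit <- unique(comp[region])
      hit <- hit[hit > 0L]
      if (length(hit) > 0L) {
        # overlaps earlier seed region(s): merge into the first, keep the
        # lower governing threshold so member voxels still satisfy it
        keep <- min(hit)
        comp[region | array(comp %in% hit, dim = dm)] <- keep
        thr_by_comp[keep] <- min(thr_by_comp[keep], thr)
      } else {
        next_id <- next_id + 1L
        comp[region] <- next_id
        thr_by_comp[next_id] <- thr
      }
    }
  }

  relab <- renumber_components(comp, thr_by_comp, vol, min_voxels)
  structure(list(labels = mask_volume(relab$comp, spacing = vol$spacing,
                                      origin = vol$origin,
                                      direction = vol$direction),
                 mode = mode, fraction = fraction,
                 thresholds = relab$thresholds),
            class = "lesion_label_map")
}

renumber_components <- function(comp, thr_by_comp, vol, min_voxels) {
  ids <- sort(unique(comp[comp > 0L]))
  if (length(ids) == 0L)
    return(list(comp = comp, thresholds = numeric(0)))
  counts <- tabulate(comp[comp > 0L], nbins = max(ids))[ids]
  keep <- ids[counts >= min_voxels]
  if (length(keep) == 0L) {
    comp[] <- 0L
    return(list(comp = comp, thresholds = numeric(0)))
  }
  cents <- t(vapply(keep, function(id)
    colMeans(linear_index_world(vol, which(comp == id))), numeric(3)))
  counts <- counts[match(keep, ids)]
  ord <- order(-counts, cents[, 1], cents[, 2], cents[, 3])
  new <- array(0L, dim = dim(comp))
  thresholds <- numeric(length(ord))
  for (r in seq_along(ord)) {
    new[comp == keep[ord[r]]] <- r
    thresholds[r] <- thr_by_comp[keep[ord[r]]]
  }
  list(comp = new, thresholds = thresholds)
}

#' @export
print.lesion_label_map <- function(x, ...) {
  k <- length(x$thresholds)
  cat(sprintf("Lesion label map (%s, fraction %.2f): %d lesion%s, %d voxels\n",
              x$mode, x$fraction, k, if (k == 1) "" else "s",
              sum(x$labels$data > 0)))
  invisible(x)
}

#' Per-lesion statistics
#'
#' One row per label: voxel count, volume (voxel count x voxel volume,
#' cm^3), SUVmax, SUVmean, and the unweighted world-coordinate centroid of
#' member voxels (mm).
#'
#' @param labels a `lesion_label_map` (or `mask_volume` of lesion labels).
#' @param vol the paired SUV `pet_volume`.
#' @return data frame of class `lesion_table` with columns `label_id`,
#'   `voxel_count`, `volume_cm3`, `suvmax`, `suvmean`, `centroid_x_mm`,
#'   `centroid_y_mm`, `centroid_z_mm`.
#' @export
lesion_stats <- function(labels, vol) {
  require_suv(vol)
  lab <- if (inherits(labels, "lesion_label_map")) labels$labels else labels
  check_paired_geometry(lab, vol)
  ids <- sort(unique(lab$data[lab$data > 0L]))
  if (length(ids) == 0L) stop("empty label map: no lesions", call. = FALSE)
  vox_vol <- prod(vol$spacing)          # mm^3
  rows <- lapply(ids, function(id) {
    lin <- which(lab$data == id)
    w <- linear_index_world(vol, lin)
    v <- vol$data[lin]
    data.frame(label_id = id, voxel_count = length(lin),
               volume_cm3 = length(lin) * vox_vol / 1000,
               suvmax = max(v), suvmean = mean(v),
               centroid_x_mm = mean(w[, 1]), centroid_y_mm = mean(w[, 2]),
               centroid_z_mm = mean(w[, 3]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lesion_table", "data.frame")
  out
}

lesion_centroids <- function(lesions) {
  as.matrix(lesions[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
}

#' Geometric center of the prostate
#'
#' Unweighted centroid of the non-zero voxels of the prostate mask, in world
#' coordinates (mm).
#'
#' @param prostate a `mask_volume`; any non-zero label counts as prostate.
#' @return length-3 world point (mm).
#' @export
prostate_center <- function(prostate) {
  stopifnot(inherits(prostate, "mask_volume"))
  lin <- which(prostate$data > 0L)
  if (length(lin) == 0L) stop("empty prostate mask", call. = FALSE)
  colMeans(linear_index_world(prostate, lin))
}
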