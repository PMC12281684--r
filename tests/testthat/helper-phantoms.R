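# Small phantom builders shared across test files. Lesion centers are placed
# on voxel centers (even-mm coordinates on the default 2 mm grid with origin
# 0) so the planted peak is realized exactly at a sampled voxel.

# one prostate + optional metastases; centers in mm
small_phantom_spec <- function(lesions, shape = c(80, 80, 60), spacing = 2,
                               prostate_center = c(80, 80, 60),
                               prostate_semiaxes = c(24, 20, 18),
                               noise_sd = 0, seed = 1, ...) {
  phantom_spec(shape = shape, spacing = spacing,
               prostate_center = prostate_center,
               prostate_semiaxes = prostate_semiaxes,
               lesions = lesions, noise_sd = noise_sd, seed = seed, ...)
}

# random multi-lesion phantom spec with grid-aligned centers; returns a spec
# whose primary sits inside the prostate and whose metastases are well
# separated (>= 60 mm apart) so per-seed regions cannot merge.
random_phantom_spec <- function(n_mets = 2, spacing = 2, shape = c(100, 100, 70)) {
  ctr <- (shape - 1) * spacing / 2
  ctr <- round(ctr / spacing) * spacing            # snap to voxel lattice
  prim <- ctr + sample(seq(-10, 10, by = spacing), 3, replace = TRUE)
  pts <- list(prim)
  lim_lo <- 30; lim_hi <- (shape - 1) * spacing - 30
  while (length(pts) < n_mets + 1) {
    cand <- round(runif(3, lim_lo, lim_hi) / spacing) * spacing
    if (all(vapply(pts, function(p) sqrt(sum((p - cand)^2)) >= 60, logical(1))))
      pts[[length(pts) + 1]] <- cand
  }
  pts <- do.call(rbind, pts)
  lesions <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        sigma = c(10, rep(6, n_mets)),
                        peak = c(round(runif(1, 8, 20), 1),
                                 round(runif(n_mets, 3, 12), 1)))
  small_phantom_spec(lesions, shape = shape, spacing = spacing,
                     prostate_center = ctr, prostate_semiaxes = c(24, 20, 18),
                     seed = sample.int(1e6, 1))
}

# full feature pipeline on a generated phantom (per-seed segmentation at the
# planted centers)
phantom_features <- function(ph, ...) {
  seg <- segment_lesions(ph$pet, seeds = ph$truth$seeds, mode = "per_seed", ...)
  compute_features(seg, ph$pet, ph$prostate, patient_id = "PH")
}

voxel_diag <- function(vol_or_spacing) {
  sp <- if (is.list(vol_or_spacing)) vol_or_spacing$spacing else vol_or_spacing
  sqrt(sum(sp^2))
}
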