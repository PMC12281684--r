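make_suv <- function(data, spacing = c(1, 1, 1)) {
  pet_volume(data, spacing = spacing, unit = "SUV")
}

test_that("a uniform sphere in zero background segments to exactly its voxels", {
  dm <- c(40, 40, 40)
  idx <- as.matrix(expand.grid(1:dm[1], 1:dm[2], 1:dm[3])) - 1
  inside <- rowSums(sweep(idx, 2, c(20, 20, 20), "-")^2) <= 8^2
  a <- array(0, dim = dm); a[inside] <- 10
  vol <- make_suv(a)
  seg <- segment_lesions(vol, mode = "global_threshold")
  expect_identical(sum(seg$labels$data > 0), sum(inside))
  expect_identical(unname(which(seg$labels$data == 1L)), unname(which(inside)))
  # per-seed mode agrees when exactly one lesion exists
  seg2 <- segment_lesions(vol, mode = "per_seed", seeds = c(20, 20, 20))
  expect_identical(seg2$labels$data, seg$labels$data)
})

test_that("a Gaussian blob's 40% region matches the analytic isocontour ball", {
  dm <- c(60, 60, 60)
  ctr <- c(30, 30, 30); sigma <- 10
  idx <- as.matrix(expand.grid(1:dm[1], 1:dm[2], 1:dm[3])) - 1
  d2 <- rowSums(sweep(idx, 2, ctr, "-")^2)
  a <- array(10 * exp(-d2 / (2 * sigma^2)), dim = dm)
  vol <- make_suv(a)      # 1 mm voxels
  seg <- segment_lesions(vol, fraction = 0.4, mode = "per_seed",
                         seeds = ctr)
  r <- sigma * sqrt(2 * log(1 / 0.4))
  expect_equal(r, 13.537, tolerance = 1e-4)
  vol_analytic <- 4 / 3 * pi * r^3
  vox_count <- sum(seg$labels$data > 0)
  expect_lt(abs(vox_count - vol_analytic) / vol_analytic, 0.02)
})

test_that("global mode thresholds both blobs at the hotter peak", {
  dm <- c(80, 40, 40)
  idx <- as.matrix(expand.grid(1:dm[1], 1:dm[2], 1:dm[3])) - 1
  d2a <- rowSums(sweep(idx, 2, c(20, 20, 20), "-")^2)
  d2b <- rowSums(sweep(idx, 2, c(60, 20, 20), "-")^2)
  a <- array(10 * exp(-d2a / (2 * 6^2)) + 5 * exp(-d2b / (2 * 6^2)), dim = dm)
  vol <- make_suv(a)
  seg <- segment_lesions(vol, fraction = 0.4, mode = "global_threshold",
                         min_voxels = 1)
  # oracle: direct enumeration of the thresholded voxel set
  thr <- 0.4 * max(a)
  expect_equal(thr, 4.0, tolerance = 1e-6)
  expect_identical(unname(which(seg$labels$data > 0)), unname(which(a >= thr)))
  expect_equal(unname(seg$thresholds), rep(4.0, length(seg$thresholds)),
               tolerance = 1e-6)
  # the cooler blob survives only as its peak neighborhood
  st <- lesion_stats(seg, vol)
  expect_identical(nrow(st), 2L)
  expect_lt(st$voxel_count[2], st$voxel_count[1] / 4)

  # per-seed mode instead recovers the full 40% region of the cool blob
  seg2 <- segment_lesions(vol, mode = "per_seed",
                          seeds = rbind(c(20, 20, 20), c(60, 20, 20)))
  st2 <- lesion_stats(seg2, vol)
  expect_gt(st2$voxel_count[2], st$voxel_count[2])
})

test_that("segmentation is invariant to global intensity scaling", {
  spec <- small_phantom_spec(data.frame(x = c(80, 30), y = c(80, 30),
                                        z = c(60, 60), sigma = c(10, 6),
                                        peak = c(12, 5)))
  ph <- generate_phantom(spec)
  base <- segment_lesions(ph$pet, seeds = ph$truth$seeds, mode = "per_seed")
  for (a in c(0.1, 10)) {
    scaled <- ph$pet; scaled$data <- scaled$data * a
    seg <- segment_lesions(scaled, seeds = ph$truth$seeds, mode = "per_seed")
    expect_identical(seg$labels$data, base$labels$data)
  }
})

test_that("every labeled voxel meets its governing threshold and labels are deterministic", {
  set.seed(7)
  for (rep in 1:3) {
    spec <- random_phantom_spec(n_mets = 2)
    ph <- generate_phantom(spec)
    seg <- segment_lesions(ph$pet, seeds = ph$truth$seeds, mode = "per_seed")
    for (k in seq_along(seg$thresholds)) {
      vals <- ph$pet$data[seg$labels$data == k]
      expect_gte(min(vals), seg$thresholds[k])
    }
    seg2 <- segment_lesions(ph$pet, seeds = ph$truth$seeds, mode = "per_seed")
    expect_identical(seg2$labels$data, seg$labels$data)
    # labels ordered by descending size
    st <- lesion_stats(seg, ph$pet)
    expect_true(all(diff(st$voxel_count) <= 0))
  }
})

test_that("min_voxels suppresses small components and errors are raised", {
  a <- array(0, dim = c(20, 20, 20))
  a[5, 5, 5] <- 10                  # single hot voxel
  a[12:14, 12:14, 12:14] <- 10      # 27-voxel block
  vol <- make_suv(a)
  seg <- segment_lesions(vol, mode = "global_threshold", min_voxels = 2)
  expect_identical(length(seg$thresholds), 1L)
  seg1 <- segment_lesions(vol, mode = "global_threshold", min_voxels = 1)
  expect_identical(length(seg1$thresholds), 2L)

  expect_error(segment_lesions(make_suv(array(0, dim = c(5, 5, 5)))),
               "all-zero")
  expect_error(segment_lesions(vol, fraction = 1.2), "fraction")
  expect_error(segment_lesions(vol, mode = "per_seed",
                               seeds = c(500, 0, 0)), "seed outside")
  act <- pet_volume(a, spacing = c(1, 1, 1), unit = "ACTIVITY_KBQ_PER_ML")
  expect_error(segment_lesions(act), "SUV")
})

test_that("lesion_stats computes volumes, intensities and centroids", {
  # 1000-voxel cube at 2 mm spacing -> 8 cm^3
  a <- array(0, dim = c(20, 20, 20)); a[6:15, 6:15, 6:15] <- 5
  vol <- make_suv(a, spacing = c(2, 2, 2))
  seg <- segment_lesions(vol, mode = "global_threshold")
  st <- lesion_stats(seg, vol)
  expect_equal(st$volume_cm3, 8.0)
  expect_equal(st$voxel_count, 1000L)
  expect_true(all(st$suvmean <= st$suvmax))

  # single-voxel lesion at index (3,3,3), identity geometry
  b <- array(0, dim = c(8, 8, 8)); b[4, 4, 4] <- 7
  volb <- make_suv(b)
  segb <- segment_lesions(volb, mode = "global_threshold", min_voxels = 1)
  stb <- lesion_stats(segb, volb)
  expect_equal(unlist(stb[1, c("centroid_x_mm", "centroid_y_mm",
                               "centroid_z_mm")], use.names = FALSE),
               c(3, 3, 3))

  # symmetric sphere: centroid equals center within half a voxel diagonal
  dm <- c(40, 40, 40)
  idx <- as.matrix(expand.grid(1:dm[1], 1:dm[2], 1:dm[3])) - 1
  inside <- rowSums(sweep(idx, 2, c(19, 21, 20), "-")^2) <= 7.5^2
  s <- array(0, dim = dm); s[inside] <- 3
  vols <- make_suv(s)
  sts <- lesion_stats(segment_lesions(vols, mode = "global_threshold"), vols)
  cent <- unlist(sts[1, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")],
                 use.names = FALSE)
  expect_lt(sqrt(sum((cent - c(19, 21, 20))^2)), voxel_diag(c(1, 1, 1)) / 2)
})

test_that("prostate_center is the world-space voxel centroid", {
  # ellipsoid centered at world (0, 50, -100) in a translated frame
  spec <- small_phantom_spec(data.frame(x = 0, y = 50, z = -100,
                                        sigma = 8, peak = 10),
                             prostate_center = c(0, 50, -100),
                             origin = c(-79, -29, -159))
  ph <- generate_phantom(spec)
  ctr <- prostate_center(ph$prostate)
  expect_lt(sqrt(sum((ctr - spec$prostate_center)^2)),
            voxel_diag(ph$prostate) / 2)

  # single-voxel and two-voxel masks
  m <- array(0L, dim = c(10, 10, 10)); m[3, 4, 5] <- 1L
  mv <- mask_volume(m, spacing = c(2, 2, 2))
  expect_equal(prostate_center(mv), c(4, 6, 8))
  m2 <- array(0L, dim = c(12, 4, 4)); m2[1, 1, 1] <- 1L; m2[11, 1, 1] <- 1L
  expect_equal(prostate_center(mask_volume(m2, spacing = c(1, 1, 1)))[1], 5)
  expect_error(prostate_center(mask_volume(array(0L, dim = c(4, 4, 4)),
                                           spacing = c(1, 1, 1))), "empty")
})
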