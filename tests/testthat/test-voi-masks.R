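# Volume-of-interest construction: spheres, gray-matter filtering,
# size equating by probability threshold, unions, and round trips.

test_that("sphere mask matches integer-offset enumeration and is shift equivariant", {
  g <- voi_grid(c(21, 21, 21), voxel_size = 3)   # centered: (11,11,11) -> 0 mm
  center <- c(0, 0, 0)

  m <- sphere_mask(center, radius = 12, grid = g)
  # brute force: integer offsets with (3i)^2+(3j)^2+(3k)^2 <= 144, i.e.
  # i^2+j^2+k^2 <= 16
  offs <- expand.grid(i = -4:4, j = -4:4, k = -4:4)
  n_expected <- sum(offs$i^2 + offs$j^2 + offs$k^2 <= 16)
  expect_equal(mask_size(m), n_expected)
  expect_equal(mask_size(m), 257L)

  expect_equal(mask_size(sphere_mask(center, radius = 1, grid = g)), 1L)

  shifted <- sphere_mask(center + c(3, 0, 0), radius = 12, grid = g)
  expect_equal(shifted$indices,
               sweep(m$indices, 2, c(-1L, 0L, 0L)),
               ignore_attr = TRUE)

  # monotone in radius
  sizes <- sapply(c(3, 6, 9, 12), function(r) {
    mask_size(sphere_mask(center, r, grid = g))
  })
  expect_true(all(diff(sizes) > 0))
  expect_error(sphere_mask(center, radius = 0, grid = g), "radius")
})

test_that("gray-matter filter keeps strictly-above-threshold voxels", {
  g <- voi_grid(c(8, 8, 8), voxel_size = 3)
  m <- sphere_mask(c(0, 0, 0), 6, g)
  gm1 <- array(1, c(8, 8, 8))
  expect_equal(gray_matter_filter(m, gm1)$indices, m$indices)

  gm0 <- array(0, c(8, 8, 8))
  expect_error(gray_matter_filter(m, gm0), "no voxel")

  set.seed(4)
  gm <- array(runif(512), c(8, 8, 8))
  f <- gray_matter_filter(m, gm, threshold = 0.5)
  # oracle: set intersection with the thresholded map
  keep <- gm[m$indices] > 0.5
  expect_equal(f$indices, m$indices[keep, , drop = FALSE], ignore_attr = TRUE)
  # boundary is strict
  gm_half <- array(0.5, c(8, 8, 8)); gm_half[1:4, , ] <- 0.6
  f2 <- gray_matter_filter(m, gm_half)
  expect_true(all(f2$indices[, 1] <= 4))
})

test_that("equate_size finds the smallest threshold meeting the target", {
  g <- voi_grid(c(10, 10, 1), voxel_size = 3)
  ramp <- array(seq(0.01, 1, length.out = 100), c(10, 10, 1))
  res <- equate_size(ramp, target_size = 100, grid = g)
  expect_equal(res$threshold, min(ramp))       # full map survives
  expect_equal(res$size, 100L)

  res1 <- equate_size(ramp, target_size = 1, grid = g)
  expect_equal(res1$size, 1L)
  expect_equal(res1$threshold, max(ramp))

  # sort-and-cut oracle for an intermediate target
  res40 <- equate_size(ramp, target_size = 40, grid = g)
  expect_equal(res40$threshold, sort(as.vector(ramp), decreasing = TRUE)[40])
  expect_equal(res40$size, 40L)

  # monotone: larger threshold never yields more voxels
  counts <- sapply(c(0.2, 0.5, 0.8), function(thr) sum(ramp >= thr))
  expect_true(all(diff(counts) <= 0))

  # unachievable target (massive ties above the cut)
  flat <- array(0.7, c(10, 10, 1))
  expect_error(equate_size(flat, target_size = 10, grid = g), "achievable")

  # gray-matter interaction
  gm <- array(c(rep(1, 50), rep(0, 50)), c(10, 10, 1))
  resg <- equate_size(ramp, target_size = 30, grid = g, gm_map = gm)
  expect_lte(resg$size, 30L)
  expect_true(all(gm[resg$mask$indices] > 0.5))
})

test_that("combine_masks is a set union with grid checking", {
  g <- voi_grid(c(9, 9, 9), voxel_size = 3)
  a <- sphere_mask(c(-6, 0, 0), 4, g)
  b <- sphere_mask(c(6, 0, 0), 4, g)
  u <- combine_masks(list(a, b), name = "ab")
  expect_equal(mask_size(u), mask_size(a) + mask_size(b))   # disjoint

  expect_equal(mask_size(combine_masks(list(a, a))), mask_size(a))

  c_ <- sphere_mask(c(-3, 0, 0), 4, g)
  overlap <- sum(paste(a$indices[, 1], a$indices[, 2], a$indices[, 3]) %in%
                   paste(c_$indices[, 1], c_$indices[, 2], c_$indices[, 3]))
  expect_equal(mask_size(combine_masks(list(a, c_))),
               mask_size(a) + mask_size(c_) - overlap)

  g2 <- voi_grid(c(9, 9, 9), voxel_size = 2)
  expect_error(combine_masks(list(a, sphere_mask(c(0, 0, 0), 4, g2))),
               "grid mismatch")
})

test_that("masks round-trip losslessly through TSV and NIfTI", {
  g <- voi_grid(c(12, 10, 8), voxel_size = 3)
  m <- sphere_mask(c(0, 0, 0), 7, g, name = "roundtrip")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_mask_tsv(m, tsv)
  m2 <- read_mask_tsv(tsv)
  expect_equal(m2$indices, m$indices)
  expect_equal(m2$grid$affine, m$grid$affine)
  expect_equal(m2$name, "roundtrip")

  nii <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask_nifti(m, nii)
  m3 <- read_mask_nifti(nii)
  expect_equal(m3$indices, m$indices, ignore_attr = TRUE)
  expect_equal(m3$grid$affine, m$grid$affine)
})

test_that("mask_timeseries extracts masked voxels in mask order", {
  g <- voi_grid(c(4, 4, 2), voxel_size = 3)
  m <- voi_mask(rbind(c(1, 1, 1), c(2, 3, 2), c(4, 4, 2)), g)
  set.seed(2)
  vol <- array(rnorm(4 * 4 * 2 * 5), c(4, 4, 2, 5))
  ts <- mask_timeseries(vol, m, tr = 2, run = 3)
  expect_equal(dim(ts$values), c(5L, 3L))
  expect_equal(ts$values[4, 2], vol[2, 3, 2, 4])
  expect_error(mask_timeseries(vol[1:3, , , , drop = FALSE], m, tr = 2),
               "do not match")
})
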