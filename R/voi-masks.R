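# Volume-of-interest construction: sphere masks around MNI coordinates,
# gray-matter filtering, probability-map thresholding with size equating,
# and mask union.

#' Define a voxel grid
#'
#' Grid geometry used by all masks and volumes: integer dimensions plus a
#' NIfTI-style affine mapping 0-based voxel indices to mm coordinates
#' (MNI space in typical use). Internally voxel indices are 1-based (R
#' convention); the affine is applied to `index - 1`.
#'
#' @param dim Integer 3-vector of grid dimensions.
#' @param voxel_size Voxel size in mm (scalar or 3-vector, default 3).
#' @param origin mm coordinate of voxel (1,1,1); default centers the grid on
#'   the mm origin.
#' @param affine Optional full 4x4 affine overriding `voxel_size`/`origin`.
#' @return A `voi_grid` object.
#' @export
voi_grid <- function(dim, voxel_size = 3, origin = NULL, affine = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  if (is.null(affine)) {
    vs <- rep_len(as.numeric(voxel_size), 3L)
    if (is.null(origin)) origin <- -(dim - 1L) / 2 * vs
    affine <- diag(4)
    diag(affine)[1:3] <- vs
    affine[1:3, 4] <- origin
  }
  stopifnot(all(dim(affine) == c(4L, 4L)))
  structure(list(dim = dim, affine = affine), class = "voi_grid")
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) && max(abs(a$affine - b$affine)) <= tol
}

# mm coordinates of voxel centers for an n x 3 matrix of 1-based indices.
voxel_centers <- function(grid, idx) {
  idx0 <- cbind(idx - 1L, 1)
  t(grid$affine %*% t(idx0))[, 1:3, drop = FALSE]
}

#' Volume of interest mask
#'
#' @param indices n x 3 integer matrix of 1-based voxel indices.
#' @param grid A `voi_grid`.
#' @param name Mask name.
#' @param provenance Named list describing how the mask was built (sphere
#'   center and radius, probability map and threshold, components of a
#'   union, ...).
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(indices, grid, name = "voi", provenance = list()) {
  stopifnot(inherits(grid, "voi_grid"))
  indices <- matrix(as.integer(indices), ncol = 3L)
  if (nrow(indices) == 0L) stopf("mask '%s' is empty", name)
  if (any(indices < 1L) ||
      any(indices > matrix(grid$dim, nrow(indices), 3L, byrow = TRUE))) {
    stopf("mask '%s' has voxel indices outside the grid", name)
  }
  lin <- (indices[, 3] - 1L) * grid$dim[1] * grid$dim[2] +
    (indices[, 2] - 1L) * grid$dim[1] + indices[, 1]
  if (anyDuplicated(lin)) stopf("mask '%s' has duplicate voxels", name)
  o <- order(lin)
  structure(list(indices = indices[o, , drop = FALSE], grid = grid,
                 name = name, provenance = provenance),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> '%s': %d voxels on a %s grid\n",
              x$name, nrow(x$indices), paste(x$grid$dim, collapse = "x")))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask A `voi_mask`.
#' @return Integer voxel count.
#' @export
mask_size <- function(mask) nrow(mask$indices)

#' Spherical mask around a mm-space coordinate
#'
#' Selects every voxel whose center lies within `radius` mm (Euclidean,
#' center-to-center) of `center` — the standard deterministic
#' voxel-center-in-sphere criterion, not partial-volume.
#'
#' @param center mm coordinate triple (e.g., an MNI peak).
#' @param radius Sphere radius in mm (> 0); 12 mm is the conventional choice
#'   for coordinate-defined parietal regions.
#' @param grid A `voi_grid`.
#' @param name Mask name.
#' @return A `voi_mask` with sphere provenance.
#' @export
sphere_mask <- function(center, radius, grid, name = "sphere") {
  stopifnot(inherits(grid, "voi_grid"), length(center) == 3L)
  if (radius <= 0) stopf("radius must be > 0")
  idx <- as.matrix(expand.grid(i = seq_len(grid$dim[1]),
                               j = seq_len(grid$dim[2]),
                               k = seq_len(grid$dim[3])))
  mm <- voxel_centers(grid, idx)
  d2 <- (mm[, 1] - center[1])^2 + (mm[, 2] - center[2])^2 + (mm[, 3] - center[3])^2
  keep <- d2 <= radius^2 + 1e-9
  if (!any(keep)) stopf("sphere at (%s), radius %g mm contains no voxel center",
                        paste(center, collapse = ", "), radius)
  voi_mask(idx[keep, , drop = FALSE], grid, name = name,
           provenance = list(kind = "sphere", center = as.numeric(center),
                             radius = radius))
}

#' Restrict a mask to gray matter
#'
#' Keeps only voxels whose gray-matter probability strictly exceeds the
#' threshold ("more than 50% gray matter" at the default).
#'
#' @param mask A `voi_mask`.
#' @param gm_map 3D array of gray-matter probabilities on the same grid.
#' @param threshold Strict lower bound (default 0.5).
#' @return The filtered `voi_mask`.
#' @export
gray_matter_filter <- function(mask, gm_map, threshold = 0.5) {
  stopifnot(inherits(mask, "voi_mask"))
  if (!identical(dim(gm_map), as.integer(mask$grid$dim))) {
    stopf("gray-matter map dimensions %s do not match grid %s",
          paste(dim(gm_map), collapse = "x"),
          paste(mask$grid$dim, collapse = "x"))
  }
  p <- gm_map[mask$indices]
  keep <- p > threshold
  if (!any(keep)) {
    stopf("no voxel of '%s' exceeds gray-matter probability %g (subject/VOI mismatch?)",
          mask$name, threshold)
  }
  voi_mask(mask$indices[keep, , drop = FALSE], mask$grid, name = mask$name,
           provenance = c(mask$provenance,
                          list(gray_matter_threshold = threshold)))
}

#' Equate mask size by raising a probability-map threshold
#'
#' Finds the smallest threshold on a (maximum-)probability map such that the
#' number of surviving voxels (probability >= threshold, optionally after
#' gray-matter filtering) does not exceed `target_size`. The search bisects
#' over the map's distinct values, exploiting the monotone relation between
#' threshold and surviving count.
#'
#' @param prob_map 3D array of probabilities.
#' @param target_size Target voxel count (>= 1).
#' @param grid A `voi_grid` matching `prob_map`.
#' @param gm_map Optional gray-matter probability array; voxels must also
#'   exceed `gm_threshold` there.
#' @param gm_threshold Strict gray-matter cut (default 0.5).
#' @param name Mask name.
#' @return List with `threshold`, `mask` (a `voi_mask`), and `size`.
#' @export
equate_size <- function(prob_map, target_size, grid, gm_map = NULL,
                        gm_threshold = 0.5, name = "equated") {
  stopifnot(inherits(grid, "voi_grid"))
  if (!identical(dim(prob_map), as.integer(grid$dim))) {
    stopf("probability map dimensions do not match grid")
  }
  if (target_size < 1) stopf("target_size must be >= 1")
  eligible <- prob_map > 0
  if (!is.null(gm_map)) eligible <- eligible & (gm_map > gm_threshold)
  vals <- prob_map[eligible]
  if (length(vals) == 0L) stopf("no eligible voxel (all zero probability or non-gray)")
  count_at <- function(thr) sum(vals >= thr)
  distinct <- sort(unique(vals))                 # ascending; count_at is non-increasing
  if (count_at(distinct[length(distinct)]) > target_size) {
    stopf("target size %d unachievable: achievable range is [%d, %d] voxels",
          target_size, count_at(distinct[length(distinct)]), length(vals))
  }
  lo <- 1L; hi <- length(distinct)               # find smallest value with count <= target
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (count_at(distinct[mid]) <= target_size) hi <- mid else lo <- mid + 1L
  }
  threshold <- distinct[lo]
  keep <- eligible & (prob_map >= threshold)
  idx <- which(keep, arr.ind = TRUE)
  mask <- voi_mask(idx, grid, name = name,
                   provenance = list(kind = "probability_map",
                                     threshold = threshold,
                                     target_size = as.integer(target_size),
                                     gray_matter_threshold =
                                       if (is.null(gm_map)) NULL else gm_threshold))
  list(threshold = threshold, mask = mask, size = mask_size(mask))
}

#' Union of masks on a common grid
#'
#' Set union of the voxel index sets (e.g., summing cytoarchitectonic
#' subdivisions into one region); provenance lists the component masks.
#'
#' @param masks List of `voi_mask` objects on identical grids.
#' @param name Name of the combined mask.
#' @return A `voi_mask`.
#' @export
combine_masks <- function(masks, name = "combined") {
  if (length(masks) < 1L) stopf("no masks to combine")
  g <- masks[[1]]$grid
  for (m in masks[-1]) {
    if (!same_grid(g, m$grid)) {
      stopf("grid mismatch between '%s' and '%s'", masks[[1]]$name, m$name)
    }
  }
  idx <- unique(do.call(rbind, lapply(masks, `[[`, "indices")))
  voi_mask(idx, g, name = name,
           provenance = list(kind = "union",
                             components = vapply(masks, `[[`, "", "name")))
}

#' Extract masked voxels from a 4D volume as a time series
#'
#' @param vol4d 4D array (x, y, z, time) on the mask's grid.
#' @param mask A `voi_mask`.
#' @param tr Repetition time in seconds.
#' @param run Run identifier.
#' @return A `voxel_timeseries` (time x voxel) in mask voxel order.
#' @export
mask_timeseries <- function(vol4d, mask, tr, run = 1L) {
  stopifnot(inherits(mask, "voi_mask"), length(dim(vol4d)) == 4L)
  if (!identical(dim(vol4d)[1:3], as.integer(mask$grid$dim))) {
    stopf("volume dimensions do not match mask grid")
  }
  n_t <- dim(vol4d)[4]
  vals <- vapply(seq_len(n_t), function(t) {
    vol4d[, , , t][mask$indices]
  }, numeric(nrow(mask$indices)))
  voxel_timeseries(t(vals), tr = tr, run = run,
                   voxel_ids = seq_len(nrow(mask$indices)))
}
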