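# Shared resampling plumbing. All resampling is trilinear with out-of-field
# values set to 0 (air); masks stay continuous unless explicitly binarized.

# Resample src onto dst_grid through a world-space affine A (dst world ->
# src world). A = identity resamples src on the new grid.
resample_affine_world <- function(src, dst_grid, A = diag(4)) {
  assert_volume(src)
  dst_grid <- grid_of(dst_grid)
  S <- voxel_from_world(src) %*% A %*% dst_grid$world_from_voxel
  out <- cpp_resample_affine(list(src$data), dim(src$data), S, dst_grid$dim)
  volume_on_grid(dst_grid, out[[1]], src$description)
}

# Sample several arrays that share src_grid at world points (n x 3).
sample_world_points <- function(arrays, src_grid, pts) {
  src_grid <- grid_of(src_grid)
  M <- solve(src_grid$world_from_voxel)
  px <- M[1, 1] * pts[, 1] + M[1, 2] * pts[, 2] + M[1, 3] * pts[, 3] + M[1, 4]
  py <- M[2, 1] * pts[, 1] + M[2, 2] * pts[, 2] + M[2, 3] * pts[, 3] + M[2, 4]
  pz <- M[3, 1] * pts[, 1] + M[3, 2] * pts[, 2] + M[3, 3] * pts[, 3] + M[3, 4]
  cpp_sample_points(arrays, src_grid$dim, px, py, pz)
}

#' Reslice a volume to isotropic voxels
#'
#' Trilinear reslicing onto an isotropic grid, preserving the field of view
#' within one voxel. When the world `x = 0` plane lies inside the field of
#' view the new x-axis grid is made symmetric about it (a voxel-centre column
#' exactly at `x = 0`), which is the precondition for grid-exact sagittal
#' flipping.
#'
#' @param vol an [image_volume] with an axis-aligned grid.
#' @param target_mm isotropic voxel size in mm (default 0.5).
#' @return The resliced [image_volume].
#' @export
reslice_isotropic <- function(vol, target_mm = 0.5) {
  assert_volume(vol)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("`target_mm` must be a single positive number", call. = FALSE)
  if (!is_axis_aligned(vol))
    stop("reslice_isotropic requires an axis-aligned (RAS) grid; reorient first",
         call. = FALSE)
  h <- target_mm
  coords <- lapply(1:3, function(a) {
    cs <- axis_coords(vol, a)
    lo <- min(cs); hi <- max(cs)
    if (a == 1L && lo <= 0 && hi >= 0) {
      k <- ceiling(max(-lo, hi) / h - 1e-9)
      h * (-k:k)
    } else {
      n <- max(1L, ceiling((hi - lo) / h - 1e-9) + 1L)
      lo + h * (0:(n - 1L))
    }
  })
  m <- diag(c(h, h, h, 1))
  m[1:3, 4] <- vapply(coords, min, 0)
  grid <- vol_grid(vapply(coords, length, 0L), m, rep(h, 3))
  resample_affine_world(vol, grid)
}
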