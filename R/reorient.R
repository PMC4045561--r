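#' Reorient a volume to the AC-PC frame
#'
#' Applies the rigid transform (rotation + translation only, no scaling) that
#' puts the anterior commissure at the world origin, the AC-PC line along the
#' y-axis, and the interhemispheric fissure in the `x = 0` plane, with the
#' z-axis through the fissure and the AC point. The image is resampled
#' trilinearly onto a grid symmetric about the origin, so the result supports
#' grid-exact sagittal flipping.
#'
#' @param vol an [image_volume].
#' @param lm a [landmarks] object in the volume's world coordinates.
#' @param target_mm optional isotropic voxel size of the output grid;
#'   defaults to the input voxel size (minimum across axes).
#' @return The reoriented [image_volume]. The rigid world transform used is
#'   attached as attribute `"acpc_from_world"`.
#' @export
reorient_acpc <- function(vol, lm, target_mm = NULL) {
  assert_volume(vol)
  if (!inherits(lm, "landmarks"))
    stop("`lm` must be a landmarks object", call. = FALSE)
  R <- acpc_rotation(lm)
  # world point p maps to acpc coords R^T (p - AC)
  if (is.null(target_mm)) target_mm <- min(vol$voxel_size)
  # output FOV: transform the 8 input corners, take symmetric cover
  d <- dim(vol$data)
  corners <- as.matrix(expand.grid(range(axis_coords(vol, 1)),
                                   range(axis_coords(vol, 2)),
                                   range(axis_coords(vol, 3))))
  tc <- t(t(corners) - lm$AC) %*% R
  half <- apply(abs(tc), 2, max)
  grid <- symmetric_grid(half, target_mm)
  # map from output (acpc) world coords to input world coords: p = R x + AC
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- lm$AC
  out <- resample_affine_world(vol, grid, A)
  out$description <- vol$description
  attr(out, "acpc_from_world") <- {
    B <- diag(4); B[1:3, 1:3] <- t(R); B[1:3, 4] <- -t(R) %*% lm$AC; B
  }
  out
}

# Rotation matrix with columns = (x, y, z) axes of the AC-PC frame expressed
# in input world coordinates; right-handed RAS.
acpc_rotation <- function(lm) {
  yv <- lm$AC - lm$PC              # AC anterior to PC: +y
  yv <- yv / sqrt(sum(yv^2))
  zv <- lm$IH - lm$AC
  zv <- zv - sum(zv * yv) * yv     # orthogonalize against y
  nz <- sqrt(sum(zv^2))
  if (nz < 1e-9)
    stop("IH landmark is collinear with the AC-PC line", call. = FALSE)
  zv <- zv / nz
  xv <- c(yv[2] * zv[3] - yv[3] * zv[2],
          yv[3] * zv[1] - yv[1] * zv[3],
          yv[1] * zv[2] - yv[2] * zv[1])
  cbind(xv, yv, zv, deparse.level = 0)
}

# Apply the stored acpc transform to world points (n x 3): used to carry
# landmarks along with a reorientation.
transform_points <- function(M, pts) {
  pts <- rbind(t(pts), 1)
  t((M %*% pts)[1:3, , drop = FALSE])
}
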