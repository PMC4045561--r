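#' 3D image volume with world-coordinate mapping
#'
#' The basic container used throughout the package: a 3D scalar array plus a
#' 4x4 homogeneous matrix mapping 0-based voxel indices to RAS world
#' coordinates in millimetres (voxel centres). Intensity images, binary
#' masks and probability maps all use this type.
#'
#' @param data 3D numeric array; all values must be finite.
#' @param voxel_size length-3 numeric, mm per axis. Ignored when
#'   `world_from_voxel` is supplied.
#' @param origin world coordinates (mm) of the centre of voxel `[1,1,1]`.
#'   Defaults to centring the grid on the world origin.
#' @param world_from_voxel optional full 4x4 homogeneous matrix (voxel
#'   indices are 0-based). Overrides `voxel_size`/`origin`.
#' @param description free-text description carried with the volume.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size = c(1, 1, 1), origin = NULL,
                         world_from_voxel = NULL, description = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("image values must all be finite", call. = FALSE)
  if (is.null(world_from_voxel)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
    if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
        any(voxel_size <= 0))
      stop("`voxel_size` must be 3 strictly positive values", call. = FALSE)
    if (is.null(origin)) origin <- -voxel_size * (dim(data) - 1) / 2
    world_from_voxel <- diag(c(voxel_size, 1))
    world_from_voxel[1:3, 4] <- origin
  } else {
    world_from_voxel <- as.matrix(world_from_voxel)
    if (!all(dim(world_from_voxel) == c(4L, 4L)) ||
        !all(is.finite(world_from_voxel)))
      stop("`world_from_voxel` must be a finite 4x4 matrix", call. = FALSE)
    voxel_size <- sqrt(colSums(world_from_voxel[1:3, 1:3]^2))
    if (any(voxel_size <= 0))
      stop("`world_from_voxel` has a degenerate axis", call. = FALSE)
  }
  structure(list(data = data, voxel_size = voxel_size,
                 world_from_voxel = world_from_voxel,
                 description = as.character(description)[1]),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (mm): [%.3f, %.3f, %.3f]  range: [%.4g, %.4g]\n",
              x$world_from_voxel[1, 4], x$world_from_voxel[2, 4],
              x$world_from_voxel[3, 4], min(x$data), max(x$data)))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

#' @export
as.array.image_volume <- function(x, ...) x$data

#' @export
dim.image_volume <- function(x) dim(x$data)

is_image_volume <- function(x) inherits(x, "image_volume")

assert_volume <- function(x, what = "volume") {
  if (!is_image_volume(x))
    stop(sprintf("`%s` must be an image_volume", what), call. = FALSE)
  invisible(x)
}

# TRUE when the voxel-to-world mapping is a positive scaling plus translation
# (RAS axis-aligned grid). flip/hemisphere operations require this.
is_axis_aligned <- function(vol) {
  m <- vol$world_from_voxel[1:3, 1:3]
  off <- m - diag(diag(m))
  all(abs(off) < 1e-9) && all(diag(m) > 0)
}

voxel_from_world <- function(vol) solve(vol$world_from_voxel)

# World coordinates of the voxel centres along one axis (axis-aligned grids).
axis_coords <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$world_from_voxel[axis, 4] +
    vol$world_from_voxel[axis, axis] * (seq_len(n) - 1)
}

# A grid is geometry without data: dim + world_from_voxel.
vol_grid <- function(dim, world_from_voxel, voxel_size = NULL) {
  if (is.null(voxel_size))
    voxel_size <- sqrt(colSums(world_from_voxel[1:3, 1:3]^2))
  structure(list(dim = as.integer(dim), world_from_voxel = world_from_voxel,
                 voxel_size = voxel_size), class = "vol_grid")
}

grid_of <- function(vol) {
  if (inherits(vol, "vol_grid")) return(vol)
  vol_grid(dim(vol$data), vol$world_from_voxel, vol$voxel_size)
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- grid_of(a); gb <- grid_of(b)
  all(ga$dim == gb$dim) &&
    max(abs(ga$world_from_voxel - gb$world_from_voxel)) < tol
}

volume_on_grid <- function(grid, data, description = "") {
  grid <- grid_of(grid)
  dim(data) <- grid$dim
  image_volume(data, world_from_voxel = grid$world_from_voxel,
               description = description)
}

grid_axis_coords <- function(grid, axis) {
  grid <- grid_of(grid)
  grid$world_from_voxel[axis, 4] +
    grid$world_from_voxel[axis, axis] * (seq_len(grid$dim[axis]) - 1)
}

# n x 3 matrix of world coordinates of all voxel centres (axis-aligned),
# in array (column-major) order; or only for the voxels in `idx`.
grid_world_points <- function(grid, idx = NULL) {
  grid <- grid_of(grid)
  d <- grid$dim
  xs <- grid_axis_coords(grid, 1)
  ys <- grid_axis_coords(grid, 2)
  zs <- grid_axis_coords(grid, 3)
  if (is.null(idx)) {
    cbind(rep(xs, times = d[2] * d[3]),
          rep(rep(ys, each = d[1]), times = d[3]),
          rep(zs, each = d[1] * d[2]))
  } else {
    i0 <- idx - 1L
    cbind(xs[(i0 %% d[1]) + 1L],
          ys[((i0 %/% d[1]) %% d[2]) + 1L],
          zs[(i0 %/% (d[1] * d[2])) + 1L])
  }
}

# Symmetric 1D grid of centres about 0 covering [-half, half]: odd count,
# one voxel centre exactly at 0 so sagittal flipping is an index reversal.
symmetric_axis <- function(half_extent, step) {
  k <- ceiling(half_extent / step - 1e-9)
  step * (-k:k)
}

# Build an axis-aligned grid with all three axes symmetric about the world
# origin (used by the phantom and by AC-PC reorientation output grids).
symmetric_grid <- function(half_extent, voxel_mm) {
  voxel_mm <- rep(as.numeric(voxel_mm), length.out = 3)
  half_extent <- rep(as.numeric(half_extent), length.out = 3)
  xs <- lapply(1:3, function(a) symmetric_axis(half_extent[a], voxel_mm[a]))
  m <- diag(c(voxel_mm, 1))
  m[1:3, 4] <- vapply(xs, min, 0)
  vol_grid(vapply(xs, length, 0L), m, voxel_mm)
}

# Total volume (mm^3) of the nonzero voxels of a mask.
mask_volume_mm3 <- function(vol, threshold = 0.5) {
  assert_volume(vol)
  sum(vol$data >= threshold) * prod(vol$voxel_size)
}

gaussian_smooth <- function(vol, fwhm_mm) {
  assert_volume(vol)
  if (fwhm_mm <= 0) return(vol)
  sigma_vox <- (fwhm_mm / 2.3548) / vol$voxel_size
  sm <- cpp_gauss_smooth(vol$data, dim(vol$data), sigma_vox)
  volume_on_grid(grid_of(vol), sm, vol$description)
}
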