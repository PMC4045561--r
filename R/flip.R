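#' Sagittal (left-right) flip of a volume
#'
#' Mirrors a volume across the midsagittal plane `x = 0` by pure index
#' reversal: `out(x, y, z) = in(-x, y, z)` with no interpolation, so
#' `flip_sagittal` is an exact involution and the voxel-value multiset is
#' preserved bit-exactly. This requires the x voxel centres to be symmetric
#' about `x = 0` (guaranteed after [reslice_isotropic] or [reorient_acpc]).
#'
#' @param vol an [image_volume] on a grid symmetric about `x = 0`.
#' @return The flipped [image_volume]; the world mapping is unchanged.
#' @export
flip_sagittal <- function(vol) {
  assert_volume(vol)
  check_flip_grid(vol)
  n <- dim(vol$data)[1]
  out <- vol
  out$data <- vol$data[n:1, , , drop = FALSE]
  out
}

# TRUE when the grid supports grid-exact flipping about x = 0.
flip_grid_ok <- function(vol, tol = 1e-6) {
  if (!is_axis_aligned(vol)) return(FALSE)
  xs <- axis_coords(vol, 1)
  max(abs(xs + rev(xs))) < tol
}

check_flip_grid <- function(vol) {
  if (!flip_grid_ok(vol))
    stop(paste("grid is not symmetric about the x = 0 plane;",
               "reslice with reslice_isotropic() or reorient_acpc() first"),
         call. = FALSE)
  invisible(vol)
}
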