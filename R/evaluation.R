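#' Voxelwise asymmetry index
#'
#' `AI = 2 (Original - mirror) / (Original + mirror)`, where the mirror is
#' the grid-exact sagittal flip. A signed, scale-free measure of left-right
#' intensity difference: positive values on the right side of the image mean
#' the right-hemisphere voxel is more intense than its left counterpart.
#' Voxels where `Original + mirror = 0` (symmetric air) get AI 0 rather than
#' NaN. For nonnegative inputs `|AI| <= 2`, and the map is antisymmetric:
#' `ai(x, y, z) = -ai(-x, y, z)`.
#'
#' @param vol an [image_volume] on a flip-exact grid.
#' @param mask optional [image_volume]; AI is zeroed outside its support.
#' @return A list of class `asymmetry_map` with elements `ai`
#'   ([image_volume]) and `mask`.
#' @export
asymmetry_index <- function(vol, mask = NULL) {
  assert_volume(vol)
  mirr <- flip_sagittal(vol)
  num <- 2 * (vol$data - mirr$data)
  den <- vol$data + mirr$data
  ai <- array(0, dim(vol$data))
  nz <- den != 0
  ai[nz] <- num[nz] / den[nz]
  if (!is.null(mask)) {
    assert_volume(mask, "mask")
    if (!same_grid(vol, mask))
      stop("mask must share the volume grid", call. = FALSE)
    ai[mask$data <= 0] <- 0
  }
  structure(list(ai = volume_on_grid(grid_of(vol), ai, "asymmetry index"),
                 mask = mask), class = "asymmetry_map")
}

#' Original-minus-flipped difference image
#'
#' `vol - flip_sagittal(vol)`, the signed voxelwise difference between the
#' two sides of the head; identically zero for a symmetric atlas and
#' antisymmetric for any input.
#'
#' @param vol an [image_volume] on a flip-exact grid.
#' @return The difference [image_volume].
#' @export
difference_image <- function(vol) {
  assert_volume(vol)
  mirr <- flip_sagittal(vol)
  volume_on_grid(grid_of(vol), vol$data - mirr$data,
                 paste("difference", vol$description))
}

#' Left-minus-right percentage difference
#'
#' The volume-report arithmetic: each hemisphere's share of a structure's
#' total volume in percent, and their difference in percentage points.
#'
#' @param left_pct,right_pct hemispheric percentages of one structure.
#' @return `left_pct - right_pct`.
#' @export
lr_difference <- function(left_pct, right_pct) left_pct - right_pct

# Left/right volumes (mm^3) of one structure; voxels centred exactly on
# x = 0 are split half to each hemisphere. `weights` NULL counts thresholded
# voxels, otherwise sums continuous mass.
hemisphere_volumes <- function(vol, threshold = 0.5, continuous = FALSE) {
  if (!is_axis_aligned(vol))
    stop("hemisphere volumes require an axis-aligned grid", call. = FALSE)
  xs <- axis_coords(vol, 1)
  vals <- if (continuous) vol$data else (vol$data >= threshold) * 1
  colsum_x <- apply(vals, 1, sum)
  vv <- prod(vol$voxel_size)
  tol <- 1e-9 * max(abs(xs), 1)
  left <- sum(colsum_x[xs < -tol]) * vv
  right <- sum(colsum_x[xs > tol]) * vv
  mid <- sum(colsum_x[abs(xs) <= tol]) * vv
  c(left = left + mid / 2, right = right + mid / 2)
}

#' Hemispheric volume report
#'
#' For each structure (brain, CSF) computes the left and right hemispheric
#' volume as a percentage of that structure's total, and their difference in
#' percentage points (`left - right`). The left hemisphere is `x < 0` in RAS
#' world coordinates; midline voxel columns are split half to each side, so
#' a perfectly mirrored mask reports exactly 50/50. Probability maps are
#' thresholded at `threshold` for the primary rows; rows computed from the
#' continuous probability mass are reported alongside (`method = "mass"`).
#'
#' @param brain,csf [image_volume]s: binary masks or probability maps on one
#'   grid.
#' @param threshold binarization threshold for probability maps.
#' @param label row label (subject or atlas name).
#' @return A data.frame with columns `label`, `structure`, `method`,
#'   `left_pct`, `right_pct`, `diff_pct`, `left_mm3`, `right_mm3`.
#' @export
hemisphere_volume_report <- function(brain, csf, threshold = 0.5,
                                     label = "subject") {
  assert_volume(brain, "brain"); assert_volume(csf, "csf")
  if (!same_grid(brain, csf))
    stop("brain and csf must share a grid", call. = FALSE)
  rows <- list()
  for (method in c("threshold", "mass")) {
    cont <- method == "mass"
    for (structure in c("brain", "csf")) {
      v <- if (structure == "brain") brain else csf
      lr <- hemisphere_volumes(v, threshold, continuous = cont)
      tot <- sum(lr)
      if (tot <= 0)
        stop(sprintf("empty structure: %s", structure), call. = FALSE)
      lp <- 100 * lr[["left"]] / tot
      rp <- 100 * lr[["right"]] / tot
      rows[[length(rows) + 1]] <- data.frame(
        label = label, structure = structure, method = method,
        left_pct = lp, right_pct = rp,
        diff_pct = lr_difference(lp, rp),
        left_mm3 = lr[["left"]], right_mm3 = lr[["right"]])
    }
  }
  do.call(rbind, rows)
}

#' Symmetry evaluation of an atlas
#'
#' Asymmetry-index maps and original-minus-flipped difference images for the
#' template and both probabilistic models, plus the hemispheric volume
#' report of the probability maps.
#'
#' @param atlas a [brain_atlas].
#' @param threshold probability threshold for the volume report.
#' @return A list with `ai` (list of [asymmetry_index] results per
#'   component), `differences` (list of difference [image_volume]s),
#'   `report` (data.frame), and `max_abs_difference` (named numeric).
#' @export
evaluate_atlas <- function(atlas, threshold = 0.5) {
  stopifnot(inherits(atlas, "brain_atlas"))
  comps <- list(template = atlas$template, brain = atlas$brain_prob,
                csf = atlas$csf_prob)
  ai <- lapply(comps, asymmetry_index)
  diffs <- lapply(comps, difference_image)
  report <- hemisphere_volume_report(atlas$brain_prob, atlas$csf_prob,
                                     threshold = threshold,
                                     label = paste0("atlas_pass_",
                                                    atlas$pass_index))
  list(ai = ai, differences = diffs, report = report,
       max_abs_difference = vapply(diffs, function(d) max(abs(d$data)), 0))
}
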