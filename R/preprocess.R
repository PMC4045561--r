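#' Brain / CSF / intracranial mask triple
#'
#' Binary brain and CSF masks plus their union, the intracranial (IC) mask
#' used to weight registration so scalp and skull do not drive the alignment.
#' Brain and CSF must be disjoint and share the source image grid.
#'
#' @param brain,csf binary [image_volume]s on the same grid.
#' @return An object of class `tissue_masks` with elements `brain`, `csf`,
#'   `ic`.
#' @export
tissue_masks <- function(brain, csf) {
  assert_volume(brain, "brain"); assert_volume(csf, "csf")
  if (!same_grid(brain, csf))
    stop("brain and csf masks must share a grid", call. = FALSE)
  if (any(brain$data * csf$data != 0))
    stop("brain and csf masks overlap", call. = FALSE)
  ic <- volume_on_grid(grid_of(brain),
                       pmax(brain$data, csf$data), "intracranial mask")
  structure(list(brain = brain, csf = csf, ic = ic), class = "tissue_masks")
}

#' Reduce smooth multiplicative intensity nonuniformity
#'
#' Iteratively estimates a smooth multiplicative field in the log domain and
#' divides it out. The field model is a separable two-harmonic Fourier
#' basis (1, cos, sin up to second order per axis) over the mask's bounding
#' box -- the scale of scanner coil nonuniformity, and deliberately far
#' smoother than anatomy. At each iteration the masked log-intensities are
#' referenced to their robust tissue-class levels (3-class 1D quantization,
#' per-class medians) so anatomical contrast does not leak into the field,
#' partial-volume outliers are trimmed at 3 MAD, and the fitted field is
#' divided out; iterations stop when the remaining field is flat. The mean
#' intensity within the mask is preserved.
#'
#' @param vol intensity [image_volume]; values inside the mask must be
#'   strictly positive.
#' @param mask [image_volume] whose nonzero voxels define the estimation
#'   region (typically the head or IC mask).
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the per-iteration log-field range.
#' @return The bias-corrected [image_volume]; the estimated total field is
#'   attached as attribute `"bias_field"`.
#' @export
bias_correct <- function(vol, mask, max_iter = 6, tol = 1e-3) {
  assert_volume(vol); assert_volume(mask, "mask")
  if (!same_grid(vol, mask))
    stop("volume and mask must share a grid", call. = FALSE)
  m <- mask$data > 0
  if (!any(m)) stop("mask is empty", call. = FALSE)
  if (any(vol$data[m] <= 0))
    stop("intensities inside the mask must be strictly positive",
         call. = FALSE)
  d <- dim(vol$data)
  g <- grid_of(vol)
  # basis support: the mask's bounding box (padded half a voxel), so the
  # fit is well conditioned on head-shaped supports much smaller than the
  # field of view
  midx <- which(m)
  mbox <- lapply(1:3, function(a) {
    cs <- grid_axis_coords(g, a)
    i0 <- midx - 1L
    ia <- switch(a, (i0 %% d[1]) + 1L, ((i0 %/% d[1]) %% d[2]) + 1L,
                 (i0 %/% (d[1] * d[2])) + 1L)
    range(cs[ia]) + c(-0.5, 0.5) * vol$voxel_size[a]
  })
  # two harmonics per axis: enough for the log of a smooth product field,
  # smooth enough that anatomy cannot be absorbed
  J <- c(2L, 2L, 2L)
  korder <- 2L * J + 1L
  Bfull <- lapply(1:3, function(a)
    fourier_basis_matrix(grid_axis_coords(g, a), mbox[[a]], J[a]))
  idx <- which(m)
  fit_idx <- if (length(idx) > 40000)
    idx[seq(1, length(idx), length.out = 40000)] else idx
  i0 <- fit_idx - 1L
  bi <- list((i0 %% d[1]) + 1L, ((i0 %/% d[1]) %% d[2]) + 1L,
             (i0 %/% (d[1] * d[2])) + 1L)
  Bpts <- lapply(1:3, function(a) Bfull[[a]][bi[[a]], , drop = FALSE])
  # design matrix over the fit points (Kronecker of per-axis bases)
  p <- prod(korder)
  X <- matrix(0, length(fit_idx), p)
  col <- 0L
  for (kz in seq_len(korder[3]))
    for (ky in seq_len(korder[2]))
      for (kx in seq_len(korder[1])) {
        col <- col + 1L
        X[, col] <- Bpts[[1]][, kx] * Bpts[[2]][, ky] * Bpts[[3]][, kz]
      }
  cur <- vol$data
  total_lf <- array(0, d)
  multi_class <- NA
  for (it in seq_len(max_iter)) {
    lv <- log(cur[fit_idx])
    if (it == 1) multi_class <- is_multi_class(lv, X)
    ref <- if (multi_class) class_log_means(lv) else rep(mean(lv),
                                                         length(lv))
    # trim partial-volume outliers (thin-interface voxels far from any
    # class mean) so they cannot pull the smooth fit
    r <- lv - ref
    keep <- abs(r) <= max(3 * stats::mad(r), 0.02)
    if (sum(keep) < 200) break
    G <- crossprod(X[keep, , drop = FALSE])
    G <- G + diag(1e-5 * mean(diag(G)), p)
    beta <- solve(G, crossprod(X[keep, , drop = FALSE], r[keep]))
    C <- array(beta, korder)
    lf <- ttm(ttm(ttm(C, Bfull[[1]], 1), Bfull[[2]], 2), Bfull[[3]], 3)
    # the field is only estimated inside the mask; clamp the global
    # evaluation to the in-mask range so basis extrapolation cannot blow
    # background intensities up
    lf <- pmin(pmax(lf, min(lf[m])), max(lf[m]))
    lf <- lf - mean(lf[m])
    cur <- cur / exp(lf)
    total_lf <- total_lf + lf
    if (max(abs(lf[m])) < tol) break
  }
  corrected <- cur * (mean(vol$data[m]) / mean(cur[m]))
  out <- volume_on_grid(grid_of(vol), corrected, vol$description)
  attr(out, "bias_field") <- exp(total_lf)
  out
}

# Per-axis field basis: 1, cos(pi j t), sin(pi j t), j = 1..J, on the
# normalized axis coordinate; a smooth field of any phase is representable.
fourier_basis_matrix <- function(coords, rng, J) {
  t <- (coords - rng[1]) / max(rng[2] - rng[1], 1e-9)
  B <- matrix(1, length(coords), 2 * J + 1)
  for (j in seq_len(J)) {
    B[, 2 * j] <- cos(pi * j * t)
    B[, 2 * j + 1] <- sin(pi * j * t)
  }
  B
}

fit_three_classes <- function(lv) {
  centers <- stats::quantile(lv, c(0.2, 0.5, 0.8), names = FALSE)
  if (length(unique(centers)) < 3)
    centers <- min(lv) + diff(range(lv)) * c(0.25, 0.5, 0.75)
  stats::kmeans(lv, centers = matrix(centers, 3, 1), iter.max = 50,
                algorithm = "Lloyd")
}

# Model comparison deciding whether the masked intensities carry genuine
# tissue-class structure: the 3-class quantization is trusted only when it
# explains the log-intensities clearly better than the smooth spatial field
# model alone. A smooth field over a homogeneous region is fitted almost
# perfectly by the field model (so classes are rejected and the field is
# removed directly), while tissue steps cannot be absorbed by a smooth
# field (so the class reference protects anatomy).
is_multi_class <- function(lv, X) {
  if (length(unique(lv)) < 3) return(FALSE)
  r0 <- lv - mean(lv)
  G <- crossprod(X)
  G <- G + diag(1e-5 * mean(diag(G)), ncol(X))
  v_field <- mean((r0 - X %*% solve(G, crossprod(X, r0)))^2)
  km <- fit_three_classes(lv)
  med <- vapply(1:3, function(k) stats::median(lv[km$cluster == k]), 0)
  v_class <- mean((lv - med[km$cluster])^2)
  v_class < 0.5 * v_field
}

# Per-point tissue-class reference: 1D 3-class quantization of the masked
# log-intensities (fixed quantile initialization, hence deterministic).
# The per-class reference is the median, which partial-volume members of a
# class cannot drag the way they drag the mean.
class_log_means <- function(lv) {
  if (length(unique(lv)) < 3) return(rep(mean(lv), length(lv)))
  km <- fit_three_classes(lv)
  med <- vapply(1:3, function(k) stats::median(lv[km$cluster == k]), 0)
  med[km$cluster]
}

#' Segment a head image into brain and CSF
#'
#' A simple intensity-driven pipeline: the head is isolated as the largest
#' connected component above an Otsu background threshold (cavities filled),
#' the head intensities are clustered into three classes by 1D k-means, and
#' classes are assigned by mean intensity -- CSF is the lowest class and
#' brain the highest (set `csf_bright = TRUE` for the opposite contrast).
#' Morphological cleanup keeps the largest brain component and fills its
#' holes; CSF is restricted to the eroded head so partial-volume voxels at
#' the scalp-air boundary are not mislabelled.
#'
#' @param vol intensity [image_volume].
#' @param csf_bright logical; newborn T1 contrast has CSF darker than brain
#'   (`FALSE`, the default).
#' @return A [tissue_masks] object.
#' @export
segment_tissues <- function(vol, csf_bright = FALSE) {
  assert_volume(vol)
  x <- vol$data
  head_mask <- head_region(vol)
  vals <- x[head_mask]
  if (length(unique(vals)) < 3)
    stop("segmentation failure: fewer than 3 intensity classes in the head",
         call. = FALSE)
  centers <- stats::quantile(vals, c(0.15, 0.5, 0.85), names = FALSE)
  if (length(unique(centers)) < 3)
    centers <- min(vals) + diff(range(vals)) * c(0.25, 0.5, 0.75)
  km <- stats::kmeans(vals, centers = matrix(centers, 3, 1),
                      iter.max = 100, algorithm = "Lloyd")
  ord <- order(km$centers)
  cls <- array(0L, dim(x))
  cls[head_mask] <- match(km$cluster, ord)  # 1 = darkest .. 3 = brightest
  brain_cls <- if (csf_bright) 1L else 3L
  csf_cls <- if (csf_bright) 3L else 1L
  brain <- cls == brain_cls
  lab_b <- cpp_label_components(brain, dim(x))
  if (max(lab_b) == 0)
    stop("segmentation failure: no brain-class voxels", call. = FALSE)
  brain <- lab_b == which.max(tabulate(lab_b))
  brain <- cpp_fill_holes(brain, dim(x))
  # CSF: lowest-class voxels whose component touches the brain; this drops
  # the partial-volume ring at the scalp-air boundary, which shares the CSF
  # intensity range but is separated from the shell by scalp
  csf0 <- (cls == csf_cls) & head_mask & !brain
  lab_c <- cpp_label_components(csf0, dim(x))
  near_brain <- dilate1(brain) & csf0
  keep <- unique(lab_c[near_brain])
  keep <- keep[keep > 0]
  csf <- array(lab_c %in% keep, dim(x)) & csf0
  g <- grid_of(vol)
  tissue_masks(volume_on_grid(g, brain * 1, "brain mask"),
               volume_on_grid(g, csf * 1, "csf mask"))
}

#' Intracranial mask and registration weight
#'
#' The binary union of brain and CSF, plus a version smoothed by a Gaussian
#' (default FWHM 1 mm) for use as the weighting image of the registration
#' cost. The unsmoothed union is retained.
#'
#' @param masks a [tissue_masks] object.
#' @param smooth_fwhm Gaussian FWHM in mm for the registration weight; 0
#'   keeps the weight binary.
#' @return A list with `ic` (binary [image_volume]) and `weight` (smoothed
#'   [image_volume]).
#' @export
make_ic_mask <- function(masks, smooth_fwhm = 1) {
  stopifnot(inherits(masks, "tissue_masks"))
  ic <- masks$ic
  if (!any(ic$data > 0)) stop("empty brain + CSF union", call. = FALSE)
  weight <- if (smooth_fwhm > 0) gaussian_smooth(ic, smooth_fwhm) else ic
  list(ic = ic, weight = weight)
}

#' Extract the head region of an intensity volume
#'
#' Otsu background threshold, interior cavities filled (CSF can fall below
#' the background threshold), largest connected component. Used as the
#' estimation region for bias reduction and as the segmentation domain.
#'
#' @param vol intensity [image_volume].
#' @return A logical array over the volume grid.
#' @export
head_region <- function(vol) {
  assert_volume(vol)
  x <- vol$data
  rng <- range(x)
  if (diff(rng) <= 0)
    stop("segmentation failure: constant image", call. = FALSE)
  xn <- (x - rng[1]) / diff(rng)
  thr <- EBImage::otsu(matrix(xn, dim(x)[1], prod(dim(x)[2:3])),
                       range = c(0, 1))
  fg <- xn > thr
  if (!any(fg) || all(fg))
    stop("segmentation failure: could not separate head from background",
         call. = FALSE)
  fg <- cpp_fill_holes(fg, dim(x))
  lab <- cpp_label_components(fg, dim(x))
  lab == which.max(tabulate(lab))
}

# One-step 6-neighbourhood binary dilation.
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

#' Bias-correct every subject of a cohort
#'
#' Convenience wrapper applying [bias_correct] to each record's image using
#' its intracranial mask as the estimation region; intensity nonuniformity
#' must be reduced before the images enter atlas construction, otherwise the
#' registration can mistake smooth intensity differences for geometry.
#'
#' @param records list of [subject_record]s with masks.
#' @return The records with bias-corrected images.
#' @export
bias_correct_cohort <- function(records) {
  lapply(records, function(r) {
    r$image <- bias_correct(r$image, r$masks$ic)
    r
  })
}

# Dice overlap of two binary masks (used throughout the tests).
#' Dice coefficient between two binary masks
#' @param a,b binary [image_volume]s on one grid.
#' @param threshold binarization threshold applied to both.
#' @return Dice overlap in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b, threshold = 0.5) {
  assert_volume(a); assert_volume(b)
  am <- a$data >= threshold; bm <- b$data >= threshold
  2 * sum(am & bm) / max(sum(am) + sum(bm), 1)
}
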