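#' One subject of an atlas cohort
#'
#' Bundles a subject's intensity image, its tissue masks, and provenance
#' (whether the record is an original acquisition or its sagittal mirror).
#'
#' @param image intensity [image_volume].
#' @param masks a [tissue_masks] on the same grid.
#' @param subject_id unique identifier.
#' @param flipped `TRUE` when the record is the mirrored copy of another.
#' @param lm optional [landmarks].
#' @param truth optional list of ground-truth transforms (phantom cohorts).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(image, masks, subject_id, flipped = FALSE,
                           lm = NULL, truth = NULL) {
  assert_volume(image, "image")
  stopifnot(inherits(masks, "tissue_masks"))
  if (!same_grid(image, masks$brain))
    stop("image and masks must share a grid", call. = FALSE)
  structure(list(image = image, masks = masks,
                 subject_id = as.character(subject_id),
                 flipped = isTRUE(flipped), lm = lm, truth = truth),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s%s, %s voxels\n", x$subject_id,
              if (x$flipped) " (flipped)" else "",
              paste(dim(x$image$data), collapse = " x ")))
  invisible(x)
}

flip_record <- function(rec) {
  subject_record(image = flip_sagittal(rec$image),
                 masks = tissue_masks(flip_sagittal(rec$masks$brain),
                                      flip_sagittal(rec$masks$csf)),
                 subject_id = paste0(rec$subject_id, "_flip"),
                 flipped = TRUE, lm = rec$lm, truth = rec$truth)
}

#' Augment a cohort with sagittally flipped copies
#'
#' Returns the 2N records entering atlas construction: the N originals plus
#' a grid-exact sagittal flip of each image and its masks.
#'
#' @param subjects list of [subject_record]s (originals).
#' @return A list of `2 * length(subjects)` records.
#' @export
augment_with_flips <- function(subjects) {
  if (length(subjects) < 1) stop("empty cohort", call. = FALSE)
  c(subjects, lapply(subjects, flip_record))
}

#' Select the reference subject
#'
#' Defaults to an explicit user choice by id. The automatic fallback picks
#' the subject with the least global shape deformation relative to the rest
#' of the cohort: for every pair a coarse affine registration is run and the
#' subject minimizing the mean of `sum(|log scale|) + sum(|shear|)` over its
#' pairings is chosen; ties break deterministically on the lowest id.
#'
#' @param subjects list of [subject_record]s.
#' @param id optional explicit subject id.
#' @param control [reg_control] for the pairwise registrations (coarse
#'   levels are enough).
#' @return The selected [subject_record].
#' @export
select_reference <- function(subjects, id = NULL,
                             control = reg_control(affine_levels = 4)) {
  if (length(subjects) < 1) stop("empty cohort", call. = FALSE)
  ids <- vapply(subjects, function(s) s$subject_id, "")
  if (!is.null(id)) {
    hit <- which(ids == id)
    if (length(hit) != 1) stop(sprintf("no subject with id %s", id),
                               call. = FALSE)
    return(subjects[[hit]])
  }
  if (length(subjects) == 1) return(subjects[[1]])
  n <- length(subjects)
  defo <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      if (i == j) next
      w <- make_ic_mask(subjects[[j]]$masks)$weight
      res <- affine_register(subjects[[i]]$image, subjects[[j]]$image, w,
                             control = control)
      p <- res$transform
      defo[i, j] <- sum(abs(log(p$scale))) + sum(abs(p$shear))
    }
  score <- rowMeans(defo) * n / (n - 1)
  best <- order(score, ids)[1]
  subjects[[best]]
}

#' Atlas: template plus probabilistic brain and CSF models
#' @param template,brain_prob,csf_prob [image_volume]s on one grid;
#'   probability maps valued in `[0, 1]`.
#' @param pass_index 1, 2, or `"final"`.
#' @param provenance free-form list (reference id, transforms, settings).
#' @return An object of class `brain_atlas`.
#' @export
brain_atlas <- function(template, brain_prob, csf_prob, pass_index = 1,
                        provenance = list()) {
  assert_volume(template, "template")
  assert_volume(brain_prob, "brain_prob")
  assert_volume(csf_prob, "csf_prob")
  if (!same_grid(template, brain_prob) || !same_grid(template, csf_prob))
    stop("atlas components must share a grid", call. = FALSE)
  for (p in list(brain_prob, csf_prob))
    if (min(p$data) < -1e-6 || max(p$data) > 1 + 1e-6)
      stop("probability maps must be valued in [0, 1]", call. = FALSE)
  if (max(brain_prob$data + csf_prob$data) > 1 + 1e-6)
    stop("brain_prob + csf_prob exceeds 1", call. = FALSE)
  structure(list(template = template, brain_prob = brain_prob,
                 csf_prob = csf_prob, pass_index = pass_index,
                 provenance = provenance), class = "brain_atlas")
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("<brain_atlas> pass %s, %s voxels\n", x$pass_index,
              paste(dim(x$template$data), collapse = " x ")))
  invisible(x)
}

#' Run one normalization pass over a cohort
#'
#' For every record: affine-register the image to the reference with the
#' intracranial weighting mask and apply the parameters to the image and all
#' masks; nonlinearly register the affine-normalized image with the cosine
#' basis and apply the deformation; numerically invert each deformation to
#' obtain the reference-to-subject map; average those maps over the cohort
#' and apply the average to every normalized image and mask (removing the
#' geometric bias of the reference choice); finally average into the
#' template and the probabilistic brain and CSF models. Records are
#' processed and averaged in subject-id order, so the result does not depend
#' on the input ordering.
#'
#' @param records list of [subject_record]s (typically the 2N output of
#'   [augment_with_flips]).
#' @param reference reference [image_volume] defining the atlas grid.
#' @param ref_weight weighting [image_volume] on the reference grid.
#' @param control a [reg_control].
#' @param pass_index label stored in the atlas.
#' @return A [brain_atlas]; per-subject transforms and objective traces are
#'   in `$provenance`.
#' @export
run_pass <- function(records, reference, ref_weight,
                     control = reg_control(), pass_index = 1) {
  if (length(records) < 1) stop("empty record list", call. = FALSE)
  ids <- vapply(records, function(r) r$subject_id, "")
  if (anyDuplicated(ids))
    stop("subject ids must be unique within a pass", call. = FALSE)
  records <- records[order(ids)]
  grid <- grid_of(reference)
  n <- length(records)
  deformations <- vector("list", n)
  normalized <- vector("list", n)
  transforms <- vector("list", n)
  traces <- vector("list", n)
  mode_kind <- if (control$binarize_masks) TRUE else FALSE
  for (i in seq_len(n)) {
    r <- records[[i]]
    if (control$verbose) message(sprintf("pass %s: %s", pass_index,
                                         r$subject_id))
    ares <- tryCatch(
      affine_register(r$image, reference, ref_weight, control = control),
      error = function(e) stop(sprintf(
        "affine registration failed for subject %s: %s", r$subject_id,
        conditionMessage(e)), call. = FALSE))
    img1 <- apply_affine(ares$transform, r$image, grid)
    b1 <- apply_affine(ares$transform, r$masks$brain, grid, kind = "mask",
                       binarize = mode_kind)
    c1 <- apply_affine(ares$transform, r$masks$csf, grid, kind = "mask",
                       binarize = mode_kind)
    nres <- tryCatch(
      nonlinear_register(img1, reference, ref_weight, control = control),
      error = function(e) stop(sprintf(
        "nonlinear registration failed for subject %s: %s", r$subject_id,
        conditionMessage(e)), call. = FALSE))
    D <- nres$transform
    img2 <- apply_deformation(D, img1)
    b2 <- apply_deformation(D, b1, kind = "mask", binarize = mode_kind)
    c2 <- apply_deformation(D, c1, kind = "mask", binarize = mode_kind)
    deformations[[i]] <- invert_deformation(D,
                                            n_points = control$invert_points)
    normalized[[i]] <- list(image = img2, brain = b2, csf = c2)
    transforms[[i]] <- list(subject_id = r$subject_id,
                            affine = ares$transform, nonlinear = D)
    traces[[i]] <- list(subject_id = r$subject_id,
                        affine = ares$objective_trace,
                        nonlinear = nres$objective_trace)
  }
  tbar <- average_deformation(deformations)
  acc_t <- 0; acc_b <- 0; acc_c <- 0
  for (i in seq_len(n)) {
    acc_t <- acc_t + apply_deformation(tbar, normalized[[i]]$image)$data
    acc_b <- acc_b + apply_deformation(tbar, normalized[[i]]$brain,
                                       kind = "mask",
                                       binarize = mode_kind)$data
    acc_c <- acc_c + apply_deformation(tbar, normalized[[i]]$csf,
                                       kind = "mask",
                                       binarize = mode_kind)$data
  }
  template <- volume_on_grid(grid, acc_t / n, "atlas template")
  bp <- volume_on_grid(grid, pmin(pmax(acc_b / n, 0), 1),
                       "brain probability")
  cpv <- pmin(pmax(acc_c / n, 0), 1)
  # warped brain+csf can overlap marginally after interpolation; keep the sum
  # within 1
  over <- (bp$data + cpv) > 1
  cpv[over] <- 1 - bp$data[over]
  cp <- volume_on_grid(grid, cpv, "csf probability")
  brain_atlas(template, bp, cp, pass_index = pass_index,
              provenance = list(transforms = transforms, traces = traces,
                                average_deformation = tbar,
                                subject_ids = sort(ids)))
}

# IC support of an atlas: brain + csf probability thresholded at 0.5,
# lightly smoothed for use as a registration weight.
atlas_ic_weight <- function(atlas, smooth_fwhm = 1) {
  supp <- (atlas$brain_prob$data + atlas$csf_prob$data) >= 0.5
  v <- volume_on_grid(grid_of(atlas$template), supp * 1, "atlas IC support")
  if (smooth_fwhm > 0) gaussian_smooth(v, smooth_fwhm) else v
}

flip_average_atlas <- function(atlas) {
  half <- function(v) {
    out <- v
    out$data <- (v$data + flip_sagittal(v)$data) / 2
    out
  }
  brain_atlas(half(atlas$template), half(atlas$brain_prob),
              half(atlas$csf_prob), pass_index = "final",
              provenance = atlas$provenance)
}

#' Build the symmetric atlas
#'
#' The full two-pass procedure: the cohort is augmented with sagittal flips;
#' pass 1 normalizes all 2N records to a selected reference subject; pass 2
#' repeats the normalization with the pass-1 template as reference (and its
#' thresholded intracranial support as weighting mask), removing reference
#' asymmetry; finally the pass-2 atlas is averaged with its own sagittal
#' flip, which makes the template and both probability maps exactly
#' flip-invariant.
#'
#' @param subjects list of original (unflipped) [subject_record]s.
#' @param reference_id optional explicit reference subject id; default picks
#'   the least-deformed subject automatically.
#' @param passes number of normalization passes (2, following the original
#'   design; more passes add convergence logging).
#' @param control a [reg_control].
#' @return The final symmetric [brain_atlas]; per-pass RMS template change is
#'   recorded in `$provenance$pass_rms_change`.
#' @export
build_symmetric_atlas <- function(subjects, reference_id = NULL, passes = 2,
                                  control = reg_control()) {
  build_atlas_pipeline(subjects, reference_id, passes, control,
                       symmetric = TRUE)
}

#' Build the asymmetric control atlas
#'
#' Identical pipeline to [build_symmetric_atlas] except the flipped copies
#' are not used and no final flip-averaging is applied; serves as the
#' control that retains cohort asymmetry.
#'
#' @inheritParams build_symmetric_atlas
#' @return The asymmetric [brain_atlas].
#' @export
build_asymmetric_atlas <- function(subjects, reference_id = NULL, passes = 2,
                                   control = reg_control()) {
  build_atlas_pipeline(subjects, reference_id, passes, control,
                       symmetric = FALSE)
}

build_atlas_pipeline <- function(subjects, reference_id, passes, control,
                                 symmetric) {
  if (length(subjects) < 1) stop("empty cohort", call. = FALSE)
  if (passes < 1) stop("at least one pass required", call. = FALSE)
  ref <- select_reference(subjects, id = reference_id)
  records <- if (symmetric) augment_with_flips(subjects) else subjects
  reference <- ref$image
  ref_weight <- make_ic_mask(ref$masks)$weight
  atlas <- NULL
  rms_change <- numeric(0)
  for (p in seq_len(passes)) {
    prev <- atlas
    atlas <- run_pass(records, reference, ref_weight, control = control,
                      pass_index = p)
    if (!is.null(prev)) {
      rms <- sqrt(mean((atlas$template$data - prev$template$data)^2))
      rms_change <- c(rms_change, rms)
      if (control$verbose)
        message(sprintf("pass %d: template RMS change %.5g", p, rms))
    }
    reference <- atlas$template
    ref_weight <- atlas_ic_weight(atlas)
  }
  out <- if (symmetric) flip_average_atlas(atlas) else atlas
  out$provenance$reference_id <- ref$subject_id
  out$provenance$pass_rms_change <- rms_change
  out$provenance$symmetric <- symmetric
  out
}

#' Write an atlas to a directory
#'
#' Writes `template.nii.gz`, `brain_prob.nii.gz`, `csf_prob.nii.gz` and the
#' per-subject transforms as JSON under `transforms/`.
#'
#' @param atlas a [brain_atlas].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "brain_atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(atlas$template, file.path(dir, "template.nii.gz"))
  write_volume(atlas$brain_prob, file.path(dir, "brain_prob.nii.gz"))
  write_volume(atlas$csf_prob, file.path(dir, "csf_prob.nii.gz"))
  tr <- atlas$provenance$transforms
  if (!is.null(tr)) {
    tdir <- file.path(dir, "transforms")
    dir.create(tdir, showWarnings = FALSE)
    for (t in tr) {
      write_transform(t$affine,
                      file.path(tdir, paste0(t$subject_id, "_affine.json")))
      write_transform(t$nonlinear,
                      file.path(tdir, paste0(t$subject_id, "_dct.json")))
    }
  }
  invisible(dir)
}

#' Read an atlas written by [write_atlas]
#' @param dir atlas directory.
#' @param pass_index label to assign.
#' @return A [brain_atlas].
#' @export
read_atlas <- function(dir, pass_index = "final") {
  brain_atlas(read_volume(file.path(dir, "template.nii.gz")),
              read_volume(file.path(dir, "brain_prob.nii.gz")),
              read_volume(file.path(dir, "csf_prob.nii.gz")),
              pass_index = pass_index)
}
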