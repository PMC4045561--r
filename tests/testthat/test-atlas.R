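make_record <- function(ph, id) {
  subject_record(image = ph$image, masks = tissue_masks(ph$brain, ph$csf),
                 subject_id = id, lm = ph$lm)
}

test_that("augment_with_flips returns 2N grid-exact mirrored records", {
  cohort <- tiny_cohort()
  recs <- augment_with_flips(cohort)
  expect_length(recs, 4)
  expect_identical(recs[[3]]$image$data,
                   flip_sagittal(cohort[[1]]$image)$data)
  expect_true(recs[[3]]$flipped)
  # a perfectly symmetric subject equals its own flip
  sym <- make_record(clean_phantom(), "SYM")
  two <- augment_with_flips(list(sym))
  expect_identical(two[[2]]$image$data, two[[1]]$image$data)
  # N = 14 originals give 28 records
  fake14 <- lapply(1:14, function(i) { r <- sym; r$subject_id <-
    sprintf("S%02d", i); r })
  expect_length(augment_with_flips(fake14), 28)
})

test_that("select_reference honors explicit ids and avoids shape outliers", {
  cohort <- tiny_cohort()
  expect_identical(select_reference(cohort, id = "S02")$subject_id, "S02")
  expect_error(select_reference(cohort, id = "nope"), "nope")
  expect_error(select_reference(list()), "empty")
  # identical subjects: deterministic lowest-id tie-break
  sym <- make_record(clean_phantom(), "B")
  sym2 <- sym; sym2$subject_id <- "A"
  expect_identical(select_reference(list(sym, sym2))$subject_id, "A")
  # a 1.3x-scaled outlier must not be selected automatically
  big <- phantom_spec(head_radii = 1.3 * c(30, 36, 27), csf_shell_mm = 5,
                      grid_mm = 2.5, noise_sd = 1, bias_amplitude = 0,
                      margin_mm = 4, seed = 31)
  outlier <- generate_head_phantom(big)
  base <- phantom_spec(head_radii = c(30, 36, 27), csf_shell_mm = 5,
                       grid_mm = 2.5, noise_sd = 1, bias_amplitude = 0,
                       seed = 32)
  g <- grid_of_pub(outlier$image)
  on_g <- function(v) resample_through(v, diag(4), g)
  subs <- lapply(1:3, function(i) {
    ph <- generate_head_phantom(
      phantom_spec(head_radii = c(30, 36, 27), csf_shell_mm = 5,
                   grid_mm = 2.5, noise_sd = 1, bias_amplitude = 0,
                   seed = 31 + i))
    subject_record(image = on_g(ph$image),
                   masks = tissue_masks(on_g(ph$brain), on_g(ph$csf)),
                   subject_id = sprintf("S%d", i))
  })
  subs[[4]] <- make_record(outlier, "S4_outlier")
  picked <- select_reference(subs)
  expect_false(picked$subject_id == "S4_outlier")
})

test_that("run_pass reproduces identical symmetric subjects and keeps
           probability maps on the binary-average lattice", {
  ph <- clean_phantom()
  r1 <- make_record(ph, "A")
  r2 <- make_record(ph, "B")
  w <- phantom_ic_weight(ph)
  ctrl <- fast_control(binarize_masks = TRUE)
  atlas <- run_pass(list(r1, r2), ph$image, w, control = ctrl)
  expect_lt(sqrt(mean((atlas$template$data - ph$image$data)^2)), 1e-4)
  # binarize mode: probability values on {0, 1/2N, ..., 1}
  lev <- unique(as.numeric(atlas$brain_prob$data))
  expect_true(all(abs(lev * 2 - round(lev * 2)) < 1e-9))
  expect_gte(min(atlas$brain_prob$data), 0)
  expect_lte(max(atlas$brain_prob$data + atlas$csf_prob$data), 1 + 1e-6)
})

test_that("run_pass is invariant to record order", {
  cohort <- tiny_cohort()
  cohort <- bias_correct_cohort(cohort)
  ref <- cohort[[1]]
  w <- make_ic_mask(ref$masks)$weight
  ctrl <- fast_control()
  a1 <- run_pass(cohort, ref$image, w, control = ctrl)
  a2 <- run_pass(rev(cohort), ref$image, w, control = ctrl)
  expect_identical(a1$template$data, a2$template$data)
  expect_identical(a1$brain_prob$data, a2$brain_prob$data)
})

test_that("a cohort of constant-translation deformations averages to the
           mean shift and flips cancel the x component", {
  ph <- clean_phantom()
  g <- grid_of_pub(ph$image)
  mk_const <- function(tx, ty) {
    d <- symatlas:::zero_deformation(g, 4)
    d$coeffs$x[1, 1, 1] <- tx
    d$coeffs$y[1, 1, 1] <- ty
    d
  }
  fields <- list(mk_const(2, 1), mk_const(4, 3))
  tbar <- average_deformation(fields)
  u <- symatlas:::deformation_field(tbar)
  expect_equal(unique(as.numeric(u$x)), 3)
  expect_equal(unique(as.numeric(u$y)), 2)
  # adding the mirror conjugates zeroes the mean x shift
  all4 <- c(fields, lapply(fields, mirror_conjugate_deformation))
  tbar2 <- average_deformation(all4)
  u2 <- symatlas:::deformation_field(tbar2)
  expect_lt(max(abs(u2$x)), 1e-12)
  expect_equal(unique(as.numeric(u2$y)), 2)
})

test_that("the symmetric atlas is bit-exactly flip-invariant and the
           asymmetric control is not", {
  sym <- small_sym_atlas()
  expect_identical(flip_sagittal(sym$template)$data, sym$template$data)
  expect_identical(flip_sagittal(sym$brain_prob)$data, sym$brain_prob$data)
  expect_identical(flip_sagittal(sym$csf_prob)$data, sym$csf_prob$data)
  expect_gte(min(sym$brain_prob$data), 0)
  expect_lte(max(sym$brain_prob$data), 1)
  asym <- small_asym_atlas()
  expect_gt(max(abs(difference_image(asym$template)$data)), 0)
  # left-enlarged cohort: left-hemisphere brain probability mass exceeds
  # the right
  rep <- hemisphere_volume_report(asym$brain_prob, asym$csf_prob)
  expect_gt(rep$left_pct[rep$structure == "brain" &
                           rep$method == "mass"], 50)
})

test_that("a symmetric single-subject cohort reproduces itself", {
  ph <- clean_phantom()
  rec <- make_record(ph, "ONLY")
  ctrl <- fast_control()
  sym <- build_symmetric_atlas(list(rec), control = ctrl)
  # final flip-average changes nothing for a symmetric subject
  expect_lt(sqrt(mean((sym$template$data - ph$image$data)^2)), 0.5)
  asym <- build_asymmetric_atlas(list(rec), control = ctrl)
  expect_lt(sqrt(mean((asym$template$data - ph$image$data)^2)), 0.5)
  expect_lt(sqrt(mean((asym$template$data - sym$template$data)^2)), 1e-3)
})

test_that("atlases round-trip through write_atlas/read_atlas", {
  sym <- small_sym_atlas()
  dir <- file.path(tempdir(), "atlas_out")
  write_atlas(sym, dir)
  back <- read_atlas(dir)
  expect_identical(back$template$data, sym$template$data)
  expect_identical(back$brain_prob$data, sym$brain_prob$data)
  tr <- list.files(file.path(dir, "transforms"))
  expect_length(tr, 2 * length(sym$provenance$transforms))
  unlink(dir, recursive = TRUE)
})
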