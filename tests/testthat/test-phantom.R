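test_that("symmetric spec yields a bit-exactly flip-invariant phantom", {
  ph <- clean_phantom()
  expect_identical(flip_sagittal(ph$image)$data, ph$image$data)
  expect_identical(flip_sagittal(ph$brain)$data, ph$brain$data)
  # compartment intensities are exactly the class means away from boundaries
  cm <- small_spec()$class_means
  interior <- symatlas:::cpp_erode(ph$brain$data > 0, dim(ph$brain$data), 2L)
  expect_true(all(ph$image$data[interior] == cm[["brain"]]))
})

test_that("phantom generation is deterministic and validates its spec", {
  s <- small_spec(seed = 42)
  p1 <- generate_head_phantom(s)
  p2 <- generate_head_phantom(s)
  expect_identical(p1$image$data, p2$image$data)
  expect_error(phantom_spec(grid_mm = 4, csf_shell_mm = 4), "coarse")
  expect_error(phantom_spec(left_scale = 0), "left_scale")
  expect_error(phantom_spec(bias_amplitude = 1), "bias_amplitude")
  expect_error(phantom_spec(class_means = c(0, 100, 40, 70)), "ordered")
})

test_that("left_scale controls the hemispheric volume ratio monotonically", {
  fracs <- vapply(c(1.0, 1.02, 1.05, 1.10), function(s) {
    ph <- generate_head_phantom(small_spec(noise_sd = 0, bias_amplitude = 0,
                                           left_scale = s, seed = 5))
    rep <- hemisphere_volume_report(ph$brain, ph$csf)
    rep$left_pct[rep$structure == "brain" & rep$method == "threshold"]
  }, 0)
  expect_true(all(diff(fracs) > 0))
  expect_equal(fracs[1], 50)
  # left_scale 1.05: left fraction in (0.50, 0.55) and exceeds the right
  expect_gt(fracs[3], 50)
  expect_lt(fracs[3], 55)
})

test_that("cohort subjects are distinct, reproducible and mask-consistent", {
  cohort <- tiny_cohort()
  expect_length(cohort, 2)
  expect_false(identical(cohort[[1]]$image$data, cohort[[2]]$image$data))
  for (r in cohort) {
    expect_true(all(r$masks$brain$data * r$masks$csf$data == 0))
    expect_identical(r$masks$ic$data,
                     pmax(r$masks$brain$data, r$masks$csf$data))
  }
  # counter-derived streams: subject 2 of an n = 3 draw equals subject 2 of
  # the n = 2 draw
  base <- phantom_spec(head_radii = c(30, 36, 27), csf_shell_mm = 5,
                       grid_mm = 2.5, noise_sd = 1, bias_amplitude = 0.05,
                       left_scale = 1.05, seed = 11)
  c3 <- generate_cohort(3, base, seed = 11)
  expect_identical(c3[[2]]$image$data, cohort[[2]]$image$data)
})

test_that("recorded ground-truth affine reproduces the subject from base", {
  base <- phantom_spec(head_radii = c(30, 36, 27), csf_shell_mm = 5,
                       grid_mm = 2.5, noise_sd = 0, bias_amplitude = 0,
                       subject_jitter = list(translate_mm = 3,
                                             rotate_deg = 4, scale = 0.04,
                                             shear = 0.02, warp_mm = 0),
                       seed = 9)
  sub <- generate_cohort(1, base, seed = 9)[[1]]
  # base phantom evaluated on the cohort grid
  g <- grid_of_pub(sub$image)
  occ <- symatlas:::occupancy_maps(g, base)
  cm <- base$class_means
  base_img <- cm[2] * occ$csf + cm[3] * occ$brain + cm[4] * occ$scalp
  base_vol <- symatlas:::volume_on_grid(g, base_img)
  pred <- apply_affine(sub$truth$affine, base_vol, g)
  # agreement within trilinear interpolation error, which concentrates at
  # the sharp compartment boundaries
  expect_lt(mean(abs(pred$data - sub$image$data)), 1.5)
  expect_lt(sqrt(mean((pred$data - sub$image$data)^2)), 6)
})
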