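# Shared fixtures, memoised so expensive phantoms are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) assign(name, fn(), envir = .fixtures)
  .fixtures[[name]]
}

# A small head phantom spec that still resolves the CSF shell.
small_spec <- function(..., grid_mm = 2) {
  phantom_spec(head_radii = c(30, 36, 27), csf_shell_mm = 5,
               grid_mm = grid_mm, ...)
}

# Noise-free, bias-free, symmetric phantom.
clean_phantom <- function() {
  fixture("clean_phantom", function()
    generate_head_phantom(small_spec(noise_sd = 0, bias_amplitude = 0,
                                     seed = 3)))
}

# Default-noise phantom (noise 3, bias 0.15).
noisy_phantom <- function() {
  fixture("noisy_phantom", function()
    generate_head_phantom(small_spec(seed = 3)))
}

# Left-enlarged phantom.
asym_phantom <- function() {
  fixture("asym_phantom", function()
    generate_head_phantom(small_spec(noise_sd = 0, bias_amplitude = 0,
                                     left_scale = 1.05, seed = 3)))
}

# Registration settings sized for unit tests.
fast_control <- function(...) {
  ctrl <- reg_control(affine_levels = c(4, 2), nonlinear_levels = 4,
                      basis_order = 6, nonlinear_maxit = 30,
                      invert_points = 15)
  over <- list(...)
  for (nm in names(over)) ctrl[[nm]] <- over[[nm]]
  ctrl
}

phantom_ic_weight <- function(ph) {
  make_ic_mask(tissue_masks(ph$brain, ph$csf))$weight
}

# Tiny two-subject cohort (2.5 mm grid) for pipeline-level tests.
tiny_cohort <- function() {
  fixture("tiny_cohort", function() {
    base <- phantom_spec(head_radii = c(30, 36, 27), csf_shell_mm = 5,
                         grid_mm = 2.5, noise_sd = 1, bias_amplitude = 0.05,
                         left_scale = 1.05, seed = 11)
    generate_cohort(2, base, seed = 11)
  })
}

expect_same_volume <- function(a, b, tol = 1e-6) {
  expect_true(same_grid(a, b))
  expect_lt(max(abs(a$data - b$data)), tol)
}

# Small symmetric / asymmetric atlases shared across atlas and evaluation
# tests.
small_sym_atlas <- function() {
  fixture("small_sym_atlas", function()
    build_symmetric_atlas(bias_correct_cohort(tiny_cohort()),
                          reference_id = "S01", control = fast_control()))
}

small_asym_atlas <- function() {
  fixture("small_asym_atlas", function()
    build_asymmetric_atlas(bias_correct_cohort(tiny_cohort()),
                           reference_id = "S01", control = fast_control()))
}

mirror_conjugate_deformation <- function(d) mirror_conjugate(d)

# Smooth positive blob for mass-preservation checks.
gaussian_blob <- function(grid, sigma = 10) {
  g <- symatlas:::grid_of(grid)
  xs <- symatlas:::grid_axis_coords(g, 1)
  ys <- symatlas:::grid_axis_coords(g, 2)
  zs <- symatlas:::grid_axis_coords(g, 3)
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  symatlas:::volume_on_grid(g, exp(-r2 / (2 * sigma^2)))
}

# Thin wrappers over internal helpers used by tests.
transform_points_pub <- function(M, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  symatlas:::transform_points(M, pts)
}

grid_of_pub <- function(v) symatlas:::grid_of(v)

resample_through <- function(vol, A, grid = NULL) {
  if (is.null(grid)) grid <- symatlas:::grid_of(vol)
  symatlas:::resample_affine_world(vol, grid, A)
}

# Put a volume onto an anisotropic 0.47 x 0.47 x 0.7 mm grid covering it.
resample_to_aniso <- function(vol) {
  h <- c(0.47, 0.47, 0.7)
  cs <- lapply(1:3, function(a) {
    r <- range(symatlas:::axis_coords(vol, a))
    seq(r[1], r[2] + h[a], by = h[a])
  })
  m <- diag(c(h, 1))
  m[1:3, 4] <- vapply(cs, min, 0)
  g <- symatlas:::vol_grid(vapply(cs, length, 0L), m, h)
  symatlas:::resample_affine_world(vol, g)
}
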