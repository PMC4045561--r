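#' Specification of a synthetic newborn head phantom
#'
#' Describes a nested-ellipsoid head (scalp > CSF shell > brain) voxelized on
#' a grid symmetric about the midsagittal plane, with controllable left-right
#' asymmetry, a smooth multiplicative bias field, and additive Gaussian
#' noise. The defaults emulate a term-born newborn head imaged with a
#' T1-weighted sequence: CSF darker than unmyelinated brain parenchyma,
#' scalp intermediate.
#'
#' @param head_radii scalp ellipsoid semi-axes (x, y, z) in mm.
#' @param brain_fraction brain semi-axes as a fraction of `head_radii`.
#' @param csf_shell_mm thickness of the CSF shell around the brain, mm.
#' @param class_means intensities for background, CSF, brain, scalp; the
#'   background, CSF and brain means must be strictly increasing.
#' @param left_scale hemispheric scale factor applied to the left (`x < 0`)
#'   half of brain and CSF; 1 gives a perfectly symmetric head, and the
#'   left-to-total brain volume ratio is `left_scale / (1 + left_scale)`.
#' @param torque_deg rotation (degrees, about z) of the left hemisphere, a
#'   surrogate for the Yakovlevian torque; applied with a smooth ramp from
#'   the midline.
#' @param bias_amplitude fractional amplitude of the multiplicative bias
#'   field (product of three low-frequency cosines), in `[0, 1)`.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   intensity units.
#' @param subject_jitter per-subject perturbation ranges used by
#'   [generate_cohort]: `translate_mm`, `rotate_deg`, `scale`, `shear`,
#'   `warp_mm` (amplitude of a smooth low-frequency warp).
#' @param grid_mm isotropic voxel size of the phantom grid, mm.
#' @param margin_mm air margin around the head.
#' @param seed integer seed; the phantom and every cohort subject are fully
#'   reproducible from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(head_radii = c(40, 50, 35),
                         brain_fraction = 0.75,
                         csf_shell_mm = 4,
                         class_means = c(background = 0, csf = 40,
                                         brain = 100, scalp = 70),
                         left_scale = 1.0,
                         torque_deg = 0,
                         bias_amplitude = 0.15,
                         noise_sd = 3,
                         subject_jitter = list(translate_mm = 3,
                                               rotate_deg = 4,
                                               scale = 0.04,
                                               shear = 0.02,
                                               warp_mm = 1.5),
                         grid_mm = 1,
                         margin_mm = 6,
                         seed = 1L) {
  spec <- list(head_radii = as.numeric(head_radii),
               brain_fraction = brain_fraction,
               csf_shell_mm = csf_shell_mm,
               class_means = class_means,
               left_scale = left_scale,
               torque_deg = torque_deg,
               bias_amplitude = bias_amplitude,
               noise_sd = noise_sd,
               subject_jitter = subject_jitter,
               grid_mm = grid_mm,
               margin_mm = margin_mm,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(head_radii) != 3 || any(head_radii <= 0))
      stop("head_radii must be 3 positive semi-axes", call. = FALSE)
    if (brain_fraction <= 0 || brain_fraction >= 1)
      stop("brain_fraction must be in (0, 1)", call. = FALSE)
    if (left_scale <= 0) stop("left_scale must be > 0", call. = FALSE)
    if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
    if (bias_amplitude < 0 || bias_amplitude >= 1)
      stop("bias_amplitude must be in [0, 1)", call. = FALSE)
    cm <- class_means
    if (length(cm) != 4) stop("class_means needs 4 values", call. = FALSE)
    if (!(cm[1] < cm[2] && cm[2] < cm[3]))
      stop("class means must be ordered background < CSF < brain",
           call. = FALSE)
    if (csf_shell_mm < 1.5 * grid_mm)
      stop(sprintf(
        "grid (%.2g mm) too coarse to resolve the %.2g mm CSF shell",
        grid_mm, csf_shell_mm), call. = FALSE)
    if (brain_fraction * min(head_radii) + csf_shell_mm >= min(head_radii))
      stop("brain plus CSF shell does not fit inside the head", call. = FALSE)
  })
  invisible(spec)
}

# Left-hemisphere asymmetry transform applied to query points: points with
# x < 0 are compressed by 1/left_scale (so left structures occupy
# left_scale times the volume) and twisted about z by a smoothly ramped
# torque angle. Exactly the identity when left_scale == 1 and torque == 0.
left_transform <- function(px, py, pz, spec) {
  s <- spec$left_scale
  th <- spec$torque_deg * pi / 180
  if (s != 1) {
    neg <- px < 0
    px[neg] <- px[neg] / s
  }
  if (th != 0) {
    ramp <- pmin(1, pmax(0, -px / 15))
    a <- -th * ramp
    ca <- cos(a); sa <- sin(a)
    x2 <- ca * px - sa * py
    py <- sa * px + ca * py
    px <- x2
  }
  list(px, py, pz)
}

# Hard compartment membership (0/1) at arbitrary world points.
compartments_at <- function(px, py, pz, spec) {
  q <- left_transform(px, py, pz, spec)
  rb <- spec$brain_fraction * spec$head_radii
  rc <- rb + spec$csf_shell_mm
  rh <- spec$head_radii
  e <- function(r) (q[[1]] / r[1])^2 + (q[[2]] / r[2])^2 + (q[[3]] / r[3])^2
  eb <- e(rb) <= 1
  ec <- e(rc) <= 1
  eh <- e(rh) <= 1
  list(brain = eb, csf = ec & !eb, scalp = eh & !ec)
}

# Occupancy fractions on a grid with 2x2x2 supersampling. map_fun (world
# points -> world points) injects per-subject deformations. The +dx/-dx
# subsample pair is summed first so that, for a symmetric spec and identity
# map, mirrored voxels accumulate identical values in identical order and
# the result is bit-exactly flip-invariant.
occupancy_maps <- function(grid, spec, map_fun = NULL) {
  grid <- grid_of(grid)
  d <- grid$dim
  h <- grid$voxel_size
  xs <- grid_axis_coords(grid, 1)
  ys <- grid_axis_coords(grid, 2)
  zs <- grid_axis_coords(grid, 3)
  X <- rep(xs, times = d[2] * d[3])
  Y <- rep(rep(ys, each = d[1]), times = d[3])
  Z <- rep(zs, each = d[1] * d[2])
  acc <- list(brain = 0, csf = 0, scalp = 0)
  for (dz in c(-0.25, 0.25) * h[3])
    for (dy in c(-0.25, 0.25) * h[2]) {
      cmp_pair <- NULL
      for (dx in c(-0.25, 0.25) * h[1]) {
        px <- X + dx; py <- Y + dy; pz <- Z + dz
        if (!is.null(map_fun)) {
          p <- map_fun(px, py, pz)
          px <- p[[1]]; py <- p[[2]]; pz <- p[[3]]
        }
        cmp <- compartments_at(px, py, pz, spec)
        if (is.null(cmp_pair)) {
          cmp_pair <- lapply(cmp, as.numeric)
        } else {
          for (nm in names(acc))
            cmp_pair[[nm]] <- cmp_pair[[nm]] + cmp[[nm]]
        }
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + cmp_pair[[nm]]
    }
  lapply(acc, function(a) array(a / 8, d))
}

# Smooth multiplicative bias field: 1 + amplitude * product of one cosine
# per axis, with per-axis phases.
bias_field_on_grid <- function(grid, amplitude, phases = c(0.15, 0.3, 0.45)) {
  grid <- grid_of(grid)
  d <- grid$dim
  tf <- function(a) {
    cs <- grid_axis_coords(grid, a)
    t <- (cs - min(cs)) / max(max(cs) - min(cs), 1e-9)
    cos(pi * (t - phases[a]))
  }
  b <- outer(outer(tf(1), tf(2)), tf(3))
  array(1 + amplitude * b, d)
}

#' Generate a synthetic newborn head phantom
#'
#' Voxelizes the nested-ellipsoid head described by a [phantom_spec] with
#' 2x2x2 subvoxel supersampling (partial-volume intensities at compartment
#' boundaries), applies the bias field and noise, and returns the noise-free
#' ground-truth brain and CSF masks together with AC/PC/IH landmarks.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `image`, `brain`, `csf` (all
#'   [image_volume]s on one grid symmetric about `x = 0`), and `lm`
#'   ([landmarks]).
#' @export
generate_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  half <- spec$head_radii * max(1, spec$left_scale) + spec$margin_mm
  grid <- symmetric_grid(half, spec$grid_mm)
  occ <- occupancy_maps(grid, spec)
  cm <- spec$class_means
  img <- cm[2] * occ$csf + cm[3] * occ$brain + cm[4] * occ$scalp
  if (spec$bias_amplitude > 0)
    img <- img * bias_field_on_grid(grid, spec$bias_amplitude)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  }
  brain <- (occ$brain >= 0.5) * 1
  csf <- (occ$csf >= 0.5 & occ$brain < 0.5) * 1
  list(image = volume_on_grid(grid, img, "phantom image"),
       brain = volume_on_grid(grid, brain, "phantom brain mask"),
       csf = volume_on_grid(grid, csf, "phantom csf mask"),
       lm = landmarks(AC = c(0, 10, 0), PC = c(0, -10, 0),
                      IH = c(0, 0, 0.8 * spec$brain_fraction *
                               spec$head_radii[3])))
}

# Deterministic per-subject stream: one base seed plus a subject counter.
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483562) + 1L
}

#' Generate a synthetic cohort of newborn head phantoms
#'
#' Draws `n` subjects by perturbing a base [phantom_spec] with a per-subject
#' rigid offset, anisotropic scale, shear, and a smooth low-frequency warp
#' (ranges taken from `base$subject_jitter`). Each subject's image is
#' evaluated analytically at the deformed sample points, so the ground-truth
#' masks are exact and the recorded ground-truth affine reproduces the
#' subject from the base within interpolation error.
#'
#' @param n number of subjects.
#' @param base a [phantom_spec]; its `left_scale`, noise and bias settings
#'   apply to every subject.
#' @param seed integer seed for the cohort; per-subject streams are derived
#'   from it by counter, so subject `i` is the same regardless of `n`.
#' @return A list of `n` [subject_record]s, each with exact ground-truth
#'   masks, transformed landmarks and a `truth` element recording the
#'   injected affine parameters and warp.
#' @export
generate_cohort <- function(n, base, seed = base$seed) {
  stopifnot(inherits(base, "phantom_spec"))
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  half <- base$head_radii * max(1, base$left_scale) + base$margin_mm +
    base$subject_jitter$translate_mm
  grid <- symmetric_grid(half, base$grid_mm)
  fov <- vapply(1:3, function(a) range(grid_axis_coords(grid, a)),
                numeric(2))
  lapply(seq_len(n), function(i)
    make_cohort_subject(i, base, grid, fov, subject_seed(seed, i)))
}

make_cohort_subject <- function(i, base, grid, fov, sseed) {
  set.seed(sseed)
  jit <- base$subject_jitter
  tr <- stats::runif(3, -jit$translate_mm, jit$translate_mm)
  ro <- stats::runif(3, -jit$rotate_deg, jit$rotate_deg) * pi / 180
  sc <- exp(stats::runif(3, -jit$scale, jit$scale))
  sh <- stats::runif(3, -jit$shear, jit$shear)
  truth_affine <- affine_params(translation = tr, rotation = ro,
                                scale = sc, shear = sh)
  A <- affine_matrix(truth_affine)
  warp <- NULL
  if (jit$warp_mm > 0) {
    k <- 2L
    warp <- lapply(1:3, function(a) {
      co <- array(stats::rnorm(k^3), rep(k, 3))
      co * jit$warp_mm / (2 * sqrt(sum(co^2)) / k^1.5)
    })
    names(warp) <- c("x", "y", "z")
  }
  map_fun <- function(px, py, pz) {
    qx <- A[1, 1] * px + A[1, 2] * py + A[1, 3] * pz + A[1, 4]
    qy <- A[2, 1] * px + A[2, 2] * py + A[2, 3] * pz + A[2, 4]
    qz <- A[3, 1] * px + A[3, 2] * py + A[3, 3] * pz + A[3, 4]
    if (!is.null(warp)) {
      u <- eval_raw_cosine_field(warp, qx, qy, qz, fov)
      qx <- qx + u[[1]]; qy <- qy + u[[2]]; qz <- qz + u[[3]]
    }
    list(qx, qy, qz)
  }
  occ <- occupancy_maps(grid, base, map_fun)
  cm <- base$class_means
  img <- cm[2] * occ$csf + cm[3] * occ$brain + cm[4] * occ$scalp
  if (base$bias_amplitude > 0)
    img <- img * bias_field_on_grid(grid, base$bias_amplitude,
                                    phases = stats::runif(3))
  if (base$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, base$noise_sd), dim(img))
  brain <- (occ$brain >= 0.5) * 1
  csf <- (occ$csf >= 0.5 & occ$brain < 0.5) * 1
  # landmark positions in the subject: x* with map_fun(x*) = landmark
  base_lm <- list(AC = c(0, 10, 0), PC = c(0, -10, 0),
                  IH = c(0, 0, 0.8 * base$brain_fraction *
                           base$head_radii[3]))
  inv_map <- function(p) {
    q <- p
    for (it in 1:50) {
      if (!is.null(warp)) {
        Aq <- A[1:3, 1:3] %*% q + A[1:3, 4]
        u <- eval_raw_cosine_field(warp, Aq[1], Aq[2], Aq[3], fov)
        target <- p - c(u[[1]], u[[2]], u[[3]])
      } else target <- p
      qn <- solve(A, c(target, 1))[1:3]
      if (max(abs(qn - q)) < 1e-10) { q <- qn; break }
      q <- qn
    }
    q
  }
  lm <- landmarks(inv_map(base_lm$AC), inv_map(base_lm$PC),
                  inv_map(base_lm$IH))
  id <- sprintf("S%02d", i)
  bv <- volume_on_grid(grid, brain, paste(id, "brain mask"))
  cv <- volume_on_grid(grid, csf, paste(id, "csf mask"))
  subject_record(image = volume_on_grid(grid, img, paste(id, "image")),
                 masks = tissue_masks(bv, cv),
                 subject_id = id, lm = lm,
                 truth = list(affine = truth_affine, warp = warp, fov = fov,
                              seed = sseed))
}

# Evaluate a low-order cosine displacement field (list of coefficient arrays
# kx x ky x kz per axis) at scattered world points; basis is
# cos(pi * k * t) on the normalized fov coordinate. Used for injected
# ground-truth warps.
eval_raw_cosine_field <- function(coeffs, px, py, pz, fov) {
  k <- dim(coeffs[[1]])[1]
  tb <- function(p, a) {
    t <- (p - fov[1, a]) / (fov[2, a] - fov[1, a])
    B <- matrix(1, length(t), k)
    if (k > 1) for (j in 2:k) B[, j] <- sqrt(2) * cos(pi * (j - 1) * t)
    B
  }
  Bx <- tb(px, 1); By <- tb(py, 2); Bz <- tb(pz, 3)
  lapply(coeffs, function(C) scattered_basis_eval(C, Bx, By, Bz))
}

# u(i) = sum_{klm} C[k,l,m] Bx[i,k] By[i,l] Bz[i,m]
scattered_basis_eval <- function(C, Bx, By, Bz) {
  k <- dim(C)
  E <- Bx %*% matrix(C, k[1], k[2] * k[3])   # n x (k2*k3)
  n <- nrow(Bx)
  u <- numeric(n)
  for (m in seq_len(k[3])) {
    block <- E[, (m - 1) * k[2] + seq_len(k[2]), drop = FALSE]
    u <- u + rowSums(block * By) * Bz[, m]
  }
  u
}
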