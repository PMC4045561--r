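#' 12-parameter affine transform
#'
#' The global transform used for affine spatial normalization: translation,
#' rotation, anisotropic scale and shear, composed as
#' `A = T %*% Rx %*% Ry %*% Rz %*% Shear %*% Scale` acting on world (mm)
#' coordinates.
#'
#' @param translation mm triple.
#' @param rotation radians triple (about x, y, z).
#' @param scale unitless strictly positive triple.
#' @param shear unitless triple (xy, xz, yz components).
#' @return An object of class `affine_params`.
#' @export
affine_params <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                          scale = c(1, 1, 1), shear = c(0, 0, 0)) {
  p <- list(translation = as.numeric(translation),
            rotation = as.numeric(rotation),
            scale = as.numeric(scale), shear = as.numeric(shear))
  if (any(vapply(p, length, 0L) != 3L) ||
      !all(is.finite(unlist(p))))
    stop("each affine component must be 3 finite values", call. = FALSE)
  if (any(p$scale <= 0)) stop("scales must be strictly positive",
                              call. = FALSE)
  structure(p, class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat(sprintf(
    "<affine_params> t = [%.3f %.3f %.3f] mm, r = [%.4f %.4f %.4f] rad\n",
    x$translation[1], x$translation[2], x$translation[3],
    x$rotation[1], x$rotation[2], x$rotation[3]))
  cat(sprintf("  s = [%.4f %.4f %.4f], shear = [%.4f %.4f %.4f]\n",
              x$scale[1], x$scale[2], x$scale[3],
              x$shear[1], x$shear[2], x$shear[3]))
  invisible(x)
}

#' 4x4 world-space matrix of an affine transform
#' @param p an [affine_params].
#' @return 4x4 homogeneous matrix.
#' @export
affine_matrix <- function(p) {
  stopifnot(inherits(p, "affine_params"))
  r <- p$rotation
  Rx <- diag(4); Rx[2:3, 2:3] <- matrix(c(cos(r[1]), sin(r[1]),
                                          -sin(r[1]), cos(r[1])), 2)
  Ry <- diag(4); Ry[c(1, 3), c(1, 3)] <- matrix(c(cos(r[2]), -sin(r[2]),
                                                  sin(r[2]), cos(r[2])), 2)
  Rz <- diag(4); Rz[1:2, 1:2] <- matrix(c(cos(r[3]), sin(r[3]),
                                          -sin(r[3]), cos(r[3])), 2)
  H <- diag(4); H[1, 2] <- p$shear[1]; H[1, 3] <- p$shear[2]
  H[2, 3] <- p$shear[3]
  Z <- diag(c(p$scale, 1))
  Tm <- diag(4); Tm[1:3, 4] <- p$translation
  Tm %*% Rx %*% Ry %*% Rz %*% H %*% Z
}

# optimizer vector <-> affine_params (scales optimized in log space)
affine_to_vec <- function(p)
  c(p$translation, p$rotation, log(p$scale), p$shear)

vec_to_affine <- function(v)
  affine_params(translation = v[1:3], rotation = v[4:6],
                scale = exp(v[7:9]), shear = v[10:12])

# d(affine_matrix)/d(vec component j), by central differences on the 4x4
# construction (cheap and effectively exact at h = 1e-6).
affine_matrix_jacobian <- function(v, h = 1e-6) {
  lapply(seq_along(v), function(j) {
    vp <- v; vp[j] <- vp[j] + h
    vm <- v; vm[j] <- vm[j] - h
    (affine_matrix(vec_to_affine(vp)) - affine_matrix(vec_to_affine(vm))) /
      (2 * h)
  })
}

#' Registration control settings
#'
#' Tuning knobs shared by the affine and nonlinear registrations and the
#' atlas pipeline.
#'
#' @param affine_levels multi-resolution pyramid for the affine stage, mm
#'   (coarse to fine); levels finer than the native resolution are clamped.
#' @param nonlinear_levels pyramid for the cosine-basis stage, mm. The
#'   displacement model is low-frequency, so the default stops at 2 mm.
#' @param basis_order number of cosine basis functions per axis (k); the
#'   deformation has `3 * k^3` coefficients.
#' @param lambda bending-energy weight of the nonlinear fit; the data term is
#'   normalized by the weighted voxel count and reference variance, so
#'   `lambda` is unitless.
#' @param affine_maxit,nonlinear_maxit optimizer iteration caps per level.
#' @param weight_eps voxels with weight below `weight_eps * max(weight)` are
#'   excluded from the cost.
#' @param binarize_masks logical; re-binarize warped masks at 0.5 instead of
#'   keeping continuous values (continuous is the default: the probabilistic
#'   models average transformed masks directly).
#' @param invert_points per-axis sample count of the grid on which
#'   deformations are numerically inverted.
#' @param verbose print per-stage progress.
#' @return A list of class `reg_control`.
#' @export
reg_control <- function(affine_levels = c(4, 2, 1),
                        nonlinear_levels = c(4, 2),
                        basis_order = 8,
                        lambda = 1,
                        affine_maxit = 40,
                        nonlinear_maxit = 40,
                        weight_eps = 1e-3,
                        binarize_masks = FALSE,
                        invert_points = 25,
                        verbose = FALSE) {
  structure(list(affine_levels = affine_levels,
                 nonlinear_levels = nonlinear_levels,
                 basis_order = as.integer(basis_order), lambda = lambda,
                 affine_maxit = affine_maxit,
                 nonlinear_maxit = nonlinear_maxit,
                 weight_eps = weight_eps, binarize_masks = binarize_masks,
                 invert_points = as.integer(invert_points),
                 verbose = verbose),
            class = "reg_control")
}

# Smooth + downsample a reference-grid volume for one pyramid level.
# Returns the volume untouched when the level is not coarser than native.
prep_level <- function(vol, level_mm) {
  native <- max(vol$voxel_size)
  if (level_mm <= native * 1.01) return(vol)
  sm <- gaussian_smooth(vol, sqrt(level_mm^2 - native^2))
  reslice_isotropic(sm, level_mm)
}

#' Mask-weighted affine registration
#'
#' Finds the 12-parameter affine transform minimizing the weighted sum of
#' squared differences `sum w(x) (ref(x) - g * mov(A x))^2` over the
#' reference grid, where `w` is the intracranial weighting mask and `g` a
#' per-evaluation least-squares intensity gain (so mixed scanner gains do
#' not bias the fit). Optimization is multi-resolution BFGS with an analytic
#' gradient; the procedure is deterministic given its inputs.
#'
#' @param moving [image_volume] to be aligned.
#' @param reference [image_volume] defining the target space.
#' @param weight nonnegative [image_volume] on the reference grid.
#' @param control a [reg_control].
#' @param init optional initial [affine_params].
#' @return A `registration_result`: list with `transform` ([affine_params]),
#'   `objective_trace` (weighted-SSD per accepted step, non-increasing),
#'   `converged`, `gain`.
#' @export
affine_register <- function(moving, reference, weight,
                            control = reg_control(), init = NULL) {
  assert_volume(moving, "moving"); assert_volume(reference, "reference")
  assert_volume(weight, "weight")
  if (!same_grid(reference, weight))
    stop("weight must live on the reference grid", call. = FALSE)
  if (all(weight$data <= 0)) stop("weight is empty", call. = FALSE)
  if (any(weight$data < 0)) stop("weight must be nonnegative", call. = FALSE)
  v <- if (is.null(init)) rep(0, 12) else affine_to_vec(init)
  trace_all <- numeric(0)
  native <- max(reference$voxel_size)
  levels <- unique(pmax(control$affine_levels, native))
  gain <- 1
  conv <- TRUE
  for (lev in levels) {
    refL <- prep_level(reference, lev)
    wL <- prep_level(weight, lev)
    movL <- if (lev > max(moving$voxel_size) * 1.01)
      gaussian_smooth(moving, sqrt(lev^2 - max(moving$voxel_size)^2))
    else moving
    idx <- which(wL$data > control$weight_eps * max(wL$data))
    if (length(idx) < 100)
      stop("weight support too small at level", call. = FALSE)
    X <- grid_world_points(grid_of(refL), idx)
    Xh <- cbind(X, 1)
    w <- wL$data[idx]
    r0 <- refL$data[idx]
    sw <- sum(w)
    mu <- sum(w * r0) / sw
    norm_const <- max(sum(w * (r0 - mu)^2), 1e-12)
    Mv <- voxel_from_world(movL)
    sample_at <- function(A) {
      Q <- Xh %*% t(Mv %*% A)
      cpp_sample_points_grad(movL$data, dim(movL$data),
                             Q[, 1], Q[, 2], Q[, 3])
    }
    fn <- function(vv) {
      A <- affine_matrix(vec_to_affine(vv))
      mv <- sample_at(A)[[1]]
      g <- sum(w * r0 * mv) / max(sum(w * mv^2), 1e-12)
      val <- sum(w * (r0 - g * mv)^2) / norm_const
      if (!is.finite(val)) stop("non-finite registration objective",
                                call. = FALSE)
      trace_all <<- c(trace_all, val)
      val
    }
    gr <- function(vv) {
      A <- affine_matrix(vec_to_affine(vv))
      s <- sample_at(A)  # value + exact interpolant gradient (voxel units)
      mv <- s[[1]]
      g <- sum(w * r0 * mv) / max(sum(w * mv^2), 1e-12)
      r <- r0 - g * mv
      dAs <- affine_matrix_jacobian(vv)
      common <- -2 * g * w * r / norm_const
      vapply(dAs, function(dA) {
        # derivative of the voxel-space sample position wrt parameter j
        D <- Xh %*% t((Mv %*% dA)[1:3, , drop = FALSE])
        sum(common * (s[[2]] * D[, 1] + s[[3]] * D[, 2] + s[[4]] * D[, 3]))
      }, 0)
    }
    parscale <- c(rep(1, 3), rep(0.02, 3), rep(0.02, 3), rep(0.02, 3))
    opt <- stats::optim(v, fn, gr, method = "BFGS",
                        control = list(maxit = control$affine_maxit,
                                       reltol = 1e-8,
                                       parscale = parscale))
    v <- opt$par
    conv <- conv && opt$convergence %in% c(0L, 1L)
    A <- affine_matrix(vec_to_affine(v))
    mv <- sample_at(A)[[1]]
    gain <- sum(w * r0 * mv) / max(sum(w * mv^2), 1e-12)
    if (control$verbose)
      message(sprintf("  affine level %.3g mm: obj %.5g (%d evals)",
                      lev, opt$value, length(trace_all)))
  }
  structure(list(transform = vec_to_affine(v),
                 objective_trace = cummin(trace_all),
                 converged = conv, gain = gain),
            class = "registration_result")
}

#' Apply an affine transform to a volume
#'
#' Resamples `vol` onto the reference grid through the world-space map
#' `x -> A x`: `out(x) = vol(A x)`. Intensity images and masks are both
#' interpolated trilinearly; masks can optionally be re-binarized at 0.5.
#'
#' @param t an [affine_params] (or a `registration_result`).
#' @param vol the [image_volume] to resample.
#' @param grid target grid (defaults to the grid of `vol`).
#' @param kind `"intensity"` or `"mask"`.
#' @param binarize when `TRUE` and `kind = "mask"`, threshold the result at
#'   0.5.
#' @return The resampled [image_volume].
#' @export
apply_affine <- function(t, vol, grid = NULL,
                         kind = c("intensity", "mask"), binarize = FALSE) {
  kind <- match.arg(kind)
  if (inherits(t, "registration_result")) t <- t$transform
  stopifnot(inherits(t, "affine_params"))
  A <- affine_matrix(t)
  if (abs(det(A[1:3, 1:3])) < 1e-12)
    stop("singular affine transform", call. = FALSE)
  if (is.null(grid)) grid <- grid_of(vol)
  out <- resample_affine_world(vol, grid, A)
  if (kind == "mask" && binarize) out$data <- (out$data >= 0.5) * 1
  out
}
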