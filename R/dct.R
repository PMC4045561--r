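#' Low-frequency cosine-basis deformation field
#'
#' A smooth 3D displacement field `u(x)` parameterized by the lowest
#' `k x k x k` 3D cosine (DCT) basis functions per displacement axis,
#' defined over the world-coordinate field of view of a reference grid.
#' Applying the deformation to an image resamples it at `x + u(x)`.
#' The basis is resolution independent: it can be evaluated at any world
#' point, which is what makes multi-resolution fitting, inversion, and
#' averaging across subjects well defined.
#'
#' @param coeffs list of three `k x k x k` coefficient arrays (named x, y,
#'   z), displacement in mm.
#' @param fov 2 x 3 matrix of world min/max per axis over which the basis is
#'   defined.
#' @param grid the reference [image_volume] grid the field displaces.
#' @param lambda bending-energy weight used at fit time (recorded).
#' @return An object of class `dct_deformation`.
#' @export
dct_deformation <- function(coeffs, fov, grid, lambda = 0) {
  stopifnot(is.list(coeffs), length(coeffs) == 3)
  names(coeffs) <- c("x", "y", "z")
  k <- dim(coeffs[[1]])
  for (co in coeffs)
    if (!all(dim(co) == k) || !all(is.finite(co)))
      stop("coefficient arrays must share dimensions and be finite",
           call. = FALSE)
  structure(list(coeffs = coeffs, fov = fov, grid = grid_of(grid),
                 k = k, lambda = lambda), class = "dct_deformation")
}

#' @export
print.dct_deformation <- function(x, ...) {
  u <- deformation_field(x)
  mx <- max(abs(u$x), abs(u$y), abs(u$z))
  cat(sprintf("<dct_deformation> order %d x %d x %d, max |u| = %.3f mm\n",
              x$k[1], x$k[2], x$k[3], mx))
  invisible(x)
}

zero_deformation <- function(grid, k, lambda = 0) {
  grid <- grid_of(grid)
  fov <- vapply(1:3, function(a) range(grid_axis_coords(grid, a)),
                numeric(2))
  dct_deformation(list(x = array(0, rep(k, 3)), y = array(0, rep(k, 3)),
                       z = array(0, rep(k, 3))), fov, grid, lambda)
}

# Basis matrix along one axis: columns are 1, sqrt(2) cos(pi k t), on the
# normalized coordinate t = (x - fov_min) / (fov_max - fov_min).
dct_basis_matrix <- function(coords, fov_axis, k) {
  t <- (coords - fov_axis[1]) / max(fov_axis[2] - fov_axis[1], 1e-9)
  B <- matrix(1, length(coords), k)
  if (k > 1) for (j in 2:k) B[, j] <- sqrt(2) * cos(pi * (j - 1) * t)
  B
}

# mode-n tensor-times-matrix: contracts dim `mode` of array A (length k)
# with matrix B (n x k), giving dim n along that mode.
ttm <- function(A, B, mode) {
  d <- dim(A)
  perm <- c(mode, setdiff(1:3, mode))
  Ap <- aperm(A, perm)
  M <- B %*% matrix(Ap, d[mode], prod(d[-mode]))
  out <- array(M, c(nrow(B), d[-mode]))
  aperm(out, order(perm))
}

# Displacement arrays (mm) on a full grid.
deformation_field <- function(d, grid = d$grid) {
  grid <- grid_of(grid)
  Bs <- lapply(1:3, function(a)
    dct_basis_matrix(grid_axis_coords(grid, a), d$fov[, a], d$k[a]))
  lapply(d$coeffs, function(C)
    ttm(ttm(ttm(C, Bs[[1]], 1), Bs[[2]], 2), Bs[[3]], 3))
}

#' Evaluate a deformation's displacement at world points
#' @param d a [dct_deformation].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of displacements (mm).
#' @export
evaluate_deformation <- function(d, pts) {
  stopifnot(inherits(d, "dct_deformation"))
  deformation_at_points(d, pts)
}

# Displacement at scattered world points (n x 3 matrix) -> n x 3 matrix.
deformation_at_points <- function(d, pts) {
  Bx <- dct_basis_matrix(pts[, 1], d$fov[, 1], d$k[1])
  By <- dct_basis_matrix(pts[, 2], d$fov[, 2], d$k[2])
  Bz <- dct_basis_matrix(pts[, 3], d$fov[, 3], d$k[3])
  cbind(scattered_basis_eval(d$coeffs$x, Bx, By, Bz),
        scattered_basis_eval(d$coeffs$y, Bx, By, Bz),
        scattered_basis_eval(d$coeffs$z, Bx, By, Bz))
}

# Diagonal bending-energy penalty weights per basis function:
# ((pi k / Lx)^2 + (pi l / Ly)^2 + (pi m / Lz)^2)^2.
bending_penalty <- function(fov, k) {
  L <- pmax(fov[2, ] - fov[1, ], 1e-9)
  f <- lapply(1:3, function(a) (pi * (0:(k - 1)) / L[a])^2)
  (outer(outer(f[[1]], f[[2]], "+"), f[[3]], "+"))^2
}

#' Mask-weighted nonlinear registration with cosine basis functions
#'
#' Fits a [dct_deformation] minimizing the weighted SSD between the
#' reference and the deformed moving image plus a bending-energy penalty
#' `lambda * int ||grad^2 u||^2`, by multi-resolution L-BFGS-B with analytic
#' gradients. The moving image is expected to be affinely normalized to the
#' reference already. Deterministic given its inputs.
#'
#' @inheritParams affine_register
#' @param k basis order per axis (>= 2); defaults to `control$basis_order`.
#' @return A `registration_result` whose `transform` is the fitted
#'   [dct_deformation].
#' @export
nonlinear_register <- function(moving, reference, weight,
                               k = control$basis_order,
                               control = reg_control()) {
  assert_volume(moving, "moving"); assert_volume(reference, "reference")
  assert_volume(weight, "weight")
  if (!same_grid(reference, weight))
    stop("weight must live on the reference grid", call. = FALSE)
  if (all(weight$data <= 0)) stop("weight is empty", call. = FALSE)
  if (k < 2) stop("basis order k must be >= 2", call. = FALSE)
  d0 <- zero_deformation(grid_of(reference), k, control$lambda)
  pen <- bending_penalty(d0$fov, k)
  cvec <- rep(0, 3 * k^3)
  trace_all <- numeric(0)
  native <- max(reference$voxel_size)
  levels <- unique(pmax(control$nonlinear_levels, native))
  conv <- TRUE
  gain <- 1
  for (lev in levels) {
    refL <- prep_level(reference, lev)
    wL <- prep_level(weight, lev)
    movL <- if (lev > max(moving$voxel_size) * 1.01)
      gaussian_smooth(moving, sqrt(lev^2 - max(moving$voxel_size)^2))
    else moving
    gL <- grid_of(refL)
    Bs <- lapply(1:3, function(a)
      dct_basis_matrix(grid_axis_coords(gL, a), d0$fov[, a], k))
    idx <- which(wL$data > control$weight_eps * max(wL$data))
    X <- grid_world_points(gL, idx)
    w <- wL$data[idx]
    r0 <- refL$data[idx]
    sw <- sum(w)
    mu <- sum(w * r0) / sw
    norm_const <- max(sum(w * (r0 - mu)^2), 1e-12)
    Mv <- voxel_from_world(movL)
    dimL <- gL$dim
    unpack <- function(vv) list(x = array(vv[1:k^3], rep(k, 3)),
                                y = array(vv[k^3 + 1:k^3], rep(k, 3)),
                                z = array(vv[2 * k^3 + 1:k^3], rep(k, 3)))
    field_at_idx <- function(C)
      vapply(C, function(co)
        ttm(ttm(ttm(co, Bs[[1]], 1), Bs[[2]], 2), Bs[[3]], 3)[idx],
        numeric(length(idx)))
    sample_moved <- function(u) {
      P <- X + u
      px <- Mv[1, 1] * P[, 1] + Mv[1, 2] * P[, 2] + Mv[1, 3] * P[, 3] +
        Mv[1, 4]
      py <- Mv[2, 1] * P[, 1] + Mv[2, 2] * P[, 2] + Mv[2, 3] * P[, 3] +
        Mv[2, 4]
      pz <- Mv[3, 1] * P[, 1] + Mv[3, 2] * P[, 2] + Mv[3, 3] * P[, 3] +
        Mv[3, 4]
      cpp_sample_points_grad(movL$data, dim(movL$data), px, py, pz)
    }
    penalty <- function(C)
      control$lambda * sum(pen * (C$x^2 + C$y^2 + C$z^2))
    fn <- function(vv) {
      C <- unpack(vv)
      u <- field_at_idx(C)
      mv <- sample_moved(u)[[1]]
      g <- sum(w * r0 * mv) / max(sum(w * mv^2), 1e-12)
      val <- sum(w * (r0 - g * mv)^2) / norm_const + penalty(C)
      if (!is.finite(val)) stop("non-finite registration objective",
                                call. = FALSE)
      trace_all <<- c(trace_all, val)
      val
    }
    gr <- function(vv) {
      C <- unpack(vv)
      u <- field_at_idx(C)
      s <- sample_moved(u)  # value + exact interpolant gradient (voxel units)
      mv <- s[[1]]
      # gradient wrt world displacement: chain voxel-space gradient through
      # the world-to-voxel map
      gw <- lapply(1:3, function(a)
        s[[2]] * Mv[1, a] + s[[3]] * Mv[2, a] + s[[4]] * Mv[3, a])
      g <- sum(w * r0 * mv) / max(sum(w * mv^2), 1e-12)
      r <- r0 - g * mv
      common <- -2 * g * w * r / norm_const
      out <- numeric(3 * k^3)
      for (a in 1:3) {
        Fa <- array(0, dimL)
        Fa[idx] <- common * gw[[a]]
        G <- ttm(ttm(ttm(Fa, t(Bs[[1]]), 1), t(Bs[[2]]), 2), t(Bs[[3]]), 3)
        out[(a - 1) * k^3 + 1:k^3] <- G + 2 * control$lambda * pen * C[[a]]
      }
      out
    }
    opt <- stats::optim(cvec, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = control$nonlinear_maxit,
                                       factr = 1e4))
    cvec <- opt$par
    conv <- conv && opt$convergence %in% c(0L, 1L)
    if (control$verbose)
      message(sprintf("  nonlinear level %.3g mm: obj %.5g", lev, opt$value))
  }
  d0$coeffs <- list(x = array(cvec[1:k^3], rep(k, 3)),
                    y = array(cvec[k^3 + 1:k^3], rep(k, 3)),
                    z = array(cvec[2 * k^3 + 1:k^3], rep(k, 3)))
  structure(list(transform = d0, objective_trace = cummin(trace_all),
                 converged = conv, gain = gain),
            class = "registration_result")
}

# Regular world-point lattice over the fov used for inversion/projection.
inversion_lattice <- function(d, n) {
  lapply(1:3, function(a) seq(d$fov[1, a], d$fov[2, a], length.out = n))
}

#' Numerically invert a cosine-basis deformation
#'
#' Computes the reverse-direction map: the field `v` with
#' `(x + u) o (x + v) = x`, by fixed-point iteration
#' `v <- -u(x + v)` on a regular lattice over the field of view, then
#' re-projects `v` onto the same cosine basis by least squares. Errors out
#' when the forward map folds (nonpositive Jacobian).
#'
#' @param d a [dct_deformation].
#' @param n_points per-axis lattice size (default from the field's stored
#'   control, 25).
#' @param max_iter fixed-point iteration cap.
#' @return The inverse [dct_deformation]; the mean composition residual (mm)
#'   on the lattice is attached as attribute `"residual_mm"`.
#' @export
invert_deformation <- function(d, n_points = 25, max_iter = 50) {
  stopifnot(inherits(d, "dct_deformation"))
  axes <- inversion_lattice(d, n_points)
  P <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  colnames(P) <- NULL
  # Jacobian check on the lattice by finite differences of u
  hstep <- vapply(1:3, function(a) (d$fov[2, a] - d$fov[1, a]) / 200, 0)
  J <- array(0, c(nrow(P), 3, 3))
  for (a in 1:3) {
    Pp <- P; Pp[, a] <- Pp[, a] + hstep[a]
    Pm <- P; Pm[, a] <- Pm[, a] - hstep[a]
    J[, , a] <- (deformation_at_points(d, Pp) -
                   deformation_at_points(d, Pm)) / (2 * hstep[a])
  }
  detJ <- (1 + J[, 1, 1]) * ((1 + J[, 2, 2]) * (1 + J[, 3, 3]) -
                               J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * (1 + J[, 3, 3]) - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - (1 + J[, 2, 2]) * J[, 3, 1])
  if (any(detJ <= 0))
    stop("deformation folds (nonpositive Jacobian); cannot invert",
         call. = FALSE)
  V <- -deformation_at_points(d, P)
  for (it in seq_len(max_iter)) {
    Vn <- -deformation_at_points(d, P + V)
    delta <- max(abs(Vn - V))
    V <- Vn
    if (delta < 1e-6) break
  }
  # least-squares projection onto the separable basis
  Bs <- lapply(1:3, function(a)
    dct_basis_matrix(axes[[a]], d$fov[, a], d$k[a]))
  Ms <- lapply(Bs, function(B) solve(crossprod(B), t(B)))
  nper <- vapply(axes, length, 0L)
  proj <- function(vals) {
    A <- array(vals, nper)
    ttm(ttm(ttm(A, Ms[[1]], 1), Ms[[2]], 2), Ms[[3]], 3)
  }
  out <- dct_deformation(list(x = proj(V[, 1]), y = proj(V[, 2]),
                              z = proj(V[, 3])),
                         d$fov, d$grid, d$lambda)
  # composition residual of the projected inverse, ||(d o inv)(x) - x||
  Vp <- deformation_at_points(out, P)
  resid <- deformation_at_points(d, P + Vp) + Vp
  attr(out, "residual_mm") <- mean(sqrt(rowSums(resid^2)))
  out
}

#' Mirror conjugate of a deformation
#'
#' The field of the mirrored problem: `u*(x, y, z) =
#' (-ux(-x, y, z), uy(-x, y, z), uz(-x, y, z))`. Requires the field of view
#' to be symmetric about `x = 0`. In the cosine basis this flips the sign of
#' every odd-frequency term along x, plus a global sign flip of the x
#' component. Averaging a field with its mirror conjugate yields an
#' x-displacement that vanishes identically on the midsagittal plane.
#'
#' @param d a [dct_deformation] on an x-symmetric field of view.
#' @return The conjugated [dct_deformation].
#' @export
mirror_conjugate <- function(d) {
  stopifnot(inherits(d, "dct_deformation"))
  if (abs(d$fov[1, 1] + d$fov[2, 1]) > 1e-6)
    stop("field of view is not symmetric about x = 0", call. = FALSE)
  s <- (-1)^(seq_len(d$k[1]) - 1)
  out <- d
  for (a in c("x", "y", "z")) {
    co <- d$coeffs[[a]] * s  # recycles along the x mode
    out$coeffs[[a]] <- if (a == "x") -co else co
  }
  out
}

#' Average a set of cosine-basis deformations
#'
#' Coefficient-wise arithmetic mean of the reference-to-subject maps: the
#' resulting field is the spatially unbiased correction applied to every
#' normalized image so the atlas geometry is the mean of the group rather
#' than the chosen reference. Exactly linear and permutation invariant.
#'
#' @param fields list of [dct_deformation]s sharing grid, fov and order.
#' @return The mean [dct_deformation].
#' @export
average_deformation <- function(fields) {
  if (length(fields) < 1) stop("no deformations to average", call. = FALSE)
  d1 <- fields[[1]]
  for (f in fields) {
    stopifnot(inherits(f, "dct_deformation"))
    if (!all(f$k == d1$k) || max(abs(f$fov - d1$fov)) > 1e-9 ||
        !same_grid(f$grid, d1$grid))
      stop("deformations must share grid, fov and basis order",
           call. = FALSE)
  }
  n <- length(fields)
  avg <- lapply(c("x", "y", "z"), function(a)
    Reduce(`+`, lapply(fields, function(f) f$coeffs[[a]])) / n)
  dct_deformation(avg, d1$fov, d1$grid, d1$lambda)
}

#' Apply a cosine-basis deformation to a volume
#'
#' Resamples `vol` at `x + u(x)` over the deformation's reference grid,
#' trilinearly, with out-of-field values set to 0.
#'
#' @param d a [dct_deformation].
#' @param vol the [image_volume] to resample.
#' @param kind `"intensity"` or `"mask"`.
#' @param binarize re-binarize a mask at 0.5 (continuous by default).
#' @return The deformed [image_volume] on the reference grid.
#' @export
apply_deformation <- function(d, vol, kind = c("intensity", "mask"),
                              binarize = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(d, "dct_deformation"))
  assert_volume(vol)
  grid <- grid_of(d$grid)
  u <- deformation_field(d, grid)
  d3 <- grid$dim
  X <- grid_world_points(grid)
  pts <- cbind(X[, 1] + as.numeric(u$x), X[, 2] + as.numeric(u$y),
               X[, 3] + as.numeric(u$z))
  vals <- sample_world_points(list(vol$data), grid_of(vol), pts)[[1]]
  out <- volume_on_grid(grid, array(vals, d3), vol$description)
  if (kind == "mask" && binarize) out$data <- (out$data >= 0.5) * 1
  out
}

# Serialize / restore transforms as JSON-friendly lists.
transform_to_list <- function(t) {
  if (inherits(t, "affine_params"))
    return(list(type = "affine", translation = t$translation,
                rotation = t$rotation, scale = t$scale, shear = t$shear))
  if (inherits(t, "dct_deformation"))
    return(list(type = "dct", k = t$k, fov = t$fov,
                grid = list(dim = t$grid$dim,
                            world_from_voxel = t$grid$world_from_voxel),
                lambda = t$lambda,
                coeffs = lapply(t$coeffs, as.numeric)))
  stop("unknown transform type", call. = FALSE)
}

list_to_transform <- function(l) {
  if (l$type == "affine")
    return(affine_params(l$translation, l$rotation, l$scale, l$shear))
  k <- as.integer(l$k)
  grid <- vol_grid(as.integer(l$grid$dim),
                   matrix(unlist(l$grid$world_from_voxel), 4, 4))
  dct_deformation(lapply(l$coeffs, function(v) array(unlist(v), k)),
                  matrix(unlist(l$fov), 2, 3), grid, l$lambda)
}

#' Export a deformation as a NIfTI displacement volume
#'
#' Writes the field evaluated on its reference grid as a 4D NIfTI file with
#' three volumes (x, y, z displacement in mm), the interchange form other
#' registration toolkits read.
#'
#' @param d a [dct_deformation].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_deformation_nifti <- function(d, path) {
  stopifnot(inherits(d, "dct_deformation"))
  u <- deformation_field(d)
  grid <- grid_of(d$grid)
  arr <- array(c(u$x, u$y, u$z), c(grid$dim, 3L))
  im <- RNifti::asNifti(
    arr, reference = list(pixdim = c(-1, grid$voxel_size, 1, 0, 0, 0),
                          intent_code = 1006L))
  m <- grid$world_from_voxel
  RNifti::sform(im) <- structure(m, code = 2L)
  RNifti::qform(im) <- structure(m, code = 2L)
  RNifti::writeNifti(im, path, datatype = "double")
  invisible(path)
}

#' Write a transform to JSON
#' @param t an [affine_params] or [dct_deformation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(transform_to_list(t), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a transform from JSON
#' @param path JSON file written by [write_transform].
#' @return The transform object.
#' @export
read_transform <- function(path) {
  list_to_transform(jsonlite::read_json(path, simplifyVector = TRUE))
}
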