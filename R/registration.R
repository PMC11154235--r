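#' Rigid or affine world-space transform
#'
#' Maps a world point `x` (mm) to `matrix %*% (x - center) + center +
#' translation`. During registration the transform maps points of the fixed
#' image's frame to sampling positions in the moving image.
#'
#' @param matrix 3x3 linear part. For `phase = "rigid"` it must be a rotation
#'   (orthonormal, det +1 within 1e-6).
#' @param translation Length-3 translation in mm.
#' @param center Rotation center in world mm (default the world origin).
#' @param phase `"rigid"` or `"affine"`.
#' @return An object of class `rigid_affine_transform`.
#' @export
rigid_affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                                   center = c(0, 0, 0),
                                   phase = c("rigid", "affine")) {
  phase <- match.arg(phase)
  matrix <- unname(as.matrix(matrix))
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  if (!all(dim(matrix) == c(3, 3)) || any(!is.finite(matrix)))
    abort("linear part must be a finite 3x3 matrix", "orthosr_type_error")
  if (abs(det(matrix)) < 1e-9)
    abort("transform is not invertible", "orthosr_singular_transform_error")
  if (phase == "rigid" &&
      (max(abs(crossprod(matrix) - diag(3))) > 1e-6 ||
       abs(det(matrix) - 1) > 1e-6))
    abort("rigid linear part must be a rotation (orthonormal, det +1)",
          "orthosr_not_rigid_error")
  structure(list(matrix = matrix, translation = translation, center = center,
                 phase = phase),
            class = "rigid_affine_transform")
}

#' @export
print.rigid_affine_transform <- function(x, ...) {
  cat(sprintf("<rigid_affine_transform> phase: %s\n", x$phase))
  cat(sprintf("  rotation/linear det = %.6f, translation (%.3f, %.3f, %.3f) mm\n",
              det(x$matrix), x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

#' Apply a transform to world points
#'
#' @param tf A [rigid_affine_transform()].
#' @param points N x 3 matrix (or length-3 vector) of world coordinates.
#' @return Transformed coordinates, same shape.
#' @export
apply_transform <- function(tf, points) {
  v <- is.null(dim(points))
  p <- if (v) matrix(points, 1) else points
  out <- t(tf$matrix %*% (t(p) - tf$center) + tf$center + tf$translation)
  if (v) as.vector(out) else out
}

#' Invert a transform
#'
#' @param tf A [rigid_affine_transform()].
#' @return The inverse transform (same center and phase).
#' @export
invert_transform <- function(tf) {
  Minv <- solve(tf$matrix)
  rigid_affine_transform(Minv, -as.vector(Minv %*% tf$translation),
                         center = tf$center, phase = tf$phase)
}

# Transform as homogeneous 4x4 world matrix (center folded into translation).
transform_matrix <- function(tf) {
  t4 <- tf$center + tf$translation - as.vector(tf$matrix %*% tf$center)
  rbind(cbind(tf$matrix, t4), c(0, 0, 0, 1))
}

#' Serialize a transform to a plain-text 4x4 matrix file
#'
#' The file holds the homogeneous world-mm matrix, row-major, one row per
#' line, for auditability.
#'
#' @param tf A [rigid_affine_transform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(tf, path) {
  m <- transform_matrix(tf)
  writeLines(apply(m, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                           collapse = " ")), path)
  invisible(path)
}

#' Read a transform from a 4x4 matrix file
#'
#' @param path File written by [write_transform()].
#' @param phase Declared phase of the stored transform.
#' @return A [rigid_affine_transform()] with center at the world origin.
#' @export
read_transform <- function(path, phase = c("affine", "rigid")) {
  phase <- match.arg(phase)
  m <- as.matrix(read.table(path))
  rigid_affine_transform(m[1:3, 1:3], m[1:3, 4], center = c(0, 0, 0),
                         phase = phase)
}

# Rotation matrix from extrinsic XYZ Euler angles (radians): R = Rz Ry Rx.
euler_matrix <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotation angle between two linear parts, in degrees
#'
#' @param m1,m2 3x3 rotation matrices.
#' @return The geodesic angle of `m1 %*% t(m2)` in degrees.
#' @export
rotation_angle_deg <- function(m1, m2 = diag(3)) {
  tr <- sum(diag(m1 %*% t(m2)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Align a volume into the fixed frame by moving its lattice
#'
#' Applies the inverse of a registration transform to the volume's geometry
#' (origin and orientation), leaving the voxel data untouched. For rigid
#' transforms this realigns the stack exactly, with no interpolation: the
#' nearest-voxel fusion consumes centroid coordinate lists, and the
#' transformed lattice is an equally valid input. Only valid for transforms
#' whose linear part is a rotation.
#'
#' @param vol An `mri_volume`.
#' @param tf A rigid [rigid_affine_transform()] mapping fixed-frame points to
#'   positions in `vol`'s frame (as returned by [register_volumes()]).
#' @return The volume with its lattice moved into the fixed frame.
#' @export
align_volume <- function(vol, tf) {
  stopifnot_volume(vol)
  if (max(abs(crossprod(tf$matrix) - diag(3))) > 1e-6)
    abort("lattice alignment requires a rigid transform",
          "orthosr_not_rigid_error")
  inv <- invert_transform(tf)
  out <- vol
  out$origin <- apply_transform(inv, vol$origin)
  out$orientation <- inv$matrix %*% vol$orientation
  out
}

#' Normalized correlation between two volumes on the same grid
#'
#' Pearson correlation of intensities over the evaluation mask; 1 for
#' identical images. This is the registration cost metric (maximized), chosen
#' because all stacks share one modality and sequence.
#'
#' @param a,b `mri_volume`s on the same grid (same dimensions).
#' @param mask Optional logical vector/array selecting the evaluated voxels.
#' @return Scalar in \[-1, 1\].
#' @export
normalized_correlation <- function(a, b, mask = NULL) {
  stopifnot_volume(a); stopifnot_volume(b)
  if (!all(dim(a$data) == dim(b$data)))
    abort("volumes must share one grid", "orthosr_shape_error")
  x <- as.vector(a$data); y <- as.vector(b$data)
  if (!is.null(mask)) {
    mask <- as.vector(mask)
    x <- x[mask]; y <- y[mask]
  }
  ncc_vec(x, y)
}

ncc_vec <- function(x, y) {
  if (length(x) < 2 || min(x) == max(x) || min(y) == max(y))
    abort("normalized correlation undefined for constant input over the mask",
          "orthosr_constant_image_error")
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc * xc) * sum(yc * yc))
}

#' Registration configuration
#'
#' Multi-resolution settings for [register_volumes()]. Defaults: a 3-level
#' pyramid (shrink factors 4/2/1 with Gaussian smoothing sigmas 2/1/0 voxels),
#' Nelder-Mead with at most `max_iterations` cost evaluations per level, and
#' the rigid phase followed by an affine phase only when the rigid phase fails
#' to converge (relative cost improvement below `convergence_tol`).
#'
#' @param phases `"auto"` (rigid, then affine only on rigid non-convergence),
#'   `"rigid"`, or `"rigid+affine"` (always run both).
#' @param shrink_factors Integer pyramid shrink factors, coarse to fine.
#' @param smoothing_sigmas Gaussian sigmas (voxels of the level) per level.
#' @param max_iterations Maximum optimizer iterations per level.
#' @param restarts Number of Nelder-Mead restarts per level (each restart
#'   rebuilds the simplex around the current optimum, refining it).
#' @param convergence_tol Relative cost improvement under which the rigid
#'   phase is declared non-converged.
#' @param sample_stride Integer voxel stride used when evaluating the metric
#'   at the finest level (deterministic subsampling; 1 = all voxels).
#' @param foreground_fraction Fixed-image intensity threshold, as a fraction
#'   of the fixed image's intensity range, below which voxels are excluded
#'   from the metric. Air background carries no alignment information but
#'   dominates the voxel count, flattening the cost surface; masking it
#'   sharpens the optimum. 0 disables the mask.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(phases = c("auto", "rigid", "rigid+affine"),
                                shrink_factors = c(4, 2, 1),
                                smoothing_sigmas = c(2, 1, 0),
                                max_iterations = 200,
                                convergence_tol = 1e-6,
                                sample_stride = 2, restarts = 2,
                                foreground_fraction = 0.02) {
  phases <- match.arg(phases)
  stopifnot(length(shrink_factors) == length(smoothing_sigmas))
  structure(list(phases = phases, shrink_factors = shrink_factors,
                 smoothing_sigmas = smoothing_sigmas,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 sample_stride = sample_stride, restarts = restarts,
                 foreground_fraction = foreground_fraction),
            class = "registration_config")
}

# Smooth then decimate a volume for one pyramid level.
pyramid_level <- function(vol, shrink, sigma) {
  v <- vol
  if (sigma > 0) {
    sm <- cpp_gauss_smooth(as.vector(vol$data), dim(vol$data),
                           rep(sigma, 3))
    v$data <- array(sm, dim = dim(vol$data))
  }
  if (shrink > 1) v <- reslice(v, spacing = vol$spacing * shrink)
  v
}

# Sample `moving` on the (strided) fixed grid through world transform m4 and
# return -NCC over the in-field foreground mask. Inf when the overlap is too
# small.
reg_cost <- function(moving, fixed_sub, m4) {
  g <- fixed_sub
  r <- cpp_resample(as.vector(moving$data), dim(moving$data), moving$spacing,
                    moving$origin, moving$orientation,
                    as.integer(g$dims), g$spacing, g$origin, g$orientation,
                    m4, 1L, 0, 0L, TRUE)
  mask <- r$mask & g$foreground
  if (sum(mask) < max(32, 0.05 * length(mask))) return(Inf)
  x <- g$values[mask]
  y <- r$data[mask]
  if (min(x) == max(x) || min(y) == max(y)) return(Inf)
  -ncc_vec(x, y)
}

# Strided subgrid of a volume, precomputing the fixed intensities and the
# foreground evaluation mask.
strided_grid <- function(vol, stride, foreground_fraction = 0) {
  d <- dim(vol$data)
  idx <- lapply(d, function(n) seq.int(1L, n, by = as.integer(stride)))
  nd <- vapply(idx, length, 1L)
  values <- as.vector(vol$data[idx[[1]], idx[[2]], idx[[3]]])
  fg <- if (foreground_fraction > 0) {
    r <- range(values)
    values > r[1] + foreground_fraction * (r[2] - r[1])
  } else rep(TRUE, length(values))
  list(dims = nd, spacing = vol$spacing * stride,
       origin = vol$origin,
       orientation = vol$orientation,
       values = values, foreground = fg)
}

params_to_m4 <- function(par, center, phase) {
  if (phase == "rigid") {
    M <- euler_matrix(par[1], par[2], par[3])
    t <- par[4:6]
  } else {
    M <- diag(3) + matrix(par[1:9], 3, 3)
    t <- par[10:12]
  }
  t4 <- center + t - as.vector(M %*% center)
  rbind(cbind(M, t4), c(0, 0, 0, 1))
}

#' Register a moving volume to a fixed volume
#'
#' Multi-resolution intensity-based registration maximizing normalized
#' correlation. A rigid (6 DOF) phase runs first; an affine (12 DOF) phase
#' refines it when the rigid phase fails to converge (or always, with
#' `phases = "rigid+affine"`). The moving volume is finally resampled onto the
#' fixed grid by linear interpolation.
#'
#' If optimization cannot improve the cost beyond its value at the identity
#' initialization, the identity transform is returned with `flagged = TRUE`
#' and a warning.
#'
#' @param moving,fixed Overlapping, non-constant `mri_volume`s.
#' @param config A [registration_config()].
#' @return A list with elements `transform` (maps fixed-frame world points to
#'   moving-frame sampling positions), `resampled` (moving on the fixed grid),
#'   `converged`, `flagged`, `phase`, `cost_initial`, `cost_final`
#'   (negated normalized correlation).
#' @export
register_volumes <- function(moving, fixed, config = registration_config()) {
  stopifnot_volume(moving); stopifnot_volume(fixed)
  if (!volumes_overlap(moving, fixed))
    abort("moving and fixed volumes do not overlap in world space",
          "orthosr_no_overlap_error")
  for (v in list(moving, fixed))
    if (min(v$data) == max(v$data))
      abort("cannot register constant images", "orthosr_constant_image_error")

  d <- dim(fixed$data)
  center <- as.vector(fixed$origin +
                        fixed$orientation %*% (fixed$spacing * (d - 1) / 2))
  nlev <- length(config$shrink_factors)
  levels <- lapply(seq_len(nlev), function(l) {
    v <- pyramid_level(fixed, config$shrink_factors[l],
                       config$smoothing_sigmas[l])
    stride <- if (config$shrink_factors[l] == 1) config$sample_stride else 1L
    strided_grid(v, stride, config$foreground_fraction)
  })
  moving_levels <- lapply(seq_len(nlev), function(l) {
    pyramid_level(moving, config$shrink_factors[l],
                  config$smoothing_sigmas[l])
  })

  run_phase <- function(phase, par0) {
    par <- par0
    conv <- TRUE
    for (l in seq_len(nlev)) {
      fs <- levels[[l]]
      mv <- moving_levels[[l]]
      fn <- function(p) reg_cost(mv, fs, params_to_m4(p, center, phase))
      scale <- if (phase == "rigid") c(rep(0.02, 3), rep(1, 3)) else
        c(rep(0.02, 9), rep(1, 3))
      c0 <- fn(par)
      best <- c0
      opt <- NULL
      for (rs in seq_len(1 + config$restarts)) {
        o <- stats::optim(par, fn, method = "Nelder-Mead",
                          control = list(maxit = config$max_iterations,
                                         parscale = scale,
                                         reltol = config$convergence_tol))
        if (is.finite(o$value) && o$value <= best) {
          par <- o$par
          best <- o$value
        }
        opt <- o
      }
      # non-convergence: optimizer hit the iteration cap or made no
      # meaningful relative improvement at the finest level
      if (l == nlev) {
        improved <- is.finite(c0) && is.finite(opt$value) &&
          (c0 - opt$value) > config$convergence_tol * abs(c0)
        conv <- opt$convergence == 0 || improved
      }
    }
    list(par = par, converged = conv)
  }

  rigid0 <- rep(0, 6)
  res <- run_phase("rigid", rigid0)
  phase <- "rigid"
  M <- euler_matrix(res$par[1], res$par[2], res$par[3])
  trans <- res$par[4:6]
  if ((config$phases == "auto" && !res$converged) ||
      config$phases == "rigid+affine") {
    par0 <- c(as.vector(M - diag(3)), trans)
    res_aff <- run_phase("affine", par0)
    phase <- "affine"
    M <- diag(3) + matrix(res_aff$par[1:9], 3, 3)
    trans <- res_aff$par[10:12]
    res <- res_aff
  }

  # monotone acceptance at full resolution
  fs <- levels[[nlev]]
  mv <- moving_levels[[nlev]]
  m4 <- params_to_m4(if (phase == "rigid") c(res$par) else c(res$par), center,
                     phase)
  cost_init <- reg_cost(mv, fs, diag(4))
  cost_final <- reg_cost(mv, fs, m4)
  flagged <- FALSE
  if (!is.finite(cost_final) || cost_final > cost_init) {
    warning("registration failed to improve on the identity; returning identity")
    flagged <- TRUE
    M <- diag(3); trans <- c(0, 0, 0)
    cost_final <- cost_init
    phase <- "rigid"
  }

  tf <- rigid_affine_transform(M, trans, center = center, phase = phase)
  resampled <- reslice_through <- cpp_resample(
    as.vector(moving$data), dim(moving$data), moving$spacing, moving$origin,
    moving$orientation, as.integer(dim(fixed$data)), fixed$spacing,
    fixed$origin, fixed$orientation, transform_matrix(tf), 1L, 0, 0L, FALSE)
  out_vol <- mri_volume(array(resampled$data, dim = dim(fixed$data)),
                        spacing = fixed$spacing, origin = fixed$origin,
                        orientation = fixed$orientation)
  list(transform = tf, resampled = out_vol, converged = res$converged,
       flagged = flagged, phase = phase, cost_initial = cost_init,
       cost_final = cost_final)
}
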