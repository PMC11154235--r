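#' Isotropic template grid for super-resolution reconstruction
#'
#' The output lattice of the fusion step. Initialized from the isotropically
#' resliced target stack: dimensions, spacing, origin and orientation are
#' copied exactly.
#'
#' @param target An isotropic `mri_volume` (all spacings equal within 1e-6,
#'   relatively).
#' @return An object of class `template_grid` with fields `dims`, `spacing`
#'   (scalar mm), `origin`, `orientation`.
#' @export
template_grid <- function(target) {
  stopifnot_volume(target)
  if (!is_isotropic(target))
    abort("template grid requires an isotropic target volume",
          "orthosr_anisotropic_error")
  structure(list(dims = dim(target$data), spacing = target$spacing[1],
                 origin = target$origin, orientation = target$orientation),
            class = "template_grid")
}

#' @export
print.template_grid <- function(x, ...) {
  cat(sprintf("<template_grid> %d x %d x %d @ %.4g mm isotropic\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}

#' Nearest source voxel for each query point
#'
#' Builds a k-d tree over all voxel centroids of `vol` (world mm) and returns,
#' for every query point, the centroid with minimal Euclidean distance. Ties
#' are broken toward the smallest flattened (column-major) voxel index, so
#' results are deterministic and identical to an exhaustive scan.
#'
#' @param vol Source `mri_volume`.
#' @param points N x 3 matrix of world query coordinates (mm), or a length-3
#'   vector for a single point.
#' @return A list with `index` (flattened 1-based voxel index), `distance`
#'   (mm), `intensity` (the matched voxel's value) and `source_index`
#'   (N x 3 array indices).
#' @export
nearest_voxels <- function(vol, points) {
  stopifnot_volume(vol)
  if (length(vol$data) == 0)
    abort("empty volume", "orthosr_empty_error")
  if (is.null(dim(points))) points <- matrix(points, 1)
  pts <- voxel_centroids(vol)
  nn <- cpp_nn_search(pts, points)
  list(index = nn$index, distance = nn$distance,
       intensity = as.vector(vol$data)[nn$index],
       source_index = arrayInd(nn$index, dim(vol$data)))
}

#' Inverse-distance fusion weights
#'
#' For P planes with nearest-voxel distances `d_p`, the weight of plane p is
#' `w_p = (d_total - d_p) / ((P - 1) * d_total)` with `d_total = sum(d_p)`,
#' so closer planes contribute more and the weights always sum to 1. With the
#' standard three planes the denominator is `2 * d_total`. When all distances
#' are zero (template voxel coincident with a voxel of every plane) the
#' symmetric limit of equal weights `1/P` is used.
#'
#' @param d Distances in mm: a length-P vector (one voxel) or an N x P matrix
#'   (one row per template voxel). All entries must be >= 0 and P >= 2.
#' @return Weights with the same shape as `d`, each in \[0, 1\], rows summing
#'   to 1.
#' @export
fusion_weights <- function(d) {
  vec <- is.null(dim(d))
  m <- if (vec) matrix(d, nrow = 1) else as.matrix(d)
  if (ncol(m) < 2)
    abort("at least two planes are required", "orthosr_too_few_planes_error")
  if (any(m < 0))
    abort("distances must be non-negative", "orthosr_negative_distance_error")
  P <- ncol(m)
  # plain double-precision left-to-right accumulation (not long-double
  # rowSums) so results are bit-identical to a scalar-loop implementation
  dtot <- m[, 1]
  for (p in 2:P) dtot <- dtot + m[, p]
  w <- (dtot - m) / ((P - 1) * dtot)
  degen <- dtot == 0
  if (any(degen)) w[degen, ] <- 1 / P
  if (vec) as.vector(w) else w
}

#' Fuse orthogonal stacks onto an isotropic template grid
#'
#' The core reconstruction: every template voxel's intensity is the weighted
#' sum of its nearest voxel in each plane, with inverse-distance weights from
#' [fusion_weights()]. Distances are Euclidean, in world mm, between the
#' template voxel centroid and the matched source centroid. The result is a
#' convex combination, so each output intensity is clamped to the
#' \[min, max\] of its contributing samples (guarding against floating-point
#' rounding); with inputs in \[0, 1\] the output stays in \[0, 1\].
#'
#' The reconstruction is deterministic: two runs on identical input are
#' bit-identical.
#'
#' @param planes Named list of >= 2 registered `mri_volume`s sharing one world
#'   frame.
#' @param grid A [template_grid()].
#' @param audit Keep per-voxel per-plane distances, indices and weights?
#' @return An object of class `fusion_result`: `volume` (the reconstructed
#'   `mri_volume` on the template grid), `audit` (NULL or a list of N x P
#'   matrices `distance`, `index`, `weight`), and `timings` (seconds spent in
#'   the coordinate-initialization, tree-build-plus-search, and reconstruction
#'   stages).
#' @export
sr_reconstruct <- function(planes, grid, audit = FALSE) {
  if (!inherits(grid, "template_grid"))
    abort("grid must be a template_grid", "orthosr_type_error")
  if (length(planes) < 2)
    abort("at least two planes are required", "orthosr_too_few_planes_error")
  for (p in planes) {
    stopifnot_volume(p)
    if (length(p$data) == 0) abort("empty plane volume", "orthosr_empty_error")
    if (!volumes_overlap(p, grid))
      abort("plane and template grid do not overlap in world space",
            "orthosr_no_overlap_error")
  }
  P <- length(planes)
  t0 <- proc.time()[["elapsed"]]
  queries <- voxel_centroids(grid)
  plane_pts <- lapply(planes, voxel_centroids)
  t1 <- proc.time()[["elapsed"]]
  n <- nrow(queries)
  D <- matrix(0, n, P)
  V <- matrix(0, n, P)
  I <- matrix(0L, n, P)
  for (p in seq_len(P)) {
    nn <- cpp_nn_search(plane_pts[[p]], queries)
    D[, p] <- nn$distance
    I[, p] <- nn$index
    V[, p] <- as.vector(planes[[p]]$data)[nn$index]
  }
  t2 <- proc.time()[["elapsed"]]
  W <- fusion_weights(D)
  out <- W[, 1] * V[, 1]
  for (p in seq_len(P)[-1]) out <- out + W[, p] * V[, p]
  # convexity clamp (floating-point guard)
  lo <- do.call(pmin, lapply(seq_len(P), function(p) V[, p]))
  hi <- do.call(pmax, lapply(seq_len(P), function(p) V[, p]))
  out <- pmin(pmax(out, lo), hi)
  vol <- mri_volume(array(out, dim = grid$dims),
                    spacing = rep(grid$spacing, 3), origin = grid$origin,
                    orientation = grid$orientation)
  t3 <- proc.time()[["elapsed"]]
  structure(list(volume = vol,
                 audit = if (audit) list(distance = D, index = I, weight = W)
                         else NULL,
                 timings = c(coordinate_init = t1 - t0,
                             tree_build_search = t2 - t1,
                             reconstruction = t3 - t2)),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result>\n")
  print(x$volume)
  cat(sprintf("  stage timings (s): coords %.2f, tree+search %.2f, reconstruction %.2f\n",
              x$timings[1], x$timings[2], x$timings[3]))
  invisible(x)
}

#' Reconstruct from the three orthogonal stacks of a study
#'
#' Convenience wrapper over [sr_reconstruct()] for the standard three-plane
#' case. The study must already be registered and histogram matched, with the
#' target stack resliced isotropic; by default the template grid is taken from
#' the target stack's geometry.
#'
#' @param study An [orthogonal_study()] (registered, intensity matched).
#' @param grid A [template_grid()]; defaults to the target stack's grid (the
#'   target must then be isotropic).
#' @param audit Keep per-voxel audit data?
#' @return A `fusion_result`; the weight columns are ordered sagittal, axial,
#'   coronal.
#' @export
reconstruct_sr <- function(study, grid = NULL, audit = FALSE) {
  if (!inherits(study, "orthogonal_study"))
    abort("expected an orthogonal_study", "orthosr_type_error")
  if (is.null(grid)) grid <- template_grid(study[[study$target_plane]])
  sr_reconstruct(list(sagittal = study$sagittal, axial = study$axial,
                      coronal = study$coronal), grid, audit = audit)
}

#' Dump fusion audit data to a compressed file
#'
#' Layout: an RDS file holding the list of N x P `distance`, `index` and
#' `weight` matrices, with template voxels in flattened (column-major) order
#' and plane columns in the order the planes were supplied.
#'
#' @param result A `fusion_result` created with `audit = TRUE`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
write_fusion_audit <- function(result, path) {
  if (!inherits(result, "fusion_result") || is.null(result$audit))
    abort("fusion result has no audit data (run with audit = TRUE)",
          "orthosr_type_error")
  saveRDS(result$audit, path, compress = "gzip")
  invisible(path)
}
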