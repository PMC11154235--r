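#' 3D image volume with world-space geometry
#'
#' The universal currency of the pipeline: a 3D scalar array plus the geometry
#' that places every voxel in world (scanner) space. The world coordinate of
#' the centroid of voxel `(i, j, k)` (0-based) is
#' `origin + orientation %*% (spacing * c(i, j, k))`.
#'
#' @param data 3D numeric array of intensities. Must not contain `NA`/`NaN`.
#' @param spacing Per-axis voxel size in mm (strictly positive, length 3).
#' @param origin World coordinates (mm) of the first voxel centroid.
#' @param orientation 3x3 direction matrix with orthonormal columns mapping
#'   index axes to world axes (`abs(det)` = 1 within 1e-6).
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       orientation = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("data must be a 3D array", "orthosr_not_3d_error")
  if (anyNA(data))
    abort("volume data contains NA/NaN values", "orthosr_nan_error")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- unname(as.matrix(orientation))
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("spacing must be three strictly positive values",
          "orthosr_bad_geometry_error")
  if (length(origin) != 3L || any(!is.finite(origin)))
    abort("origin must be three finite values", "orthosr_bad_geometry_error")
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6 ||
      abs(abs(det(orientation)) - 1) > 1e-6)
    abort("orientation must be a 3x3 matrix with orthonormal columns",
          "orthosr_bad_geometry_error")
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mri_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm; intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.mri_volume <- function(x) dim(x$data)

is_mri_volume <- function(x) inherits(x, "mri_volume")

stopifnot_volume <- function(x) {
  if (!is_mri_volume(x))
    abort("expected an mri_volume object", "orthosr_type_error")
  invisible(x)
}

#' 4x4 voxel-to-world affine of a volume
#'
#' @param vol An `mri_volume`.
#' @return 4x4 matrix mapping homogeneous 0-based voxel indices to world mm.
#' @export
vol_affine <- function(vol) {
  stopifnot_volume(vol)
  rbind(cbind(vol$orientation %*% diag(vol$spacing), vol$origin),
        c(0, 0, 0, 1))
}

#' World coordinates of all voxel centroids
#'
#' Centroids are returned in flattened (column-major, i fastest) voxel order,
#' the order in which `as.vector(vol$data)` enumerates intensities.
#'
#' @param vol An `mri_volume` or `template_grid`.
#' @return N x 3 matrix of world coordinates in mm.
#' @export
voxel_centroids <- function(vol) {
  g <- vol_geometry(vol)
  d <- g$dims
  i <- rep.int(seq_len(d[1]) - 1, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  R <- g$orientation
  sp <- g$spacing
  cbind(g$origin[1] + R[1, 1] * sp[1] * i + R[1, 2] * sp[2] * j + R[1, 3] * sp[3] * k,
        g$origin[2] + R[2, 1] * sp[1] * i + R[2, 2] * sp[2] * j + R[2, 3] * sp[3] * k,
        g$origin[3] + R[3, 1] * sp[1] * i + R[3, 2] * sp[2] * j + R[3, 3] * sp[3] * k)
}

# Uniform geometry accessor for mri_volume and template_grid objects.
vol_geometry <- function(x) {
  if (is_mri_volume(x)) {
    list(dims = dim(x$data), spacing = x$spacing, origin = x$origin,
         orientation = x$orientation)
  } else if (inherits(x, "template_grid")) {
    list(dims = x$dims, spacing = rep(x$spacing, 3), origin = x$origin,
         orientation = x$orientation)
  } else {
    abort("expected an mri_volume or template_grid", "orthosr_type_error")
  }
}

# World-space axis-aligned bounding box of the voxel centroids.
vol_bbox <- function(x) {
  g <- vol_geometry(x)
  d <- g$dims
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  w <- t(g$orientation %*% (t(corners) * g$spacing) + g$origin)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

# Do two objects sample exactly the same world lattice?
same_geometry <- function(a, b, tol = 1e-6) {
  ga <- vol_geometry(a); gb <- vol_geometry(b)
  all(ga$dims == gb$dims) &&
    max(abs(ga$spacing - gb$spacing)) < tol &&
    max(abs(ga$origin - gb$origin)) < tol &&
    max(abs(ga$orientation - gb$orientation)) < tol
}

# Nonzero-volume intersection of two world bounding boxes.
volumes_overlap <- function(a, b) {
  ba <- vol_bbox(a); bb <- vol_bbox(b)
  all(pmin(ba[2, ], bb[2, ]) - pmax(ba[1, ], bb[1, ]) > 0)
}

#' Is a volume isotropic?
#'
#' @param vol An `mri_volume`.
#' @param tol Relative tolerance on spacing equality.
#' @return Logical.
#' @export
is_isotropic <- function(vol, tol = 1e-6) {
  sp <- vol_geometry(vol)$spacing
  diff(range(sp)) <= tol * max(sp)
}

#' Triplet of orthogonal stacks for one subject
#'
#' Bundles the three orthogonal acquisitions plus the designated target plane
#' (the plane whose geometry seeds the isotropic template; sagittal by default
#' because it gives the best view of knee structures such as the ACL).
#'
#' @param sagittal,axial,coronal `mri_volume` objects that overlap in world
#'   space.
#' @param target_plane One of `"sagittal"`, `"axial"`, `"coronal"`.
#' @return An object of class `orthogonal_study`.
#' @export
orthogonal_study <- function(sagittal, axial, coronal,
                             target_plane = c("sagittal", "axial", "coronal")) {
  target_plane <- match.arg(target_plane)
  stopifnot_volume(sagittal); stopifnot_volume(axial); stopifnot_volume(coronal)
  pairs <- list(c("sagittal", "axial"), c("sagittal", "coronal"),
                c("axial", "coronal"))
  vols <- list(sagittal = sagittal, axial = axial, coronal = coronal)
  for (p in pairs) {
    if (!volumes_overlap(vols[[p[1]]], vols[[p[2]]]))
      abort(sprintf("%s and %s stacks do not overlap in world space",
                    p[1], p[2]), "orthosr_no_overlap_error")
  }
  structure(list(sagittal = sagittal, axial = axial, coronal = coronal,
                 target_plane = target_plane),
            class = "orthogonal_study")
}

#' @export
print.orthogonal_study <- function(x, ...) {
  cat("<orthogonal_study> target plane:", x$target_plane, "\n")
  for (p in c("sagittal", "axial", "coronal")) {
    d <- dim(x[[p]]$data)
    cat(sprintf("  %-8s %d x %d x %d @ %.3g x %.3g x %.3g mm\n", p,
                d[1], d[2], d[3], x[[p]]$spacing[1], x[[p]]$spacing[2],
                x[[p]]$spacing[3]))
  }
  invisible(x)
}
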