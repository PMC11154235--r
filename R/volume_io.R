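#' Read a 3D NIfTI volume
#'
#' Decodes geometry from the header affine: spacing as the column norms of the
#' 3x3 block, orientation as the normalized columns, origin as the
#' translation. When both qform and sform are present RNifti's policy of
#' preferring the qform is kept.
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a single 3D scalar
#'   image.
#' @return An [mri_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), "orthosr_missing_file_error")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    d <- d[1:3]
  } else if (length(d) != 3L) {
    abort(sprintf("expected a 3D scalar image, got %d dimensions", length(d)),
          "orthosr_not_3d_error")
  }
  aff <- unclass(RNifti::xform(img))[1:3, , drop = FALSE]
  lin <- aff[, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(lin^2))
  if (any(spacing < 1e-12))
    abort("degenerate affine: zero-norm direction column",
          "orthosr_bad_affine_error")
  orientation <- sweep(lin, 2, spacing, "/")
  data <- array(as.numeric(img), dim = d)
  if (anyNA(data))
    abort("NIfTI data contains NaN values", "orthosr_nan_error")
  mri_volume(data, spacing = spacing, origin = aff[, 4],
             orientation = orientation)
}

#' Write a volume as NIfTI
#'
#' Round-trips bit-exactly for data (stored as float64) and within 1e-6 mm for
#' geometry. Both qform and sform are written with the same affine.
#'
#' @param vol An [mri_volume()].
#' @param path Output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  if (!dir.exists(dirname(path)))
    abort(paste0("directory does not exist: ", dirname(path)),
          "orthosr_unwritable_error")
  data <- vol$data
  attr(data, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(data, datatype = "double")
  aff <- vol_affine(vol)
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Min-max normalize intensities to [0, 1]
#'
#' @param vol An [mri_volume()] with at least two distinct intensity values.
#' @return A volume with identical geometry and intensities mapped linearly so
#'   the minimum is 0 and the maximum 1.
#' @export
minmax_normalize <- function(vol) {
  stopifnot_volume(vol)
  r <- range(vol$data)
  if (r[1] == r[2])
    abort("cannot normalize a constant image (zero intensity range)",
          "orthosr_constant_image_error")
  out <- vol
  out$data <- (vol$data - r[1]) / (r[2] - r[1])
  out
}

#' Histogram match one volume to a reference
#'
#' Exact-quantile matching over all voxels (no binning): every source voxel is
#' remapped monotonically so the empirical CDF of the output equals that of
#' the reference. Rank order is preserved (ties allowed). Used before
#' registration to remove per-stack intensity scale differences, and again as
#' the pipeline's final step.
#'
#' @param source Volume to remap.
#' @param reference Volume supplying the target intensity distribution.
#' @return A volume with `source`'s geometry and matched intensities.
#' @export
match_histogram <- function(source, reference) {
  stopifnot_volume(source); stopifnot_volume(reference)
  for (v in list(source, reference)) {
    r <- range(v$data)
    if (r[1] == r[2])
      abort("histogram matching requires non-constant images",
            "orthosr_constant_image_error")
  }
  src <- as.vector(source$data)
  ref <- as.vector(reference$data)
  uv <- sort(unique(src))
  # empirical CDF of the source evaluated at its own unique values
  cnt <- tabulate(match(src, uv), nbins = length(uv))
  src_q <- cumsum(cnt) / length(src)
  # reference quantile function (piecewise-linear inverse ECDF) at those levels
  ref_sorted <- sort(ref)
  m <- length(ref_sorted)
  mapped <- stats::approx(x = seq_len(m) / m, y = ref_sorted, xout = src_q,
                          rule = 2)$y
  out <- source
  out$data <- array(mapped[match(src, uv)], dim = dim(source$data))
  out
}

#' Reslice a volume to a new sampling lattice
#'
#' Samples the volume in world space on either an isotropic/arbitrary spacing
#' (keeping the world center and extent of the input) or an explicit target
#' grid. Voxels falling outside the source field of view are filled with
#' `fill` (default 0, MRI background) unless `boundary = "nearest"` clamps to
#' the edge voxel.
#'
#' @param vol An [mri_volume()].
#' @param spacing New voxel size in mm: a scalar (isotropic) or length-3
#'   vector. Exactly one of `spacing`/`grid` must be given.
#' @param grid A [template_grid()] or `mri_volume` whose lattice to sample on.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @param fill Out-of-field intensity for `boundary = "constant"`.
#' @param boundary `"constant"` (default) or `"nearest"` (edge clamp).
#' @return The resampled `mri_volume`.
#' @export
reslice <- function(vol, spacing = NULL, grid = NULL,
                    interpolation = c("linear", "nearest"), fill = 0,
                    boundary = c("constant", "nearest")) {
  stopifnot_volume(vol)
  interpolation <- match.arg(interpolation)
  boundary <- match.arg(boundary)
  if (is.null(spacing) == is.null(grid))
    abort("supply exactly one of `spacing` or `grid`", "orthosr_type_error")
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) == 1L) spacing <- rep(spacing, 3)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      abort("target spacing must be positive", "orthosr_bad_geometry_error")
    d <- dim(vol$data)
    extent <- d * vol$spacing
    nd <- pmax(1L, as.integer(round(extent / spacing)))
    # keep the world center fixed
    center <- vol$origin + vol$orientation %*% (vol$spacing * (d - 1) / 2)
    origin <- as.vector(center - vol$orientation %*% (spacing * (nd - 1) / 2))
    g <- list(dims = nd, spacing = spacing, origin = origin,
              orientation = vol$orientation)
  } else {
    g <- vol_geometry(grid)
  }
  out <- cpp_resample(as.vector(vol$data), dim(vol$data), vol$spacing,
                      vol$origin, vol$orientation,
                      as.integer(g$dims), g$spacing, g$origin, g$orientation,
                      diag(4), if (interpolation == "linear") 1L else 0L,
                      fill, if (boundary == "constant") 0L else 1L, FALSE)
  mri_volume(array(out$data, dim = g$dims), spacing = g$spacing,
             origin = g$origin, orientation = g$orientation)
}
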