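#' Digital phantom specification
#'
#' Defines the high-resolution isotropic ground-truth volume from which the
#' degraded orthogonal stacks are synthesized. The default is a 128^3 lattice
#' at 0.5 mm isotropic spacing carrying a schematic knee: nested ellipsoids
#' for soft tissue, bone, cartilage and joint fluid plus a tube-like vessel,
#' modulated by a smooth within-tissue texture field. Anatomical realism is
#' not required — the reconstruction pipeline is purely intensity-geometric —
#' but the phantom provides both the sharp tissue boundaries at which
#' partial-volume mixing and block artefacts arise and the continuous
#' within-tissue signal variation that thick slices destroy.
#'
#' @param dims Integer triple of voxel counts.
#' @param spacing Isotropic voxel size in mm.
#' @param structures List of structures, each a list with `shape`
#'   (`"ellipsoid"`, `"slab"` or `"tube"`), `center` (world mm), `radii`
#'   (mm; for a slab the half-thickness per axis, for a tube the two
#'   cross-sectional radii with `axis` giving the tube axis), `intensity` in
#'   \[0, 1\], and optionally `axis` (1-3). Later structures overwrite earlier
#'   ones where they overlap.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units); 0 disables noise. The synthesis of degraded stacks models
#'   resolution loss, not receiver noise, so the default is 0.
#' @param texture_amp Amplitude of the smooth multiplicative intensity
#'   modulation applied inside the structures (a tissue-texture and
#'   coil-shading surrogate). Real MR intensities vary continuously within
#'   tissues; without this frequency content a slab average would be lossless
#'   inside flat regions and the phantom could not measure through-plane
#'   resolution recovery. 0 disables the modulation.
#' @param texture_wavelength Wavelength of the modulation in mm; `NULL` uses
#'   1/8 of the smallest volume extent.
#' @param seed Integer seed making the phantom deterministic.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(128, 128, 128), spacing = 0.5,
                         structures = NULL, noise_sd = 0,
                         texture_amp = 0.25, texture_wavelength = NULL,
                         seed = 42L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1))
    abort("dims must be three positive integers", "orthosr_type_error")
  if (spacing <= 0) abort("spacing must be positive",
                          "orthosr_bad_geometry_error")
  if (is.null(structures)) structures <- knee_structures(dims * spacing)
  for (s in structures) {
    if (!s$shape %in% c("ellipsoid", "slab", "tube"))
      abort("unknown structure shape", "orthosr_type_error")
    if (any(s$radii <= 0)) abort("structure radii must be positive",
                                 "orthosr_type_error")
    if (s$intensity < 0 || s$intensity > 1)
      abort("structure intensity must lie in [0, 1]", "orthosr_type_error")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0", "orthosr_type_error")
  if (texture_amp < 0 || texture_amp >= 1)
    abort("texture_amp must lie in [0, 1)", "orthosr_type_error")
  if (is.null(texture_wavelength))
    texture_wavelength <- min(dims * spacing) / 8
  structure(list(dims = dims, spacing = spacing, structures = structures,
                 noise_sd = noise_sd, texture_amp = texture_amp,
                 texture_wavelength = texture_wavelength,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Schematic knee for a given world extent (mm): soft-tissue bulk, two bones,
# a cartilage layer, joint fluid and a vessel-like tube, with distinct
# intensities. Curved (ellipsoidal) boundaries keep the boundary-orientation
# mix roughly isotropic, as in real anatomy, so no single stack's coarse
# direction is favoured or penalised by the geometry.
knee_structures <- function(extent) {
  c0 <- extent / 2
  r <- min(extent) / 2
  list(
    list(shape = "ellipsoid", center = c0 + c(0, 0.05, 0) * extent,
         radii = r * c(0.85, 0.80, 0.85), intensity = 0.35),
    list(shape = "ellipsoid", center = c0 + c(0, -0.12, 0.20) * extent,
         radii = r * c(0.40, 0.34, 0.32), intensity = 0.55),
    list(shape = "ellipsoid", center = c0 + c(0, -0.10, -0.24) * extent,
         radii = r * c(0.38, 0.28, 0.26), intensity = 0.50),
    list(shape = "ellipsoid", center = c0 + c(0, -0.12, -0.02) * extent,
         radii = r * c(0.32, 0.22, 0.12), intensity = 0.85),
    list(shape = "ellipsoid", center = c0 + c(0.12, -0.05, 0.0) * extent,
         radii = r * c(0.10, 0.16, 0.08), intensity = 0.95),
    list(shape = "tube", center = c0 + c(-0.28, 0.18, 0) * extent,
         radii = r * c(0.07, 0.07), intensity = 0.70, axis = 3)
  )
}

#' Generate the high-resolution ground-truth phantom volume
#'
#' Rasterizes the structures onto the isotropic lattice (last listed structure
#' wins at overlaps), optionally adds Gaussian noise, and clips to \[0, 1\].
#' Deterministic under the specification's `seed`. Structures extending outside the
#' volume are clipped with a warning.
#'
#' @param spec A [phantom_spec()].
#' @return An `mri_volume` with identity orientation and origin at 0.
#' @export
generate_hr <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    abort("expected a phantom_spec", "orthosr_type_error")
  d <- spec$dims
  sp <- spec$spacing
  x <- (seq_len(d[1]) - 1) * sp
  y <- (seq_len(d[2]) - 1) * sp
  z <- (seq_len(d[3]) - 1) * sp
  vol <- array(0, d)
  # physical volume edges (half a voxel beyond the outermost centroids)
  extent_lo <- -sp / 2
  extent_hi <- (d - 0.5) * sp
  for (s in spec$structures) {
    ax <- if (!is.null(s$axis)) s$axis else 3L
    rr <- if (s$shape == "tube") {
      r3 <- rep(Inf, 3); r3[setdiff(1:3, ax)] <- s$radii; r3
    } else s$radii
    bounded <- is.finite(rr)
    if (any((s$center - rr)[bounded] < extent_lo) ||
        any((s$center + rr)[bounded] > extent_hi[bounded]))
      warning("structure extends outside the volume; clipping")
    if (s$shape == "ellipsoid") {
      u2 <- ((x - s$center[1]) / s$radii[1])^2
      v2 <- ((y - s$center[2]) / s$radii[2])^2
      w2 <- ((z - s$center[3]) / s$radii[3])^2
      inside <- outer(outer(u2, v2, "+"), w2, "+") <= 1
    } else if (s$shape == "slab") {
      inside <- outer(outer(abs(x - s$center[1]) <= s$radii[1],
                            abs(y - s$center[2]) <= s$radii[2], "&"),
                      abs(z - s$center[3]) <= s$radii[3], "&")
    } else { # tube along `axis`
      cross <- setdiff(1:3, ax)
      coords <- list(x, y, z)
      u2 <- ((coords[[cross[1]]] - s$center[cross[1]]) / s$radii[1])^2
      v2 <- ((coords[[cross[2]]] - s$center[cross[2]]) / s$radii[2])^2
      disc <- outer(u2, v2, "+") <= 1
      inside <- array(FALSE, d)
      perm <- order(c(cross, ax))
      inside <- aperm(array(rep(disc, d[ax]), c(d[cross], d[ax])), perm)
    }
    vol[inside] <- s$intensity
  }
  set.seed(spec$seed)
  if (spec$texture_amp > 0) {
    # smooth multiplicative modulation: an aperiodic Gaussian random field
    # (white noise smoothed to the requested correlation scale), emulating
    # within-tissue texture and coil shading; background (0) is unaffected
    sigma_vox <- spec$texture_wavelength / 4 / sp
    f <- cpp_gauss_smooth(stats::rnorm(prod(d)), d, rep(sigma_vox, 3))
    f <- f / stats::sd(f)
    f[f > 2.5] <- 2.5
    f[f < -2.5] <- -2.5
    vol <- vol * (1 + (0.4 * spec$texture_amp) * array(f, d))
  }
  if (spec$noise_sd > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sd), d)
  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  mri_volume(vol, spacing = rep(sp, 3))
}

# Orientation matrices mapping stack index axes (in-plane i, in-plane j,
# slice k) to world axes; all proper rotations. Slice normals: sagittal = x,
# coronal = y, axial = z.
plane_orientation <- function(plane) {
  switch(plane,
         axial = diag(3),
         sagittal = matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3),
         coronal = matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3),
         abort("plane must be sagittal, axial or coronal",
               "orthosr_type_error"))
}

#' Degradation recipe for one synthesized stack
#'
#' Describes how a clinical acquisition is emulated from the high-resolution
#' phantom: slices are slab averages of the stated thickness along the plane
#' normal (boxcar profile by default, modelling partial-volume mixing), the
#' in-plane lattice is resampled to the stated spacing, a per-stack linear
#' intensity change (`gain`, `offset`) emulates inter-acquisition scaling, and
#' a small rigid perturbation emulates patient motion between acquisitions.
#'
#' @param in_plane In-plane spacing (mm pair); `NULL` keeps the phantom's
#'   spacing.
#' @param slice Slice thickness/spacing along the stack normal (mm); must
#'   exceed the in-plane spacing for a realistically anisotropic stack.
#' @param gain,offset Linear intensity change applied to the stack.
#' @param rotation_deg,translation_mm Rigid perturbation of the stack in world
#'   space (Euler XYZ degrees; mm).
#' @param slab_profile `"boxcar_mean"` (default) or `"gaussian"` slice
#'   profile.
#' @return A list of class `stack_degradation`.
#' @export
stack_degradation <- function(in_plane = NULL, slice = 4, gain = 1,
                              offset = 0, rotation_deg = c(0, 0, 0),
                              translation_mm = c(0, 0, 0),
                              slab_profile = c("boxcar_mean", "gaussian")) {
  slab_profile <- match.arg(slab_profile)
  structure(list(in_plane = in_plane, slice = slice, gain = gain,
                 offset = offset, rotation_deg = rotation_deg,
                 translation_mm = translation_mm,
                 slab_profile = slab_profile),
            class = "stack_degradation")
}

#' Default degradation recipes for the three stacks
#'
#' Mirrors the synthesis used to turn high-resolution acquisitions into
#' clinical-like stacks: the sagittal stack (the reconstruction target) keeps
#' the high-resolution in-plane spacing and gets 4 mm slices; the axial and
#' coronal stacks get 5 mm slices and a 1.6x coarser second in-plane axis
#' (the 0.31 x 0.5 mm / 0.31 x 0.31 mm in-plane ratio of the clinical
#' protocol). The sagittal stack is left unperturbed — it defines the study's
#' reference frame — while axial and coronal get distinct intensity
#' gain/offset (motivating histogram matching) and small rigid misalignments
#' within 2 mm / 2 degrees (motivating registration).
#'
#' @param spacing_hr The phantom's isotropic spacing in mm.
#' @return Named list of three [stack_degradation()] recipes.
#' @export
degradation_spec <- function(spacing_hr = 0.5) {
  list(
    sagittal = stack_degradation(slice = 4),
    axial = stack_degradation(in_plane = c(spacing_hr, 1.6 * spacing_hr),
                              slice = 5, gain = 1.15, offset = 0.02,
                              rotation_deg = c(0, 0, 2),
                              translation_mm = c(1.5, -1.0, 0.5)),
    coronal = stack_degradation(in_plane = c(spacing_hr, 1.6 * spacing_hr),
                                slice = 5, gain = 0.9, offset = -0.01,
                                rotation_deg = c(-1.5, 0, 0),
                                translation_mm = c(-1.0, 0.5, 1.5))
  )
}

# Rigid perturbation as a transform about the HR volume's world center.
perturbation_transform <- function(deg, hr) {
  d <- dim(hr$data)
  center <- as.vector(hr$origin +
                        hr$orientation %*% (hr$spacing * (d - 1) / 2))
  ang <- deg$rotation_deg * pi / 180
  rigid_affine_transform(euler_matrix(ang[1], ang[2], ang[3]),
                         deg$translation_mm, center = center,
                         phase = "rigid")
}

#' Degrade the phantom into one anisotropic orthogonal stack
#'
#' Each output slice is the average of the high-resolution volume over a slab
#' of the requested thickness along the plane normal (partial-volume model);
#' in-plane the volume is resampled linearly to the requested spacing. The
#' intensity gain/offset is then applied, and finally the stack's geometry is
#' moved by the rigid perturbation (the data are untouched, so applying the
#' inverse transform restores alignment exactly).
#'
#' @param hr Isotropic ground-truth `mri_volume`.
#' @param plane `"sagittal"`, `"axial"` or `"coronal"`.
#' @param deg A [stack_degradation()].
#' @return An `mri_volume` with slices along its third index axis.
#' @export
degrade_to_stack <- function(hr, plane = c("sagittal", "axial", "coronal"),
                             deg = stack_degradation()) {
  plane <- match.arg(plane)
  stopifnot_volume(hr)
  if (!is_isotropic(hr))
    abort("phantom degradation requires an isotropic HR volume",
          "orthosr_anisotropic_error")
  hr_sp <- hr$spacing[1]
  if (deg$slice < hr_sp)
    abort("slab thickness must be at least the HR spacing",
          "orthosr_bad_geometry_error")
  in_plane <- if (is.null(deg$in_plane)) c(hr_sp, hr_sp) else deg$in_plane
  R <- plane_orientation(plane)
  # world extent of the HR volume along the stack's axes
  d_hr <- dim(hr$data)
  extent <- abs(as.vector(t(R) %*% (d_hr * hr$spacing)))
  n1 <- max(1L, as.integer(round(extent[1] / in_plane[1])))
  n2 <- max(1L, as.integer(round(extent[2] / in_plane[2])))
  ns <- max(1L, as.integer(floor(extent[3] / deg$slice)))
  m <- max(1L, as.integer(round(deg$slice / hr_sp)))   # samples per slab
  # fine sampling grid: in-plane target spacing, slab sampled at m positions
  fine_sp <- c(in_plane, deg$slice / m)
  fine_dims <- c(n1, n2, ns * m)
  # center the stack on the HR volume's world center
  hr_center <- as.vector(hr$origin +
                           hr$orientation %*% (hr$spacing * (d_hr - 1) / 2))
  fine_origin <- as.vector(hr_center - R %*% (fine_sp * (fine_dims - 1) / 2))
  fine <- cpp_resample(as.vector(hr$data), d_hr, hr$spacing, hr$origin,
                       hr$orientation, as.integer(fine_dims), fine_sp,
                       fine_origin, R, diag(4), 1L, 0, 0L, FALSE)
  fine <- array(fine$data, fine_dims)
  if (deg$slab_profile == "boxcar_mean") {
    w <- rep(1 / m, m)
  } else {
    u <- seq_len(m) - (m + 1) / 2
    w <- exp(-0.5 * (u / (m / 4))^2)
    w <- w / sum(w)
  }
  slab <- array(0, c(n1, n2, ns))
  for (t in seq_len(m))
    slab <- slab + w[t] * fine[, , seq(t, by = m, length.out = ns),
                               drop = FALSE]
  # slice centroids sit at the slab centers
  origin <- as.vector(fine_origin +
                        R %*% c(0, 0, (m - 1) / 2 * fine_sp[3]))
  out <- mri_volume(slab * deg$gain + deg$offset,
                    spacing = c(in_plane, deg$slice), origin = origin,
                    orientation = R)
  tf <- perturbation_transform(deg, hr)
  if (any(deg$rotation_deg != 0) || any(deg$translation_mm != 0)) {
    out$origin <- apply_transform(tf, out$origin)
    out$orientation <- tf$matrix %*% out$orientation
  }
  out
}

#' Synthesize a complete orthogonal study from the phantom
#'
#' Produces everything an end-to-end validation needs in one call: the three
#' degraded stacks bundled as an [orthogonal_study()], the ground-truth
#' high-resolution volume, and the rigid perturbations that were injected
#' (ground truth for registration tests).
#'
#' @param spec A [phantom_spec()].
#' @param deg Named list of per-plane [stack_degradation()] recipes, as
#'   produced by [degradation_spec()].
#' @return A list with `study`, `ground_truth` and `true_transforms` (named
#'   list of [rigid_affine_transform()]s mapping aligned positions to the
#'   perturbed stack's frame).
#' @export
make_study <- function(spec = phantom_spec(),
                       deg = degradation_spec(spec$spacing)) {
  hr <- generate_hr(spec)
  stacks <- list()
  transforms <- list()
  for (plane in c("sagittal", "axial", "coronal")) {
    stacks[[plane]] <- degrade_to_stack(hr, plane, deg[[plane]])
    transforms[[plane]] <- perturbation_transform(deg[[plane]], hr)
  }
  study <- orthogonal_study(stacks$sagittal, stacks$axial, stacks$coronal)
  list(study = study, ground_truth = hr, true_transforms = transforms)
}

#' Write a study to disk as NIfTI files plus a JSON manifest
#'
#' @param study_bundle Output of [make_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study_bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (plane in c("sagittal", "axial", "coronal"))
    write_volume(study_bundle$study[[plane]],
                 file.path(dir, paste0(plane, ".nii.gz")))
  write_volume(study_bundle$ground_truth,
               file.path(dir, "ground_truth.nii.gz"))
  manifest <- list(
    target_plane = study_bundle$study$target_plane,
    true_transforms = lapply(study_bundle$true_transforms, transform_matrix))
  jsonlite::write_json(manifest, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
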