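test_that("the generator is deterministic and bounded", {
  spec <- small_phantom(c(24, 24, 24), seed = 5)
  a <- generate_hr(spec)
  b <- generate_hr(spec)
  expect_identical(a$data, b$data)
  expect_gte(min(a$data), 0)
  expect_lte(max(a$data), 1)
  c2 <- generate_hr(small_phantom(c(24, 24, 24), seed = 6))
  expect_false(identical(a$data, c2$data))
})

test_that("structures rasterize by definition, last structure winning", {
  # empty structure list: all background
  spec0 <- phantom_spec(dims = c(16, 16, 16), spacing = 1,
                        structures = list(), texture_amp = 0, noise_sd = 0)
  expect_true(all(generate_hr(spec0)$data == 0))
  # one centered ellipsoid: interior at its intensity, exterior 0
  ell <- list(list(shape = "ellipsoid", center = c(8, 8, 8),
                   radii = c(5, 4, 3), intensity = 0.8))
  spec1 <- phantom_spec(dims = c(16, 16, 16), spacing = 1, structures = ell,
                        texture_amp = 0)
  v <- generate_hr(spec1)
  expect_setequal(unique(as.vector(v$data)), c(0, 0.8))
  expect_equal(v$data[9, 9, 9], 0.8)   # center voxel (0-based index 8)
  expect_equal(v$data[1, 1, 1], 0)
  # overlap: later structure overwrites
  two <- c(ell, list(list(shape = "ellipsoid", center = c(8, 8, 8),
                          radii = c(2, 2, 2), intensity = 0.3)))
  v2 <- generate_hr(phantom_spec(dims = c(16, 16, 16), spacing = 1,
                                 structures = two, texture_amp = 0))
  expect_equal(v2$data[9, 9, 9], 0.3)
  # out-of-volume structure warns
  far <- list(list(shape = "ellipsoid", center = c(20, 8, 8),
                   radii = c(5, 5, 5), intensity = 0.5))
  expect_warning(generate_hr(phantom_spec(dims = c(16, 16, 16), spacing = 1,
                                          structures = far,
                                          texture_amp = 0)),
                 "outside")
})

test_that("rasterized ellipsoid volume approaches the analytic volume", {
  r <- c(40, 30, 25)
  spec <- phantom_spec(dims = c(128, 128, 128), spacing = 1,
                       structures = list(list(shape = "ellipsoid",
                                              center = c(63.5, 63.5, 63.5),
                                              radii = r, intensity = 1)),
                       texture_amp = 0)
  v <- generate_hr(spec)
  analytic <- 4 / 3 * pi * prod(r)
  expect_lt(abs(sum(v$data) - analytic) / analytic, 0.02)
})

test_that("slab averaging models partial volume and conserves mean intensity", {
  spec <- small_phantom(c(32, 32, 32), spacing = 1)
  hr <- generate_hr(spec)
  # no-op slab (thickness = spacing, no gain/offset/perturbation) equals an
  # in-plane resample of the HR volume
  noop <- degrade_to_stack(hr, "sagittal", stack_degradation(slice = 1))
  hr_on <- reslice(hr, grid = noop)
  expect_lt(max(abs(noop$data - hr_on$data)), 1e-12)
  # boxcar over a binary edge: the intermediate value equals the sub-slab
  # volume fraction. Step at world x = 18 splits the slab covering x in
  # 16..19 into two zero and two unit samples -> exactly 0.5.
  arr <- array(0, c(32, 32, 32))
  arr[19:32, , ] <- 1   # 0-based x index >= 18
  edge <- mri_volume(arr)
  st <- degrade_to_stack(edge, "sagittal", stack_degradation(slice = 4))
  vals <- sort(unique(round(as.vector(st$data), 12)))
  expect_equal(vals, c(0, 0.5, 1))
  # boxcar averaging conserves mean intensity over the covered extent
  deg <- degrade_to_stack(hr, "axial", stack_degradation(slice = 4))
  expect_lt(abs(mean(deg$data) - mean(hr$data)) / mean(hr$data), 0.01)
  # slab thinner than HR spacing is rejected
  expect_error(degrade_to_stack(hr, "axial", stack_degradation(slice = 0.5)),
               class = "orthosr_bad_geometry_error")
  # gaussian slice profile: still a weighted average, values stay in range
  dg <- degrade_to_stack(hr, "axial",
                         stack_degradation(slice = 4,
                                           slab_profile = "gaussian"))
  expect_gte(min(dg$data), 0)
  expect_lte(max(dg$data), 1)
  expect_false(identical(dg$data, deg$data))
})

test_that("stack geometry is anisotropic with the slice axis third", {
  spec <- small_phantom(c(32, 32, 32), spacing = 1)
  hr <- generate_hr(spec)
  st <- degrade_to_stack(hr, "coronal",
                         stack_degradation(in_plane = c(1, 1.6), slice = 5))
  expect_equal(st$spacing, c(1, 1.6, 5))
  expect_equal(dim(st$data)[3], floor(32 / 5))
  # coronal slice normal is world y
  expect_equal(abs(st$orientation[, 3]), c(0, 1, 0))
})

test_that("injected perturbations are stored and exactly invertible", {
  spec <- small_phantom(c(24, 24, 24), spacing = 1)
  b <- make_study(spec)
  tfa <- b$true_transforms$axial
  expect_s3_class(tfa, "rigid_affine_transform")
  # the sagittal stack defines the frame: identity transform
  expect_equal(b$true_transforms$sagittal$matrix, diag(3))
  expect_equal(b$true_transforms$sagittal$translation, c(0, 0, 0))
  # geometry round-trip: inverse restores the unperturbed lattice
  aligned <- align_volume(b$study$axial, tfa)
  unpert <- degrade_to_stack(b$ground_truth, "axial",
                             stack_degradation(
                               in_plane = c(1, 1.6), slice = 5,
                               gain = 1.15, offset = 0.02))
  expect_lt(max(abs(aligned$origin - unpert$origin)), 1e-9)
  expect_identical(aligned$data, unpert$data)
})

test_that("a full study is deterministic and carries expected slice counts", {
  spec <- phantom_spec(dims = c(64, 64, 64))
  b1 <- make_study(spec)
  b2 <- make_study(spec)
  expect_identical(b1$study$sagittal$data, b2$study$sagittal$data)
  expect_identical(b1$study$coronal$data, b2$study$coronal$data)
  # extent 32 mm: sagittal ~ extent/4, axial/coronal ~ extent/5 slices
  expect_equal(dim(b1$study$sagittal$data)[3], 32 %/% 4)
  expect_equal(dim(b1$study$axial$data)[3], floor(32 / 5))
  expect_equal(dim(b1$study$coronal$data)[3], floor(32 / 5))
  expect_s3_class(b1$study, "orthogonal_study")
})

test_that("a study can be written out with its manifest", {
  tmp <- withr::local_tempdir()
  b <- make_study(phantom_spec(dims = c(24, 24, 24)))
  d <- write_study(b, file.path(tmp, "study"))
  expect_true(file.exists(file.path(d, "sagittal.nii.gz")))
  expect_true(file.exists(file.path(d, "ground_truth.nii.gz")))
  man <- jsonlite::read_json(file.path(d, "study.json"),
                             simplifyVector = TRUE)
  expect_equal(man$target_plane, "sagittal")
  back <- read_volume(file.path(d, "axial.nii.gz"))
  expect_equal(back$data, b$study$axial$data, tolerance = 1e-12)
})
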