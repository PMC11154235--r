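test_that("NIfTI round-trip preserves data bit-exactly and geometry", {
  tmp <- withr::local_tempdir()
  cases <- list(
    list(v = rand_volume(c(4, 4, 4), seed = 1, spacing = c(0.5, 0.5, 4)),
         file = "a.nii.gz"),
    list(v = rand_volume(c(8, 8, 8), seed = 2,
                         spacing = c(0.31, 0.31, 4), origin = c(1, -2, 3),
                         orientation = matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0),
                                              3, 3)),
         file = "b.nii.gz"),
    list(v = rand_volume(c(5, 6, 7), seed = 3, spacing = c(1, 1, 1)),
         file = "c.nii")
  )
  for (cs in cases) {
    path <- file.path(tmp, cs$file)
    write_volume(cs$v, path)
    v2 <- read_volume(path)
    expect_identical(v2$data, cs$v$data)
    expect_lt(max(abs(v2$spacing - cs$v$spacing)), 1e-6)
    expect_lt(max(abs(v2$origin - cs$v$origin)), 1e-6)
    expect_lt(max(abs(v2$orientation - cs$v$orientation)), 1e-6)
  }
})

test_that("identity-affine NIfTI decodes to origin 0 and identity orientation", {
  tmp <- withr::local_tempdir()
  v <- rand_volume(c(4, 4, 4))
  path <- file.path(tmp, "id.nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_equal(v2$origin, c(0, 0, 0))
  expect_equal(v2$orientation, diag(3))
})

test_that("loading decodes a rotated affine to the stored rotation", {
  # fixed 90-degree rotation about z, decomposed by hand:
  # columns (0,1,0), (-1,0,0), (0,0,1); spacings (2, 3, 4)
  tmp <- withr::local_tempdir()
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  v <- rand_volume(c(4, 5, 6), seed = 9, spacing = c(2, 3, 4),
                   origin = c(5, 6, 7), orientation = R)
  path <- file.path(tmp, "rot.nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_lt(max(abs(v2$orientation - R)), 1e-6)
  expect_lt(max(abs(v2$spacing - c(2, 3, 4))), 1e-6)
})

test_that("load errors are distinct and named", {
  tmp <- withr::local_tempdir()
  expect_error(read_volume(file.path(tmp, "nope.nii")),
               class = "orthosr_missing_file_error")
  # 4D image
  img <- RNifti::asNifti(array(0, c(3, 3, 3, 2)))
  p4 <- file.path(tmp, "4d.nii.gz")
  RNifti::writeNifti(img, p4)
  expect_error(read_volume(p4), class = "orthosr_not_3d_error")
  # unwritable path
  expect_error(write_volume(rand_volume(), file.path(tmp, "no/dir/x.nii")),
               class = "orthosr_unwritable_error")
  # NaN data rejected at construction
  bad <- array(1, c(2, 2, 2)); bad[1] <- NaN
  expect_error(mri_volume(bad), class = "orthosr_nan_error")
})

test_that("minmax_normalize maps the range onto [0, 1] and is idempotent", {
  v <- rand_volume(c(6, 6, 6), seed = 4)
  v$data <- v$data * 7 + 3
  n1 <- minmax_normalize(v)
  expect_equal(min(n1$data), 0)
  expect_equal(max(n1$data), 1)
  expect_equal(n1$spacing, v$spacing)
  # forced linear map
  v2 <- mri_volume(array(c(2, 4, 6, 2, 4, 6, 2, 4), c(2, 2, 2)))
  expect_equal(sort(unique(as.vector(minmax_normalize(v2)$data))),
               c(0, 0.5, 1))
  # idempotent
  expect_equal(minmax_normalize(n1)$data, n1$data)
  # constant image errors
  expect_error(minmax_normalize(mri_volume(array(1, c(2, 2, 2)))),
               class = "orthosr_constant_image_error")
})

test_that("histogram matching equates intensity distributions", {
  v <- rand_volume(c(8, 8, 8), seed = 5)
  # self-match is the identity (within matching quantization)
  self <- match_histogram(v, v)
  expect_lt(max(abs(self$data - v$data)), 1e-12)
  # a monotone shift is exactly inverted
  shifted <- v
  shifted$data <- v$data + 10
  m <- match_histogram(shifted, v)
  expect_lt(max(abs(sort(as.vector(m$data)) - sort(as.vector(v$data)))), 1e-9)
  expect_lt(max(abs(m$data - v$data)), 1e-9)
  # quantile-function comparison oracle on unrelated volumes
  a <- rand_volume(c(8, 8, 8), seed = 6)
  b <- rand_volume(c(8, 8, 8), seed = 7)
  m2 <- match_histogram(a, b)
  expect_lt(max(abs(sort(as.vector(m2$data)) - sort(as.vector(b$data)))),
            1e-6)
  # rank order preserved
  expect_true(all(diff(as.vector(m2$data)[order(a$data)]) >= 0))
  # idempotent
  m3 <- match_histogram(m2, b)
  expect_lt(max(abs(m3$data - m2$data)), 1e-9)
  expect_error(match_histogram(mri_volume(array(1, c(2, 2, 2))), v),
               class = "orthosr_constant_image_error")
})

test_that("reslice is exact where exactness is forced", {
  v <- rand_volume(c(6, 7, 8), seed = 8, spacing = c(1, 1.5, 2))
  # identity resample
  expect_equal(reslice(v, grid = v)$data, v$data, tolerance = 1e-12)
  # linear interpolation reproduces a linear field exactly (strictly inside
  # the source centroid hull; outside it the background fill applies)
  r <- ramp_volume(c(8, 8, 8), spacing = c(1, 1, 2))
  up <- reslice(r, spacing = c(0.5, 0.5, 1))
  idx <- voxel_centroids(up)
  expected <- 0.1 + idx %*% c(0.01, 0.02, 0.03)
  inside <- idx[, 1] >= 0 & idx[, 1] <= 7 &
    idx[, 2] >= 0 & idx[, 2] <= 7 &
    idx[, 3] >= 0 & idx[, 3] <= 14
  expect_lt(max(abs(as.vector(up$data)[inside] - expected[inside])), 1e-6)
})

test_that("reslicing an anisotropic stack to isotropic multiplies slice count", {
  v <- rand_volume(c(16, 16, 8), seed = 10, spacing = c(0.31, 0.31, 4))
  iso <- reslice(v, spacing = 0.31)
  expect_equal(dim(iso$data)[3], round(8 * 4 / 0.31))
  expect_true(is_isotropic(iso))
  expect_error(reslice(v, spacing = -1), class = "orthosr_bad_geometry_error")
})

test_that("out-of-field voxels fill with background or clamp on request", {
  v <- rand_volume(c(4, 4, 4), seed = 11)
  big <- mri_volume(array(0, c(8, 8, 8)), origin = c(-2, -2, -2))
  filled <- reslice(v, grid = big)
  expect_equal(filled$data[1, 1, 1], 0)
  clamped <- reslice(v, grid = big, boundary = "nearest")
  expect_equal(clamped$data[1, 1, 1], v$data[1, 1, 1])
})
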