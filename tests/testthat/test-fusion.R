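test_that("template grids copy the target geometry and demand isotropy", {
  v <- rand_volume(c(10, 10, 10), seed = 1, spacing = c(1, 1, 1),
                   origin = c(0, 0, 0))
  g <- template_grid(v)
  expect_equal(g$dims, c(10, 10, 10))
  expect_equal(g$spacing, 1)
  cents <- voxel_centroids(g)
  expect_equal(nrow(cents), 1000)
  expect_equal(range(cents[, 1]), c(0, 9))
  expect_equal(range(cents[, 3]), c(0, 9))
  aniso <- rand_volume(c(4, 4, 4), spacing = c(1, 1, 2))
  expect_error(template_grid(aniso), class = "orthosr_anisotropic_error")
})

test_that("nearest-voxel queries return exact matches and break ties low", {
  v <- rand_volume(c(3, 3, 3), seed = 2)
  # query exactly at a centroid
  nn <- nearest_voxels(v, c(1, 2, 0))
  expect_equal(nn$distance, 0)
  expect_equal(nn$source_index[1, ], c(2, 3, 1))
  expect_equal(nn$intensity, v$data[2, 3, 1])
  # midpoint between x = 0 and x = 1: tie broken to the lower flattened index
  nn2 <- nearest_voxels(v, c(0.5, 0, 0))
  expect_equal(nn2$distance, 0.5)
  expect_equal(nn2$index, 1L)
})

test_that("the spatial index agrees with exhaustive search on random queries", {
  v <- rand_volume(c(15, 15, 15), seed = 3, spacing = c(0.7, 1.1, 2.3),
                   origin = c(-3, 1, 2),
                   orientation = matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3))
  set.seed(99)
  q <- cbind(runif(1000, -5, 20), runif(1000, -5, 20), runif(1000, -5, 35))
  nn <- nearest_voxels(v, q)
  cents <- voxel_centroids(v)
  for (i in seq_len(nrow(q))) {
    orc <- oracle_nearest(cents, q[i, ])
    expect_identical(nn$index[i], as.integer(orc$index))
    expect_identical(nn$distance[i], orc$distance)
  }
})

test_that("fusion weights follow the inverse-distance formula", {
  expect_equal(fusion_weights(c(1, 1, 1)), rep(1 / 3, 3))
  # a coincident plane gets weight 1/2, not 1
  expect_equal(fusion_weights(c(0, 1, 1)), c(1 / 2, 1 / 4, 1 / 4))
  # hand-worked: d_total = 6 -> (5, 4, 3)/12, checked independently:
  # w_p = (6 - d_p) / (2 * 6)
  expect_equal(fusion_weights(c(1, 2, 3)), c(5, 4, 3) / 12)
  expect_equal(fusion_weights(c(1, 2, 3)), (6 - c(1, 2, 3)) / (2 * 6))
  # all-zero distances: symmetric limit
  expect_equal(fusion_weights(c(0, 0, 0)), rep(1 / 3, 3))
  # two-plane generalization
  expect_equal(fusion_weights(c(1, 3)), c(3 / 4, 1 / 4))
  expect_error(fusion_weights(c(-1, 1, 1)),
               class = "orthosr_negative_distance_error")
  expect_error(fusion_weights(5), class = "orthosr_too_few_planes_error")
})

test_that("fusion weights are a partition of unity over random distances", {
  set.seed(7)
  for (P in 2:4) {
    D <- matrix(runif(5000 * P, 0, 10), ncol = P)
    W <- fusion_weights(D)
    expect_lt(max(abs(rowSums(W) - 1)), 1e-9)
    expect_gte(min(W), 0)
    expect_lte(max(W), 1)
  }
})

test_that("identical stacks on the template grid are a fixed point", {
  v <- rand_volume(c(9, 9, 9), seed = 4)
  g <- template_grid(v)
  fr <- sr_reconstruct(list(a = v, b = v, c = v), g)
  expect_identical(max(abs(fr$volume$data - v$data)), 0)
})

test_that("constant stacks reconstruct to the constant regardless of geometry", {
  mk <- function(dims, sp, or) mri_volume(array(0.4, dims), spacing = sp,
                                          origin = or)
  g <- template_grid(mri_volume(array(0, c(6, 6, 6))))
  fr <- sr_reconstruct(list(mk(c(4, 7, 3), c(2, 1, 3), c(0, -1, 0)),
                            mk(c(9, 3, 4), c(1, 2, 2), c(1, 0, 1)),
                            mk(c(5, 5, 5), c(1.5, 1.5, 1.5), c(-2, 0, 2))),
                       g)
  expect_true(all(fr$volume$data == 0.4))
})

test_that("index-based fusion equals brute-force fusion voxel for voxel", {
  for (seed in 1:4) {
    st <- tiny_study(seed = seed, n = 9)
    iso <- mri_volume(array(0, c(7, 7, 7)), spacing = c(1.1, 1.1, 1.1),
                      origin = c(0.3, 0.2, 0.4))
    g <- template_grid(iso)
    planes <- list(s = st$sagittal, a = st$axial, c = st$coronal)
    fr <- sr_reconstruct(planes, g, audit = TRUE)
    orc <- oracle_fusion(planes, g)
    expect_identical(as.vector(fr$volume$data), orc$values)
    expect_identical(fr$audit$distance, orc$distance)
    expect_identical(fr$audit$weight, orc$weight)
    expect_identical(fr$audit$index, orc$index)
  }
})

test_that("two-plane reconstruction matches its oracle and the 3-plane path", {
  st <- tiny_study(seed = 5, n = 8)
  g <- template_grid(mri_volume(array(0, c(6, 6, 6))))
  two <- sr_reconstruct(list(st$sagittal, st$axial), g, audit = TRUE)
  orc <- oracle_fusion(list(st$sagittal, st$axial), g)
  expect_identical(as.vector(two$volume$data), orc$values)
  expect_error(sr_reconstruct(list(st$sagittal), g),
               class = "orthosr_too_few_planes_error")
})

test_that("reconstruction is convex and deterministic", {
  st <- tiny_study(seed = 6, n = 9)
  g <- template_grid(mri_volume(array(0, c(8, 8, 8))))
  planes <- list(st$sagittal, st$axial, st$coronal)
  f1 <- sr_reconstruct(planes, g, audit = TRUE)
  f2 <- sr_reconstruct(planes, g, audit = TRUE)
  expect_identical(f1$volume$data, f2$volume$data)
  expect_identical(f1$audit, f2$audit)
  # convexity: inputs in [0,1] so outputs in [0,1]; per-voxel bound
  vals <- vapply(planes, function(p) as.vector(p$data)[f1$audit$index[, 1]],
                 numeric(prod(g$dims)))
  expect_gte(min(f1$volume$data), 0)
  expect_lte(max(f1$volume$data), 1)
})

test_that("reconstruct_sr wraps the study with the target grid", {
  spec <- small_phantom(c(24, 24, 24))
  b <- make_study(spec, list(sagittal = stack_degradation(slice = 2),
                             axial = stack_degradation(slice = 2.5),
                             coronal = stack_degradation(slice = 2.5)))
  iso <- reslice(b$study$sagittal, spacing = min(b$study$sagittal$spacing))
  st <- b$study
  st$sagittal <- iso
  fr <- reconstruct_sr(st)
  expect_equal(dim(fr$volume$data), dim(iso$data))
  expect_named(fr$timings,
               c("coordinate_init", "tree_build_search", "reconstruction"))
})

test_that("audit data can be dumped to a compressed file", {
  tmp <- withr::local_tempdir()
  st <- tiny_study(seed = 7, n = 6)
  g <- template_grid(mri_volume(array(0, c(5, 5, 5))))
  fr <- sr_reconstruct(list(st$sagittal, st$axial, st$coronal), g,
                       audit = TRUE)
  p <- file.path(tmp, "audit.rds")
  write_fusion_audit(fr, p)
  back <- readRDS(p)
  expect_identical(back$weight, fr$audit$weight)
  fr0 <- sr_reconstruct(list(st$sagittal, st$axial, st$coronal), g)
  expect_error(write_fusion_audit(fr0, p), class = "orthosr_type_error")
})
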