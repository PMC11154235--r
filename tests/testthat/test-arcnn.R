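test_that("the built network matches the five-layer architecture field for field", {
  m <- arcnn_build(arcnn_config(), seed = 1)
  expect_length(m$layers, 5)
  expect_equal(vapply(m$layers, `[[`, 0L, "cout"), c(64, 32, 32, 64, 1))
  expect_equal(vapply(m$layers, `[[`, 0L, "kernel"), c(9, 1, 7, 1, 7))
  expect_equal(vapply(m$layers, `[[`, "", "type"),
               c("conv", "conv", "conv", "conv", "conv_transpose"))
  expect_equal(vapply(m$layers, `[[`, "", "activation"),
               c("relu", "relu", "relu", "relu", "none"))
  expect_equal(vapply(m$layers, `[[`, 0L, "pad"), c(4, 0, 3, 0, 3))
  expect_equal(m$cfg$stride, 1L)
  expect_equal(m$cfg$learning_rate, 5e-4)
  expect_equal(m$cfg$beta1, 0.9)
  expect_equal(m$cfg$beta2, 0.999)
  expect_equal(m$cfg$batch_size, 32L)
  expect_equal(m$cfg$epochs, 600L)
  expect_equal(m$cfg$input_size, 256L)
  # parameter count equals the closed-form sum over Table-style layer specs
  expect_equal(arcnn_param_count(m),
               (81 * 1 * 64 + 64) + (1 * 64 * 32 + 32) + (49 * 32 * 32 + 32) +
                 (1 * 32 * 64 + 64) + (49 * 64 * 1 + 1))
})

test_that("forward pass preserves spatial dimensions at any input size", {
  m <- arcnn_build(arcnn_config(), seed = 2)
  for (n in c(8, 17, 32)) {
    y <- orthosr:::arcnn_forward(m, matrix(runif(n * n), n, n))$output
    expect_equal(dim(y), c(n, n, 1))
  }
})

test_that("backpropagation matches numerical gradients", {
  set.seed(3)
  m <- arcnn_build(arcnn_config(), seed = 5)
  x <- matrix(runif(36), 6, 6)
  target <- matrix(runif(36), 6, 6)
  fw <- orthosr:::arcnn_forward(m, x, keep_cache = TRUE)
  resid <- as.vector(fw$output) - as.vector(target)
  npx <- length(resid)
  loss0 <- sum(resid^2) / npx
  grads <- orthosr:::arcnn_backward(m, fw$cache,
                                    array(2 * resid / npx, dim(fw$output)))
  eps <- 1e-6
  for (li in 1:5) {
    for (rep in 1:3) {
      idx <- sample(length(m$layers[[li]]$W), 1)
      m2 <- m
      m2$layers[[li]]$W[idx] <- m2$layers[[li]]$W[idx] + eps
      f2 <- orthosr:::arcnn_forward(m2, x)
      l2 <- sum((as.vector(f2$output) - as.vector(target))^2) / npx
      expect_equal(grads[[li]]$dW[idx], (l2 - loss0) / eps, tolerance = 1e-3)
    }
  }
})

test_that("training pairs are normalized, resized and index-aligned", {
  spec <- small_phantom(c(16, 16, 8))
  hr <- generate_hr(spec)
  noisy <- hr
  set.seed(4)
  noisy$data <- array(pmin(1, pmax(0, hr$data * 3 +
                                     0.05 * rnorm(length(hr$data)))),
                      dim(hr$data))
  pairs <- make_training_pairs(noisy, hr, size = 12)
  expect_equal(dim(pairs$inputs), c(12, 12, 8))
  expect_equal(dim(pairs$targets), c(12, 12, 8))
  expect_gte(min(pairs$inputs), 0)
  expect_lte(max(pairs$inputs), 1)
  # identical volumes give input == target
  same <- make_training_pairs(hr, hr, size = 12)
  expect_equal(same$inputs, same$targets, tolerance = 1e-12)
  # slice-count mismatch errors
  half <- hr
  half$data <- hr$data[, , 1:4, drop = FALSE]
  expect_error(make_training_pairs(half, hr), class = "orthosr_shape_error")
  # area resampling: 2x block mean is exact
  sl <- matrix(as.numeric(1:16), 4, 4)
  rs <- resize_slice(sl, 2, 2)
  expect_equal(rs[1, 1], mean(sl[1:2, 1:2]))
  expect_equal(rs[2, 2], mean(sl[3:4, 3:4]))
})

test_that("short training reduces the loss and is bit-reproducible", {
  set.seed(6)
  n <- 8
  inputs <- array(runif(12 * 12 * n), c(12, 12, n))
  targets <- array(pmin(1, inputs + 0.1), dim(inputs))
  pairs <- structure(list(inputs = inputs, targets = targets,
                          provenance = NULL), class = "slice_pair_set")
  m <- arcnn_build(arcnn_config(batch_size = 4), seed = 11)
  t1 <- arcnn_train(m, pairs, epochs = 5, seed = 21)
  expect_length(t1$history, 5)
  expect_lt(t1$history[5], t1$history[1])
  t2 <- arcnn_train(m, pairs, epochs = 5, seed = 21)
  expect_identical(t1$history, t2$history)
  expect_true(t1$model$trained)
  expect_error(arcnn_train(m, structure(list(inputs = array(0, c(4, 4, 0)),
                                             targets = array(0, c(4, 4, 0))),
                                        class = "slice_pair_set")),
               class = "orthosr_empty_error")
})

test_that("the identity mapping is learnable to small error", {
  # structured (phantom) slices; target = input. Generalization to a held-out
  # slice checks the optimization loop end to end, not just memorization.
  hr <- generate_hr(phantom_spec(dims = c(32, 32, 32), seed = 3))
  vol <- minmax_normalize(hr)
  pairs <- make_training_pairs(vol, vol, size = 16)
  train <- structure(list(inputs = pairs$inputs[, , 1:24],
                          targets = pairs$targets[, , 1:24],
                          provenance = NULL), class = "slice_pair_set")
  m <- arcnn_build(arcnn_config(), seed = 12)
  tr <- arcnn_train(m, train, epochs = 100, learning_rate = 5e-3,
                    batch_size = 8, seed = 31)
  # loss trend decreases (median of successive 10-epoch means)
  blocks <- colMeans(matrix(tr$history, nrow = 10))
  expect_true(median(diff(blocks)) < 0)
  # held-out slice reproduced within MSE 1e-3
  held <- pairs$inputs[, , 28]
  out <- orthosr:::arcnn_forward(tr$model, held)$output[, , 1]
  expect_lt(mean((out - held)^2), 1e-3)
})

test_that("denoising preserves shape, range and geometry", {
  spec <- small_phantom(c(12, 12, 12))
  vol <- minmax_normalize(generate_hr(spec))
  pairs <- make_training_pairs(vol, vol, size = 12)
  m <- arcnn_build(arcnn_config(batch_size = 4), seed = 13)
  tr <- arcnn_train(m, pairs, epochs = 3, seed = 41)
  den <- arcnn_denoise(tr$model, vol)
  expect_equal(dim(den$data), dim(vol$data))
  expect_equal(den$spacing, vol$spacing)
  expect_gte(min(den$data), 0)
  expect_lte(max(den$data), 1)
  # degenerate constant-zero input: finite output, no NaN
  zero <- mri_volume(array(0, c(12, 12, 3)))
  dz <- arcnn_denoise(tr$model, zero)
  expect_false(anyNA(dz$data))
  expect_true(all(is.finite(dz$data)))
  # untrained model rejected
  expect_error(arcnn_denoise(m, vol), class = "orthosr_untrained_error")
})

test_that("activation maps expose the 32 feature-enhancement channels", {
  m <- arcnn_build(arcnn_config(), seed = 14)
  sl <- matrix(runif(100), 10, 10)
  am <- activation_maps(m, sl)
  expect_equal(dim(am), c(10, 10, 32))
  # zero input with zero biases -> zero maps
  am0 <- activation_maps(m, matrix(0, 8, 8))
  expect_true(all(am0 == 0))
})

test_that("checkpoints round-trip the model", {
  tmp <- withr::local_tempdir()
  m <- arcnn_build(arcnn_config(), seed = 15)
  p <- file.path(tmp, "ck.rds")
  arcnn_save(m, p)
  m2 <- arcnn_load(p)
  expect_identical(m2$layers[[1]]$W, m$layers[[1]]$W)
  expect_identical(m2$cfg$epochs, m$cfg$epochs)
})

test_that("final histogram matching binds the output to the reference range", {
  a <- rand_volume(c(8, 8, 8), seed = 16)
  b <- rand_volume(c(8, 8, 8), seed = 17)
  out <- final_histogram_match(a, b)
  expect_gte(min(out$data), min(b$data))
  expect_lte(max(out$data), max(b$data))
  expect_lt(max(abs(sort(as.vector(out$data)) - sort(as.vector(b$data)))),
            1e-6)
})
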