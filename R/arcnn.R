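#' Artefact-reduction CNN configuration
#'
#' The five-layer architecture (all strides 1, "same" zero padding on kernels
#' larger than 1, ReLU on the first four layers, none on the last, which is a
#' transposed convolution):
#'
#' | layer | role | type | filters | kernel |
#' |---|---|---|---|---|
#' | i | feature extraction | conv | 64 | 9x9 |
#' | ii | shrinking | conv | 32 | 1x1 |
#' | iii | feature enhancement | conv | 32 | 7x7 |
#' | iv | mapping | conv | 64 | 1x1 |
#' | v | reconstruction | transposed conv | 1 | 7x7 |
#'
#' Training: Adam with learning rate 5e-4, betas 0.9/0.999, no weight decay,
#' batch size 32, 600 epochs over 256x256 slices normalized to \[0, 1\], MSE
#' loss. These defaults are the full-scale recipe; tests and the phantom
#' pipeline use reduced `epochs`/`input_size`.
#'
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param batch_size Training batch size.
#' @param epochs Number of passes over the pair set.
#' @param input_size Square slice size used for training pairs.
#' @return A list of class `arcnn_config` with a `layers` field describing the
#'   architecture.
#' @export
arcnn_config <- function(learning_rate = 5e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 32, epochs = 600,
                         input_size = 256) {
  layers <- list(
    list(name = "feature_extraction", type = "conv", kernel = 9L,
         filters = 64L, activation = "relu"),
    list(name = "shrinking", type = "conv", kernel = 1L, filters = 32L,
         activation = "relu"),
    list(name = "feature_enhancement", type = "conv", kernel = 7L,
         filters = 32L, activation = "relu"),
    list(name = "mapping", type = "conv", kernel = 1L, filters = 64L,
         activation = "relu"),
    list(name = "reconstruction", type = "conv_transpose", kernel = 7L,
         filters = 1L, activation = "none"))
  for (l in layers) {
    if (l$kernel > 1 && l$kernel %% 2 != 1)
      abort("kernels larger than 1 must be odd for same-size zero padding",
            "orthosr_arcnn_config_error")
  }
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 input_size = as.integer(input_size),
                 stride = 1L, layers = layers),
            class = "arcnn_config")
}

#' Build an (untrained) artefact-reduction network
#'
#' Weights use Glorot-uniform initialization, biases start at zero; `seed`
#' makes the initialization reproducible.
#'
#' @param cfg An [arcnn_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `arcnn_model`.
#' @export
arcnn_build <- function(cfg = arcnn_config(), seed = 1L) {
  if (!inherits(cfg, "arcnn_config"))
    abort("expected an arcnn_config", "orthosr_arcnn_config_error")
  set.seed(seed)
  cin <- 1L
  layers <- list()
  for (spec in cfg$layers) {
    k <- spec$kernel
    cout <- spec$filters
    limit <- sqrt(6 / (k * k * cin + k * k * cout))
    W <- array(stats::runif(k * k * cin * cout, -limit, limit),
               c(k, k, cin, cout))
    layers[[length(layers) + 1]] <- list(
      name = spec$name, type = spec$type, kernel = k, cin = cin, cout = cout,
      pad = if (k > 1) (k - 1L) %/% 2L else 0L,
      activation = spec$activation, W = W, b = numeric(cout))
    cin <- cout
  }
  structure(list(cfg = cfg, layers = layers, trained = FALSE, seed = seed),
            class = "arcnn_model")
}

#' @export
print.arcnn_model <- function(x, ...) {
  cat(sprintf("<arcnn_model> 5 layers, %d parameters, %s\n",
              arcnn_param_count(x),
              if (x$trained) "trained" else "untrained"))
  for (l in x$layers)
    cat(sprintf("  %-20s %-14s %dx%d, %d -> %d channels, %s\n", l$name,
                l$type, l$kernel, l$kernel, l$cin, l$cout, l$activation))
  invisible(x)
}

#' Total trainable parameter count
#'
#' Closed form: sum over layers of `k^2 * c_in * c_out + c_out`.
#'
#' @param model An `arcnn_model`.
#' @return Integer parameter count.
#' @export
arcnn_param_count <- function(model) {
  sum(vapply(model$layers,
             function(l) l$kernel^2 * l$cin * l$cout + l$cout, 0))
}

# Weight matrix in the (k*k*cin) x cout layout the C++ kernels expect.
# Transposed-convolution forward at stride 1 is convolution with the
# spatially flipped kernel.
layer_w2d <- function(l, flip = FALSE) {
  W <- l$W
  if (flip && l$kernel > 1)
    W <- W[l$kernel:1, l$kernel:1, , , drop = FALSE]
  matrix(W, nrow = l$kernel^2 * l$cin, ncol = l$cout)
}

# Forward pass for one slice. x: H x W matrix (or H x W x 1 array).
# Returns the output plus, when keep_cache, the input and post-activation of
# every layer for backprop.
arcnn_forward <- function(model, x, keep_cache = FALSE) {
  a <- if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
  cache <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    y <- cpp_conv2d_forward(a, layer_w2d(l, flip = l$type == "conv_transpose"),
                            l$b, l$kernel, l$pad)
    act <- if (l$activation == "relu") {
      y * (y > 0)
    } else y
    if (keep_cache) cache[[li]] <- list(input = a, out = act)
    a <- act
  }
  list(output = a, cache = cache)
}

# Backward pass; dout has the output's shape. Returns per-layer gradients.
arcnn_backward <- function(model, cache, dout) {
  n <- length(model$layers)
  grads <- vector("list", n)
  dy <- dout
  for (li in n:1) {
    l <- model$layers[[li]]
    cc <- cache[[li]]
    if (l$activation == "relu") dy <- dy * (cc$out > 0)
    flip <- l$type == "conv_transpose"
    g <- cpp_conv2d_backward(cc$input, layer_w2d(l, flip = flip), dy,
                             l$kernel, l$pad)
    dW <- array(g$dw, c(l$kernel, l$kernel, l$cin, l$cout))
    if (flip && l$kernel > 1)
      dW <- dW[l$kernel:1, l$kernel:1, , , drop = FALSE]
    grads[[li]] <- list(dW = dW, db = as.vector(g$db))
    dy <- g$dx
  }
  grads
}

# Area (local-mean) 1D resampling matrix: n_out x n_in, rows averaging the
# input cells each output cell covers. Exact for integer ratios, alias-free
# for the block artefacts the network must learn.
area_matrix <- function(n_out, n_in) {
  r <- n_in / n_out
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * r
    hi <- i * r
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) A[i, j] <- ov / r
    }
  }
  A
}

#' Area-resample a 2D slice
#'
#' Local-mean resampling to `n1 x n2`, the down-sampling used to bring slices
#' to the network's common training size.
#'
#' @param slice 2D matrix.
#' @param n1,n2 Target dimensions.
#' @return Resampled matrix.
#' @export
resize_slice <- function(slice, n1, n2) {
  A <- area_matrix(n1, nrow(slice))
  B <- area_matrix(n2, ncol(slice))
  A %*% slice %*% t(B)
}

#' Build (noisy, clean) training slice pairs
#'
#' Pairs the slices of the reconstructed (noisy) volume with the corresponding
#' slices of the clean reference: both volumes are min-max normalized, then
#' every slice along `slice_axis` is area-resampled to `size x size`. Pairs
#' are aligned by slice index.
#'
#' @param noisy,clean `mri_volume`s with equal slice counts along
#'   `slice_axis`.
#' @param size Common square slice size (default from [arcnn_config()]).
#' @param slice_axis Axis along which slices are taken (default 3).
#' @return An object of class `slice_pair_set`: arrays `inputs` and `targets`
#'   of shape `size x size x n`, plus `provenance`.
#' @export
make_training_pairs <- function(noisy, clean, size = 256, slice_axis = 3) {
  stopifnot_volume(noisy); stopifnot_volume(clean)
  if (dim(noisy$data)[slice_axis] != dim(clean$data)[slice_axis])
    abort("noisy and clean volumes must share the slice count",
          "orthosr_shape_error")
  nv <- minmax_normalize(noisy)
  cv <- minmax_normalize(clean)
  n <- dim(nv$data)[slice_axis]
  inputs <- array(0, c(size, size, n))
  targets <- array(0, c(size, size, n))
  for (k in seq_len(n)) {
    idx <- list(TRUE, TRUE, TRUE)
    idx[[slice_axis]] <- k
    sn <- as.matrix(do.call(`[`, c(list(nv$data), idx, drop = TRUE)))
    sc <- as.matrix(do.call(`[`, c(list(cv$data), idx, drop = TRUE)))
    inputs[, , k] <- resize_slice(sn, size, size)
    targets[, , k] <- resize_slice(sc, size, size)
  }
  # area means of [0,1] data stay in [0,1]; clamp floating-point overshoot
  inputs[inputs < 0] <- 0; inputs[inputs > 1] <- 1
  targets[targets < 0] <- 0; targets[targets > 1] <- 1
  structure(list(inputs = inputs, targets = targets,
                 provenance = data.frame(pair = seq_len(n),
                                         slice = seq_len(n),
                                         axis = slice_axis)),
            class = "slice_pair_set")
}

#' Train the artefact-reduction network
#'
#' Minimizes the mean squared error between network output and target slices
#' with Adam (no weight decay). The loss is reported per epoch as the mean
#' over batches of the per-element MSE. One integer seed controls both weight
#' initialization (via [arcnn_build()]) and the per-epoch batch shuffling
#' here, so a fixed seed yields a bit-identical loss history.
#'
#' @param model An `arcnn_model` from [arcnn_build()].
#' @param pairs A [make_training_pairs()] pair set (values in \[0, 1\]).
#' @param epochs,batch_size,learning_rate Optional overrides of the model
#'   config.
#' @param seed Integer seed for batch shuffling.
#' @return A list with `model` (trained) and `history` (numeric vector of
#'   length `epochs`).
#' @export
arcnn_train <- function(model, pairs, epochs = NULL, batch_size = NULL,
                        learning_rate = NULL, seed = 1L) {
  if (!inherits(model, "arcnn_model"))
    abort("expected an arcnn_model", "orthosr_type_error")
  if (!inherits(pairs, "slice_pair_set") || dim(pairs$inputs)[3] < 1)
    abort("training requires a non-empty slice_pair_set",
          "orthosr_empty_error")
  cfg <- model$cfg
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) cfg$batch_size else
    as.integer(batch_size)
  lr <- if (is.null(learning_rate)) cfg$learning_rate else learning_rate
  n <- dim(pairs$inputs)[3]
  set.seed(seed)
  # Adam state
  mW <- lapply(model$layers, function(l) array(0, dim(l$W)))
  vW <- lapply(model$layers, function(l) array(0, dim(l$W)))
  mb <- lapply(model$layers, function(l) numeric(l$cout))
  vb <- lapply(model$layers, function(l) numeric(l$cout))
  step <- 0L
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      batch <- perm[start:min(start + batch_size - 1, n)]
      gW <- lapply(model$layers, function(l) array(0, dim(l$W)))
      gb <- lapply(model$layers, function(l) numeric(l$cout))
      loss <- 0
      npx <- length(batch) * dim(pairs$inputs)[1] * dim(pairs$inputs)[2]
      for (b in batch) {
        fw <- arcnn_forward(model, pairs$inputs[, , b], keep_cache = TRUE)
        resid <- as.vector(fw$output) - as.vector(pairs$targets[, , b])
        loss <- loss + sum(resid^2)
        dout <- array(2 * resid / npx, dim(fw$output))
        grads <- arcnn_backward(model, fw$cache, dout)
        for (li in seq_along(grads)) {
          gW[[li]] <- gW[[li]] + grads[[li]]$dW
          gb[[li]] <- gb[[li]] + grads[[li]]$db
        }
      }
      loss <- loss / npx
      losses <- c(losses, loss)
      step <- step + 1L
      bc1 <- 1 - cfg$beta1^step
      bc2 <- 1 - cfg$beta2^step
      for (li in seq_along(model$layers)) {
        mW[[li]] <- cfg$beta1 * mW[[li]] + (1 - cfg$beta1) * gW[[li]]
        vW[[li]] <- cfg$beta2 * vW[[li]] + (1 - cfg$beta2) * gW[[li]]^2
        model$layers[[li]]$W <- model$layers[[li]]$W -
          lr * (mW[[li]] / bc1) / (sqrt(vW[[li]] / bc2) + cfg$epsilon)
        mb[[li]] <- cfg$beta1 * mb[[li]] + (1 - cfg$beta1) * gb[[li]]
        vb[[li]] <- cfg$beta2 * vb[[li]] + (1 - cfg$beta2) * gb[[li]]^2
        model$layers[[li]]$b <- model$layers[[li]]$b -
          lr * (mb[[li]] / bc1) / (sqrt(vb[[li]] / bc2) + cfg$epsilon)
      }
    }
    history[ep] <- mean(losses)
  }
  model$trained <- TRUE
  list(model = model, history = history)
}

#' Denoise a reconstructed volume slice by slice
#'
#' Each slice along `slice_axis` is passed through the network independently
#' (the network denoises 2D slices, not the 3D volume); outputs are clipped to
#' \[0, 1\]. Geometry is preserved. The network is fully convolutional, so any
#' in-plane size is accepted.
#'
#' @param model A trained `arcnn_model`.
#' @param vol Normalized `mri_volume` (values in \[0, 1\]).
#' @param slice_axis Slice axis (default 3).
#' @return The denoised `mri_volume`.
#' @export
arcnn_denoise <- function(model, vol, slice_axis = 3) {
  if (!inherits(model, "arcnn_model"))
    abort("expected an arcnn_model", "orthosr_type_error")
  if (!model$trained)
    abort("model has not been trained", "orthosr_untrained_error")
  stopifnot_volume(vol)
  out <- vol$data
  n <- dim(vol$data)[slice_axis]
  for (k in seq_len(n)) {
    idx <- list(TRUE, TRUE, TRUE)
    idx[[slice_axis]] <- k
    sl <- as.matrix(do.call(`[`, c(list(vol$data), idx, drop = TRUE)))
    y <- arcnn_forward(model, sl)$output[, , 1]
    y[y < 0] <- 0
    y[y > 1] <- 1
    out <- do.call(`[<-`, c(list(out), idx, list(y)))
  }
  res <- vol
  res$data <- out
  res
}

#' Final histogram match of the denoised output
#'
#' The pipeline's last step: the denoised reconstruction is histogram matched
#' to the down-sampled, normalized original target stack so its intensity
#' distribution faithfully follows the acquisition it enhances.
#'
#' @param denoised Denoised `mri_volume`.
#' @param reference The normalized original target stack.
#' @return Matched `mri_volume`.
#' @export
final_histogram_match <- function(denoised, reference) {
  match_histogram(denoised, reference)
}

#' Feature-enhancement-layer activation maps
#'
#' Runs a slice through the first three layers and returns the 32 activations
#' of the feature enhancement layer — the intermediate convolution responsible
#' for denoising the extracted features. Useful for inspecting where the
#' network focuses (typically tissue boundaries carrying block artefacts).
#'
#' @param model An `arcnn_model`.
#' @param slice 2D matrix (one image slice in \[0, 1\]).
#' @return `H x W x 32` array of activations (same spatial size as the input).
#' @export
activation_maps <- function(model, slice) {
  if (!inherits(model, "arcnn_model"))
    abort("expected an arcnn_model", "orthosr_type_error")
  a <- array(slice, c(dim(slice), 1L))
  for (li in 1:3) {
    l <- model$layers[[li]]
    y <- cpp_conv2d_forward(a, layer_w2d(l), l$b, l$kernel, l$pad)
    a <- y * (y > 0)
  }
  a
}

#' Save / load a model checkpoint
#'
#' A single file embedding the config, weights, training state and seed.
#'
#' @param model An `arcnn_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
arcnn_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname arcnn_save
#' @export
arcnn_load <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "arcnn_model"))
    abort("file does not hold an arcnn_model", "orthosr_type_error")
  m
}
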