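# Independent brute-force oracles. These deliberately avoid the package's
# spatial index and vectorized shortcuts: exhaustive scans and scalar loops
# only, so they can certify the optimized implementations.

# exhaustive nearest neighbour: for one query, scan every source centroid;
# ties broken toward the smallest flattened index (first minimum wins)
oracle_nearest <- function(centroids, query) {
  dx <- centroids[, 1] - query[1]
  dy <- centroids[, 2] - query[2]
  dz <- centroids[, 3] - query[3]
  d2 <- (dx * dx + dy * dy) + dz * dz
  i <- which.min(d2)   # which.min returns the first (smallest-index) minimum
  list(index = i, distance = sqrt(d2[i]))
}

# full brute-force fusion: loops over template voxels and planes with no
# spatial index; same weight formula and convexity clamp as the definition of the
# reconstruction, evaluated with scalar arithmetic
oracle_fusion <- function(planes, grid) {
  queries <- voxel_centroids(grid)
  cents <- lapply(planes, voxel_centroids)
  vals <- lapply(planes, function(p) as.vector(p$data))
  P <- length(planes)
  n <- nrow(queries)
  out <- numeric(n)
  D <- matrix(0, n, P)
  I <- matrix(0L, n, P)
  W <- matrix(0, n, P)
  for (q in seq_len(n)) {
    d <- numeric(P)
    v <- numeric(P)
    for (p in seq_len(P)) {
      nn <- oracle_nearest(cents[[p]], queries[q, ])
      d[p] <- nn$distance
      v[p] <- vals[[p]][nn$index]
      I[q, p] <- nn$index
    }
    dtot <- 0
    for (p in seq_len(P)) dtot <- dtot + d[p]
    w <- if (dtot == 0) rep(1 / P, P) else (dtot - d) / ((P - 1) * dtot)
    acc <- 0
    for (p in seq_len(P)) acc <- acc + w[p] * v[p]
    out[q] <- min(max(acc, min(v)), max(v))
    D[q, ] <- d
    W[q, ] <- w
  }
  list(values = out, distance = D, index = I, weight = W)
}

# scalar-loop image metrics over 3D arrays
oracle_metrics <- function(H, S) {
  d <- dim(H)
  n <- prod(d)
  s_abs <- 0; s_sq <- 0; mx <- -Inf; mn <- Inf
  mh <- 0; ms <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    e <- abs(H[i, j, k] - S[i, j, k])
    s_abs <- s_abs + e
    s_sq <- s_sq + e * e
    if (e > mx) mx <- e
    if (e < mn) mn <- e
    mh <- mh + H[i, j, k]
    ms <- ms + S[i, j, k]
  }
  mh <- mh / n; ms <- ms / n
  vh <- 0; vs <- 0; cv <- 0; s_dev <- 0
  mean_abs <- s_abs / n
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    vh <- vh + (H[i, j, k] - mh)^2
    vs <- vs + (S[i, j, k] - ms)^2
    cv <- cv + (H[i, j, k] - mh) * (S[i, j, k] - ms)
    s_dev <- s_dev + (abs(H[i, j, k] - S[i, j, k]) - mean_abs)^2
  }
  mse_v <- s_sq / n
  C1 <- 0.01^2; C2 <- 0.03^2
  list(mean = mean_abs, sd = sqrt(s_dev / (n - 1)), max = mx, min = mn,
       mse = mse_v,
       psnr = if (mse_v == 0) Inf else 10 * log10(1 / mse_v),
       ssim = ((2 * mh * ms + C1) * (2 * cv / n + C2)) /
         ((mh^2 + ms^2 + C1) * (vh / n + vs / n + C2)))
}

# scalar two-pass Pearson correlation
oracle_ncc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}
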