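check_same_grid <- function(H, S) {
  stopifnot_volume(H); stopifnot_volume(S)
  if (!all(dim(H$data) == dim(S$data)))
    abort("volumes must have identical dimensions", "orthosr_shape_error")
}

#' Mean absolute voxel error
#'
#' Mean, standard deviation, maximum and minimum of `|H_i - S_i|` over all
#' voxels. With intensities normalized to \[0, 1\] the values are fractions;
#' multiply by 100 to report percentages.
#'
#' @param H,S `mri_volume`s on identical grids (reference and reconstruction).
#' @return A list with `mean`, `sd`, `max`, `min`.
#' @export
mean_error <- function(H, S) {
  check_same_grid(H, S)
  e <- abs(as.vector(H$data) - as.vector(S$data))
  list(mean = mean(e), sd = stats::sd(e), max = max(e), min = min(e))
}

#' Mean squared voxel error
#'
#' @inheritParams mean_error
#' @return Mean of `(H_i - S_i)^2`.
#' @export
mse <- function(H, S) {
  check_same_grid(H, S)
  mean((as.vector(H$data) - as.vector(S$data))^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(MAX^2 / MSE)`. Identical images have zero MSE; `Inf` is
#' returned as the sentinel rather than an error.
#'
#' @inheritParams mean_error
#' @param max_value Maximum possible intensity (1 for normalized volumes).
#' @return PSNR in dB (`Inf` when MSE is 0).
#' @export
psnr <- function(H, S, max_value = 1) {
  m <- mse(H, S)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Global structural similarity index
#'
#' The single-window SSIM computed from global means, variances and
#' covariance:
#' \deqn{SSIM = \frac{(2\mu_h\mu_s + C_1)(2\sigma_{hs} + C_2)}
#'   {(\mu_h^2 + \mu_s^2 + C_1)(\sigma_h^2 + \sigma_s^2 + C_2)}}
#' with the standard stabilizers `C1 = (0.01 MAX)^2`, `C2 = (0.03 MAX)^2`.
#' Values lie in \[-1, 1\]; 1 indicates perfect similarity. Moments are
#' population moments (divide by N). For the conventional local sliding-window
#' variant see [ssim_windowed()].
#'
#' @inheritParams psnr
#' @param C1,C2 Stabilizing constants.
#' @return Scalar SSIM.
#' @export
ssim_global <- function(H, S, max_value = 1, C1 = (0.01 * max_value)^2,
                        C2 = (0.03 * max_value)^2) {
  check_same_grid(H, S)
  h <- as.vector(H$data); s <- as.vector(S$data)
  n <- length(h)
  mh <- mean(h); ms <- mean(s)
  vh <- sum((h - mh)^2) / n
  vs <- sum((s - ms)^2) / n
  cov <- sum((h - mh) * (s - ms)) / n
  ((2 * mh * ms + C1) * (2 * cov + C2)) /
    ((mh^2 + ms^2 + C1) * (vh + vs + C2))
}

#' Sliding-window (local) structural similarity index
#'
#' Conventional mean-of-local-SSIM over a cubic uniform window. This is not
#' the single global-window formula used by [ssim_global()] (the package
#' default); it is provided for comparison with common image libraries.
#'
#' @inheritParams ssim_global
#' @param window Odd cubic window side in voxels.
#' @return Mean local SSIM.
#' @export
ssim_windowed <- function(H, S, max_value = 1, window = 7,
                          C1 = (0.01 * max_value)^2,
                          C2 = (0.03 * max_value)^2) {
  check_same_grid(H, S)
  if (window %% 2 != 1 || window < 3)
    abort("window must be an odd integer >= 3", "orthosr_type_error")
  h <- H$data; s <- S$data
  mh <- box_mean3(h, window); ms <- box_mean3(s, window)
  mh2 <- box_mean3(h * h, window); ms2 <- box_mean3(s * s, window)
  mhs <- box_mean3(h * s, window)
  vh <- mh2 - mh^2; vs <- ms2 - ms^2; cov <- mhs - mh * ms
  ssim_map <- ((2 * mh * ms + C1) * (2 * cov + C2)) /
    ((mh^2 + ms^2 + C1) * (vh + vs + C2))
  mean(ssim_map)
}

# Uniform box mean over a cubic window via running sums along each axis,
# with edge windows truncated (same normalization as the counts).
box_mean3 <- function(a, window) {
  r <- (window - 1) / 2
  sums <- a
  cnts <- array(1, dim(a))
  for (ax in 1:3) {
    sums <- run_sum_axis(sums, ax, r)
    cnts <- run_sum_axis(cnts, ax, r)
  }
  sums / cnts
}

run_sum_axis <- function(a, axis, r) {
  d <- dim(a)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(n, seq_len(n) + r) + 1L
  lo <- pmax(0L, seq_len(n) - r - 1L) + 1L
  out <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}

#' Per-slice absolute error map
#'
#' Returns the `|H - S|` map for one slice, by default the slice with the
#' largest summed error (the convention used when displaying the
#' worst-affected slice of a reconstruction).
#'
#' @inheritParams mean_error
#' @param slice_axis Axis along which slices are indexed (default 3, the
#'   slice-select axis).
#' @param slice_index Slice to extract; `NULL` selects the slice maximizing
#'   the summed absolute error.
#' @return A list with `map` (2D error matrix), `slice_index`, `slice_axis`,
#'   and `per_slice_error` (summed absolute error of every slice).
#' @export
error_contour <- function(H, S, slice_axis = 3, slice_index = NULL) {
  check_same_grid(H, S)
  err <- abs(H$data - S$data)
  d <- dim(err)
  per_slice <- apply(err, slice_axis, sum)
  if (is.null(slice_index)) slice_index <- which.max(per_slice)
  if (slice_index < 1 || slice_index > d[slice_axis])
    abort("slice index out of range", "orthosr_index_error")
  idx <- list(TRUE, TRUE, TRUE)
  idx[[slice_axis]] <- slice_index
  map <- do.call(`[`, c(list(err), idx))
  list(map = as.matrix(map), slice_index = slice_index,
       slice_axis = slice_axis, per_slice_error = per_slice)
}

#' Render an error contour figure to PNG
#'
#' @param contour Output of [error_contour()].
#' @param path PNG path.
#' @param levels Number of contour levels.
#' @return `path`, invisibly.
#' @export
plot_error_contour <- function(contour, path, levels = 12) {
  grDevices::png(path, width = 800, height = 700)
  on.exit(grDevices::dev.off())
  graphics::filled.contour(
    x = seq_len(nrow(contour$map)), y = seq_len(ncol(contour$map)),
    z = contour$map, nlevels = levels,
    color.palette = grDevices::hcl.colors,
    main = sprintf("Absolute error, slice %d", contour$slice_index))
  invisible(path)
}

#' Full image-quality report for a reconstruction
#'
#' Computes the evaluation suite comparing a reconstruction `S` against ground
#' truth `H`: mean error and its SD/max/min, MSE, PSNR and global SSIM, plus
#' the per-slice error profile and the worst slice's error map.
#'
#' @inheritParams psnr
#' @param slice_axis Slice axis for the per-slice error profile.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(H, S, max_value = 1, slice_axis = 3) {
  me <- mean_error(H, S)
  ct <- error_contour(H, S, slice_axis = slice_axis)
  structure(list(mean_error = me$mean, error_sd = me$sd, max_error = me$max,
                 min_error = me$min, mse = mse(H, S),
                 psnr = psnr(H, S, max_value),
                 ssim = ssim_global(H, S, max_value),
                 per_slice_error = ct$per_slice_error,
                 worst_slice = ct$slice_index,
                 worst_slice_map = ct$map),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  mean error %.3f%% +/- %.3f%%  (max %.2f%%, min %.2f%%)\n",
              100 * x$mean_error, 100 * x$error_sd, 100 * x$max_error,
              100 * x$min_error))
  cat(sprintf("  MSE %.5g   PSNR %.2f dB   SSIM %.4f\n", x$mse, x$psnr,
              x$ssim))
  cat(sprintf("  worst slice: %d\n", x$worst_slice))
  invisible(x)
}

#' Serialize a metrics report as JSON
#'
#' Scalar metrics are written both as fractions and as the percentage form in
#' which they are conventionally reported; the worst-slice map is omitted.
#'
#' @param report A [metrics_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  out <- list(
    mean_error = report$mean_error, error_sd = report$error_sd,
    max_error = report$max_error, min_error = report$min_error,
    mse = report$mse, psnr_db = report$psnr, ssim = report$ssim,
    mean_error_pct = 100 * report$mean_error,
    error_sd_pct = 100 * report$error_sd,
    worst_slice = report$worst_slice,
    per_slice_error = report$per_slice_error)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
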