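# Shared fixtures: small volumes and studies built in code at test time.

rand_volume <- function(dims = c(8, 8, 8), seed = 1, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), orientation = diag(3)) {
  set.seed(seed)
  mri_volume(array(runif(prod(dims)), dims), spacing = spacing,
             origin = origin, orientation = orientation)
}

# linear-ramp volume: intensity is an affine function of world position
ramp_volume <- function(dims = c(8, 8, 8), spacing = c(1, 1, 1),
                        coef = c(0.01, 0.02, 0.03), intercept = 0.1) {
  idx <- expand.grid(i = seq_len(dims[1]) - 1, j = seq_len(dims[2]) - 1,
                     k = seq_len(dims[3]) - 1)
  w <- t(t(as.matrix(idx)) * spacing)
  mri_volume(array(intercept + as.matrix(w) %*% coef, dims),
             spacing = spacing)
}

# a small study of three overlapping random stacks on permuted orientations,
# suitable for fusion oracle checks (no registration needed: geometry given)
tiny_study <- function(seed = 1, n = 10) {
  set.seed(seed)
  dims <- function() sample(5:n, 3, replace = TRUE)
  mk <- function(plane) {
    R <- switch(plane,
                axial = diag(3),
                sagittal = matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3),
                coronal = matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3))
    d <- dims()
    sp <- runif(3, 0.5, 2)
    mri_volume(array(runif(prod(d)), d), spacing = sp,
               origin = runif(3, -1, 1), orientation = R)
  }
  orthogonal_study(mk("sagittal"), mk("axial"), mk("coronal"))
}

small_phantom <- function(dims = c(32, 32, 32), ...) {
  phantom_spec(dims = dims, ...)
}
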