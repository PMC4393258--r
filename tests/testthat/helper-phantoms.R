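# Shared fixtures, all generated in code.

# Small uniform-noise volume for I/O and grid tests.
tiny_volume <- function(dims = c(10, 10, 5), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), orientation = diag(3),
                        modality = "ADC", seed = 42) {
  set.seed(seed)
  image_volume(array(runif(prod(dims)), dim = dims), spacing = spacing,
               origin = origin, orientation = orientation,
               modality = modality, units = "a.u.")
}

full_mask <- function(vol) voi_mask(array(TRUE, dim = dim(vol$data)))

# Textured registration phantom: structure in every direction so that both
# translation and rotation are well determined by mutual information.
reg_phantom_spec <- function(seed = 5) {
  phantom_spec(grid_shape = c(36, 36, 28), spacing = c(1.5, 1.5, 2),
               lesion_radii = c(12, 9, 10), noise_sd_adc = 0.02,
               texture_amp = 0.3, seed = seed)
}

# Build a moving image carrying a known planted transform: moving is the
# fixed image resampled through the inverse, so registering fixed onto
# moving should recover `true_tf` (background filled so MI sees no NaN).
planted_moving <- function(fixed, true_tf, fill = 1.0) {
  mv <- resample_to_baseline(fixed, fixed, invert_rigid(true_tf))$followup_resampled
  mv$data[is.na(mv$data)] <- fill
  mv
}

grid_center <- function(vol) (dim(vol$data) - 1) / 2 * vol$spacing

# Brute-force reference for classify(): per-voxel loop with no vectorized
# shortcuts, used as the independent oracle.
classify_bruteforce <- function(pre, post, voi, overlap, hw) {
  d <- dim(pre)
  labels <- array(NA_integer_, dim = d)
  n_plus <- n_minus <- n_zero <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!voi[i, j, k] || !overlap[i, j, k]) next
    a <- pre[i, j, k]; b <- post[i, j, k]
    if (is.na(a) || is.na(b)) next
    delta <- b - a
    lab <- if (delta > hw) 1L else if (delta < -hw) -1L else 0L
    labels[i, j, k] <- lab
    if (lab == 1L) n_plus <- n_plus + 1L
    else if (lab == -1L) n_minus <- n_minus + 1L
    else n_zero <- n_zero + 1L
  }
  n <- n_plus + n_minus + n_zero
  list(labels = labels, frac_plus = 100 * n_plus / n,
       frac_minus = 100 * n_minus / n, frac_zero = 100 * n_zero / n,
       n_valid = n)
}
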