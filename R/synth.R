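# Synthetic longitudinal phantoms with known ground truth: tumor ADC
# volumes, tibia-like CT volumes, same-day test-retest replicates, and
# cohort-level effect structure. Everything is deterministic given the
# seeds carried in the spec objects; the generators save and restore the
# caller's RNG state.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  force(expr)
}

#' Specify a longitudinal imaging phantom
#'
#' Geometry and intensity parameters for piecewise-constant digital
#' phantoms. ADC phantoms are a soft-tissue background with an ellipsoidal
#' tumor; CT phantoms are a tibia-like cylinder (cortical shell around a
#' trabecular core) with an ellipsoidal lesion inside the core. Intensity
#' defaults sit in the physiological ranges for the respective maps
#' (ADC ~0.5-2.0 x 1e-3 mm^2/s; cortical bone ~1500 HU, trabecular
#' ~300 HU).
#'
#' @param grid_shape Lattice dimensions (length 3).
#' @param spacing Voxel size, mm (length 3).
#' @param lesion_center Ellipsoid center in world mm; default is the grid
#'   center.
#' @param lesion_radii Ellipsoid semi-axes, mm.
#' @param background_adc,tumor_adc ADC compartments, 1e-3 mm^2/s.
#' @param cortical_hu,trabecular_hu,lesion_hu CT compartments, HU.
#' @param noise_sd_adc,noise_sd_hu Additive Gaussian noise SDs (>= 0) in
#'   map units.
#' @param texture_amp Amplitude of a deterministic smooth texture (a fixed
#'   asymmetric arrangement of Gaussian bumps) added to the noiseless
#'   compartments, in map units. Zero by default; set it positive for
#'   registration phantoms, where a single near-spherical lesion leaves
#'   rotation nearly unconstrained. The bump field is non-periodic, so it
#'   cannot alias under translation the way a sinusoidal pattern does.
#' @param texture_scale Bump width (Gaussian sigma), mm.
#' @param seed Integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40, 40, 30), spacing = c(1, 1, 1),
                         lesion_center = NULL, lesion_radii = c(8, 8, 6),
                         background_adc = 1.0, tumor_adc = 0.7,
                         cortical_hu = 1500, trabecular_hu = 300,
                         lesion_hu = 700,
                         noise_sd_adc = 0.05, noise_sd_hu = 30,
                         texture_amp = 0, texture_scale = 6,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            length(spacing) == 3L, all(spacing > 0),
            noise_sd_adc >= 0, noise_sd_hu >= 0)
  if (is.null(lesion_center)) lesion_center <- (grid_shape - 1) / 2 * spacing
  fov <- (grid_shape - 1) * spacing
  if (any(lesion_center - lesion_radii < 0) ||
      any(lesion_center + lesion_radii > fov))
    stop("phantom_spec: lesion ellipsoid does not fit inside the grid",
         call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 lesion_center = as.numeric(lesion_center),
                 lesion_radii = as.numeric(lesion_radii),
                 background_adc = background_adc, tumor_adc = tumor_adc,
                 cortical_hu = cortical_hu, trabecular_hu = trabecular_hu,
                 lesion_hu = lesion_hu, noise_sd_adc = noise_sd_adc,
                 noise_sd_hu = noise_sd_hu, texture_amp = texture_amp,
                 texture_scale = texture_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specify a planted longitudinal change
#'
#' @param mode One of `"response_adc_up"` (treatment-induced diffusion
#'   increase), `"lysis_hu_down"` (osteolytic attenuation loss),
#'   `"blastic_hu_up"` (osteoblastic mineralization), `"mixed"` (half the
#'   changed voxels shift up, half down), `"null"` (noise only).
#' @param changed_fraction Fraction of VOI voxels to shift, in [0, 1].
#' @param effect_size Shift magnitude in map units (sign applied per mode).
#' @param spatial_pattern `"random_voxels"` or `"core_shell"` (changed
#'   voxels nearest the lesion center first).
#' @param seed Integer RNG seed.
#' @return An object of class `change_spec`.
#' @export
change_spec <- function(mode = c("response_adc_up", "lysis_hu_down",
                                 "blastic_hu_up", "mixed", "null"),
                        changed_fraction = 0.3, effect_size = 0.4,
                        spatial_pattern = c("random_voxels", "core_shell"),
                        seed = 1L) {
  mode <- match.arg(mode)
  spatial_pattern <- match.arg(spatial_pattern)
  if (changed_fraction < 0 || changed_fraction > 1)
    stop("change_spec: changed_fraction must lie in [0, 1]", call. = FALSE)
  stopifnot(effect_size >= 0)
  structure(list(mode = mode, changed_fraction = changed_fraction,
                 effect_size = effect_size, spatial_pattern = spatial_pattern,
                 seed = as.integer(seed)),
            class = "change_spec")
}

# world coordinates of every voxel center on the spec grid (n x 3)
phantom_grid_points <- function(spec) {
  d <- spec$grid_shape
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  sweep(idx, 2L, spec$spacing, "*")
}

phantom_masks <- function(spec, modality) {
  d <- spec$grid_shape
  pts <- phantom_grid_points(spec)
  m <- sweep(pts, 2L, spec$lesion_center, "-")
  inside <- rowSums(sweep(m, 2L, spec$lesion_radii, "/")^2) <= 1
  lesion <- array(inside, dim = d)
  if (modality == "ADC") {
    bone <- array(FALSE, dim = d)
  } else {
    # tibia-like cylinder along z: outer cortical shell, trabecular core
    cxy <- spec$lesion_center[1:2]
    r <- sqrt((pts[, 1] - cxy[1])^2 + (pts[, 2] - cxy[2])^2)
    r_out <- min(0.45 * (d[1:2] - 1) * spec$spacing[1:2])
    r_in <- 0.75 * r_out
    bone <- array(r <= r_out, dim = d)
    attr(bone, "cortical") <- array(r <= r_out & r > r_in, dim = d)
    attr(bone, "trabecular") <- array(r <= r_in, dim = d)
  }
  list(lesion = lesion, bone = bone)
}

#' Generate a baseline phantom volume
#'
#' Piecewise-constant compartments plus additive Gaussian voxel noise,
#' deterministic given `spec$seed`. For `modality = "ADC"`: background with
#' a tumor ellipsoid. For `modality = "HU"`: cortical shell, trabecular
#' core and a lesion ellipsoid. The returned masks trace the noiseless
#' geometry.
#'
#' @param spec A [phantom_spec()].
#' @param modality `"ADC"` or `"HU"`.
#' @return List with `volume` ([image_volume()]), `lesion_mask` and
#'   `bone_mask` ([voi_mask()] objects), and `noiseless` (the clean array).
#' @export
make_baseline <- function(spec, modality = c("ADC", "HU")) {
  stopifnot(inherits(spec, "phantom_spec"))
  modality <- match.arg(modality)
  d <- spec$grid_shape
  masks <- phantom_masks(spec, modality)
  if (modality == "ADC") {
    clean <- array(spec$background_adc, dim = d)
    clean[masks$lesion] <- spec$tumor_adc
    sdv <- spec$noise_sd_adc
    units <- "1e-3 mm^2/s"
  } else {
    clean <- array(-1000, dim = d)                     # air outside the bone
    clean[attr(masks$bone, "trabecular")] <- spec$trabecular_hu
    clean[attr(masks$bone, "cortical")] <- spec$cortical_hu
    clean[masks$lesion] <- spec$lesion_hu
    sdv <- spec$noise_sd_hu
    units <- "HU"
  }
  if (spec$texture_amp > 0) {
    pts <- phantom_grid_points(spec)
    fov <- (d - 1) * spec$spacing
    # fixed asymmetric bump arrangement in fractional FOV coordinates
    bumps <- matrix(c(0.25, 0.30, 0.40, 0.70, 0.60, 0.30,
                      0.40, 0.75, 0.70, 0.80, 0.20, 0.75,
                      0.30, 0.50, 0.25, 0.60, 0.40, 0.80),
                    ncol = 3, byrow = TRUE)
    sgn <- c(1, -1, 1, -1, 1, -1)
    tex <- numeric(nrow(pts))
    for (k in seq_len(nrow(bumps))) {
      ctr <- bumps[k, ] * fov
      d2 <- rowSums(sweep(pts, 2L, ctr, "-")^2)
      tex <- tex + sgn[k] * exp(-d2 / (2 * spec$texture_scale^2))
    }
    clean <- clean + spec$texture_amp * array(tex, dim = d)
  }
  data <- with_seed(spec$seed,
                    clean + array(stats::rnorm(prod(d), 0, sdv), dim = d))
  vol <- image_volume(data, spacing = spec$spacing, modality = modality,
                      units = units)
  list(volume = vol,
       lesion_mask = voi_mask(masks$lesion, reference = "baseline"),
       bone_mask = voi_mask(array(as.logical(masks$bone), dim = d),
                            reference = "baseline"),
       noiseless = clean)
}

#' Generate a follow-up phantom with planted change
#'
#' Shifts a known subset of lesion-VOI voxels of the noiseless baseline by
#' `effect_size` (sign per mode), then adds fresh independent noise. The
#' ground-truth changed-voxel mask is returned so recovery can be scored.
#'
#' @param baseline A [make_baseline()] result.
#' @param spec The [phantom_spec()] that generated it.
#' @param change A [change_spec()].
#' @return List with `volume` ([image_volume()]) and `truth_mask`
#'   ([voi_mask()] of planted changed voxels; also carries attribute
#'   `signs` for mixed mode).
#' @export
make_followup <- function(baseline, spec, change) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(change, "change_spec"))
  d <- spec$grid_shape
  modality <- baseline$volume$modality
  sdv <- if (modality == "ADC") spec$noise_sd_adc else spec$noise_sd_hu
  clean <- baseline$noiseless
  truth <- array(FALSE, dim = d)
  signs <- array(0, dim = d)
  if (change$mode != "null" && change$changed_fraction > 0) {
    voi_idx <- which(baseline$lesion_mask$data)
    n_change <- round(change$changed_fraction * length(voi_idx))
    sel <- with_seed(change$seed, {
      if (change$spatial_pattern == "random_voxels") {
        sample(voi_idx, n_change)
      } else {
        pts <- phantom_grid_points(spec)[voi_idx, , drop = FALSE]
        dist2 <- rowSums(sweep(pts, 2L, spec$lesion_center, "-")^2)
        voi_idx[order(dist2)][seq_len(n_change)]
      }
    })
    sgn <- switch(change$mode,
                  response_adc_up = rep(1, length(sel)),
                  blastic_hu_up = rep(1, length(sel)),
                  lysis_hu_down = rep(-1, length(sel)),
                  mixed = rep(c(1, -1), length.out = length(sel)))
    clean[sel] <- clean[sel] + sgn * change$effect_size
    truth[sel] <- TRUE
    signs[sel] <- sgn
  }
  data <- with_seed(change$seed + 1000003L,
                    clean + array(stats::rnorm(prod(d), 0, sdv), dim = d))
  tm <- voi_mask(truth, reference = "baseline")
  attr(tm, "signs") <- signs
  list(volume = image_volume(data, spacing = spec$spacing,
                             modality = modality,
                             units = baseline$volume$units),
       truth_mask = tm)
}

#' Generate a same-day test-retest replicate pair
#'
#' Two acquisitions of the same noiseless structure with independent noise
#' draws; the voxel-wise difference is Gaussian with SD `sqrt(2)` times the
#' voxel noise SD, which is what the 95% no-change threshold calibrates.
#'
#' @param spec A [phantom_spec()].
#' @param modality `"ADC"` or `"HU"`.
#' @param seed2 Seed for the second replicate's noise (must differ from
#'   `spec$seed` for independence).
#' @return List with `test`, `retest` ([image_volume()]), `lesion_mask`,
#'   `bone_mask`.
#' @export
make_testretest <- function(spec, modality = c("ADC", "HU"), seed2 = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  modality <- match.arg(modality)
  if (is.null(seed2)) seed2 <- spec$seed + 500009L
  b1 <- make_baseline(spec, modality)
  spec2 <- spec
  spec2$seed <- as.integer(seed2)
  b2 <- make_baseline(spec2, modality)
  list(test = b1$volume, retest = b2$volume,
       lesion_mask = b1$lesion_mask, bone_mask = b1$bone_mask)
}

#' Generate a synthetic two-group longitudinal cohort
#'
#' Emulates a responder/progressor cohort structure: each subject gets a
#' baseline phantom and a follow-up with a planted changed fraction drawn
#' from its group's distribution (truncated to [0, 1]). The defaults plant
#' group mean PRM+ fractions of 17.2% versus 7.1% with small between-
#' subject spread.
#'
#' @param n_responders,n_progressors Group sizes (>= 1).
#' @param spec A [phantom_spec()] shared by all subjects.
#' @param mode Change mode passed to [change_spec()].
#' @param effect_size Planted shift in map units.
#' @param frac_mean Length-2: mean changed fraction for responders and
#'   progressors.
#' @param frac_sd Length-2: between-subject SD of the changed fraction.
#' @param seed Integer master seed.
#' @return List with `subjects` (per-subject list: `id`, `group`,
#'   `baseline`, `followup`, `planted_fraction`) and `truth` (data frame
#'   `id`, `group`, `planted_fraction`).
#' @export
make_cohort <- function(n_responders, n_progressors, spec,
                        mode = "response_adc_up", effect_size = 0.4,
                        frac_mean = c(0.172, 0.071),
                        frac_sd = c(0.04, 0.02), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_responders < 1L || n_progressors < 1L)
    stop("make_cohort: both group sizes must be >= 1", call. = FALSE)
  groups <- c(rep("responder", n_responders), rep("progressor", n_progressors))
  n <- length(groups)
  fracs <- with_seed(seed, {
    g <- as.integer(groups == "progressor") + 1L
    pmin(pmax(stats::rnorm(n, frac_mean[g], frac_sd[g]), 0), 1)
  })
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- as.integer(spec$seed + 7L * i)
    bl <- make_baseline(sp, "ADC")
    ch <- change_spec(mode = mode, changed_fraction = fracs[i],
                      effect_size = effect_size,
                      seed = as.integer(seed + 13L * i))
    fu <- make_followup(bl, sp, ch)
    subjects[[i]] <- list(id = sprintf("S%02d", i), group = groups[i],
                          baseline = bl, followup = fu,
                          planted_fraction = fracs[i])
  }
  truth <- data.frame(id = vapply(subjects, `[[`, "", "id"),
                      group = groups, planted_fraction = fracs)
  list(subjects = subjects, truth = truth)
}

#' Simulate a two-b-value DW acquisition from a diffusivity map
#'
#' Monoexponential decay `S(b) = S0 * exp(-D * b)` evaluated at two
#' b-values, optionally with Rician noise (magnitude of a complex Gaussian),
#' for exercising the ADC estimator against known diffusivity.
#'
#' @param adc An [image_volume()] of diffusivities in 1e-3 mm^2/s.
#' @param b1,b2 b-values, s/mm^2.
#' @param s0 Proton-density signal at b = 0.
#' @param rician_sigma Noise SD per channel; 0 for noiseless.
#' @param seed RNG seed (used only when `rician_sigma > 0`).
#' @return A [dw_pair()].
#' @export
simulate_dw_pair <- function(adc, b1 = 120, b2 = 1200, s0 = 1000,
                             rician_sigma = 0, seed = 1L) {
  stopifnot(inherits(adc, "image_volume"))
  d <- dim(adc$data)
  D <- adc$data * 1e-3                            # back to mm^2/s
  sig <- function(b) s0 * exp(-D * b)
  s1 <- sig(b1); s2 <- sig(b2)
  if (rician_sigma > 0) {
    noisy <- with_seed(seed, {
      rice <- function(s) sqrt((s + stats::rnorm(length(s), 0, rician_sigma))^2 +
                                 stats::rnorm(length(s), 0, rician_sigma)^2)
      list(array(rice(s1), d), array(rice(s2), d))
    })
    s1 <- noisy[[1]]; s2 <- noisy[[2]]
  }
  mk <- function(x) image_volume(x, spacing = adc$spacing, origin = adc$origin,
                                 orientation = adc$orientation,
                                 modality = "DW", units = "a.u.")
  dw_pair(mk(s1), mk(s2), b1 = b1, b2 = b2)
}
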