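# The parametric response map (PRM): calibrate a 95% no-change threshold
# from same-day test-retest data, classify registered voxel pairs into
# increased / decreased / unchanged, and summarize volume fractions,
# scatter data and color overlays.

#' Fixed no-change thresholds shipped with the package
#'
#' Cohort-wide 95% confidence half-widths, by modality and subject type:
#' ADC 0.32 (mouse) / 0.55 (human) x 1e-3 mm^2/s, HU 391 (mouse) /
#' 100 (human).
#'
#' @param modality `"ADC"` or `"HU"`.
#' @param subject `"mouse"` or `"human"`.
#' @return A [prm_threshold()] with method `"fixed"`.
#' @export
default_threshold <- function(modality = c("ADC", "HU"),
                              subject = c("mouse", "human")) {
  modality <- match.arg(modality)
  subject <- match.arg(subject)
  hw <- switch(modality,
               ADC = c(mouse = 0.32, human = 0.55),
               HU  = c(mouse = 391, human = 100))[[subject]]
  prm_threshold(hw, method = "fixed", modality = modality)
}

#' Construct a PRM no-change threshold
#'
#' @param half_width Non-negative half-width of the no-change band, in map
#'   units (1e-3 mm^2/s for ADC, HU for CT).
#' @param method Provenance: `"sd_1p96"`, `"percentile_2p5_97p5"`, or
#'   `"fixed"` (explicitly supplied).
#' @param modality `"ADC"` or `"HU"`.
#' @param n_voxels Calibration sample size (0 for fixed thresholds).
#' @return An object of class `prm_threshold`.
#' @export
prm_threshold <- function(half_width, method = "fixed",
                          modality = c("ADC", "HU"), n_voxels = 0L) {
  method <- match.arg(method, c("sd_1p96", "percentile_2p5_97p5", "fixed"))
  modality <- match.arg(modality)
  half_width <- as.numeric(half_width)
  if (length(half_width) != 1L || !is.finite(half_width) || half_width < 0)
    stop("prm_threshold: half_width must be a single finite value >= 0",
         call. = FALSE)
  structure(list(half_width = half_width, method = method,
                 modality = modality, n_voxels = as.integer(n_voxels)),
            class = "prm_threshold")
}

#' @export
print.prm_threshold <- function(x, ...) {
  units <- if (x$modality == "ADC") "1e-3 mm^2/s" else "HU"
  cat(sprintf("<prm_threshold> %s: +/- %.4g %s (method %s, n = %d)\n",
              x$modality, x$half_width, units, x$method, x$n_voxels))
  invisible(x)
}

#' Calibrate the no-change threshold from test-retest data
#'
#' Computes voxel-wise differences `retest - test` over the valid VOI
#' voxels of a same-day scan pair (no intervening biological change) and
#' returns the 95% confidence half-width of no change: `1.96 * SD` of the
#' differences (method `sd_1p96`, symmetric), or the larger of |2.5th| and
#' 97.5th percentile (method `percentile_2p5_97p5`, for skewed noise).
#'
#' @param test,retest [image_volume()] objects registered on a shared grid.
#' @param voi [voi_mask()] of the calibration region (non-empty).
#' @param method `"sd_1p96"` (default) or `"percentile_2p5_97p5"`.
#' @return A [prm_threshold()].
#' @export
calibrate_threshold <- function(test, retest, voi,
                                method = c("sd_1p96", "percentile_2p5_97p5")) {
  stopifnot(inherits(test, "image_volume"), inherits(retest, "image_volume"),
            inherits(voi, "voi_mask"))
  method <- match.arg(method)
  if (!same_grid(test, retest))
    stop("calibrate_threshold: test and retest do not share a grid", call. = FALSE)
  if (!all(dim(voi$data) == dim(test$data)))
    stop("calibrate_threshold: VOI dimensions do not match the grid", call. = FALSE)
  d <- (retest$data - test$data)[voi$data]
  d <- d[!is.na(d)]
  if (length(d) < 30L)
    stop("calibrate_threshold: only ", length(d),
         " valid voxels; too few for a 95% confidence interval (need >= 30)",
         call. = FALSE)
  hw <- switch(method,
               sd_1p96 = 1.96 * stats::sd(d),
               percentile_2p5_97p5 = {
                 q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
                 max(abs(q[1]), q[2])
               })
  if (hw == 0)
    warning("calibrate_threshold: degenerate calibration (test == retest); half_width = 0")
  modality <- if (test$modality == "HU") "HU" else "ADC"
  prm_threshold(hw, method = method, modality = modality,
                n_voxels = length(d))
}

#' Classify voxel-wise change against a no-change threshold
#'
#' For every valid voxel in the VOI (and inside the registration overlap),
#' the change `delta = post - pre` is classified as increased (+1) when
#' `delta > half_width`, decreased (-1) when `delta < -half_width`, and
#' unchanged (0) otherwise; ties at the threshold count as unchanged.
#' Fractions are reported as percentages of the valid VOI voxels; voxels
#' carrying the invalid marker in either map are excluded from numerator
#' and denominator and counted in `n_excluded`. The absolute changed
#' volumes in cm^3 are also reported.
#'
#' @param pair A `registered_pair` from [resample_to_baseline()].
#' @param voi [voi_mask()] on the baseline grid.
#' @param threshold A [prm_threshold()] whose modality matches the pair.
#' @return An object of class `prm_result` with `labels` (3D array,
#'   -1/0/+1, `NA` outside the valid set), `frac_plus`, `frac_minus`,
#'   `frac_zero` (percent), `vol_plus_cm3`, `vol_minus_cm3`, `n_valid`,
#'   `n_excluded`, `scatter` (data frame pre, post, label), `threshold`.
#' @export
classify <- function(pair, voi, threshold) {
  stopifnot(inherits(pair, "registered_pair"), inherits(voi, "voi_mask"),
            inherits(threshold, "prm_threshold"))
  pre <- pair$baseline_map
  post <- pair$followup_resampled
  if (!all(dim(voi$data) == dim(pre$data)))
    stop("classify: VOI dimensions do not match the baseline grid", call. = FALSE)
  if (threshold$modality != (if (pre$modality == "HU") "HU" else "ADC"))
    stop("classify: threshold modality (", threshold$modality,
         ") does not match map modality (", pre$modality, ")", call. = FALSE)
  sel <- voi$data & pair$overlap_mask$data
  valid <- sel & !is.na(pre$data) & !is.na(post$data)
  n_valid <- sum(valid)
  n_excluded <- sum(sel) - n_valid
  if (n_valid == 0L)
    stop("classify: no valid voxels in VOI after masking", call. = FALSE)
  hw <- threshold$half_width
  delta <- post$data[valid] - pre$data[valid]
  lab <- integer(n_valid)
  lab[delta > hw] <- 1L
  lab[delta < -hw] <- -1L
  labels <- array(NA_integer_, dim = dim(pre$data))
  labels[valid] <- lab
  vox_cm3 <- prod(pre$spacing) / 1000
  structure(list(labels = labels,
                 frac_plus = 100 * sum(lab == 1L) / n_valid,
                 frac_minus = 100 * sum(lab == -1L) / n_valid,
                 frac_zero = 100 * sum(lab == 0L) / n_valid,
                 vol_plus_cm3 = sum(lab == 1L) * vox_cm3,
                 vol_minus_cm3 = sum(lab == -1L) * vox_cm3,
                 n_valid = n_valid, n_excluded = n_excluded,
                 scatter = data.frame(pre = pre$data[valid],
                                      post = post$data[valid],
                                      label = lab),
                 threshold = threshold),
            class = "prm_result")
}

#' @export
print.prm_result <- function(x, ...) {
  cat(sprintf("<prm_result> %s: +%.1f%% / -%.1f%% / 0 %.1f%% of %d valid voxels (%d excluded)\n",
              x$threshold$modality, x$frac_plus, x$frac_minus, x$frac_zero,
              x$n_valid, x$n_excluded))
  invisible(x)
}

#' PRM time course against a common baseline
#'
#' Classifies each follow-up in a longitudinal series against the shared
#' baseline and returns one summary row per day. The baseline may be the
#' pre-treatment scan or (for natural-history comparisons) the
#' implantation-day scan; that choice is made upstream when constructing
#' the registered pairs.
#'
#' @param series Named or unnamed list of `registered_pair` objects sharing
#'   one baseline.
#' @param days Numeric vector of acquisition days, strictly increasing.
#' @param voi [voi_mask()] on the baseline grid.
#' @param threshold [prm_threshold()].
#' @return Data frame with columns `day`, `frac_plus`, `frac_minus`,
#'   `frac_zero`, `vol_plus_cm3`, `vol_minus_cm3`, `n_valid`, `n_excluded`.
#' @export
prm_timecourse <- function(series, days, voi, threshold) {
  if (length(series) != length(days))
    stop("prm_timecourse: series and days lengths differ", call. = FALSE)
  empty <- data.frame(day = numeric(0), frac_plus = numeric(0),
                      frac_minus = numeric(0), frac_zero = numeric(0),
                      vol_plus_cm3 = numeric(0), vol_minus_cm3 = numeric(0),
                      n_valid = integer(0), n_excluded = integer(0))
  if (length(series) == 0L) return(empty)
  if (anyDuplicated(days))
    stop("prm_timecourse: duplicate days", call. = FALSE)
  if (is.unsorted(days, strictly = TRUE))
    stop("prm_timecourse: days must be strictly increasing", call. = FALSE)
  rows <- lapply(seq_along(series), function(i) {
    r <- classify(series[[i]], voi, threshold)
    data.frame(day = days[i], frac_plus = r$frac_plus,
               frac_minus = r$frac_minus, frac_zero = r$frac_zero,
               vol_plus_cm3 = r$vol_plus_cm3, vol_minus_cm3 = r$vol_minus_cm3,
               n_valid = r$n_valid, n_excluded = r$n_excluded)
  })
  do.call(rbind, rows)
}

#' Export PRM color overlays as per-slice PNGs
#'
#' Renders each slice along the chosen axis as a grayscale background with
#' the PRM labels alpha-blended on top: red for increased, blue for
#' decreased, green for statistically unchanged. Invalid voxels are left
#' uncolored.
#'
#' @param result A [classify()] result.
#' @param background [image_volume()] on the baseline grid.
#' @param slice_axis Axis (1, 2 or 3) perpendicular to the slices.
#' @param path Output directory for `slice_###.png` files.
#' @param alpha Blend weight of the label colors in (0, 1].
#' @return Invisibly, the vector of file paths written.
#' @export
export_overlay <- function(result, background, slice_axis = 3L, path,
                           alpha = 0.6) {
  stopifnot(inherits(result, "prm_result"), inherits(background, "image_volume"))
  if (!all(dim(result$labels) == dim(background$data)))
    stop("export_overlay: background grid does not match the label lattice",
         call. = FALSE)
  slice_axis <- as.integer(slice_axis)
  stopifnot(slice_axis %in% 1:3)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  bg <- background$data
  rng <- range(bg[!is.na(bg)])
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  gray <- (bg - rng[1]) / diff(rng)
  gray[is.na(gray)] <- 0
  nsl <- dim(bg)[slice_axis]
  cols <- rbind(`1` = c(1, 0, 0), `0` = c(0, 1, 0), `-1` = c(0, 0, 1))
  files <- character(nsl)
  for (s in seq_len(nsl)) {
    g <- switch(slice_axis, gray[s, , ], gray[, s, ], gray[, , s])
    lb <- switch(slice_axis,
                 result$labels[s, , ], result$labels[, s, ],
                 result$labels[, , s])
    rgb <- array(rep(g, 3L), dim = c(dim(g), 3L))
    lab_idx <- which(!is.na(lb))
    for (i in lab_idx) {
      ci <- cols[as.character(lb[i]), ]
      ij <- arrayInd(i, dim(lb))
      rgb[ij[1], ij[2], ] <- (1 - alpha) * rgb[ij[1], ij[2], ] + alpha * ci
    }
    # PNG rasters index (row = y from top); transpose so x runs horizontally
    files[s] <- file.path(path, sprintf("slice_%03d.png", s))
    png::writePNG(aperm(rgb, c(2, 1, 3)), files[s])
  }
  invisible(files)
}

#' Write the PRM scatter pairs to CSV
#'
#' One row per valid VOI voxel with its baseline value, follow-up value and
#' ternary label; the raw material for pre/post scatter plots.
#'
#' @param result A [classify()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_scatter <- function(result, path) {
  stopifnot(inherits(result, "prm_result"))
  utils::write.csv(result$scatter, path, row.names = FALSE)
  invisible(path)
}

#' Write PRM labels as a NIfTI volume
#'
#' Codes: +1 increased, -1 decreased, 0 unchanged, -128 invalid.
#'
#' @param result A [classify()] result.
#' @param grid The baseline [image_volume()] (for the affine).
#' @param path Output NIfTI path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(result, grid, path) {
  stopifnot(inherits(result, "prm_result"), inherits(grid, "image_volume"))
  codes <- result$labels
  codes[is.na(codes)] <- -128L
  img <- RNifti::asNifti(array(as.integer(codes), dim = dim(codes)),
                         pixdim = grid$spacing)
  img <- RNifti::`sform<-`(img, structure(grid_affine(grid), code = 2L))
  RNifti::writeNifti(img, path, datatype = "int8")
  invisible(path)
}
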