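# Quantitative parameter maps: ADC from a two-b-value DW pair, and
# Hounsfield-calibrated CT from raw attenuation.

#' Compute an apparent diffusion coefficient map
#'
#' Two-point estimate of the water diffusivity from a pair of
#' diffusion-weighted acquisitions at b-values `b1 < b2`:
#' \deqn{ADC = \ln(S_1 / S_2) / (b_2 - b_1)}
#' where \eqn{S_1, S_2} are the signal intensities at the low and high
#' b-value. Using a non-zero low b-value (the default pairing is
#' b1 = 120, b2 = 1200 s/mm^2) desensitizes the estimate to local perfusion.
#' The map is reported in units of 1e-3 mm^2/s.
#'
#' Voxels where either signal is non-positive (log undefined) are set to
#' the invalid marker and counted. Negative ADC values — possible when
#' noise pushes the high-b signal above the low-b signal — are retained
#' and flagged rather than clipped, so that downstream difference
#' statistics are not biased.
#'
#' @param pair A [dw_pair()].
#' @return A list of class `adc_map` with elements `vol` (an
#'   [image_volume()], modality `"ADC"`, units `"1e-3 mm^2/s"`),
#'   `b1_used`, `b2_used`, `invalid_count`, and `negative_count`.
#' @export
compute_adc <- function(pair) {
  stopifnot(inherits(pair, "dw_pair"))
  s1 <- pair$low_b$data
  s2 <- pair$high_b$data
  bad <- is.na(s1) | is.na(s2) | s1 <= 0 | s2 <= 0
  adc <- array(invalid_value(), dim = dim(s1))
  ok <- !bad
  # log(S1/S2)/(b2-b1) is in mm^2/s; scale to the conventional 1e-3 mm^2/s
  adc[ok] <- log(s1[ok] / s2[ok]) / (pair$b2 - pair$b1) * 1e3
  vol <- image_volume(adc, spacing = pair$low_b$spacing,
                      origin = pair$low_b$origin,
                      orientation = pair$low_b$orientation,
                      modality = "ADC", units = "1e-3 mm^2/s")
  structure(list(vol = vol, b1_used = pair$b1, b2_used = pair$b2,
                 invalid_count = sum(bad),
                 negative_count = sum(adc[ok] < 0)),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("<adc_map> b = (%g, %g) s/mm^2; %d invalid, %d negative voxels\n",
              x$b1_used, x$b2_used, x$invalid_count, x$negative_count))
  print(x$vol)
  invisible(x)
}

#' Reference regions for Hounsfield calibration
#'
#' @param water_roi,air_roi [voi_mask()] objects on the raw CT grid marking
#'   a water(-equivalent) phantom region and a surrounding-air region.
#' @return An object of class `calibration_pair`.
#' @export
calibration_pair <- function(water_roi, air_roi) {
  stopifnot(inherits(water_roi, "voi_mask"), inherits(air_roi, "voi_mask"))
  if (sum(water_roi$data) == 0L || sum(air_roi$data) == 0L)
    stop("calibration_pair: both reference ROIs must be non-empty", call. = FALSE)
  structure(list(water_roi = water_roi, air_roi = air_roi),
            class = "calibration_pair")
}

#' Calibrate raw CT attenuation to Hounsfield units
#'
#' Fits the affine map sending the mean raw value over the water ROI to
#' 0 HU and the mean over the air ROI to -1000 HU (the linear definition of
#' the Hounsfield scale) and applies it voxel-wise.
#'
#' @param raw An [image_volume()] of modality `"CT_RAW"`.
#' @param cal A [calibration_pair()] on the raw grid.
#' @return An [image_volume()] of modality `"HU"`, units `"HU"`.
#' @export
calibrate_hu <- function(raw, cal) {
  stopifnot(inherits(raw, "image_volume"), inherits(cal, "calibration_pair"))
  if (raw$modality != "CT_RAW")
    stop("calibrate_hu: input modality must be CT_RAW, got ", raw$modality,
         call. = FALSE)
  for (roi in list(cal$water_roi, cal$air_roi))
    if (!all(dim(roi$data) == dim(raw$data)))
      stop("calibrate_hu: ROI dimensions do not match the raw volume", call. = FALSE)
  m_w <- mean(raw$data[cal$water_roi$data], na.rm = TRUE)
  m_a <- mean(raw$data[cal$air_roi$data], na.rm = TRUE)
  if (!is.finite(m_w) || !is.finite(m_a) || isTRUE(all.equal(m_w, m_a)))
    stop("calibrate_hu: water and air ROI means coincide (", m_w,
         "); cannot fit the linear scale", call. = FALSE)
  # slope/intercept solving  a*m_w + b = 0,  a*m_a + b = -1000
  a <- 1000 / (m_w - m_a)
  b <- -a * m_w
  image_volume(a * raw$data + b, spacing = raw$spacing, origin = raw$origin,
               orientation = raw$orientation, modality = "HU", units = "HU")
}
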