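#' @keywords internal
"_PACKAGE"

# Recognized modality tags for an image volume.
MODALITIES <- c("DW", "ADC", "CT_RAW", "HU")

# Relative tolerance for deciding that two grids are "the same". NIfTI
# headers store the affine in float32, so exact equality is unattainable
# after a round trip through disk.
GRID_TOL <- 1e-4

#' Sentinel for invalid or missing voxels
#'
#' Invalid voxels (masked-out, out-of-field after resampling, undefined ADC)
#' are marked with IEEE NaN. Every summary in the package excludes these
#' voxels from both numerator and denominator and reports the excluded
#' count. Test for invalidity with [is.na()], which is `TRUE` for `NaN`.
#'
#' @return The scalar sentinel value (`NaN`).
#' @export
invalid_value <- function() NaN

#' Construct an image volume
#'
#' A 3D scalar lattice with physical grid metadata. World coordinates follow
#' the NIfTI affine convention:
#' `world = orientation %*% diag(spacing) %*% index + origin`
#' with 0-based voxel indices.
#'
#' @param data 3D numeric array. May contain `NaN` invalid markers but no
#'   infinities.
#' @param spacing Numeric length-3, voxel size per axis in mm (all > 0).
#' @param origin Numeric length-3, world position of voxel (0,0,0) in mm.
#' @param orientation 3x3 direction matrix; must be orthonormal to within
#'   `1e-6`.
#' @param modality One of `"DW"`, `"ADC"`, `"CT_RAW"`, `"HU"`.
#' @param units Free-text unit label, e.g. `"1e-3 mm^2/s"` or `"HU"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = diag(3), modality = "ADC",
                         units = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("image_volume: 'data' must be a 3D array, got ",
         paste(dim(data), collapse = "x"), call. = FALSE)
  storage.mode(data) <- "double"
  if (any(is.infinite(data)))
    stop("image_volume: data contains infinities; use invalid_value() for missing voxels",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: spacing must be 3 positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image_volume: origin must be 3 finite values", call. = FALSE)
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("image_volume: orientation must be a 3x3 orthonormal matrix", call. = FALSE)
  modality <- match.arg(modality, MODALITIES)
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = orientation, modality = modality,
                 units = units),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s [%s]\n", x$modality, x$units))
  cat(sprintf("  dims: %s  spacing: %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x ")))
  v <- x$data[!is.na(x$data)]
  cat(sprintf("  valid voxels: %d/%d  range: [%.4g, %.4g]\n",
              length(v), length(x$data),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Construct a binary volume-of-interest mask
#'
#' @param data 3D logical (or 0/1 numeric) array on the reference grid.
#' @param reference Identifier of the grid the mask indexes (free text),
#'   or an `image_volume` whose dimensions the mask must match.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(data, reference = "baseline") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("voi_mask: 'data' must be a 3D array", call. = FALSE)
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      stop("voi_mask: numeric mask values must be 0 or 1", call. = FALSE)
    data <- array(data != 0, dim = dim(data))
  }
  if (!is.logical(data))
    stop("voi_mask: mask must be logical or 0/1 numeric", call. = FALSE)
  ref_id <- reference
  if (inherits(reference, "image_volume")) {
    if (!all(dim(data) == dim(reference$data)))
      stop("voi_mask: mask dimensions ", paste(dim(data), collapse = "x"),
           " do not match reference grid ",
           paste(dim(reference$data), collapse = "x"), call. = FALSE)
    ref_id <- reference$modality
  }
  structure(list(data = data, reference = ref_id), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %d/%d voxels true (ref: %s)\n",
              sum(x$data), length(x$data), x$reference))
  invisible(x)
}

#' Do two volumes share a grid?
#'
#' Grids are shared when dimensions match exactly and spacing, origin and
#' orientation agree within a relative tolerance (default `1e-4`, absorbing
#' float32 header round-off).
#'
#' @param a,b `image_volume` objects.
#' @param tol Relative tolerance.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = GRID_TOL) {
  stopifnot(inherits(a, "image_volume"), inherits(b, "image_volume"))
  if (!all(dim(a$data) == dim(b$data))) return(FALSE)
  rel <- function(x, y) max(abs(x - y)) <= tol * max(1, max(abs(x)), max(abs(y)))
  rel(a$spacing, b$spacing) && rel(a$origin, b$origin) &&
    rel(a$orientation, b$orientation)
}

# 4x4 affine mapping 0-based voxel indices to world mm.
grid_affine <- function(vol) {
  aff <- diag(4)
  aff[1:3, 1:3] <- vol$orientation %*% diag(vol$spacing)
  aff[1:3, 4] <- vol$origin
  aff
}

# idx: n x 3 matrix of 0-based (possibly fractional) voxel indices.
index_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(idx %*% t(vol$orientation %*% diag(vol$spacing)), 2L, vol$origin, "+")
}

# pts: n x 3 matrix of world coordinates in mm -> 0-based fractional indices.
world_to_index <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  m <- solve(vol$orientation %*% diag(vol$spacing))
  sweep(pts, 2L, vol$origin, "-") %*% t(m)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D scalar NIfTI-1 file, taking the grid (spacing, origin,
#' orientation) from the header affine and attaching the caller-supplied
#' modality and units. Voxel data are not rescaled or otherwise touched.
#'
#' @param path Path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param modality Modality tag to attach (see [image_volume()]).
#' @param units Unit label to attach.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = "ADC", units = "") {
  if (!file.exists(path))
    stop("read_volume: file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_volume: unreadable NIfTI file '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop("read_volume: '", path, "' declares ", length(d),
         "D data (dim field); expected a 3D volume", call. = FALSE)
  aff <- RNifti::xform(img)
  lin <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("read_volume: non-finite or non-positive spacing in header (pixdim/srow) of '",
         path, "'", call. = FALSE)
  orientation <- sweep(lin, 2L, spacing, "/")
  image_volume(array(as.numeric(img), dim = d), spacing = spacing,
               origin = aff[1:3, 4], orientation = orientation,
               modality = modality, units = units)
}

#' Write a volume to NIfTI-1
#'
#' Writes float64 voxel data (bit-exact on re-read, `NaN` invalid markers
#' preserved) with the grid stored in the sform affine. The unit label is
#' recorded in the header `descrip` field.
#'
#' @param vol An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  if (!dir.exists(dirname(path)))
    stop("write_volume: directory does not exist: ", dirname(path), call. = FALSE)
  img <- RNifti::asNifti(vol$data, pixdim = vol$spacing)
  aff <- grid_affine(vol)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  hdr <- RNifti::niftiHeader(img)
  hdr$descrip <- paste0(vol$modality, ";", vol$units)
  img <- RNifti::updateNifti(img, hdr)
  tryCatch(RNifti::writeNifti(img, path, datatype = "double"),
           error = function(e) stop("write_volume: failed to write '", path,
                                    "': ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Write a VOI mask to NIfTI-1 (values 0/1)
#'
#' @param mask A [voi_mask()].
#' @param grid The `image_volume` supplying grid metadata.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, grid, path) {
  stopifnot(inherits(mask, "voi_mask"), inherits(grid, "image_volume"))
  vol <- image_volume(array(as.numeric(mask$data), dim = dim(mask$data)),
                      spacing = grid$spacing, origin = grid$origin,
                      orientation = grid$orientation, modality = grid$modality,
                      units = "binary")
  write_volume(vol, path)
}

#' Read a VOI mask from NIfTI-1
#'
#' @param path Path to a NIfTI mask with values 0/1.
#' @param reference Reference-grid identifier or `image_volume`.
#' @return A [voi_mask()].
#' @export
read_mask <- function(path, reference = "baseline") {
  vol <- read_volume(path, modality = "ADC", units = "binary")
  voi_mask(vol$data, reference = reference)
}

#' Physical volume of a VOI
#'
#' The count of true mask voxels times the voxel volume, in cm^3 (the scale
#' on which the >= 4 cm^3 lesion-inclusion rule operates).
#'
#' @param mask A [voi_mask()].
#' @param grid The `image_volume` the mask indexes.
#' @return Volume in cm^3.
#' @export
voi_volume <- function(mask, grid) {
  stopifnot(inherits(mask, "voi_mask"), inherits(grid, "image_volume"))
  if (!all(dim(mask$data) == dim(grid$data)))
    stop("voi_volume: mask and grid dimensions differ", call. = FALSE)
  n <- sum(mask$data)
  if (n == 0L) {
    warning("voi_volume: empty mask; volume is 0")
    return(0)
  }
  n * prod(grid$spacing) / 1000
}

#' Construct a paired two-b-value diffusion acquisition
#'
#' @param low_b,high_b `image_volume` objects (modality `"DW"`) sharing one
#'   grid.
#' @param b1,b2 Diffusion weightings in s/mm^2 with `b2 > b1 >= 0`.
#' @return An object of class `dw_pair`.
#' @export
dw_pair <- function(low_b, high_b, b1 = 120, b2 = 1200) {
  stopifnot(inherits(low_b, "image_volume"), inherits(high_b, "image_volume"))
  if (!(b2 > b1 && b1 >= 0))
    stop("dw_pair: need b2 > b1 >= 0 (got b1=", b1, ", b2=", b2, ")",
         call. = FALSE)
  if (!same_grid(low_b, high_b))
    stop("dw_pair: low_b and high_b do not share a grid", call. = FALSE)
  structure(list(low_b = low_b, high_b = high_b, b1 = b1, b2 = b2),
            class = "dw_pair")
}
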