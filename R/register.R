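# Longitudinal co-registration: rigid alignment by mutual information (CT),
# thin-plate-spline landmark warping (MRI), and resampling of the follow-up
# onto the baseline grid. All transforms map baseline-world coordinates to
# follow-up-world coordinates; classification always happens on the baseline
# grid, with the follow-up as the moving image.

euler_to_matrix <- function(rot) {
  a <- rot[1]; b <- rot[2]; c <- rot[3]          # about x, y, z
  rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

matrix_to_euler <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  c <- atan2(R[2, 1], R[1, 1])
  c(a, b, c)
}

#' Construct a 6-DOF rigid transform
#'
#' Maps a world point p to `R (p - center) + center + translation`, where
#' `R = Rz %*% Ry %*% Rx` from the three Euler angles.
#'
#' @param rotation Length-3, rotation angles about x, y, z in radians.
#' @param translation Length-3 offsets in mm.
#' @param center Length-3 rotation center in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3L, length(translation) == 3L,
            length(center) == 3L)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %s  trans (mm): %s\n",
              paste(signif(x$rotation * 180 / pi, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

#' Apply a spatial transform to world points
#'
#' @param transform A `rigid_transform`, `tps_warp`, or `NULL` (identity).
#' @param pts n x 3 matrix of world coordinates, mm.
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  if (is.null(transform)) return(pts)
  UseMethod("transform_points")
}

#' @export
transform_points.rigid_transform <- function(transform, pts) {
  R <- euler_to_matrix(transform$rotation)
  ctr <- transform$center
  sweep(sweep(pts, 2L, ctr, "-") %*% t(R), 2L,
        ctr + transform$translation, "+")
}

#' Invert a rigid transform
#'
#' Composition with the inverse is the identity to within 1e-6 in
#' parameter space.
#'
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform` (same center).
#' @export
invert_rigid <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  R <- euler_to_matrix(transform$rotation)
  rigid_transform(rotation = matrix_to_euler(t(R)),
                  translation = as.numeric(-t(R) %*% transform$translation),
                  center = transform$center)
}

# Trilinear interpolation of a 3D array at 0-based fractional indices
# (n x 3). Out-of-bounds samples return NaN. Fractional offsets below
# `snap` are rounded so that integer-index sampling is bit-exact.
interp_trilinear <- function(arr, idx, snap = 1e-9) {
  d <- dim(arr)
  n <- nrow(idx)
  i0 <- floor(idx)
  f <- idx - i0
  hi <- f > 1 - snap
  i0[hi] <- i0[hi] + 1
  f[hi] <- 0
  f[f < snap] <- 0
  out <- rep(invalid_value(), n)
  inb <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    (i0[, 1] + (f[, 1] > 0)) <= d[1] - 1 &
    (i0[, 2] + (f[, 2] > 0)) <= d[2] - 1 &
    (i0[, 3] + (f[, 3] > 0)) <= d[3] - 1
  if (!any(inb)) return(out)
  i0 <- i0[inb, , drop = FALSE]
  f <- f[inb, , drop = FALSE]
  ix <- i0[, 1]; iy <- i0[, 2]; iz <- i0[, 3]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  dx <- as.integer(fx > 0); dy <- as.integer(fy > 0); dz <- as.integer(fz > 0)
  lin <- function(x, y, z) arr[1 + x + d[1] * (y + d[2] * z)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * lin(ix, iy, iz)
  if (any(dx > 0)) v <- v + fx * (1 - fy) * (1 - fz) * lin(ix + dx, iy, iz)
  if (any(dy > 0)) v <- v + (1 - fx) * fy * (1 - fz) * lin(ix, iy + dy, iz)
  if (any(dz > 0)) v <- v + (1 - fx) * (1 - fy) * fz * lin(ix, iy, iz + dz)
  if (any(dx > 0 & dy > 0)) v <- v + fx * fy * (1 - fz) * lin(ix + dx, iy + dy, iz)
  if (any(dx > 0 & dz > 0)) v <- v + fx * (1 - fy) * fz * lin(ix + dx, iy, iz + dz)
  if (any(dy > 0 & dz > 0)) v <- v + (1 - fx) * fy * fz * lin(ix, iy + dy, iz + dz)
  if (any(dx > 0 & dy > 0 & dz > 0)) v <- v + fx * fy * fz * lin(ix + dx, iy + dy, iz + dz)
  out[inb] <- v
  out
}

# Mutual information (nats) of two paired samples from a joint histogram
# with nbins x nbins linear bins between each sample's supplied range.
mutual_information <- function(u, v, range_u, range_v, nbins = 32L) {
  ok <- !is.na(u) & !is.na(v)
  u <- u[ok]; v <- v[ok]
  if (length(u) < 2L) return(-Inf)
  bin <- function(x, r) {
    b <- floor((x - r[1]) / (r[2] - r[1]) * nbins)
    pmin(pmax(b, 0), nbins - 1L)
  }
  joint <- tabulate(1L + bin(u, range_u) + nbins * bin(v, range_v),
                    nbins = nbins * nbins)
  p <- joint / sum(joint)
  pm <- matrix(p, nbins, nbins)
  px <- rowSums(pm); py <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / outer(px, py)[nz]))
}

# Robust intensity range: 1st-99th percentile, widened if degenerate.
robust_range <- function(x) {
  r <- stats::quantile(x[!is.na(x)], c(0.01, 0.99), names = FALSE)
  if (r[2] <= r[1]) r <- r + c(-0.5, 0.5)
  r
}

#' Rigid registration by mutual-information maximization
#'
#' Automated iterative 6-DOF alignment of a moving volume onto a fixed
#' volume using mutual information estimated from a 32x32-bin joint
#' intensity histogram over the overlap region (intensities binned between
#' each image's 1st and 99th percentiles). Optimization is derivative-free
#' (Nelder-Mead simplex): a translation-only stage from a fixed set of
#' multi-start perturbations, then a full 6-parameter refinement. The seed
#' fixes only the order in which starts are visited, so results are
#' deterministic given the seed.
#'
#' @param fixed,moving [image_volume()] objects; both need at least two
#'   distinct intensity levels.
#' @param seed Integer controlling multi-start ordering.
#' @param nbins Joint-histogram bins per axis.
#' @param maxit Simplex iteration cap per stage.
#' @return A [rigid_transform()] mapping fixed-world to moving-world
#'   coordinates, with attributes `mi` (final mutual information) and
#'   `mi_identity`.
#' @export
register_rigid_mi <- function(fixed, moving, seed = 1L, nbins = 32L,
                              maxit = 600L) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  for (v in list(fixed, moving)) {
    vals <- v$data[!is.na(v$data)]
    if (length(unique(vals)) < 2L)
      stop("register_rigid_mi: degenerate (constant) image; mutual information is undefined",
           call. = FALSE)
  }
  d <- dim(fixed$data)
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  pts <- index_to_world(fixed, idx)
  uf <- as.numeric(fixed$data)
  ru <- robust_range(uf)
  rv <- robust_range(moving$data)
  ctr <- index_to_world(fixed, matrix((d - 1) / 2, 1))[1, ]
  rot_scale <- 10 * pi / 180    # one scaled unit = 10 degrees
  tr_scale <- 10                # one scaled unit = 10 mm

  neg_mi <- function(par6) {
    tf <- rigid_transform(par6[1:3] * rot_scale, par6[4:6] * tr_scale, ctr)
    s <- interp_trilinear(moving$data, world_to_index(moving,
                                                      transform_points(tf, pts)))
    -mutual_information(uf, s, ru, rv, nbins)
  }
  mi_identity <- -neg_mi(rep(0, 6))

  starts <- list(c(0, 0, 0), c(0.5, 0.5, 0.5), c(-0.5, -0.5, -0.5),
                 c(0.5, -0.5, 0))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  ord <- sample.int(length(starts))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  # stage 1: alternate a multi-start translation-only search with a coarse
  # rotation sweep; either parameter block far from identity can trap a
  # joint search started at the origin
  rot_grid <- as.matrix(expand.grid(r1 = c(-0.8, 0, 0.8), r2 = c(-0.8, 0, 0.8),
                                    r3 = c(-0.8, 0, 0.8)))
  best_r <- c(0, 0, 0); best_t <- c(0, 0, 0); best_val <- neg_mi(rep(0, 6))
  tr_grid <- as.matrix(expand.grid(t1 = c(-0.8, 0, 0.8), t2 = c(-0.8, 0, 0.8),
                                   t3 = c(-0.8, 0, 0.8)))
  for (pass in 1:2) {
    base_t <- best_t
    for (k in seq_len(nrow(tr_grid))) {
      val <- neg_mi(c(best_r, base_t + tr_grid[k, ]))
      if (val < best_val) { best_val <- val; best_t <- base_t + tr_grid[k, ] }
    }
    for (k in ord) {
      o <- stats::optim(best_t + starts[[k]],
                        function(t3) neg_mi(c(best_r, t3)),
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-9))
      if (o$value < best_val) { best_val <- o$value; best_t <- o$par }
    }
    for (k in seq_len(nrow(rot_grid))) {
      val <- neg_mi(c(rot_grid[k, ], best_t))
      if (val < best_val) { best_val <- val; best_r <- rot_grid[k, ] }
    }
  }
  # stage 2: full 6-DOF, with one restart to re-expand the simplex
  par <- c(best_r, best_t)
  conv <- 1L
  for (pass in 1:3) {
    o <- stats::optim(par, neg_mi, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
    par <- o$par; conv <- o$convergence
  }
  mi_final <- -neg_mi(par)
  tf <- rigid_transform(par[1:3] * rot_scale, par[4:6] * tr_scale, ctr)
  if (mi_final < mi_identity) {      # optimizer must never worsen the objective
    tf <- rigid_transform(c(0, 0, 0), c(0, 0, 0), ctr)
    mi_final <- mi_identity
    conv <- 0L
  }
  if (conv != 0L) {
    cond <- structure(class = c("prmap_registration_error", "error", "condition"),
                      message = sprintf(
                        "register_rigid_mi: simplex did not converge (final MI %.4f); best transform attached",
                        mi_final),
                      call = NULL, transform = tf, mi = mi_final)
    stop(cond)
  }
  attr(tf, "mi") <- mi_final
  attr(tf, "mi_identity") <- mi_identity
  tf
}

#' Fit an exact 3D thin-plate-spline warp to landmark pairs
#'
#' Standard thin-plate-spline interpolant in three dimensions with radial
#' kernel `U(r) = r` and a full affine part. The warp maps each source
#' landmark exactly onto its target (interpolation, not smoothing).
#'
#' @param source_landmarks,target_landmarks n x 3 matrices of paired world
#'   points (mm); n >= 4, sources not coplanar.
#' @return An object of class `tps_warp` with the landmark sets, the
#'   per-landmark kernel weights and the affine coefficients.
#' @export
fit_tps <- function(source_landmarks, target_landmarks) {
  src <- matrix(as.numeric(source_landmarks), ncol = 3L)
  tgt <- matrix(as.numeric(target_landmarks), ncol = 3L)
  n <- nrow(src)
  if (nrow(tgt) != n)
    stop("fit_tps: source and target landmark counts differ", call. = FALSE)
  if (n < 4L)
    stop("fit_tps: at least 4 landmark pairs are required (got ", n, ")",
         call. = FALSE)
  K <- as.matrix(stats::dist(src))
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(tgt, matrix(0, 4, 3))
  sol <- tryCatch({
    x <- solve(L, rhs)
    x + solve(L, rhs - L %*% x)      # one step of iterative refinement
  }, error = function(e)
    stop("fit_tps: singular landmark system (coplanar or duplicate source points)",
         call. = FALSE))
  if (any(!is.finite(sol)))
    stop("fit_tps: singular landmark system (coplanar or duplicate source points)",
         call. = FALSE)
  dimnames(sol) <- NULL
  structure(list(source_landmarks = src, target_landmarks = tgt,
                 weights = sol[1:n, , drop = FALSE],
                 affine = sol[(n + 1):(n + 4), , drop = FALSE]),
            class = "tps_warp")
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("<tps_warp> %d landmark pairs; max |weight| = %.3g\n",
              nrow(x$source_landmarks), max(abs(x$weights))))
  invisible(x)
}

#' @export
transform_points.tps_warp <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  src <- transform$source_landmarks
  # distances computed per landmark by explicit subtraction: the expanded
  # |x|^2+|p|^2-2xp form cancels catastrophically near the landmarks and
  # would break the exact-interpolation guarantee
  U <- matrix(0, nrow(pts), nrow(src))
  for (k in seq_len(nrow(src)))
    U[, k] <- sqrt((pts[, 1] - src[k, 1])^2 + (pts[, 2] - src[k, 2])^2 +
                     (pts[, 3] - src[k, 3])^2)
  cbind(1, pts) %*% transform$affine + U %*% transform$weights
}

#' Resample a follow-up volume onto the baseline grid
#'
#' Pulls each baseline voxel center back through the transform (which maps
#' baseline-world to follow-up-world coordinates) and interpolates the
#' follow-up trilinearly. Voxels whose pull-back falls outside the
#' follow-up field of view are set invalid and excluded via the overlap
#' mask. Integer-voxel shifts on a shared grid reproduce the shifted
#' originals exactly (no interpolation blur).
#'
#' @param baseline The fixed [image_volume()] defining the output grid.
#' @param followup The moving [image_volume()].
#' @param transform A [rigid_transform()], [fit_tps()] warp, or `NULL` for
#'   identity.
#' @return An object of class `registered_pair` with `baseline_map`,
#'   `followup_resampled`, `overlap_mask` ([voi_mask()]) and `transform`.
#' @export
resample_to_baseline <- function(baseline, followup, transform = NULL) {
  stopifnot(inherits(baseline, "image_volume"),
            inherits(followup, "image_volume"))
  d <- dim(baseline$data)
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  pts <- transform_points(transform, index_to_world(baseline, idx))
  vals <- interp_trilinear(followup$data, world_to_index(followup, pts))
  res <- array(vals, dim = d)
  overlap <- array(!is.na(vals), dim = d)
  fu <- image_volume(res, spacing = baseline$spacing, origin = baseline$origin,
                     orientation = baseline$orientation,
                     modality = followup$modality, units = followup$units)
  structure(list(baseline_map = baseline, followup_resampled = fu,
                 overlap_mask = voi_mask(overlap, reference = "baseline"),
                 transform = transform),
            class = "registered_pair")
}

#' Read landmark correspondences from CSV
#'
#' Expected columns: `x_src,y_src,z_src,x_tgt,y_tgt,z_tgt` in world mm.
#'
#' @param path CSV path.
#' @return List with `source` and `target` n x 3 matrices.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_src", "y_src", "z_src", "x_tgt", "y_tgt", "z_tgt")
  if (!all(need %in% names(df)))
    stop("read_landmarks: CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  list(source = as.matrix(df[, need[1:3]]),
       target = as.matrix(df[, need[4:6]]))
}

#' Serialize a transform to a plain-text key-value file
#'
#' @param transform A `rigid_transform` or `tps_warp`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_transform <- function(transform, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- if (inherits(transform, "rigid_transform")) {
    c("type: rigid",
      paste0("rotation: ", num(transform$rotation)),
      paste0("translation: ", num(transform$translation)),
      paste0("center: ", num(transform$center)))
  } else if (inherits(transform, "tps_warp")) {
    c("type: tps",
      paste0("n: ", nrow(transform$source_landmarks)),
      paste0("source: ", num(t(transform$source_landmarks))),
      paste0("target: ", num(t(transform$target_landmarks))))
  } else stop("write_transform: unsupported transform class", call. = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a transform written by [write_transform()]
#'
#' @param path Path to the key-value text file.
#' @return A `rigid_transform` or `tps_warp` (TPS warps are re-fit from the
#'   stored landmarks).
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) x[2]),
                          vapply(kv, function(x) x[1], ""))
  nums <- function(k) as.numeric(strsplit(vals[[k]], " +")[[1]])
  if (vals$type == "rigid") {
    rigid_transform(nums("rotation"), nums("translation"), nums("center"))
  } else if (vals$type == "tps") {
    n <- as.integer(vals$n)
    fit_tps(matrix(nums("source"), n, 3, byrow = TRUE),
            matrix(nums("target"), n, 3, byrow = TRUE))
  } else stop("read_transform: unknown transform type '", vals$type, "'",
              call. = FALSE)
}
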