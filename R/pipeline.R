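# Config-driven end-to-end runs: calibrate -> register -> classify ->
# summarize, with a run log recording every effective parameter and the
# voxel accounting after each masking step. Configs are plain-text YAML so
# a committed config plus a seed reproduces a run byte-for-byte.

#' Load a run configuration
#'
#' @param path YAML file; see [validate_config()] for the schema.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("read_run_config: file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

config_defaults <- list(
  modality = NULL, baseline = NULL, followup = NULL, followup_days = NULL,
  voi = NULL, registration = "none", landmarks = NULL,
  threshold = NULL, baseline_convention = "pretreatment",
  output_dir = NULL, seed = 1L, overlays = FALSE, overlay_axis = 3L)

# modality tag recorded by write_volume in the NIfTI descrip field, or NA
descrip_modality <- function(path) {
  hdr <- tryCatch(RNifti::niftiHeader(RNifti::readNifti(path)),
                  error = function(e) NULL)
  if (is.null(hdr)) return(NA_character_)
  tag <- strsplit(hdr$descrip, ";", fixed = TRUE)[[1]][1]
  if (length(tag) == 1L && tag %in% MODALITIES) tag else NA_character_
}

#' Validate a run configuration
#'
#' Checks the schema: `modality` (ADC or HU), `baseline`, `followup` (one
#' path or a list with matching `followup_days`), `voi`, `registration`
#' (none / rigid / tps, with `landmarks` required for tps), `threshold`
#' (either `source: fixed` with `value`, or `source: testretest` with
#' `test`/`retest` paths), `baseline_convention` (pretreatment or
#' implantation), `output_dir`, `seed`. Referenced files must exist, and a
#' declared modality must not contradict the modality tag recorded in an
#' input volume's header.
#'
#' @param config A `run_config` or plain named list.
#' @return Character vector of problems, each naming the offending key;
#'   empty when the configuration is runnable.
#' @export
validate_config <- function(config) {
  cfg <- utils::modifyList(config_defaults, as.list(config))
  p <- character(0)
  say <- function(...) p <<- c(p, sprintf(...))
  if (is.null(cfg$modality) || !cfg$modality %in% c("ADC", "HU"))
    say("modality: must be 'ADC' or 'HU'")
  need_file <- function(key, path) {
    if (is.null(path)) { say("%s: missing required path", key); return(FALSE) }
    if (!file.exists(path)) { say("%s: file not found: %s", key, path); return(FALSE) }
    TRUE
  }
  check_modality <- function(key, path) {
    if (is.null(cfg$modality) || !cfg$modality %in% c("ADC", "HU")) return()
    tag <- descrip_modality(path)
    if (is.na(tag)) return()
    compatible <- if (cfg$modality == "ADC") c("ADC", "DW") else c("HU", "CT_RAW")
    if (!tag %in% compatible)
      say("%s: volume is tagged %s but config modality is %s", key, tag,
          cfg$modality)
  }
  if (need_file("baseline", cfg$baseline)) check_modality("baseline", cfg$baseline)
  fu <- cfg$followup
  if (is.null(fu)) say("followup: missing required path(s)") else {
    fu <- unlist(fu)
    for (i in seq_along(fu))
      if (need_file(sprintf("followup[%d]", i), fu[i]))
        check_modality(sprintf("followup[%d]", i), fu[i])
    if (length(fu) > 1L) {
      if (is.null(cfg$followup_days) ||
          length(unlist(cfg$followup_days)) != length(fu))
        say("followup_days: must list one day per follow-up volume")
      else if (anyDuplicated(unlist(cfg$followup_days)) ||
               is.unsorted(unlist(cfg$followup_days), strictly = TRUE))
        say("followup_days: days must be strictly increasing and unique")
    }
  }
  need_file("voi", cfg$voi)
  if (!cfg$registration %in% c("none", "rigid", "tps"))
    say("registration: must be none, rigid or tps")
  if (identical(cfg$registration, "tps")) need_file("landmarks", cfg$landmarks)
  th <- cfg$threshold
  if (is.null(th$source) || !th$source %in% c("fixed", "testretest")) {
    say("threshold.source: must be 'fixed' or 'testretest'")
  } else if (th$source == "fixed") {
    if (is.null(th$value) || !is.numeric(th$value) || th$value < 0)
      say("threshold.value: fixed threshold needs a numeric half-width >= 0")
  } else {
    need_file("threshold.test", th$test)
    need_file("threshold.retest", th$retest)
  }
  if (!cfg$baseline_convention %in% c("pretreatment", "implantation"))
    say("baseline_convention: must be pretreatment or implantation")
  if (is.null(cfg$output_dir)) say("output_dir: missing")
  p
}

#' Run the PRM pipeline end to end
#'
#' Executes calibrate -> register -> classify -> summarize for one lesion
#' per the configuration, writing under `output_dir`: `summary.csv` (one
#' row per follow-up day), per-day label NIfTIs and scatter CSVs, optional
#' overlay PNGs, the serialized transform(s), and `run.log` recording
#' every effective parameter and voxel count. Deterministic for a fixed
#' config and seed.
#'
#' @param config A `run_config`, plain list, or path to a YAML file.
#' @return List of class `run_result` with `status` (0 on success),
#'   `summary` (data frame), `threshold`, and `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(config_defaults, as.list(config))
  problems <- validate_config(cfg)
  if (length(problems))
    stop("run_pipeline: invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run.log")
  logf <- file(log_path, open = "wt")
  on.exit(close(logf), add = TRUE)
  logline <- function(...) writeLines(sprintf(...), logf)
  stage <- "config"
  tryCatch({
    logline("prmap pipeline run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    for (k in setdiff(names(cfg), "threshold"))
      logline("param %s = %s", k, paste(unlist(cfg[[k]]), collapse = ", "))
    for (k in names(cfg$threshold))
      logline("param threshold.%s = %s", k, cfg$threshold[[k]])

    stage <- "load"
    modality <- cfg$modality
    baseline <- read_volume(cfg$baseline, modality = modality,
                            units = if (modality == "ADC") "1e-3 mm^2/s" else "HU")
    voi <- read_mask(cfg$voi, reference = "baseline")
    logline("load: baseline %s; VOI %d/%d voxels",
            paste(dim(baseline$data), collapse = "x"),
            sum(voi$data), length(voi$data))

    stage <- "calibrate"
    th <- cfg$threshold
    threshold <- if (th$source == "fixed") {
      prm_threshold(th$value, method = "fixed", modality = modality)
    } else {
      test <- read_volume(th$test, modality = modality)
      retest <- read_volume(th$retest, modality = modality)
      calibrate_threshold(test, retest, voi)
    }
    logline("calibrate: half_width = %.6g (%s, n = %d)",
            threshold$half_width, threshold$method, threshold$n_voxels)

    fu_paths <- unlist(cfg$followup)
    days <- if (is.null(cfg$followup_days)) seq_along(fu_paths)
            else unlist(cfg$followup_days)
    pairs <- vector("list", length(fu_paths))
    tf_paths <- character(0)
    for (i in seq_along(fu_paths)) {
      stage <- "register"
      followup <- read_volume(fu_paths[i], modality = modality)
      transform <- switch(cfg$registration,
        none = NULL,
        rigid = register_rigid_mi(baseline, followup, seed = cfg$seed),
        tps = {
          lm <- read_landmarks(cfg$landmarks)
          fit_tps(lm$source, lm$target)
        })
      if (!is.null(transform)) {
        tp <- file.path(cfg$output_dir, sprintf("transform_day%g.txt", days[i]))
        write_transform(transform, tp)
        tf_paths <- c(tf_paths, tp)
        if (inherits(transform, "rigid_transform"))
          logline("register day %g: rigid rot (rad) = %s, trans (mm) = %s, MI = %.4f",
                  days[i], paste(signif(transform$rotation, 6), collapse = ", "),
                  paste(signif(transform$translation, 6), collapse = ", "),
                  attr(transform, "mi"))
        else
          logline("register day %g: TPS with %d landmarks", days[i],
                  nrow(transform$source_landmarks))
      } else logline("register day %g: none (shared grid assumed)", days[i])
      pairs[[i]] <- resample_to_baseline(baseline, followup, transform)
      logline("resample day %g: overlap %d/%d voxels", days[i],
              sum(pairs[[i]]$overlap_mask$data), length(voi$data))
    }

    stage <- "classify"
    summary <- prm_timecourse(pairs, days, voi, threshold)
    for (i in seq_along(pairs)) {
      res <- classify(pairs[[i]], voi, threshold)
      write_labels(res, baseline,
                   file.path(cfg$output_dir, sprintf("labels_day%g.nii.gz", days[i])))
      export_scatter(res,
                     file.path(cfg$output_dir, sprintf("scatter_day%g.csv", days[i])))
      if (isTRUE(cfg$overlays))
        export_overlay(res, baseline, cfg$overlay_axis,
                       file.path(cfg$output_dir, sprintf("overlay_day%g", days[i])))
      logline("classify day %g: +%.4f%% / -%.4f%% / 0 %.4f%%; n_valid = %d, n_excluded = %d",
              days[i], res$frac_plus, res$frac_minus, res$frac_zero,
              res$n_valid, res$n_excluded)
    }
    stage <- "summarize"
    sum_path <- file.path(cfg$output_dir, "summary.csv")
    utils::write.csv(summary, sum_path, row.names = FALSE)
    logline("summarize: wrote %s (%d rows)", sum_path, nrow(summary))
    structure(list(status = 0L, summary = summary, threshold = threshold,
                   paths = list(summary = sum_path, log = log_path,
                                transforms = tf_paths,
                                output_dir = cfg$output_dir)),
              class = "run_result")
  }, error = function(e) {
    logline("ERROR in stage '%s': %s", stage, conditionMessage(e))
    stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> status %d; %d day(s); threshold +/- %.4g\n",
              x$status, nrow(x$summary), x$threshold$half_width))
  print(x$summary)
  invisible(x)
}
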