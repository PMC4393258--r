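# Trial-level analytics: PSA-based response calls, tumor growth-delay
# metrics, and group comparisons (mean +/- SEM, two-tailed t-test).

#' Construct a PSA time series
#'
#' @param times Weeks from treatment start, strictly increasing, first
#'   entry 0 (the baseline draw) or omitted if `baseline` is supplied.
#' @param values PSA in ng/ml, all >= 0, same length as `times`.
#' @param baseline Baseline PSA at week 0 in ng/ml; defaults to the value
#'   at the first time point if that time is 0.
#' @return An object of class `psa_series` with post-baseline measurements
#'   only in `times`/`values`.
#' @export
psa_series <- function(times, values, baseline = NULL) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("psa_series: times and values lengths differ", call. = FALSE)
  if (any(values < 0) || any(!is.finite(values)))
    stop("psa_series: PSA values must be finite and >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("psa_series: times must be strictly increasing", call. = FALSE)
  if (is.null(baseline)) {
    if (length(times) == 0L || times[1] != 0)
      stop("psa_series: supply 'baseline' or include a week-0 measurement",
           call. = FALSE)
    baseline <- values[1]
    times <- times[-1]; values <- values[-1]
  }
  structure(list(times = times, values = values,
                 baseline = as.numeric(baseline)),
            class = "psa_series")
}

# Earliest confirmation time of a per-measurement predicate: the qualifying
# measurement and a later one at >= window weeks must both satisfy it.
confirm_time <- function(times, qualifies, window) {
  for (i in which(qualifies)) {
    j <- which(qualifies & times >= times[i] + window)
    j <- j[j > i]
    if (length(j)) return(list(time = times[j[1]], indices = c(i, j[1])))
  }
  NULL
}

#' PSA-based clinical response call
#'
#' Applies the trial's post-therapy PSA criteria:
#' \itemize{
#'   \item CR: undetectable PSA (< 0.2 ng/ml) confirmed by another
#'     measurement < 0.2 at no less than `confirm_window_weeks` later.
#'   \item PR: a decrease of >= 50% from baseline, similarly confirmed.
#'   \item PD: a 25% increase over the lower of baseline and the nadir
#'     observed so far, together with an absolute increase of >= 5 ng/ml
#'     over that reference, similarly confirmed.
#'   \item SD: the residual category when none of the above fire.
#' }
#' When several rules confirm, the one whose confirmation completes first
#' wins (so appending later measurements never changes an already-confirmed
#' call); ties at the same confirmation time resolve CR > PR > PD.
#'
#' @param series A [psa_series()] with at least 2 post-baseline values.
#' @param confirm_window_weeks Minimum weeks between a qualifying and its
#'   confirming measurement ("no less than 4 weeks"); must be >= 4.
#' @param strict_pd_confirmation If `TRUE` (default) the confirming PD
#'   measurement must itself satisfy both PD criteria; if `FALSE` any later
#'   measurement confirms.
#' @return An object of class `response_call` with `call` (one of CR, PR,
#'   SD, PD) and `basis` (the rule that fired and the measurement indices).
#' @export
classify_psa_response <- function(series, confirm_window_weeks = 4,
                                  strict_pd_confirmation = TRUE) {
  stopifnot(inherits(series, "psa_series"))
  if (confirm_window_weeks < 4)
    stop("classify_psa_response: confirm_window_weeks must be >= 4", call. = FALSE)
  t <- series$times; v <- series$values; b <- series$baseline
  if (length(v) < 2L)
    stop("classify_psa_response: need at least 2 post-baseline measurements",
         call. = FALSE)

  cr <- confirm_time(t, v < 0.2, confirm_window_weeks)
  pr <- confirm_time(t, v <= 0.5 * b, confirm_window_weeks)

  # PD reference: min(baseline, nadir observed strictly before each value)
  nadir_before <- c(b, cummin(pmin(v, b)))[seq_along(v)]
  rises <- v >= 1.25 * nadir_before & (v - nadir_before) >= 5
  pd <- if (strict_pd_confirmation) {
    confirm_time(t, rises, confirm_window_weeks)
  } else {
    hit <- which(rises)
    out <- NULL
    for (i in hit) {
      j <- which(t >= t[i] + confirm_window_weeks)
      j <- j[j > i]
      if (length(j)) { out <- list(time = t[j[1]], indices = c(i, j[1])); break }
    }
    out
  }

  cand <- Filter(Negate(is.null),
                 list(CR = cr, PR = pr, PD = pd))
  if (length(cand) == 0L)
    return(structure(list(call = "SD",
                          basis = list(rule = "residual", indices = integer(0))),
                     class = "response_call"))
  ctimes <- vapply(cand, function(x) x$time, 0)
  # earliest confirmation wins; names(cand) is already in precedence order
  # CR > PR > PD, so which.min breaks ties correctly
  k <- which.min(ctimes)
  structure(list(call = names(cand)[k],
                 basis = list(rule = names(cand)[k],
                              indices = cand[[k]]$indices)),
            class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("<response_call> %s (rule %s; measurements %s)\n", x$call,
              x$basis$rule, paste(x$basis$indices, collapse = ",")))
  invisible(x)
}

#' Time to a percent-growth endpoint per subject
#'
#' For each subject's (day, volume) series starting at day 0, returns the
#' first day at which the volume reaches `(1 + threshold_pct/100)` times
#' the initial volume, linearly interpolating between scan days. Subjects
#' that never reach the endpoint are censored at their last scan day.
#'
#' @param volumes Data frame with columns `subject`, `day`, `volume` (any
#'   consistent volume unit); each subject must have a day-0 row with
#'   positive volume.
#' @param threshold_pct Percent increase defining the endpoint (the
#'   terminal endpoint in the growth studies is 400%, i.e. 5x initial).
#' @return Data frame with columns `subject`, `crossing_day`, `censored`
#'   (logical), `last_day`.
#' @export
growth_delay <- function(volumes, threshold_pct = 400) {
  need <- c("subject", "day", "volume")
  if (!all(need %in% names(volumes)))
    stop("growth_delay: need columns ", paste(need, collapse = ","), call. = FALSE)
  out <- lapply(split(volumes, volumes$subject), function(df) {
    df <- df[order(df$day), ]
    if (df$day[1] != 0 || df$volume[1] <= 0)
      stop("growth_delay: subject ", df$subject[1],
           " must start at day 0 with positive volume", call. = FALSE)
    target <- (1 + threshold_pct / 100) * df$volume[1]
    hit <- which(df$volume >= target)
    if (length(hit) == 0L)
      return(data.frame(subject = df$subject[1], crossing_day = NA_real_,
                        censored = TRUE, last_day = max(df$day)))
    k <- hit[1]
    day <- if (k == 1L) df$day[1] else {
      # linear interpolation between the bracketing scans
      df$day[k - 1] + (target - df$volume[k - 1]) /
        (df$volume[k] - df$volume[k - 1]) * (df$day[k] - df$day[k - 1])
    }
    data.frame(subject = df$subject[1], crossing_day = day,
               censored = FALSE, last_day = max(df$day))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare a metric between two groups
#'
#' Means, standard errors (`sd/sqrt(n)`) and a two-tailed two-sample
#' Student's t-test. The equal-variance test is the default, mirroring the
#' common spreadsheet convention; Welch's correction is available.
#'
#' @param a,b Numeric metric values per subject, each of length >= 2.
#' @param var_equal Pool the variances (classic Student's test)?
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `group_comparison`: per-group `n`, `mean`,
#'   `sem`, plus `p_value`, `t_statistic`, `df`, `significant`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("compare_groups: each group needs n >= 2", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = var_equal,
                      alternative = "two.sided")
  structure(list(groups = data.frame(
    group = c("a", "b"), n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sem = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b)))),
    p_value = tt$p.value, t_statistic = unname(tt$statistic),
    df = unname(tt$parameter), significant = tt$p.value < alpha),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  g <- x$groups
  cat(sprintf("<group_comparison> a: %.3g +/- %.3g (n=%d)  b: %.3g +/- %.3g (n=%d)\n",
              g$mean[1], g$sem[1], g$n[1], g$mean[2], g$sem[2], g$n[2]))
  cat(sprintf("  two-tailed t-test: t = %.3g, p = %.3g%s\n", x$t_statistic,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Read PSA series from CSV
#'
#' Expected columns: `patient_id`, `week`, `psa_ng_ml`; week 0 is the
#' baseline draw.
#'
#' @param path CSV path.
#' @return Named list of [psa_series()], one per patient.
#' @export
read_psa_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("patient_id", "week", "psa_ng_ml")
  if (!all(need %in% names(df)))
    stop("read_psa_csv: CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$week), ]
    psa_series(d$week, d$psa_ng_ml)
  })
}
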