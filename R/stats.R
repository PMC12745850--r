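#' Label the frames of a series against a schedule
#'
#' Adds `cycle`, `condition`, `interval` and `day_length_h` columns via
#' [label_time()]. Frames outside the schedule span are dropped.
#'
#' @param series A `frame_series`.
#' @param schedule A `lighting_schedule`.
#' @return The labelled series.
#' @export
label_frames <- function(series, schedule) {
  span <- schedule_span(schedule)
  keep <- series$timestamp_s >= span[1] & series$timestamp_s < span[2]
  series <- series[keep, , drop = FALSE]
  lab <- label_time(schedule, series$timestamp_s)
  series$cycle <- lab$cycle
  series$condition <- lab$condition
  series$interval <- lab$interval
  series$day_length_h <- lab$day_length_h
  series
}

#' Mean motion per cycle x day-condition x time-of-day cell
#'
#' Averages the motion of valid frames within each
#' (cycle, condition, interval) cell. The full grid is returned: a cell with
#' no valid frames is flagged `missing` with mean `NA`, never zero.
#'
#' @param series A labelled `frame_series` (see [label_frames()]), or an
#'   unlabelled one if `schedule` is supplied.
#' @param schedule Optional `lighting_schedule` used to label the series.
#' @return A `cell_table` tibble: `cycle`, `condition`, `interval`,
#'   `day_length_h`, `mean_motion`, `n_frames`, `missing`.
#' @export
cell_means <- function(series, schedule = NULL) {
  if (!is.null(schedule)) series <- label_frames(series, schedule)
  if (is.null(series$condition)) {
    stop_domain("Series has no labels; pass `schedule` or use label_frames().",
                "stats_error")
  }
  ok <- series$valid & is.finite(series$motion)
  agg <- dplyr::summarise(
    dplyr::group_by(series[ok, , drop = FALSE],
                    .data$cycle, .data$condition, .data$interval),
    mean_motion = mean(.data$motion),
    n_frames = dplyr::n(),
    .groups = "drop"
  )
  lens <- dplyr::distinct(series, .data$cycle, .data$day_length_h)
  grid <- tidyr::expand_grid(
    cycle = sort(unique(series$cycle)),
    condition = CONDITIONS,
    interval = INTERVALS
  )
  out <- dplyr::left_join(grid, agg, by = c("cycle", "condition", "interval"))
  out <- dplyr::left_join(out, lens, by = "cycle")
  out$n_frames[is.na(out$n_frames)] <- 0L
  out$missing <- out$n_frames == 0L
  out <- out[, c("cycle", "condition", "interval", "day_length_h",
                 "mean_motion", "n_frames", "missing")]
  class(out) <- c("cell_table", class(out))
  out
}

#' Pre-light anticipation statistic
#'
#' For each cycle, the difference between the pre-light motion preceding lit
#' days and the pre-light motion preceding the dark day:
#' `(Light1 + Light2)/2 - Dark`, all three terms being pre-light cell means.
#' Positive values mean the plants moved more in the hours before light was
#' due than before a day of continued darkness. A missing pre-light cell
#' propagates to a missing difference.
#'
#' @param cells A `cell_table`.
#' @param cycle Optional single cycle index; if given, the scalar difference
#'   for that cycle is returned.
#' @return A tibble `cycle`, `day_length_h`, `motion_diff` (or a scalar when
#'   `cycle` is supplied).
#' @export
motion_difference <- function(cells, cycle = NULL) {
  pre <- cells[cells$interval == "pre-light", , drop = FALSE]
  wide <- tidyr::pivot_wider(
    pre[, c("cycle", "day_length_h", "condition", "mean_motion")],
    names_from = "condition", values_from = "mean_motion"
  )
  for (cn in CONDITIONS) if (is.null(wide[[cn]])) wide[[cn]] <- NA_real_
  out <- tibble::tibble(
    cycle = wide$cycle,
    day_length_h = wide$day_length_h,
    motion_diff = (wide$Light1 + wide$Light2) / 2 - wide$Dark
  )
  out <- out[order(out$cycle), , drop = FALSE]
  if (!is.null(cycle)) {
    i <- match(cycle, out$cycle)
    if (is.na(i)) stop_domain("Cycle not present in the cell table.",
                              "stats_error")
    return(out$motion_diff[i])
  }
  out
}

#' Fit the logarithmic learning curve of the anticipation statistic
#'
#' Least-squares fit of `d_c = a * log(c) + b` over cycle indices `c >= 1`.
#' The natural logarithm is the default; the base only rescales the slope.
#' With a zero-variance response the slope is 0 and `r_squared` is reported
#' as `NA` (the usual 1 - SS_res/SS_tot form is undefined).
#'
#' @param differences A tibble from [motion_difference()] (columns `cycle`,
#'   `motion_diff`), or a numeric vector of differences.
#' @param cycles Cycle indices when `differences` is a bare vector.
#' @param log_base Base of the logarithm (default `exp(1)`).
#' @return A `learning_curve_fit` list: `a`, `b`, `r_squared`, `n_cycles`,
#'   `log_base`, `fitted`, `cycles`.
#' @examples
#' d <- 0.10 * log(1:23) - 0.18
#' fit_log_curve(d, 1:23)  # recovers a = 0.10, b = -0.18, r^2 = 1
#' @export
fit_log_curve <- function(differences, cycles = NULL, log_base = exp(1)) {
  if (is.data.frame(differences)) {
    cycles <- differences$cycle
    differences <- differences$motion_diff
  }
  ok <- is.finite(differences) & is.finite(cycles)
  d <- differences[ok]
  cyc <- cycles[ok]
  if (length(d) < 2L || length(unique(cyc)) < 2L) {
    stop_domain("Need differences at >= 2 distinct cycles.", "stats_error")
  }
  if (any(cyc < 1)) {
    stop_domain("Cycle indices must be >= 1.", "stats_error")
  }
  lx <- log(cyc, base = log_base)
  fit <- lm(d ~ lx)
  ss_tot <- sum((d - mean(d))^2)
  ss_res <- sum(fit$residuals^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(
    a = unname(coef(fit)[2]),
    b = unname(coef(fit)[1]),
    r_squared = r2,
    n_cycles = length(d),
    log_base = log_base,
    cycles = cyc,
    fitted = unname(fit$fitted.values)
  ), class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat(sprintf(
    "Learning-curve fit over %d cycles:\n  diff = %.4f * log(cycle) + %.4f   (log base %.4g, r^2 = %s)\n",
    x$n_cycles, x$a, x$b, x$log_base,
    if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared)
  ))
  invisible(x)
}

#' Partial eta-squared effect size
#'
#' `SS_effect / (SS_effect + SS_residual)`, the effect-size measure reported
#' alongside repeated-measures ANOVA tables.
#'
#' @param ss_effect Effect sum of squares (>= 0).
#' @param ss_residual Residual sum of squares of the matching error stratum.
#' @return Value in `[0, 1]`.
#' @examples
#' partial_eta_sq(0.1284, 0.4867)  # 0.209
#' @export
partial_eta_sq <- function(ss_effect, ss_residual) {
  if (any(ss_effect < 0) || any(ss_residual < 0)) {
    stop_domain("Sums of squares must be non-negative.", "stats_error")
  }
  if (any(ss_effect + ss_residual == 0)) {
    stop_domain("SS_effect and SS_residual cannot both be zero.",
                "stats_error")
  }
  ss_effect / (ss_effect + ss_residual)
}

#' Error degrees of freedom for a within-subject effect
#'
#' The repeated-measures convention `df_error = (n - 1) * df_factor`, where
#' `n` is the number of observational units entering the stratum.
#'
#' @param n_units Number of observational units.
#' @param df_factor Numerator degrees of freedom of the effect.
#' @return Error degrees of freedom.
#' @examples
#' rm_error_df(22, 2)  # 42
#' @export
rm_error_df <- function(n_units, df_factor) {
  (n_units - 1) * df_factor
}
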