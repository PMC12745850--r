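#' Configuration of an end-to-end analysis run
#'
#' Validates a run configuration before any computation. Exactly one input
#' mode must be chosen: `"synthetic"` (generate motion with
#' [simulate_motion()]; requires `seed`), `"series"` (load a per-frame
#' motion CSV) or `"frames"` (extract motion from an image directory).
#'
#' @param phase Experimental phase (1, 2 or 3).
#' @param n_cycles Number of Light1-Light2-Dark cycles.
#' @param mode Input mode: `"synthetic"`, `"series"` or `"frames"`.
#' @param seed Root seed; all module substreams are derived from it.
#'   Mandatory in synthetic mode and for Phase 3 schedules.
#' @param out_dir Output directory for the report bundle.
#' @param series_path,frames_dir Input paths for the respective modes.
#' @param watering_path Optional watering-log CSV (`start_s`, `end_s`).
#' @param capture_interval_s Capture grid spacing, seconds.
#' @param keyframe_period Optional key-frame exclusion period.
#' @param band Day-length band (hours) for Phase-3 stratification.
#' @param log_base Base of the learning-curve logarithm.
#' @param day_lengths Phase-3 candidate day lengths.
#' @param sim SimParams overrides (named list) for synthetic mode.
#' @param make_plots Write PNG figures (requires ggplot2).
#' @return A validated `run_config` list.
#' @export
run_config <- function(phase, n_cycles, mode = c("synthetic", "series",
                                                 "frames"),
                       seed = NULL, out_dir = tempfile("nyctinast_run_"),
                       series_path = NULL, frames_dir = NULL,
                       watering_path = NULL, capture_interval_s = 20,
                       keyframe_period = NULL, band = c(12, 24),
                       log_base = exp(1), day_lengths = seq(10, 32, 2),
                       sim = list(), make_plots = FALSE) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(seed)) {
    stop_domain("Synthetic mode requires `seed`.", "config_error")
  }
  if (mode == "series" && (is.null(series_path) || !file.exists(series_path))) {
    stop_domain("Series mode requires an existing `series_path`.",
                "config_error")
  }
  if (mode == "frames" && (is.null(frames_dir) || !dir.exists(frames_dir))) {
    stop_domain("Frames mode requires an existing `frames_dir`.",
                "config_error")
  }
  if (!is.null(watering_path) && !file.exists(watering_path)) {
    stop_domain("`watering_path` does not exist.", "config_error")
  }
  if (phase == 3 && is.null(seed)) {
    stop_domain("Phase 3 requires `seed`.", "config_error")
  }
  structure(list(
    phase = phase, n_cycles = n_cycles, mode = mode, seed = seed,
    out_dir = out_dir, series_path = series_path, frames_dir = frames_dir,
    watering_path = watering_path, capture_interval_s = capture_interval_s,
    keyframe_period = keyframe_period, band = band, log_base = log_base,
    day_lengths = day_lengths, sim = sim, make_plots = make_plots
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Field names mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_domain(paste0("Unknown config fields: ",
                       paste(unknown, collapse = ", ")), "config_error")
  }
  do.call(run_config, raw)
}

#' Run the full schedule -> motion -> statistics pipeline
#'
#' Builds the phase schedule, obtains a motion series (simulated, loaded, or
#' extracted from frames), applies artifact exclusions, aggregates cell
#' means, computes the per-cycle anticipation statistic, fits its
#' logarithmic learning curve, runs the repeated-measures ANOVA (plus the
#' pre-light simple-effects analysis), stratifies by day length for Phase 3,
#' and writes every table plus a manifest to `out_dir`. In synthetic mode a
#' repeated run with the same config reproduces all numeric outputs
#' bit-for-bit.
#'
#' @param config A `run_config` (or path to a YAML config file).
#' @return Invisibly, a list with `schedule`, `series`, `cells`,
#'   `differences`, `fit`, `anova`, `prelight_anova`, `stratified` (Phase 3
#'   only) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    stop_domain("`config` must be a run_config or a YAML path.",
                "config_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  schedule <- build_phase(config$phase, config$n_cycles,
                          seed = if (config$phase == 3) {
                            sub_seed(config$seed, "schedule")
                          },
                          day_lengths = config$day_lengths)

  watering <- if (!is.null(config$watering_path)) {
    read.csv(config$watering_path)
  }

  series <- switch(config$mode,
    synthetic = {
      p <- do.call(sim_params, utils::modifyList(
        config$sim, list(seed = sub_seed(config$seed, "simulate"))
      ))
      simulate_motion(schedule, p, config$capture_interval_s)$series
    },
    series = label_frames(read_series(config$series_path,
                                      config$capture_interval_s), schedule),
    frames = label_frames(
      motion_series(config$frames_dir, schedule, config$capture_interval_s),
      schedule
    )
  )
  series <- apply_exclusions(series, schedule, watering,
                             config$keyframe_period)

  cells <- cell_means(series)
  differences <- motion_difference(cells)
  fit <- tryCatch(fit_log_curve(differences, log_base = config$log_base),
                  error = function(e) NULL)
  covs <- if (config$phase == 3) c("cycle", "day_length") else "cycle"
  anova_tab <- tryCatch(rm_anova(cells, covariates = covs),
                        error = function(e) NULL)
  prelight <- tryCatch(simple_effects(cells, "pre-light", covariates = covs),
                       error = function(e) NULL)
  strat <- if (config$phase == 3) {
    stratify_by_day_length(differences, config$band, config$log_base)
  }

  paths <- list(
    schedule = file.path(config$out_dir, "schedule.csv"),
    series = file.path(config$out_dir, "series.csv"),
    cells = file.path(config$out_dir, "cell_table.csv"),
    differences = file.path(config$out_dir, "motion_differences.csv"),
    fit = file.path(config$out_dir, "learning_curve.json"),
    anova = file.path(config$out_dir, "anova.csv"),
    prelight_anova = file.path(config$out_dir, "anova_prelight.csv"),
    config = file.path(config$out_dir, "config.json"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_schedule(schedule, paths$schedule)
  write_series(series, paths$series)
  write.csv(as.data.frame(cells), paths$cells, row.names = FALSE)
  write.csv(as.data.frame(differences), paths$differences, row.names = FALSE)
  if (!is.null(fit)) {
    jsonlite::write_json(fit[c("a", "b", "r_squared", "n_cycles",
                               "log_base")],
                         paths$fit, auto_unbox = TRUE, digits = NA)
  } else {
    paths$fit <- NULL
  }
  if (!is.null(anova_tab)) {
    write.csv(as.data.frame(anova_tab), paths$anova, row.names = FALSE)
  } else {
    paths$anova <- NULL
  }
  if (!is.null(prelight)) {
    write.csv(as.data.frame(prelight), paths$prelight_anova,
              row.names = FALSE)
  } else {
    paths$prelight_anova <- NULL
  }
  if (!is.null(strat)) {
    paths$stratified <- file.path(config$out_dir, "stratified.json")
    s <- strat
    if (!is.null(s$in_band_fit)) {
      s$in_band_fit <- s$in_band_fit[c("a", "b", "r_squared", "n_cycles")]
    }
    jsonlite::write_json(s, paths$stratified, auto_unbox = TRUE, digits = NA)
  }
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # location-independent hash
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (isTRUE(config$make_plots)) {
    paths <- c(paths, write_figures(series, differences, fit,
                                    config$out_dir))
  }
  manifest <- list(
    package = "nyctinast",
    version = as.character(utils::packageVersion("nyctinast")),
    seed = config$seed,
    phase = config$phase,
    config_hash = unname(tools::md5sum(paths$config)),
    files = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(schedule = schedule, series = series, cells = cells,
                 differences = differences, fit = fit, anova = anova_tab,
                 prelight_anova = prelight, stratified = strat,
                 manifest = manifest))
}

# Optional diagnostic figures: smoothed motion trace and the learning curve.
write_figures <- function(series, differences, fit, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE) ||
      !capabilities("png")) {
    return(list())
  }
  paths <- list()
  sm <- series
  sm$smoothed <- gaussian_smooth(ifelse(sm$valid, sm$motion, NA), 50)
  p1 <- ggplot2::ggplot(sm, ggplot2::aes(x = .data$timestamp_s / 3600,
                                         y = .data$smoothed)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Time (h)", y = "Motion (smoothed)",
                  title = "Group motion trace")
  paths$fig_motion <- file.path(out_dir, "fig_motion_trace.png")
  ggplot2::ggsave(paths$fig_motion, p1, width = 8, height = 3, dpi = 120)
  p2 <- ggplot2::ggplot(differences,
                        ggplot2::aes(x = .data$cycle, y = .data$motion_diff)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "Cycle", y = "(Light1 + Light2)/2 - Dark",
                  title = "Pre-light anticipation by cycle")
  if (!is.null(fit)) {
    curve_df <- tibble::tibble(
      cycle = differences$cycle,
      motion_diff = fit$a * log(differences$cycle, base = fit$log_base) +
        fit$b
    )
    p2 <- p2 + ggplot2::geom_line(data = curve_df, colour = "steelblue")
  }
  paths$fig_diff <- file.path(out_dir, "fig_learning_curve.png")
  ggplot2::ggsave(paths$fig_diff, p2, width = 5, height = 3.5, dpi = 120)
  paths
}

#' Published group summary tables
#'
#' Returns one of the published summary tables shipped with the package:
#' per-phase descriptive statistics of motion by day condition and
#' time-of-day (`"phase1_descriptives"`, `"phase2_descriptives"`,
#' `"phase3_descriptives"`, `"phase3_inband_descriptives"`) and the
#' repeated-measures ANOVA tables (`"phase1_anova"`,
#' `"phase1_prelight_anova"`, `"phase2_anova"`, `"phase2_prelight_anova"`,
#' `"phase3_anova"`). These are the printed group-level summaries of the
#' source recordings, used for arithmetic cross-checks (effect sizes,
#' anticipation differences, df bookkeeping); the raw recordings themselves
#' are not shipped.
#'
#' @param name Table name (see above).
#' @return A tibble.
#' @examples
#' published_summaries("phase1_descriptives")
#' @export
published_summaries <- function(name) {
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "nyctinast")
  if (path == "") {
    stop_domain(sprintf("Unknown published table '%s'.", name),
                "data_error")
  }
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
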