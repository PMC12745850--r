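#' Lighting schedules for light-light-dark cycling experiments
#'
#' A lighting schedule is an ordered table of contiguous, half-open time
#' segments `[start_s, end_s)` covering one or more Light1-Light2-Dark
#' cycles. Within a cycle of day length `N` hours each lit day follows the
#' dark/light/dark rule `N/4 + N/2 + N/4`; the third day is `N` hours of
#' uninterrupted darkness. Segment rows carry the light state, 1-based cycle
#' index, day condition (`Light1`, `Light2`, `Dark`) and, for lit days, the
#' time-of-day interval (`pre-light`, `light-on`, `post-light`). The Dark day
#' is stored as a single dark segment; [label_time()] applies the same clock
#' partition to it when labelling frames.
#'
#' @name lighting_schedule
#' @keywords internal
NULL

CONDITIONS <- c("Light1", "Light2", "Dark")
INTERVALS <- c("pre-light", "light-on", "post-light")

new_schedule <- function(segments, phase_id = NA_character_, seed = NULL) {
  out <- tibble::as_tibble(segments)
  attr(out, "phase_id") <- phase_id
  attr(out, "rng_seed") <- seed
  class(out) <- c("lighting_schedule", class(out))
  out
}

#' Build the segments of one Light1-Light2-Dark cycle
#'
#' Constructs the seven labelled segments of a single cycle of day length
#' `day_length_h`: for each of the two lit days a dark `N/4` h (pre-light),
#' lit `N/2` h (light-on) and dark `N/4` h (post-light) segment, followed by
#' one dark segment of `N` h (the Dark day). The cycle spans exactly
#' `3 * day_length_h` hours starting at `t0_s`.
#'
#' @param day_length_h Day length `N` in hours; must be positive.
#' @param cycle_index 1-based index of the cycle within its phase.
#' @param t0_s Start of the cycle, in seconds from the phase origin.
#' @return A [tibble::tibble()] with columns `start_s`, `end_s`, `state`
#'   (`"on"`/`"off"`), `cycle`, `condition`, `interval` (`NA` for the Dark
#'   day's single segment), `day_length_h` and `day_start_s`.
#' @examples
#' build_cycle(16)          # 4 h dark, 8 h light, 4 h dark, twice, then 16 h dark
#' build_cycle(24, cycle_index = 2, t0_s = 72 * 3600)
#' @export
build_cycle <- function(day_length_h, cycle_index = 1L, t0_s = 0) {
  if (!is.numeric(day_length_h) || length(day_length_h) != 1L ||
      !is.finite(day_length_h) || day_length_h <= 0) {
    stop_domain("`day_length_h` must be a single positive number of hours.",
                "schedule_error")
  }
  if (cycle_index < 1L) {
    stop_domain("`cycle_index` must be >= 1.", "schedule_error")
  }
  n_s <- day_length_h * 3600
  q <- n_s / 4
  day <- function(day_start, condition) {
    if (condition == "Dark") {
      tibble::tibble(
        start_s = day_start, end_s = day_start + n_s, state = "off",
        condition = condition, interval = NA_character_
      )
    } else {
      tibble::tibble(
        start_s = day_start + c(0, q, 3 * q),
        end_s = day_start + c(q, 3 * q, 4 * q),
        state = c("off", "on", "off"),
        condition = condition,
        interval = INTERVALS
      )
    }
  }
  segs <- dplyr::bind_rows(
    day(t0_s, "Light1"),
    day(t0_s + n_s, "Light2"),
    day(t0_s + 2 * n_s, "Dark")
  )
  segs$cycle <- as.integer(cycle_index)
  segs$day_length_h <- day_length_h
  segs$day_start_s <- t0_s + n_s * ((segs$start_s - t0_s) %/% n_s)
  segs[, c("start_s", "end_s", "state", "cycle", "condition", "interval",
           "day_length_h", "day_start_s")]
}

#' Build the lighting schedule of a whole experimental phase
#'
#' Phase 1 uses 24-h days (72-h cycles, lights on over the middle half of
#' each lit day); Phase 2 uses 20-h days (60-h cycles, first 5 h off, 10 h
#' on, 5 h off). In Phase 3 a day length is drawn uniformly from
#' `day_lengths` at the start of every cycle, reproducibly from `seed`.
#'
#' @param phase Phase identifier: 1, 2 or 3.
#' @param n_cycles Number of Light1-Light2-Dark cycles (>= 1).
#' @param seed Integer seed for the Phase-3 day-length draws; required when
#'   `phase = 3`, ignored otherwise.
#' @param day_lengths Candidate day lengths (hours) for Phase 3. Defaults to
#'   the even hours 10, 12, ..., 32.
#' @return A `lighting_schedule` tibble (see [build_cycle()] for columns)
#'   with attributes `phase_id` and `rng_seed`.
#' @examples
#' build_phase(1, n_cycles = 2)
#' build_phase(3, n_cycles = 5, seed = 42)
#' @export
build_phase <- function(phase, n_cycles, seed = NULL,
                        day_lengths = seq(10, 32, by = 2)) {
  if (!phase %in% c(1, 2, 3)) {
    stop_domain("`phase` must be 1, 2 or 3.", "schedule_error")
  }
  if (n_cycles < 1) {
    stop_domain("`n_cycles` must be >= 1.", "schedule_error")
  }
  n_cycles <- as.integer(n_cycles)
  if (phase == 3) {
    if (is.null(seed)) {
      stop_domain("Phase 3 requires a `seed` for its day-length draws.",
                  "schedule_error")
    }
    lens <- with_seed(seed, sample(day_lengths, n_cycles, replace = TRUE))
  } else {
    lens <- rep(if (phase == 1) 24 else 20, n_cycles)
  }
  t0 <- c(0, cumsum(lens * 3 * 3600))[seq_len(n_cycles)]
  segs <- dplyr::bind_rows(
    lapply(seq_len(n_cycles), function(c) build_cycle(lens[c], c, t0[c]))
  )
  new_schedule(segs, phase_id = paste0("phase", phase),
               seed = if (phase == 3) seed else NULL)
}

schedule_span <- function(schedule) {
  if (nrow(schedule) == 0L) {
    stop_domain("Empty schedule.", "schedule_error")
  }
  c(min(schedule$start_s), max(schedule$end_s))
}

#' Longest contiguous run of darkness in a schedule
#'
#' Merges adjacent lights-off segments (across day and cycle boundaries) and
#' returns the maximum contiguous off duration in hours. For a constant day
#' length `N` with a following cycle this is `1.5 * N`: post-light `N/4`,
#' the Dark day `N`, and the next cycle's pre-light `N/4`.
#'
#' @param schedule A `lighting_schedule`.
#' @return Maximum contiguous lights-off duration, hours.
#' @examples
#' longest_dark_run(build_phase(1, 2))  # 36 h
#' @export
longest_dark_run <- function(schedule) {
  span <- schedule_span(schedule)  # validates non-empty
  off <- schedule[schedule$state == "off", , drop = FALSE]
  if (nrow(off) == 0L) return(0)
  off <- off[order(off$start_s), , drop = FALSE]
  run_start <- off$start_s[1]
  best <- 0
  cur_end <- off$end_s[1]
  for (i in seq_len(nrow(off))[-1]) {
    if (off$start_s[i] <= cur_end) {
      cur_end <- max(cur_end, off$end_s[i])
    } else {
      best <- max(best, cur_end - run_start)
      run_start <- off$start_s[i]
      cur_end <- off$end_s[i]
    }
  }
  best <- max(best, cur_end - run_start)
  best / 3600
}

#' Label time points with cycle, day condition, interval and light state
#'
#' Every time point inside the schedule span receives the cycle index, day
#' condition and light state of its enclosing segment, plus the time-of-day
#' interval derived from the clock position within the day: pre-light over
#' `[0, N/4)`, light-on over `[N/4, 3N/4)` and post-light over `[3N/4, N)`
#' local hours. The Dark day is partitioned by the same clock even though
#' the lights never turn on. All boundaries are half-open: a time equal to a
#' segment start belongs to that segment.
#'
#' @param schedule A `lighting_schedule`.
#' @param t_s Numeric vector of times, seconds from the phase origin.
#' @return A tibble with columns `t_s`, `cycle`, `condition`, `interval`,
#'   `state` and `day_length_h`, one row per element of `t_s`.
#' @examples
#' sched <- build_phase(1, 1)
#' label_time(sched, 3 * 3600)   # 03:00 of day 1: Light1, pre-light, off
#' @export
label_time <- function(schedule, t_s) {
  span <- schedule_span(schedule)
  if (any(t_s < span[1] | t_s >= span[2])) {
    stop_domain("`t_s` outside the schedule span.", "schedule_error")
  }
  # Locate the enclosing segment: last segment with start_s <= t.
  idx <- findInterval(t_s, schedule$start_s)
  seg <- schedule[idx, , drop = FALSE]
  local_s <- t_s - seg$day_start_s
  quarter_s <- seg$day_length_h * 900  # N/4 h in seconds
  interval <- ifelse(local_s < quarter_s, "pre-light",
                     ifelse(local_s < 3 * quarter_s, "light-on", "post-light"))
  tibble::tibble(
    t_s = t_s,
    cycle = seg$cycle,
    condition = seg$condition,
    interval = interval,
    state = seg$state,
    day_length_h = seg$day_length_h
  )
}

#' Frame-capture timestamps over a schedule
#'
#' Returns the time-lapse capture grid `t0, t0 + d, t0 + 2d, ...` strictly
#' inside the schedule span, where `d` is the capture interval (20 s in the
#' recordings the package models, giving 4320 frames per 24-h day).
#'
#' @param schedule A `lighting_schedule`.
#' @param capture_interval_s Seconds between captures; must be positive.
#' @return Numeric vector of timestamps; length `floor(span / d)`.
#' @examples
#' length(frame_times(build_phase(1, 1))) # 72 h at 20 s = 12960 frames
#' @export
frame_times <- function(schedule, capture_interval_s = 20) {
  if (capture_interval_s <= 0) {
    stop_domain("`capture_interval_s` must be positive.", "schedule_error")
  }
  span <- schedule_span(schedule)
  n <- floor((span[2] - span[1]) / capture_interval_s)
  span[1] + capture_interval_s * (seq_len(n) - 1)
}

#' Read and write schedules as CSV
#'
#' The on-disk form is one row per segment with columns `start_s`, `end_s`,
#' `state`, `cycle`, `condition`, `interval`, `day_length_h`, `day_start_s`;
#' the round trip is lossless.
#'
#' @param schedule A `lighting_schedule`.
#' @param path File path.
#' @param phase_id,seed Metadata restored onto the read schedule.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `lighting_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(schedule), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, phase_id = NA_character_, seed = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$interval[!is.na(df$interval) & df$interval == ""] <- NA_character_
  df$cycle <- as.integer(df$cycle)
  new_schedule(df, phase_id = phase_id, seed = seed)
}
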