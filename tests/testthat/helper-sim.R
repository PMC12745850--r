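# Shared fixtures, built in code.

# A frame series with constant motion over a schedule's capture grid.
constant_series <- function(schedule, value = 1, capture_interval_s = 300) {
  ts <- frame_times(schedule, capture_interval_s)
  lab <- label_time(schedule, ts)
  nyctinast:::new_frame_series(tibble::tibble(
    frame_index = seq_along(ts), timestamp_s = ts, motion = value,
    valid = TRUE, cycle = lab$cycle, condition = lab$condition,
    interval = lab$interval, day_length_h = lab$day_length_h
  ), capture_interval_s)
}

# Brute-force longest lights-off run: scan a fine time grid, run-length
# encode the state sequence. Independent of the segment-merging code path.
brute_dark_run_h <- function(schedule, step_s = 60) {
  ts <- frame_times(schedule, step_s)
  off <- label_time(schedule, ts)$state == "off"
  r <- rle(off)
  max(r$lengths[r$values]) * step_s / 3600
}

# Uniform small test image stack: list of matrices with one moving pixel.
toy_frames <- function(n = 5, size = 4) {
  lapply(seq_len(n), function(i) {
    m <- matrix(10, size, size)
    m[1 + (i %% size), 1] <- 200
    m
  })
}
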