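#' Per-frame motion from successive images
#'
#' Group-level plant motion is quantified as the mean absolute change in the
#' green channel between an image and its predecessor. Pixel values are on
#' the 8-bit scale 0-255; larger plant movement displaces more leaf pixels
#' and yields larger mean change.
#'
#' @param prev_image,cur_image Numeric matrices (taken as the green channel)
#'   or `height x width x channel` arrays, identical dimensions, values in
#'   `[0, 255]`.
#' @return A single non-negative motion value.
#' @examples
#' a <- matrix(0, 2, 2); b <- a; b[1, 1] <- 255
#' frame_motion(a, b)  # 255 / 4
#' @export
frame_motion <- function(prev_image, cur_image) {
  g1 <- green_channel(prev_image)
  g2 <- green_channel(cur_image)
  if (!identical(dim(g1), dim(g2))) {
    stop_domain("Images must have identical dimensions.", "motion_error")
  }
  mean(abs(g2 - g1))
}

# Green plane of an image: channel 2 of an RGB(A) array, or the matrix
# itself for single-channel input.
green_channel <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    ch <- if (dim(img)[3] >= 2L) 2L else 1L
    return(img[, , ch])
  }
  stop_domain("Image must be a matrix or a 3-d array.", "motion_error")
}

# Read a frame from disk as 0-255 values. PNG natively; other formats via
# EBImage when available.
read_frame <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    return(png::readPNG(path) * 255)
  }
  if (requireNamespace("EBImage", quietly = TRUE)) {
    img <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(img)) == 3L) img <- aperm(img, c(2, 1, 3)) else img <- t(img)
    return(img * 255)
  }
  stop_domain(
    sprintf("Cannot read '%s': only PNG input is supported without EBImage.",
            path),
    "motion_error"
  )
}

#' Extract a per-frame motion series from an image sequence
#'
#' Computes [frame_motion()] between each frame and its predecessor. The
#' series keeps one row per frame; the first frame has no predecessor and is
#' flagged invalid. A missing frame (a `NULL` list element or an unreadable
#' file) invalidates the two difference values it participates in rather
#' than aborting the run.
#'
#' @param frames A list of image matrices/arrays (`NULL` marks a missing
#'   frame), a character vector of image file paths, or a directory
#'   containing frames named by zero-padded index.
#' @param schedule Optional `lighting_schedule` supplying the capture grid;
#'   when omitted, timestamps are `0, d, 2d, ...`.
#' @param capture_interval_s Seconds between captures.
#' @return A `frame_series` tibble: `frame_index`, `timestamp_s`, `motion`,
#'   `valid`.
#' @export
motion_series <- function(frames, schedule = NULL, capture_interval_s = 20) {
  if (is.character(frames) && length(frames) == 1L && dir.exists(frames)) {
    frames <- sort(list.files(frames, pattern = "\\.(png|jpe?g)$",
                              ignore.case = TRUE, full.names = TRUE))
  }
  if (is.character(frames)) {
    frames <- lapply(frames, function(p) {
      tryCatch(read_frame(p), error = function(e) {
        warning(sprintf("Skipping unreadable frame '%s'", p), call. = FALSE)
        NULL
      })
    })
  }
  n <- length(frames)
  if (n < 2L) {
    stop_domain("Need at least two frames.", "motion_error")
  }
  ts <- if (is.null(schedule)) {
    capture_interval_s * (seq_len(n) - 1)
  } else {
    ft <- frame_times(schedule, capture_interval_s)
    if (length(ft) < n) {
      stop_domain("More frames than schedule capture grid points.",
                  "motion_error")
    }
    ft[seq_len(n)]
  }
  motion <- rep(NA_real_, n)
  valid <- rep(TRUE, n)
  valid[1] <- FALSE
  missing <- vapply(frames, is.null, logical(1))
  for (i in 2:n) {
    if (!missing[i - 1] && !missing[i]) {
      motion[i] <- frame_motion(frames[[i - 1]], frames[[i]])
    }
  }
  # a missing frame poisons both adjacent diffs
  valid[missing] <- FALSE
  valid[pmin(which(missing) + 1L, n)] <- FALSE
  new_frame_series(tibble::tibble(
    frame_index = seq_len(n), timestamp_s = ts, motion = motion, valid = valid
  ), capture_interval_s)
}

new_frame_series <- function(df, capture_interval_s) {
  attr(df, "capture_interval_s") <- capture_interval_s
  class(df) <- unique(c("frame_series", class(df)))
  df
}

#' Artifact-exclusion mask over a frame grid
#'
#' Marks frames whose difference values are artifactual rather than
#' biological: (i) at every lighting on/off transition the frame spanning
#' the switch plus one frame before and after (the camera's infrared
#' changeover produces a one-frame flash); (ii) every frame at an index that
#' is a multiple of `keyframe_period` (compressed-video key frames);
#' (iii) frames recorded during a watering event or within the 70 minutes
#' after it ends, the window `[start_s, end_s + 4200)` being half-open like
#' all intervals in the package.
#'
#' @param schedule A `lighting_schedule`.
#' @param frame_times Sorted frame timestamps (seconds).
#' @param watering_events `NULL` or a data frame with columns `start_s`,
#'   `end_s`.
#' @param keyframe_period `NULL` (no key frames) or a positive integer
#'   period in frames.
#' @return Logical vector, `TRUE` where the frame is valid.
#' @examples
#' sched <- build_phase(1, 1)
#' ft <- frame_times(sched)
#' mask <- exclusion_mask(sched, ft)
#' sum(!mask)  # 3 frames at each of the 4 lighting transitions
#' @export
exclusion_mask <- function(schedule, frame_times, watering_events = NULL,
                           keyframe_period = NULL) {
  if (is.unsorted(frame_times)) {
    stop_domain("`frame_times` must be sorted.", "motion_error")
  }
  n <- length(frame_times)
  valid <- rep(TRUE, n)
  for (t_tr in transition_times(schedule)) {
    k <- match(TRUE, frame_times >= t_tr)
    if (!is.na(k)) {
      valid[max(1L, k - 1L):min(n, k + 1L)] <- FALSE
    }
  }
  if (!is.null(keyframe_period)) {
    if (keyframe_period < 1) {
      stop_domain("`keyframe_period` must be a positive integer.",
                  "motion_error")
    }
    valid[seq_len(n) %% as.integer(keyframe_period) == 0L] <- FALSE
  }
  if (!is.null(watering_events) && nrow(watering_events) > 0L) {
    if (any(watering_events$end_s < watering_events$start_s)) {
      stop_domain("Watering events must have end_s >= start_s.",
                  "motion_error")
    }
    for (i in seq_len(nrow(watering_events))) {
      lo <- watering_events$start_s[i]
      hi <- watering_events$end_s[i] + 70 * 60
      valid[frame_times >= lo & frame_times < hi] <- FALSE
    }
  }
  valid
}

# Times at which the light state switches (interior on/off boundaries).
transition_times <- function(schedule) {
  span <- schedule_span(schedule)
  on <- schedule[schedule$state == "on", , drop = FALSE]
  tt <- sort(unique(c(on$start_s, on$end_s)))
  tt[tt > span[1] & tt < span[2]]
}

#' Apply artifact exclusions to a frame series
#'
#' Conjunction of the series' existing validity flags with
#' [exclusion_mask()].
#'
#' @inheritParams exclusion_mask
#' @param series A `frame_series`.
#' @return The series with its `valid` column updated.
#' @export
apply_exclusions <- function(series, schedule, watering_events = NULL,
                             keyframe_period = NULL) {
  mask <- exclusion_mask(schedule, series$timestamp_s, watering_events,
                         keyframe_period)
  series$valid <- series$valid & mask
  series
}

#' Gaussian smoothing for display
#'
#' Convolution with a normalised Gaussian kernel truncated to `window`
#' frames (sigma = `window / 6`, so the window covers about +/- 3 sigma).
#' Edges and missing values are handled by renormalising over the weights
#' actually present, so a constant series passes through unchanged. Intended
#' for plotting only; all statistics use the raw valid frames.
#'
#' @param values Numeric vector, may contain `NA`.
#' @param window_frames Kernel window length in frames (>= 1).
#' @return Smoothed vector of the same length.
#' @export
gaussian_smooth <- function(values, window_frames = 50) {
  if (window_frames < 1) {
    stop_domain("`window_frames` must be >= 1.", "motion_error")
  }
  h <- floor(window_frames / 2)
  if (h == 0L) return(values)
  sigma <- window_frames / 6
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  k <- k / sum(k)
  x <- values
  miss <- !is.finite(x)
  x[miss] <- 0
  w <- as.numeric(!miss)
  n <- length(x)
  if (n >= 2 * h + 1) {
    num <- stats::filter(x, k, method = "convolution", sides = 2)
    den <- stats::filter(w, k, method = "convolution", sides = 2)
    # stats::filter leaves the h edge values NA; direct sums fill them in
    out <- as.numeric(num) / as.numeric(den)
    edge <- which(is.na(as.numeric(den)))
  } else {
    den <- rep(NA_real_, n)
    out <- rep(NA_real_, n)
    edge <- seq_len(n)
  }
  for (i in edge) {
    j <- max(1L, i - h):min(n, i + h)
    kk <- k[j - i + h + 1L]
    s <- sum(kk * w[j])
    out[i] <- if (s > 0) sum(kk * x[j]) / s else NA_real_
  }
  out[which(den == 0)] <- NA_real_
  out
}

#' Read and write frame series as CSV
#'
#' Columns `frame_index`, `timestamp_s`, `motion`, `valid` plus any label
#' columns present (`cycle`, `condition`, `interval`).
#'
#' @param series A `frame_series`.
#' @param path File path.
#' @param capture_interval_s Capture interval restored on read.
#' @return `write_series()` returns `path` invisibly; `read_series()` a
#'   `frame_series`.
#' @export
write_series <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, capture_interval_s = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("frame_index", "timestamp_s", "motion") %in% names(df))) {
    stop_domain("Series file needs frame_index, timestamp_s, motion columns.",
                "motion_error")
  }
  if (is.null(df$valid)) df$valid <- !is.na(df$motion)
  df$valid <- as.logical(df$valid)
  if (is.null(capture_interval_s) && nrow(df) > 1L) {
    capture_interval_s <- stats::median(diff(df$timestamp_s))
  }
  new_frame_series(tibble::as_tibble(df), capture_interval_s)
}
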