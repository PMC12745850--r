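#' Parameters of the synthetic scene renderer
#'
#' Describes the toy overhead scene used to exercise the image pipeline: a
#' dark tray with `n_leaflets` bright green leaflets radiating from fixed
#' anchor points. Frames default to 320 x 180, the 16:9 shape of the
#' modelled recordings at desk scale.
#'
#' @param width,height Frame size in pixels.
#' @param n_leaflets Number of leaflets.
#' @param leaflet_length Leaflet length, pixels.
#' @param thickness Painted stroke thickness, pixels.
#' @param leaf_green Green intensity of leaflets (0-255).
#' @param bg_dark,bg_light Background green level with lights off / on.
#' @param sway_gain Tip displacement in pixels per motion unit.
#' @param seed Seed for anchor placement and per-frame jitter.
#' @return A validated `scene_params` list.
#' @export
scene_params <- function(width = 320, height = 180, n_leaflets = 24,
                         leaflet_length = 40, thickness = 3,
                         leaf_green = 220, bg_dark = 30, bg_light = 110,
                         sway_gain = 6, seed = 1L) {
  if (sway_gain <= 0) stop_domain("`sway_gain` must be > 0.", "synth_error")
  if (leaflet_length + 4 > min(width, height) / 1) {
    stop_domain("Leaflets must fit inside the frame.", "synth_error")
  }
  structure(list(
    width = width, height = height, n_leaflets = n_leaflets,
    leaflet_length = leaflet_length, thickness = thickness,
    leaf_green = leaf_green, bg_dark = bg_dark, bg_light = bg_light,
    sway_gain = sway_gain, seed = as.integer(seed)
  ), class = "scene_params")
}

#' Render a motion series as a synthetic image sequence
#'
#' Each frame paints the leaflets at base angles perturbed by a uniform
#' jitter whose amplitude is proportional to that frame's motion value
#' (`sway_gain` pixels of tip travel per motion unit), over a background
#' that switches brightness with the light state. Rendering is fully
#' deterministic given the scene seed. Because the background steps at
#' every lighting transition, the rendered sequence reproduces the
#' transition-flash artifact that [exclusion_mask()] removes.
#'
#' @param series A `frame_series` aligned to `schedule`'s capture grid.
#' @param scene A [scene_params()] list.
#' @param schedule A `lighting_schedule` (supplies the light state per
#'   frame); `NULL` renders everything on the dark background.
#' @param dir Optional directory; when given, frames are written as
#'   zero-padded PNGs and the paths are returned instead of arrays.
#' @return A list of `height x width` green-channel matrices (0-255), or
#'   PNG file paths when `dir` is given.
#' @export
render_frames <- function(series, scene = scene_params(), schedule = NULL,
                          dir = NULL) {
  n <- nrow(series)
  st <- if (is.null(schedule)) {
    rep("off", n)
  } else {
    label_time(schedule, series$timestamp_s)$state
  }
  motion <- series$motion
  motion[!is.finite(motion)] <- 0
  geom <- with_seed(scene$seed, {
    list(
      x0 = runif(scene$n_leaflets, scene$leaflet_length + 2,
                 scene$width - scene$leaflet_length - 2),
      y0 = runif(scene$n_leaflets, scene$leaflet_length + 2,
                 scene$height - scene$leaflet_length - 2),
      theta0 = runif(scene$n_leaflets, 0, 2 * pi),
      jitter = matrix(runif(n * scene$n_leaflets, -1, 1), nrow = n)
    )
  })
  frames <- vector("list", n)
  for (f in seq_len(n)) {
    bg <- if (st[f] == "on") scene$bg_light else scene$bg_dark
    img <- matrix(bg, nrow = scene$height, ncol = scene$width)
    amp <- scene$sway_gain * motion[f] / scene$leaflet_length  # radians
    theta <- geom$theta0 + amp * geom$jitter[f, ]
    img <- paint_leaflets(img, geom$x0, geom$y0, theta,
                          scene$leaflet_length, scene$thickness,
                          scene$leaf_green)
    frames[[f]] <- img
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, sprintf("frame_%06d.png", seq_len(n)))
    for (f in seq_len(n)) {
      g <- frames[[f]] / 255
      rgb <- array(0, dim = c(scene$height, scene$width, 3))
      rgb[, , 1] <- g * 0.25
      rgb[, , 2] <- g
      rgb[, , 3] <- g * 0.2
      png::writePNG(rgb, paths[f])
    }
    return(paths)
  }
  frames
}

# Rasterise leaflets as thick line segments by stamping squares along each
# segment at sub-pixel steps.
paint_leaflets <- function(img, x0, y0, theta, len, thickness, value) {
  h <- nrow(img)
  w <- ncol(img)
  half <- floor(thickness / 2)
  steps <- seq(0, 1, length.out = 2 * len)
  for (l in seq_along(x0)) {
    xs <- round(x0[l] + steps * len * cos(theta[l]))
    ys <- round(y0[l] + steps * len * sin(theta[l]))
    pts <- unique(cbind(ys, xs))
    for (dx in -half:half) {
      for (dy in -half:half) {
        yy <- pts[, 1] + dy
        xx <- pts[, 2] + dx
        ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
        img[cbind(yy[ok], xx[ok])] <- value
      }
    }
  }
  img
}
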