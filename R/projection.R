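#' Rendering window
#'
#' Linear display window in camera counts. The defaults (min 400, max 5500)
#' are a setting at which foci remain visible throughout a time lapse while
#' background is suppressed.
#'
#' @param lo,hi window bounds in counts, `hi > lo`.
#' @return A `render_window` list.
#' @export
render_window <- function(lo = 400, hi = 5500) {
  stopifnot(hi > lo)
  structure(list(lo = lo, hi = hi), class = "render_window")
}

#' Clamp-render an intensity plane to [0, 1]
#'
#' `(I - lo) / (hi - lo)`, clipped to `[0, 1]`.
#'
#' @param plane numeric matrix.
#' @param window a [render_window].
#' @return Matrix in `[0, 1]`.
#' @export
clamp_render <- function(plane, window = render_window()) {
  pmin(pmax((plane - window$lo) / (window$hi - window$lo), 0), 1)
}

#' Time-indexed colour lookup table
#'
#' Evenly spaced hue sweep from red (0 degrees, first frame) to blue (240
#' degrees, last frame) at full saturation and value.
#'
#' @param n_frames number of frames.
#' @return `n_frames * 3` matrix of RGB colours in `[0, 1]`.
#' @export
temporal_lut <- function(n_frames) {
  stopifnot(n_frames >= 1)
  h <- if (n_frames == 1) 0 else (240 / 360) * (seq_len(n_frames) - 1) / (n_frames - 1)
  t(grDevices::col2rgb(grDevices::hsv(h, 1, 1)) / 255)
}

#' Temporal colour-coded projection
#'
#' Each frame is clamp-rendered, tinted with its time-indexed colour, and
#' the frames are superimposed by a per-channel maximum: for channel `c`,
#' `proj[c] = max_t lut[t, c] * render(frame_t)`. A pixel fluorescent in a
#' single frame takes that frame's colour; a pixel fluorescent across many
#' time points blends towards white, which is how same-site persistence is
#' read off the image. An additive-then-clip blend is available for
#' comparison.
#'
#' @param frames list of numeric matrices (one per time point).
#' @param window a [render_window].
#' @param lut `n * 3` RGB matrix; defaults to [temporal_lut()].
#' @param blend `"max"` (default) or `"additive"`.
#' @return A `temporal_projection`: list with `rgb` (`H * W * 3` array in
#'   `[0, 1]`), `lut`, `n_frames`.
#' @export
temporal_projection <- function(frames, window = render_window(),
                                lut = NULL, blend = c("max", "additive")) {
  blend <- match.arg(blend)
  n <- length(frames)
  stopifnot(n >= 1)
  if (is.null(lut)) lut <- temporal_lut(n)
  if (nrow(lut) != n)
    stop("lut must have one row per frame (", n, "), got ", nrow(lut))
  d <- dim(frames[[1]])
  rgb <- array(0, dim = c(d[1], d[2], 3))
  for (t in seq_len(n)) {
    r <- clamp_render(frames[[t]], window)
    for (ch in 1:3) {
      layer <- lut[t, ch] * r
      rgb[, , ch] <- if (blend == "max") pmax(rgb[, , ch], layer)
                     else rgb[, , ch] + layer
    }
  }
  if (blend == "additive") rgb <- pmin(rgb, 1)
  structure(list(rgb = rgb, lut = lut, n_frames = n),
            class = "temporal_projection")
}

#' Write a temporal projection as PNG (plus its LUT as CSV)
#'
#' @param proj a [temporal_projection()].
#' @param path output PNG path.
#' @param lut_path optional CSV path for the per-frame LUT.
#' @return `path`, invisibly.
#' @export
write_projection <- function(proj, path, lut_path = NULL) {
  png::writePNG(proj$rgb, path)
  if (!is.null(lut_path)) {
    df <- data.frame(frame = seq_len(proj$n_frames),
                     r = proj$lut[, 1], g = proj$lut[, 2], b = proj$lut[, 3])
    utils::write.csv(df, lut_path, row.names = FALSE)
  }
  invisible(path)
}
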