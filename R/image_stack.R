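#' Five-dimensional image stack with physical metadata
#'
#' An `image_stack` holds fluorescence microscopy data as a 5-D numeric array
#' in canonical `(t, z, c, y, x)` axis order, together with the physical
#' metadata the downstream analysis needs (pixel size, z-step, frame
#' interval). Intensities are camera counts: non-negative, and at most 65535
#' when written to disk (16-bit contract). Missing axes of an input array are
#' padded to length 1, so a plain `y * x` matrix becomes a
#' `1 * 1 * 1 * y * x` stack.
#'
#' All indices in this package are 1-based and pixel coordinates are
#' `(y, x)` = (row, column) with the origin at the top-left, following R's
#' matrix convention.
#'
#' @param pixels numeric array with 2 to 5 dimensions; interpreted as
#'   `(y, x)`, `(t, y, x)`, `(t, z, y, x)` or `(t, z, c, y, x)`.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param z_step_um spacing between z-sections in micrometres.
#' @param frame_interval_s time between frames in seconds (1 for static
#'   stacks).
#' @param channel_names character vector of channel labels, one per channel.
#' @return An object of class `image_stack` with fields `pixels` (5-D array),
#'   `pixel_size_um`, `z_step_um`, `frame_interval_s`, `channel_names`.
#' @examples
#' st <- image_stack(matrix(0, 16, 16))
#' dim(st$pixels)  # 1 1 1 16 16
#' @export
image_stack <- function(pixels, pixel_size_um = 0.065, z_step_um = 0.25,
                        frame_interval_s = 1,
                        channel_names = NULL) {
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  d <- dim(pixels)
  if (is.null(d)) stop("pixels must be an array or matrix")
  if (length(d) < 2 || length(d) > 5)
    stop("pixels must have between 2 and 5 dimensions")
  # pad leading singleton axes: (y,x) -> (1,1,1,y,x) etc.
  d5 <- c(rep(1L, 5L - length(d)), d)
  dim(pixels) <- d5
  if (any(pixels < 0)) stop("intensities must be non-negative")
  stopifnot(pixel_size_um > 0, z_step_um > 0, frame_interval_s > 0)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(d5[3]))
  if (length(channel_names) != d5[3])
    stop("channel_names length must equal the channel dimension")
  structure(
    list(pixels = pixels,
         pixel_size_um = pixel_size_um,
         z_step_um = z_step_um,
         frame_interval_s = frame_interval_s,
         channel_names = as.character(channel_names)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "image_stack: %d t x %d z x %d c x %d y x %d x | %.3f um/px, dz %.3f um, dt %g s\n",
    d[1], d[2], d[3], d[4], d[5],
    x$pixel_size_um, x$z_step_um, x$frame_interval_s))
  invisible(x)
}

#' Extract a single 2-D plane from a stack
#'
#' @param stack an [image_stack].
#' @param t,z,channel 1-based indices.
#' @return A `y * x` numeric matrix.
#' @export
get_plane <- function(stack, t = 1L, z = 1L, channel = 1L) {
  d <- dim(stack$pixels)
  if (t < 1 || t > d[1] || z < 1 || z > d[2] || channel < 1 || channel > d[3])
    stop("plane index out of range")
  stack$pixels[t, z, channel, , , drop = TRUE]
}

companion_path <- function(path) paste0(path, ".json")

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' Pixels are stored losslessly as 16-bit unsigned integers, pages ordered
#' t-major (t, then z, then channel). Because baseline TIFF carries no axis
#' metadata that the `tiff` package can write, the axis lengths and physical
#' metadata are stored in a JSON companion file at `<path>.json`;
#' [read_stack()] uses it when present. Overwriting an existing file replaces
#' both files.
#'
#' @param stack an [image_stack] with all intensities in `[0, 65535]`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  px <- stack$pixels
  if (any(px > 65535))
    stop("intensities exceed 65535: cannot store as 16-bit")
  if (any(px != round(px)))
    px <- round(px)
  d <- dim(px)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- px[t, z, ch, , , drop = TRUE] / 65535
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none"),
    error = function(e) stop("cannot write TIFF at '", path, "': ",
                             conditionMessage(e)))
  meta <- list(axes = "tzcyx", shape = as.integer(d),
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               frame_interval_s = stack$frame_interval_s,
               channel_names = stack$channel_names)
  jsonlite::write_json(meta, companion_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Reads a multi-page TIFF written by [write_stack()] (whose JSON companion
#' file restores axis order and metadata) or any plain TIFF, in which case
#' pages are taken as the time axis and metadata come from the arguments.
#'
#' @param path TIFF file path.
#' @param pixel_size_um,z_step_um,frame_interval_s,channel_names metadata
#'   defaults used when no companion file is present.
#' @return An [image_stack].
#' @export
read_stack <- function(path, pixel_size_um = 0.065, z_step_um = 0.25,
                       frame_interval_s = 1, channel_names = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p  # collapse RGB-coded pages
  })
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  cp <- companion_path(path)
  if (file.exists(cp)) {
    meta <- jsonlite::read_json(cp, simplifyVector = TRUE)
    if (!identical(meta$axes, "tzcyx"))
      stop("unparseable axes string in companion file: '", meta$axes, "'")
    d <- as.integer(meta$shape)
    if (length(pages) != d[1] * d[2] * d[3])
      stop("page count does not match companion shape")
    px <- array(0, dim = d)
    i <- 0L
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
      i <- i + 1L
      px[t, z, ch, , ] <- pages[[i]]
    }
    image_stack(px, pixel_size_um = meta$pixel_size_um,
                z_step_um = meta$z_step_um,
                frame_interval_s = meta$frame_interval_s,
                channel_names = meta$channel_names)
  } else {
    px <- array(0, dim = c(length(pages), 1L, 1L, ny, nx))
    for (t in seq_along(pages)) px[t, 1L, 1L, , ] <- pages[[t]]
    image_stack(px, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                frame_interval_s = frame_interval_s,
                channel_names = channel_names)
  }
}

#' Select the highest-contrast z-section
#'
#' For temporal projections and 2-D focus analysis the sharpest z-section of
#' the analysis channel is isolated. Contrast is measured as the per-slice
#' standard deviation of intensities (configurable via `metric`), which is
#' invariant under global additive offsets and selects the slice with the
#' strongest structure. Ties break to the lowest z index.
#'
#' @param stack an [image_stack].
#' @param channel,t 1-based channel and frame indices.
#' @param metric a function mapping a `y * x` matrix to a single contrast
#'   score; the default is `stats::sd`.
#' @return The 1-based z index of the maximising slice.
#' @export
select_best_z <- function(stack, channel = 1L, t = 1L, metric = stats::sd) {
  d <- dim(stack$pixels)
  if (t < 1 || t > d[1] || channel < 1 || channel > d[3])
    stop("index out of range")
  scores <- vapply(seq_len(d[2]), function(z)
    metric(as.numeric(stack$pixels[t, z, channel, , ])), numeric(1))
  which.max(scores)  # which.max takes the first maximum: lowest z on ties
}
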