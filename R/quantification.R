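#' Mean intensity of a focus object
#'
#' The signal intensity of a segmented object is its mean intensity over all
#' pixels in the object.
#'
#' @param plane `y * x` numeric matrix.
#' @param focus a focus object from [extract_foci()].
#' @return Arithmetic mean of intensities over the focus pixel set.
#' @export
measure_focus <- function(plane, focus) {
  ps <- focus$pixel_set
  if (is.null(ps) || nrow(ps) == 0) stop("focus has an empty pixel set")
  mean(plane[ps])
}

# dilate a pixel set by one 3x3 (8-connected) step, `width` times,
# clipped to the plane bounds; returns linear indices
dilate_pixels <- function(ps, dim, width = 1L) {
  ny <- dim[1]; nx <- dim[2]
  cur <- unique((ps[, 2] - 1L) * ny + ps[, 1])
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  for (i in seq_len(width)) {
    ys <- ((cur - 1L) %% ny) + 1L
    xs <- ((cur - 1L) %/% ny) + 1L
    allY <- outer(ys, offs$dy, "+")
    allX <- outer(xs, offs$dx, "+")
    ok <- allY >= 1L & allY <= ny & allX >= 1L & allX <= nx
    cur <- unique((allX[ok] - 1L) * ny + allY[ok])
  }
  cur
}

#' Local background in a one-pixel annulus
#'
#' The background around a segmented object is the mean intensity over an
#' annulus obtained by dilating the object by `width_px` steps of a 3x3
#' structuring element and removing (i) the object itself, (ii) pixels
#' belonging to any other segmented focus (so a bright neighbour cannot
#' contaminate the estimate), and (iii) anything outside the image. The
#' default annulus width is one pixel.
#'
#' @param plane `y * x` numeric matrix.
#' @param focus a focus object.
#' @param all_foci_mask logical matrix marking every segmented focus pixel
#'   (may be `NULL` to skip neighbour exclusion).
#' @param width_px annulus width in pixels, >= 1.
#' @return Mean background intensity over the annulus pixels.
#' @export
annulus_background <- function(plane, focus, all_foci_mask = NULL,
                               width_px = 1L) {
  stopifnot(width_px >= 1)
  ny <- nrow(plane); nx <- ncol(plane)
  ps <- focus$pixel_set
  own <- (ps[, 2] - 1L) * ny + ps[, 1]
  ring <- setdiff(dilate_pixels(ps, c(ny, nx), width_px), own)
  if (!is.null(all_foci_mask)) {
    other <- which(all_foci_mask)
    other <- setdiff(other, own)
    ring <- setdiff(ring, other)
  }
  if (length(ring) == 0)
    stop("degenerate annulus for focus ", focus$id,
         ": no background pixels available")
  mean(plane[ring])
}

#' Measure all foci with background subtraction
#'
#' Applies [measure_focus()] and [annulus_background()] to every focus and
#' reports the corrected intensity `mean_intensity - background_mean`.
#' Corrected values may be negative under noise and are reported as-is.
#' Output rows are ordered by focus id.
#'
#' @param plane `y * x` numeric matrix.
#' @param foci list of focus objects (e.g. `segment_foci(...)$foci`).
#' @param width_px annulus width in pixels.
#' @param exclude_other_foci if `TRUE` (default), annulus pixels under any
#'   other focus are excluded from the background estimate.
#' @return Data frame with columns `roi_label`, `focus_id`, `area_px`,
#'   `mean_intensity`, `background_mean`, `corrected_intensity`,
#'   `centroid_y`, `centroid_x`.
#' @export
quantify_foci <- function(plane, foci, width_px = 1L,
                          exclude_other_foci = TRUE) {
  mask <- NULL
  if (exclude_other_foci && length(foci) > 0) {
    mask <- matrix(FALSE, nrow(plane), ncol(plane))
    for (f in foci) mask[f$pixel_set] <- TRUE
  }
  rows <- lapply(foci, function(f) {
    m <- measure_focus(plane, f)
    b <- annulus_background(plane, f, mask, width_px)
    data.frame(roi_label = f$roi_label, focus_id = f$id,
               area_px = f$area_px, mean_intensity = m,
               background_mean = b, corrected_intensity = m - b,
               centroid_y = unname(f$centroid["y"]),
               centroid_x = unname(f$centroid["x"]),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(roi_label = character(), focus_id = integer(),
                      area_px = integer(), mean_intensity = numeric(),
                      background_mean = numeric(),
                      corrected_intensity = numeric(),
                      centroid_y = numeric(), centroid_x = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$focus_id), , drop = FALSE]
}

#' Foci per cell frequency
#'
#' The frequency of foci, expressed per cell at a single instant: the exact
#' ratio of the automated focus count to a (manually supplied) cell count.
#' Stored unrounded; round only for display.
#'
#' @param n_foci focus count, >= 0.
#' @param n_cells cell count, >= 1.
#' @param strain_label optional strain identifier.
#' @return A `frequency_estimate` list with `strain_label`, `n_foci`,
#'   `n_cells`, `foci_per_cell`.
#' @export
foci_per_cell <- function(n_foci, n_cells, strain_label = "") {
  if (n_cells < 1) stop("n_cells must be >= 1")
  stopifnot(n_foci >= 0)
  structure(list(strain_label = strain_label,
                 n_foci = as.integer(n_foci), n_cells = as.integer(n_cells),
                 foci_per_cell = n_foci / n_cells),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("%s: %d foci / %d cells = %.2f foci per cell\n",
              if (nzchar(x$strain_label)) x$strain_label else "(unnamed)",
              x$n_foci, x$n_cells, x$foci_per_cell))
  invisible(x)
}
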