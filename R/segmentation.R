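#' Segmentation parameters
#'
#' Foci are defined by signal intensity greater than `k_sd` standard
#' deviations above the mean intensity over the whole ROI, and by being
#' larger than `min_size_px` pixels (strictly: a component of exactly
#' `min_size_px` pixels is discarded). Defaults are k = 2.2 and 6 pixels.
#' The standard deviation is the population SD (divisor N). Connectivity is
#' 8 (2-D, including diagonals) by default so diffraction-limited spots are
#' not split; 4 selects edge-neighbours only.
#'
#' @param k_sd threshold multiplier, unitless, >= 0.
#' @param min_size_px minimum object size in pixels (exclusive bound).
#' @param connectivity 4 or 8.
#' @param exclude_border drop foci touching the ROI footprint border
#'   (default `FALSE`: boundary-touching foci are kept).
#' @return A `seg_params` list.
#' @export
seg_params <- function(k_sd = 2.2, min_size_px = 6L, connectivity = 8L,
                       exclude_border = FALSE) {
  stopifnot(k_sd >= 0, min_size_px >= 0, connectivity %in% c(4L, 8L))
  structure(list(k_sd = k_sd, min_size_px = as.integer(min_size_px),
                 connectivity = as.integer(connectivity),
                 exclude_border = isTRUE(exclude_border)),
            class = "seg_params")
}

#' Threshold an ROI into a binary focus mask
#'
#' Each pixel of the ROI is assigned to focus (white) or not-focus (black):
#' a pixel is a focus pixel iff it lies in the ROI footprint and its
#' intensity is strictly greater than `mean + k_sd * SD`, both computed over
#' all ROI pixels of the analysed plane (population SD). A uniform ROI
#' therefore yields an empty mask, and the mask is invariant under any
#' transformation `I -> a*I + b` with `a > 0`, `b >= 0`.
#'
#' @param plane `y * x` numeric matrix.
#' @param r an [roi].
#' @param params a [seg_params].
#' @return A `binary_mask`: list with logical `mask`, logical `footprint`,
#'   `roi_label`, and the `threshold` used.
#' @export
threshold_roi <- function(plane, r, params = seg_params()) {
  stopifnot(is.matrix(plane))
  fp <- rasterize_roi(r, dim(plane))
  n <- sum(fp)
  if (n < 2)
    stop("degenerate ROI '", r$label, "': fewer than 2 pixels, SD undefined")
  vals <- plane[fp]
  mu <- mean(vals)
  sdp <- sqrt(sum((vals - mu)^2) / n)  # population SD, divisor N
  thr <- mu + params$k_sd * sdp
  mask <- fp & (plane > thr)
  structure(list(mask = mask, footprint = fp, roi_label = r$label,
                 threshold = thr), class = "binary_mask")
}

# Two-pass connected-component labelling with union-find.
# Returns an integer matrix of labels (0 = background), labels renumbered
# 1..k in raster order (row-major: by smallest y, then x) of each
# component's first pixel.
#' Label connected components of a logical mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge neighbours) or 8 (edges + diagonals).
#' @return Integer matrix of component labels, 0 for background, components
#'   numbered in raster (row-major) order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  ny <- nrow(mask); nx <- ncol(mask)
  idx <- which(mask)                      # column-major linear indices
  if (length(idx) == 0) return(matrix(0L, ny, nx))
  id_of <- integer(ny * nx)               # map linear index -> node id
  id_of[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  ys <- ((idx - 1L) %% ny) + 1L
  xs <- ((idx - 1L) %/% ny) + 1L
  offs <- list(c(-1L, 0L), c(0L, -1L))
  if (connectivity == 8L) offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L)))
  for (o in offs) {
    ny2 <- ys + o[1]; nx2 <- xs + o[2]
    ok <- ny2 >= 1L & ny2 <= ny & nx2 >= 1L & nx2 <= nx
    nidx <- (nx2[ok] - 1L) * ny + ny2[ok]
    nid <- id_of[nidx]
    cur <- which(ok)[nid > 0L]
    nid <- nid[nid > 0L]
    for (k in seq_along(cur)) {
      a <- find(cur[k]); b <- find(nid[k])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  # renumber components in raster order (smallest y, then x) of first pixel
  ord <- order(ys, xs)
  lab_of_root <- integer(length(idx))
  nextlab <- 0L
  for (i in ord) {
    r <- roots[i]
    if (lab_of_root[r] == 0L) {
      nextlab <- nextlab + 1L
      lab_of_root[r] <- nextlab
    }
  }
  out <- matrix(0L, ny, nx)
  out[idx] <- lab_of_root[roots]
  out
}

#' Extract focus objects from a binary mask
#'
#' Connected components of the mask under the configured connectivity;
#' components whose area is not strictly larger than `min_size_px` are
#' discarded. Focus ids are assigned in raster order of each component's
#' first pixel, so repeated runs on identical input give identical ids.
#'
#' @param bm a `binary_mask` from [threshold_roi()] (or a logical matrix).
#' @param params a [seg_params].
#' @return A list of `focus` objects, each with `id`, `roi_label`,
#'   `pixel_set` (n x 2 matrix of `(y, x)`), `area_px` and `centroid`.
#' @export
extract_foci <- function(bm, params = seg_params()) {
  mask <- if (inherits(bm, "binary_mask")) bm$mask else bm
  roi_label <- if (inherits(bm, "binary_mask")) bm$roi_label else ""
  labs <- label_components(mask, params$connectivity)
  k <- max(labs)
  if (k == 0L) return(list())
  border <- NULL
  if (params$exclude_border && inherits(bm, "binary_mask")) {
    fp <- bm$footprint
    er <- fp
    er[-1, ] <- er[-1, ] & fp[-nrow(fp), ]
    er[-nrow(er), ] <- er[-nrow(er), ] & fp[-1, ]
    er[, -1] <- er[, -1] & fp[, -ncol(fp)]
    er[, -ncol(er)] <- er[, -ncol(er)] & fp[, -1]
    border <- fp & !er
  }
  out <- list()
  nid <- 0L
  for (lab in seq_len(k)) {
    idx <- which(labs == lab)
    if (length(idx) <= params$min_size_px) next
    ys <- ((idx - 1L) %% nrow(mask)) + 1L
    xs <- ((idx - 1L) %/% nrow(mask)) + 1L
    if (!is.null(border) && any(border[idx])) next
    nid <- nid + 1L
    out[[nid]] <- structure(
      list(id = nid, roi_label = roi_label,
           pixel_set = cbind(y = ys, x = xs),
           area_px = length(idx),
           centroid = c(y = mean(ys), x = mean(xs))),
      class = "focus")
  }
  out
}

#' Segment foci in a stack
#'
#' Full 2-D segmentation: pick the analysis plane (the highest-contrast
#' z-section of the given channel, or a fixed `z`), then threshold each ROI
#' and extract size-filtered connected components. Deterministic for fixed
#' inputs.
#'
#' @param stack an [image_stack].
#' @param rois an `roi_set`.
#' @param channel,t channel and frame to analyse.
#' @param params a [seg_params].
#' @param z analysis z-section; `NULL` (default) selects [select_best_z()].
#' @return List with `foci` (list of focus objects across all ROIs, ids
#'   unique), `masks` (per-ROI binary masks), `z` (the analysed section) and
#'   `plane`.
#' @export
segment_foci <- function(stack, rois, channel = 1L, t = 1L,
                         params = seg_params(), z = NULL) {
  if (is.null(z)) z <- select_best_z(stack, channel = channel, t = t)
  plane <- get_plane(stack, t = t, z = z, channel = channel)
  masks <- list()
  foci <- list()
  nid <- 0L
  for (r in rois) {
    bm <- threshold_roi(plane, r, params)
    masks[[r$label]] <- bm
    for (f in extract_foci(bm, params)) {
      nid <- nid + 1L
      f$id <- nid
      foci[[nid]] <- f
    }
  }
  list(foci = foci, masks = masks, z = z, plane = plane)
}

#' Write a focus table as CSV
#'
#' Columns: `roi_label`, `focus_id`, `area_px`, `centroid_y`, `centroid_x`.
#'
#' @param foci list of focus objects.
#' @param path output CSV path (omit to just get the data frame).
#' @return The focus table, invisibly when written.
#' @export
focus_table <- function(foci, path = NULL) {
  df <- data.frame(
    roi_label = vapply(foci, function(f) f$roi_label, character(1)),
    focus_id = vapply(foci, function(f) f$id, integer(1)),
    area_px = vapply(foci, function(f) f$area_px, integer(1)),
    centroid_y = vapply(foci, function(f) unname(f$centroid["y"]), numeric(1)),
    centroid_x = vapply(foci, function(f) unname(f$centroid["x"]), numeric(1)),
    stringsAsFactors = FALSE)
  if (length(foci) == 0)
    df <- data.frame(roi_label = character(), focus_id = integer(),
                     area_px = integer(), centroid_y = numeric(),
                     centroid_x = numeric())
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
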