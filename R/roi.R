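#' Regions of interest around cell groups
#'
#' ROIs are drawn around visible groups of cells and propagated through the z
#' dimension; they are the unit over which threshold statistics are computed.
#' An `roi` is a polygon in pixel coordinates `(y, x)` (1-based, origin
#' top-left) with an inclusive z-range. Rectangles are represented as their
#' four-vertex polygon equivalent; [roi_rect()] builds one from two opposite
#' corners. Vertex validity against a particular image is checked at
#' segmentation time, not at construction.
#'
#' @param label character identifier.
#' @param vertices numeric matrix with >= 3 rows and columns `(y, x)`.
#' @param z_range inclusive `(z_lo, z_hi)` integer pair.
#' @return An object of class `roi`.
#' @export
roi <- function(label, vertices, z_range = c(1L, 1L)) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("vertices must be an n x 2 (y, x) matrix with n >= 3")
  if (!all(is.finite(vertices))) stop("vertices must be finite")
  z_range <- as.integer(z_range)
  if (length(z_range) != 2 || z_range[1] > z_range[2])
    stop("z_range must be (z_lo, z_hi) with z_lo <= z_hi")
  colnames(vertices) <- c("y", "x")
  structure(list(label = as.character(label), vertices = vertices,
                 z_range = z_range), class = "roi")
}

#' @rdname roi
#' @param y1,x1,y2,x2 opposite rectangle corners in pixel coordinates.
#' @export
roi_rect <- function(label, y1, x1, y2, x2, z_range = c(1L, 1L)) {
  ylo <- min(y1, y2); yhi <- max(y1, y2)
  xlo <- min(x1, x2); xhi <- max(x1, x2)
  roi(label, rbind(c(ylo, xlo), c(ylo, xhi), c(yhi, xhi), c(yhi, xlo)),
      z_range = z_range)
}

#' @rdname roi
#' @param ... `roi` objects.
#' @export
roi_set <- function(...) {
  rois <- list(...)
  if (length(rois) == 1 && is.list(rois[[1]]) && !inherits(rois[[1]], "roi"))
    rois <- rois[[1]]
  stopifnot(all(vapply(rois, inherits, logical(1), "roi")))
  structure(rois, class = "roi_set")
}

#' Rasterise an ROI polygon to a pixel mask
#'
#' A pixel belongs to the ROI iff its centre (the integer `(y, x)` grid
#' point) is inside the polygon under the even-odd rule; pixels whose centre
#' lies exactly on a polygon edge are included.
#'
#' @param r an [roi].
#' @param dim image dimensions `c(ny, nx)`.
#' @return Logical `ny * nx` matrix.
#' @export
rasterize_roi <- function(r, dim) {
  ny <- dim[1]; nx <- dim[2]
  v <- r$vertices
  if (any(v[, 1] < 1 - 1e-9) || any(v[, 1] > ny + 1e-9) ||
      any(v[, 2] < 1 - 1e-9) || any(v[, 2] > nx + 1e-9))
    stop("ROI '", r$label, "' has vertices outside image bounds")
  ylo <- max(1L, floor(min(v[, 1]))); yhi <- min(ny, ceiling(max(v[, 1])))
  xlo <- max(1L, floor(min(v[, 2]))); xhi <- min(nx, ceiling(max(v[, 2])))
  ys <- ylo:yhi; xs <- xlo:xhi
  py <- rep(ys, times = length(xs))
  px <- rep(xs, each = length(ys))
  inside <- rep(FALSE, length(py))
  onedge <- rep(FALSE, length(py))
  n <- nrow(v)
  j <- n
  eps <- 1e-9
  for (i in seq_len(n)) {
    yi <- v[i, 1]; xi <- v[i, 2]; yj <- v[j, 1]; xj <- v[j, 2]
    # even-odd ray casting along +x
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # centre exactly on the closed segment [i, j]
    dy <- yj - yi; dx <- xj - xi
    len2 <- dy * dy + dx * dx
    if (len2 > 0) {
      tt <- ((py - yi) * dy + (px - xi) * dx) / len2
      cross <- (py - yi) * dx - (px - xi) * dy
      onedge <- onedge | (abs(cross) < eps * sqrt(len2) &
                          tt > -eps & tt < 1 + eps)
    } else {
      onedge <- onedge | (abs(py - yi) < eps & abs(px - xi) < eps)
    }
    j <- i
  }
  keep <- inside | onedge
  mask <- matrix(FALSE, ny, nx)
  mask[cbind(py[keep], px[keep])] <- TRUE
  mask
}

fmt_vertices <- function(v)
  paste(sprintf("%g,%g", v[, 1], v[, 2]), collapse = ";")

parse_vertices <- function(s, lineno) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- matrix(NA_real_, length(parts), 2)
  for (i in seq_along(parts)) {
    yx <- suppressWarnings(as.numeric(strsplit(parts[i], ",", fixed = TRUE)[[1]]))
    if (length(yx) != 2 || any(is.na(yx)))
      stop("malformed vertex '", parts[i], "' at line ", lineno)
    out[i, ] <- yx
  }
  out
}

#' Read and write ROI sets
#'
#' Two equivalent on-disk forms are supported. The tab-separated dialect has
#' one record per line with fields `label`, `type` (`polygon` or `rect`),
#' `vertices` (semicolon-separated `y,x` pairs; two opposite corners for
#' `rect`), `z_lo`, `z_hi`; lines starting with `#` are comments. Files
#' ending in `.json` use an equivalent JSON array of records. Rectangles are
#' expanded to their four-vertex polygon on reading. An empty file yields an
#' empty set.
#'
#' @param path file path; `.json` selects the JSON form.
#' @return [read_rois()] returns an `roi_set`.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  if (grepl("\\.json$", path)) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    rois <- lapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      v <- do.call(rbind, lapply(r$vertices, unlist))
      record_to_roi(r$label, r$type, v, r$z_lo, r$z_hi, i)
    })
    return(roi_set(rois))
  }
  lines <- readLines(path)
  rois <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 5)
      stop("malformed ROI record (need 5 tab-separated fields) at line ", i)
    v <- parse_vertices(f[3], i)
    zl <- suppressWarnings(as.integer(f[4])); zh <- suppressWarnings(as.integer(f[5]))
    if (is.na(zl) || is.na(zh)) stop("malformed z-range at line ", i)
    rois[[length(rois) + 1]] <- record_to_roi(f[1], f[2], v, zl, zh, i)
  }
  roi_set(rois)
}

record_to_roi <- function(label, type, v, zl, zh, lineno) {
  if (identical(type, "rect")) {
    if (nrow(v) != 2)
      stop("rect record needs exactly 2 corner vertices at line ", lineno)
    roi_rect(label, v[1, 1], v[1, 2], v[2, 1], v[2, 2], z_range = c(zl, zh))
  } else if (identical(type, "polygon")) {
    roi(label, v, z_range = c(zl, zh))
  } else {
    stop("unknown ROI type '", type, "' at line ", lineno)
  }
}

#' @rdname read_rois
#' @param rois an `roi_set`.
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  if (grepl("\\.json$", path)) {
    recs <- lapply(rois, function(r) list(
      label = r$label, type = "polygon",
      vertices = lapply(seq_len(nrow(r$vertices)),
                        function(i) as.numeric(r$vertices[i, ])),
      z_lo = r$z_range[1], z_hi = r$z_range[2]))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- vapply(rois, function(r)
      paste(r$label, "polygon", fmt_vertices(r$vertices),
            r$z_range[1], r$z_range[2], sep = "\t"), character(1))
    writeLines(lines, path)
  }
  invisible(path)
}
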