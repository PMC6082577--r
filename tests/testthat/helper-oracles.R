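# Independent brute-force oracles used to cross-check the pipeline.
# These deliberately share no code with the package internals: direct
# summation statistics and a stack-based flood fill.

# population mean/SD by direct summation
oracle_mean_sd <- function(values) {
  n <- length(values)
  s <- 0
  for (v in values) s <- s + v
  mu <- s / n
  ss <- 0
  for (v in values) ss <- ss + (v - mu)^2
  list(mean = mu, sd = sqrt(ss / n))
}

# flood fill from each unvisited foreground pixel (explicit stack)
oracle_components <- function(mask, connectivity = 8) {
  ny <- nrow(mask); nx <- ncol(mask)
  offs <- if (connectivity == 8)
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  seen <- matrix(FALSE, ny, nx)
  comps <- list()
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (!mask[y, x] || seen[y, x]) next
    stack <- list(c(y, x))
    seen[y, x] <- TRUE
    px <- NULL
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      px <- rbind(px, p)
      for (o in offs) {
        q <- p + o
        if (q[1] >= 1 && q[1] <= ny && q[2] >= 1 && q[2] <= nx &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    comps[[length(comps) + 1]] <- px
  }
  comps
}

# full brute-force segmentation: threshold over the ROI footprint, flood
# fill, strict size filter; returns canonical pixel-set strings
oracle_segment <- function(plane, roi_mask, k_sd = 2.2, min_size = 6,
                           connectivity = 8) {
  st <- oracle_mean_sd(plane[roi_mask])
  thr <- st$mean + k_sd * st$sd
  mask <- roi_mask & (plane > thr)
  comps <- oracle_components(mask, connectivity)
  comps <- Filter(function(p) nrow(p) > min_size, comps)
  sort(vapply(comps, canonical_pixels, character(1)))
}

canonical_pixels <- function(px) {
  ord <- order(px[, 1], px[, 2])
  paste(px[ord, 1], px[ord, 2], sep = ",", collapse = ";")
}

foci_pixel_strings <- function(foci)
  sort(vapply(foci, function(f) canonical_pixels(f$pixel_set), character(1)))

# detections data frame from a focus list
detections_of <- function(foci) {
  if (length(foci) == 0) return(data.frame(y = numeric(0), x = numeric(0)))
  data.frame(y = vapply(foci, function(f) unname(f$centroid["y"]), numeric(1)),
             x = vapply(foci, function(f) unname(f$centroid["x"]), numeric(1)))
}

# segment every frame of a single-z time-lapse stack with one whole-image ROI
segment_frames <- function(stack, params = seg_params()) {
  d <- dim(stack$pixels)
  r <- roi_rect("field", 1, 1, d[4], d[5])
  lapply(seq_len(d[1]), function(t) {
    plane <- get_plane(stack, t = t, z = 1, channel = 1)
    detections_of(extract_foci(threshold_roi(plane, r, params), params))
  })
}
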