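#' Synthetic microcolony scene specification
#'
#' Parameters of a simulated fluorescence acquisition of a bacterial
#' microcolony, with defaults emulating the study conditions this package's
#' analyses assume: 512 x 512 pixel fields, up to 11 z-sections 0.25 um
#' apart, and time lapse every 90 s over 30 min (21 frames). Cells are
#' non-overlapping spherocylinders (rods) of 2.5 x 0.9 um; each carries a
#' diffraction-limited focus with probability `focus_prob_per_cell`
#' (reference regimes 0.55 and 0.76 foci per cell). Spots are isotropic 2-D
#' Gaussians (sigma 1.3 px) with lognormal amplitudes; the camera model is
#' Poisson shot noise times gain plus Gaussian read noise, quantised to
#' 16 bits. The pixel size default of 0.065 um/px is an assumption typical
#' of a 100x/1.4 NA widefield system, not a measured value.
#'
#' @param image_shape `(ny, nx)` field size in pixels.
#' @param n_z number of z-sections.
#' @param z_step_um z spacing in micrometres.
#' @param n_cells cells per field.
#' @param cell_length_um,cell_width_um rod dimensions.
#' @param pixel_size_um micrometres per pixel.
#' @param focus_prob_per_cell probability a cell shows a focus at an instant
#'   (static scenes) / hosts a focus process (time lapse).
#' @param focus_amplitude_meanlog,focus_amplitude_sdlog lognormal peak
#'   amplitude parameters, camera counts.
#' @param psf_sigma_px in-focus Gaussian spot sigma, pixels.
#' @param defocus_slices defocus scale: at `dz` slices from the focal plane
#'   the spot sigma grows as `sqrt(1 + (dz/defocus_slices)^2)` with its
#'   integral preserved, and cytoplasm contrast falls off accordingly.
#' @param cytoplasm_level,background_level counts.
#' @param poisson_gain,read_noise_sd camera noise model parameters.
#' @param n_frames,frame_interval_s time-lapse geometry.
#' @param focus_lifetime_frames mean of the geometric assembly lifetime.
#' @param reassembly_delay_frames frames between disassembly and the next
#'   assembly of the same process.
#' @param relocation_prob probability that a reassembly occurs at a new site
#'   within the same cell rather than the previous site.
#' @param dropout_prob per-frame probability that a visible focus transiently
#'   drops out (disappears entirely for that frame).
#' @param jitter_px per-frame positional jitter SD of a focus, pixels.
#' @param drift_per_frame `(dx, dy, theta)` stage drift added every frame
#'   (pixels, pixels, degrees).
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_shape = c(512L, 512L),
                       n_z = 11L, z_step_um = 0.25,
                       n_cells = 100L,
                       cell_length_um = 2.5, cell_width_um = 0.9,
                       pixel_size_um = 0.065,
                       focus_prob_per_cell = 0.55,
                       focus_amplitude_meanlog = log(2000),
                       focus_amplitude_sdlog = 0.25,
                       psf_sigma_px = 1.3,
                       defocus_slices = 2,
                       cytoplasm_level = 300, background_level = 100,
                       poisson_gain = 1, read_noise_sd = 20,
                       n_frames = 21L, frame_interval_s = 90,
                       focus_lifetime_frames = 3,
                       reassembly_delay_frames = 1L,
                       relocation_prob = 0.5,
                       dropout_prob = 0.05,
                       jitter_px = 0.3,
                       drift_per_frame = c(dx = 0, dy = 0, theta = 0),
                       seed = 1L) {
  stopifnot(focus_prob_per_cell >= 0, focus_prob_per_cell <= 1,
            relocation_prob >= 0, relocation_prob <= 1,
            dropout_prob >= 0, dropout_prob <= 1,
            psf_sigma_px > 0, cytoplasm_level >= 0, background_level >= 0,
            read_noise_sd >= 0, poisson_gain > 0,
            n_cells >= 0, n_z >= 1, n_frames >= 1,
            focus_lifetime_frames >= 1)
  spec <- as.list(environment())
  spec$image_shape <- as.integer(image_shape)
  spec$drift_per_frame <- as.numeric(drift_per_frame)
  structure(spec, class = "scene_spec")
}

cell_geometry <- function(spec) {
  len_px <- spec$cell_length_um / spec$pixel_size_um
  wid_px <- spec$cell_width_um / spec$pixel_size_um
  list(len = len_px, wid = wid_px, half_axis = pmax((len_px - wid_px) / 2, 0))
}

# place non-overlapping rods by rejection sampling with restarts; cells are
# represented by their axis segment, clearance = mean width + 2 px between
# axis point sets. The orientation is drawn first so the admissible centre
# box can hug the borders for border-parallel cells.
place_cells <- function(spec) {
  g <- cell_geometry(spec)
  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  margin <- g$wid / 2 + 2
  n <- spec$n_cells
  if (n == 0)
    return(data.frame(cell_id = integer(), y = numeric(), x = numeric(),
                      theta_deg = numeric(), length_px = numeric(),
                      width_px = numeric()))
  npts <- max(2L, ceiling(g$half_axis))
  tpar <- seq(-1, 1, length.out = npts)
  clearance <- g$wid + 2
  budget <- 300L * n
  n_restarts <- 20L
  for (round in seq_len(n_restarts)) {
    placed_pts <- NULL
    out <- vector("list", n)
    attempts <- 0L
    k <- 0L
    while (k < n && attempts <= budget) {
      attempts <- attempts + 1L
      th <- stats::runif(1, 0, 180)
      dy <- sin(th * pi / 180) * g$half_axis
      dx <- cos(th * pi / 180) * g$half_axis
      ylo <- 1 + margin + abs(dy); yhi <- ny - margin - abs(dy)
      xlo <- 1 + margin + abs(dx); xhi <- nx - margin - abs(dx)
      if (ylo >= yhi || xlo >= xhi) next
      cy <- stats::runif(1, ylo, yhi)
      cx <- stats::runif(1, xlo, xhi)
      pts <- cbind(cy + tpar * dy, cx + tpar * dx)
      if (!is.null(placed_pts)) {
        dmin <- min(sqrt(outer(pts[, 1], placed_pts[, 1], "-")^2 +
                         outer(pts[, 2], placed_pts[, 2], "-")^2))
        if (dmin < clearance) next
      }
      k <- k + 1L
      out[[k]] <- data.frame(cell_id = k, y = cy, x = cx, theta_deg = th,
                             length_px = g$len, width_px = g$wid)
      placed_pts <- rbind(placed_pts, pts)
    }
    if (k == n) return(do.call(rbind, out))
  }
  stop("infeasible packing: could not place ", n, " cells in a ",
       ny, " x ", nx, " field after ", n_restarts, " rounds of ",
       budget, " attempts")
}

# distance from pixel grid points to a segment (p1, p2); vectorised
seg_dist <- function(py, px, p1, p2) {
  vy <- p2[1] - p1[1]; vx <- p2[2] - p1[2]
  len2 <- vy^2 + vx^2
  if (len2 == 0) return(sqrt((py - p1[1])^2 + (px - p1[2])^2))
  tt <- pmin(pmax(((py - p1[1]) * vy + (px - p1[2]) * vx) / len2, 0), 1)
  sqrt((py - p1[1] - tt * vy)^2 + (px - p1[2] - tt * vx)^2)
}

# render cytoplasm of one cell into img (modified in place by return),
# given its (possibly drift-transformed) centre/orientation
render_cell <- function(img, cy, cx, theta_deg, half_axis, wid, level) {
  ny <- nrow(img); nx <- ncol(img)
  dy <- sin(theta_deg * pi / 180) * half_axis
  dx <- cos(theta_deg * pi / 180) * half_axis
  p1 <- c(cy - dy, cx - dx); p2 <- c(cy + dy, cx + dx)
  r <- wid / 2
  ylo <- max(1L, floor(min(p1[1], p2[1]) - r - 1))
  yhi <- min(ny, ceiling(max(p1[1], p2[1]) + r + 1))
  xlo <- max(1L, floor(min(p1[2], p2[2]) - r - 1))
  xhi <- min(nx, ceiling(max(p1[2], p2[2]) + r + 1))
  if (ylo > yhi || xlo > xhi) return(img)
  ys <- ylo:yhi; xs <- xlo:xhi
  py <- rep(ys, times = length(xs))
  px <- rep(xs, each = length(ys))
  d <- seg_dist(py, px, p1, p2)
  w <- pmin(pmax(r + 0.5 - d, 0), 1)   # soft 1 px edge
  img[ylo:yhi, xlo:xhi] <- img[ylo:yhi, xlo:xhi] +
    matrix(level * w, length(ys), length(xs))
  img
}

# render a Gaussian spot of peak amplitude amp and sigma sig at (cy, cx)
render_spot <- function(img, cy, cx, amp, sig) {
  ny <- nrow(img); nx <- ncol(img)
  halo <- ceiling(5 * sig)
  ylo <- max(1L, floor(cy - halo)); yhi <- min(ny, ceiling(cy + halo))
  xlo <- max(1L, floor(cx - halo)); xhi <- min(nx, ceiling(cx + halo))
  if (ylo > yhi || xlo > xhi) return(img)
  ys <- ylo:yhi; xs <- xlo:xhi
  gy <- exp(-(ys - cy)^2 / (2 * sig^2))
  gx <- exp(-(xs - cx)^2 / (2 * sig^2))
  img[ylo:yhi, xlo:xhi] <- img[ylo:yhi, xlo:xhi] + amp * outer(gy, gx)
  img
}

# camera: Poisson(signal/gain) * gain + Gaussian read noise, 16-bit clamp
apply_camera <- function(clean, gain, read_sd) {
  n <- length(clean)
  shot <- stats::rpois(n, clean / gain) * gain
  obs <- shot + stats::rnorm(n, 0, read_sd)
  obs <- round(pmin(pmax(obs, 0), 65535))
  array(obs, dim = dim(clean))
}

# defocus factors at dz slices from the focal plane
defocus_sigma <- function(sig, dz, d0) sig * sqrt(1 + (dz / d0)^2)
defocus_amp <- function(amp, dz, d0) amp / (1 + (dz / d0)^2)

# sample a focus position inside a cell (world frame)
sample_site <- function(cell, g) {
  tt <- stats::runif(1, -0.8, 0.8)
  lat <- stats::runif(1, -0.25, 0.25) * g$wid
  th <- cell$theta_deg * pi / 180
  ay <- sin(th); ax <- cos(th)
  c(y = cell$y + tt * g$half_axis * ay - lat * ax,
    x = cell$x + tt * g$half_axis * ax + lat * ay)
}

render_scene_frame <- function(spec, cells, foci_pos, foci_amp, tf = NULL) {
  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  g <- cell_geometry(spec)
  center <- c((ny + 1) / 2, (nx + 1) / 2)
  ccy <- cells$y; ccx <- cells$x; cth <- cells$theta_deg
  if (!is.null(tf) && nrow(cells) > 0) {
    p <- transform_points(cbind(ccy, ccx), tf, center)
    ccy <- p[, 1]; ccx <- p[, 2]
    cth <- cth + tf$theta
  }
  fy <- fx <- numeric(0)
  if (!is.null(foci_pos) && nrow(foci_pos) > 0) {
    fp <- foci_pos
    if (!is.null(tf)) fp <- transform_points(foci_pos, tf, center)
    fy <- fp[, 1]; fx <- fp[, 2]
  }
  z0 <- (spec$n_z + 1) / 2
  slices <- vector("list", spec$n_z)
  cyto <- matrix(0, ny, nx)
  for (i in seq_len(nrow(cells)))
    cyto <- render_cell(cyto, ccy[i], ccx[i], cth[i], g$half_axis, g$wid, 1)
  for (z in seq_len(spec$n_z)) {
    dz <- z - z0
    img <- matrix(spec$background_level, ny, nx) +
      spec$cytoplasm_level * defocus_amp(1, dz, spec$defocus_slices) * cyto
    if (length(fy) > 0) {
      sig <- defocus_sigma(spec$psf_sigma_px, dz, spec$defocus_slices)
      for (k in seq_along(fy))
        img <- render_spot(img, fy[k], fx[k],
                           defocus_amp(foci_amp[k], dz, spec$defocus_slices),
                           sig)
    }
    slices[[z]] <- img
  }
  slices
}

#' Generate a static synthetic microcolony stack with ground truth
#'
#' Places non-overlapping rod-shaped cells by rejection sampling, plants a
#' Gaussian focus in each cell with probability `focus_prob_per_cell`,
#' renders cytoplasm + spots over `n_z` defocus-attenuated z-sections, and
#' applies the Poisson + read-noise camera model. Deterministic for a fixed
#' seed.
#'
#' @param spec a [scene_spec()].
#' @return List with `stack` (an [image_stack]) and `truth`, a
#'   `ground_truth` list holding `cells` and `foci` data frames, the
#'   noise-free stack (`clean`, same axes), and the spec.
#' @export
generate_microcolony <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, {
    cells <- place_cells(spec)
    g <- cell_geometry(spec)
    has_focus <- stats::runif(nrow(cells)) < spec$focus_prob_per_cell
    foci <- list()
    for (i in which(has_focus)) {
      pos <- sample_site(cells[i, ], g)
      amp <- stats::rlnorm(1, spec$focus_amplitude_meanlog,
                           spec$focus_amplitude_sdlog)
      foci[[length(foci) + 1]] <- data.frame(
        focus_id = length(foci) + 1L, cell_id = cells$cell_id[i],
        frame = 1L, y = pos["y"], x = pos["x"],
        z = (spec$n_z + 1) / 2, amplitude = amp, row.names = NULL)
    }
    foci <- if (length(foci)) do.call(rbind, foci) else
      data.frame(focus_id = integer(), cell_id = integer(), frame = integer(),
                 y = numeric(), x = numeric(), z = numeric(),
                 amplitude = numeric())
    slices <- render_scene_frame(spec, cells,
                                 as.matrix(foci[, c("y", "x")]),
                                 foci$amplitude)
    ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
    clean <- array(0, dim = c(1L, spec$n_z, 1L, ny, nx))
    noisy <- array(0, dim = c(1L, spec$n_z, 1L, ny, nx))
    for (z in seq_len(spec$n_z)) {
      clean[1, z, 1, , ] <- slices[[z]]
      noisy[1, z, 1, , ] <- apply_camera(slices[[z]], spec$poisson_gain,
                                         spec$read_noise_sd)
    }
    stack <- image_stack(noisy, pixel_size_um = spec$pixel_size_um,
                         z_step_um = spec$z_step_um, frame_interval_s = 1,
                         channel_names = "GFP")
    truth <- structure(list(cells = cells, foci = foci,
                            relocations = empty_relocations(),
                            drift = data.frame(frame = 1L, dx = 0, dy = 0,
                                               theta = 0),
                            clean = clean, spec = spec),
                       class = "ground_truth")
    list(stack = stack, truth = truth)
  })
}

empty_relocations <- function()
  data.frame(focus_id = integer(), frame = integer(),
             from_y = numeric(), from_x = numeric(),
             to_y = numeric(), to_x = numeric(), distance = numeric())

#' Generate a synthetic time lapse with focus dynamics and drift
#'
#' Cells placed as in [generate_microcolony()]; a fraction
#' `focus_prob_per_cell` of cells host a focus process that alternates
#' geometric-lifetime assemblies (mean `focus_lifetime_frames`) with
#' `reassembly_delay_frames` dark frames. Each reassembly relocates to a new
#' uniformly drawn site within the cell with probability `relocation_prob`,
#' otherwise reuses the previous site; visible foci jitter by `jitter_px`
#' per frame and may transiently drop out for single frames
#' (`dropout_prob`). A constant per-frame rigid stage drift accumulates over
#' the sequence and is applied to the rendered scene; the cumulative
#' transform per frame is recorded in the ground truth.
#'
#' @param spec a [scene_spec()] with `n_frames >= 2`.
#' @return As [generate_microcolony()]; `truth$foci` has one row per
#'   visible focus per frame with both frame (drifted) and world
#'   coordinates, `truth$relocations` lists relocation events, and
#'   `truth$drift` the cumulative per-frame transforms.
#' @export
generate_timelapse <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"), spec$n_frames >= 2)
  withr::with_seed(spec$seed, {
    cells <- place_cells(spec)
    g <- cell_geometry(spec)
    ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
    center <- c((ny + 1) / 2, (nx + 1) / 2)
    p_on <- spec$focus_lifetime_frames /
      (spec$focus_lifetime_frames + spec$reassembly_delay_frames)
    procs <- list()
    for (i in seq_len(nrow(cells))) {
      if (stats::runif(1) >= spec$focus_prob_per_cell) next
      procs[[length(procs) + 1]] <- list(
        id = length(procs) + 1L, cell = cells[i, ],
        site = sample_site(cells[i, ], g),
        on = stats::runif(1) < p_on,
        timer = NA_integer_,
        amp = stats::rlnorm(1, spec$focus_amplitude_meanlog,
                            spec$focus_amplitude_sdlog))
    }
    # geometric lifetime with mean m: number of frames >= 1
    rlife <- function(m) 1L + stats::rgeom(1, 1 / m)
    for (k in seq_along(procs))
      procs[[k]]$timer <- if (procs[[k]]$on)
        rlife(spec$focus_lifetime_frames) else
        sample.int(spec$reassembly_delay_frames, 1)
    foci_rows <- list()
    reloc_rows <- list()
    drift_rows <- list()
    step <- rigid_transform(spec$drift_per_frame[1], spec$drift_per_frame[2],
                            spec$drift_per_frame[3])
    cum <- rigid_transform()
    z0 <- (spec$n_z + 1) / 2
    clean <- array(0, dim = c(spec$n_frames, spec$n_z, 1L, ny, nx))
    noisy <- array(0, dim = c(spec$n_frames, spec$n_z, 1L, ny, nx))
    for (t in seq_len(spec$n_frames)) {
      if (t > 1) cum <- compose_rigid(cum, step)
      drift_rows[[t]] <- data.frame(frame = t, dx = cum$dx, dy = cum$dy,
                                    theta = cum$theta)
      pos <- NULL; amp <- numeric(0); meta <- list()
      for (k in seq_along(procs)) {
        pr <- procs[[k]]
        if (pr$on) {
          dropped <- stats::runif(1) < spec$dropout_prob
          p <- pr$site + stats::rnorm(2, 0, spec$jitter_px)
          if (!dropped) {
            pos <- rbind(pos, p)
            amp <- c(amp, pr$amp)
            meta[[length(meta) + 1]] <- data.frame(
              focus_id = pr$id, cell_id = pr$cell$cell_id, frame = t,
              world_y = p[1], world_x = p[2],
              site_y = pr$site[1], site_x = pr$site[2],
              amplitude = pr$amp)
          }
        }
        pr$timer <- pr$timer - 1L
        if (pr$timer <= 0L) {
          if (pr$on) {
            pr$on <- FALSE
            pr$timer <- spec$reassembly_delay_frames
          } else {
            pr$on <- TRUE
            pr$timer <- rlife(spec$focus_lifetime_frames)
            if (stats::runif(1) < spec$relocation_prob) {
              old <- pr$site
              pr$site <- sample_site(pr$cell, g)
              # reassemblies beyond the last frame never render: no event
              if (t < spec$n_frames)
                reloc_rows[[length(reloc_rows) + 1]] <- data.frame(
                  focus_id = pr$id, frame = t + 1L,
                  from_y = old[1], from_x = old[2],
                  to_y = pr$site[1], to_x = pr$site[2],
                  distance = sqrt(sum((pr$site - old)^2)))
            }
            pr$amp <- stats::rlnorm(1, spec$focus_amplitude_meanlog,
                                    spec$focus_amplitude_sdlog)
          }
        }
        procs[[k]] <- pr
      }
      slices <- render_scene_frame(spec, cells, pos, amp, tf = cum)
      for (z in seq_len(spec$n_z)) {
        clean[t, z, 1, , ] <- slices[[z]]
        noisy[t, z, 1, , ] <- apply_camera(slices[[z]], spec$poisson_gain,
                                           spec$read_noise_sd)
      }
      if (length(meta) > 0) {
        m <- do.call(rbind, meta)
        fp <- transform_points(cbind(m$world_y, m$world_x), cum, center)
        m$y <- fp[, 1]; m$x <- fp[, 2]
        foci_rows[[length(foci_rows) + 1]] <- m
      }
    }
    foci <- if (length(foci_rows)) do.call(rbind, foci_rows) else
      data.frame(focus_id = integer(), cell_id = integer(), frame = integer(),
                 world_y = numeric(), world_x = numeric(),
                 site_y = numeric(), site_x = numeric(),
                 amplitude = numeric(), y = numeric(), x = numeric())
    rownames(foci) <- NULL
    stack <- image_stack(noisy, pixel_size_um = spec$pixel_size_um,
                         z_step_um = spec$z_step_um,
                         frame_interval_s = spec$frame_interval_s,
                         channel_names = "GFP")
    truth <- structure(
      list(cells = cells, foci = foci,
           relocations = if (length(reloc_rows))
             do.call(rbind, reloc_rows) else empty_relocations(),
           drift = do.call(rbind, drift_rows),
           clean = clean, spec = spec),
      class = "ground_truth")
    list(stack = stack, truth = truth)
  })
}

#' Export (and re-import) ground truth tables
#'
#' Writes `cells.csv`, `foci.csv`, `relocations.csv`, `drift.csv` and a
#' `scene.json` with the scene parameters into a directory. The noise-free
#' image stack is not exported (regenerate it from the spec and seed).
#' [read_ground_truth()] restores the tables; the roundtrip is stable.
#'
#' @param truth a `ground_truth` from the generators.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$foci, file.path(dir, "foci.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$relocations, file.path(dir, "relocations.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$drift, file.path(dir, "drift.csv"),
                   row.names = FALSE)
  sp <- unclass(truth$spec)
  jsonlite::write_json(sp, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  sp <- jsonlite::read_json(file.path(dir, "scene.json"),
                            simplifyVector = TRUE)
  structure(list(cells = rd("cells.csv"), foci = rd("foci.csv"),
                 relocations = rd("relocations.csv"), drift = rd("drift.csv"),
                 clean = NULL, spec = sp),
            class = "ground_truth")
}
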