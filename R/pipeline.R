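#' Pipeline configuration
#'
#' A single nested configuration drives every pipeline command. Defaults
#' carry the analysis constants: segmentation k = 2.2 SD and > 6 px,
#' annulus width 1 px, rendering window 400-5500 counts, tracking gap
#' tolerance 1 frame, alpha 0.05. The schema is strict: unknown keys are an
#' error, so parameters cannot drift silently under a typo.
#'
#' @param ... named overrides of the default sections (`segmentation`,
#'   `quantification`, `render`, `tracking`, `statistics`, `scene`, `seed`),
#'   each a named list of leaf values.
#' @return A `pipeline_config` nested list.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  merge_strict(cfg, list(...), path = "")
}

default_config <- function() {
  structure(list(
    segmentation = list(k_sd = 2.2, min_size_px = 6L, connectivity = 8L,
                        exclude_border = FALSE),
    quantification = list(annulus_width_px = 1L, exclude_other_foci = TRUE),
    render = list(lo = 400, hi = 5500),
    tracking = list(link_radius_px = 5, max_gap = 1L, site_radius_px = 3,
                    static_threshold = 0.5, min_span_frames = 8L,
                    max_rotation = 1.5),
    statistics = list(alpha = 0.05, percentile_type = 7L,
                      p_adjust_method = "holm", value_type = "corrected"),
    scene = list(),
    seed = 1L), class = "pipeline_config")
}

merge_strict <- function(base, override, path) {
  if (length(override) == 0) return(base)
  nm <- names(override)
  if (is.null(nm) || any(nm == ""))
    stop("config entries must be named (at '", path, "')")
  for (k in nm) {
    full <- paste0(path, if (nzchar(path)) "." else "", k)
    if (k == "scene") {
      allowed <- names(formals(scene_spec))
      bad <- setdiff(names(override[[k]]), allowed)
      if (length(bad))
        stop("unknown scene key(s): ", paste(bad, collapse = ", "))
      base[[k]] <- override[[k]]
    } else if (!k %in% names(base)) {
      stop("unknown config key '", full, "'")
    } else if (is.list(base[[k]])) {
      base[[k]] <- merge_strict(base[[k]], override[[k]], full)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' @rdname pipeline_config
#' @param path YAML (or JSON) config file; keys merge over the defaults.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE) else
    yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_to <- function(config) {
  sp <- config$segmentation
  list(seg = seg_params(sp$k_sd, sp$min_size_px, sp$connectivity,
                        sp$exclude_border),
       window = render_window(config$render$lo, config$render$hi))
}

write_manifest <- function(outdir, config, extra = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  save_config(config, file.path(outdir, "config.yaml"))
  manifest <- c(list(
    package = "focipipe",
    version = as.character(utils::packageVersion("focipipe")),
    seed = config$seed), extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

whole_image_rois <- function(stack) {
  d <- dim(stack$pixels)
  roi_set(list(roi_rect("field", 1, 1, d[4], d[5],
                        z_range = c(1L, d[2]))))
}

#' Run static focus segmentation and quantification
#'
#' For each image: read the stack, pick the highest-contrast z-section,
#' segment foci in every ROI, and measure object means with annulus
#' background subtraction. Writes per-image `foci_<id>.csv`, a combined
#' `measurements.csv`, the echoed config and a manifest.
#'
#' @param image_paths character vector of TIFF paths.
#' @param roi_path ROI file applied to every image, or `NULL` to use one
#'   whole-image rectangle ROI.
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param channel,t plane selection.
#' @return The combined measurements data frame, invisibly.
#' @export
run_segment <- function(image_paths, roi_path = NULL,
                        config = pipeline_config(), outdir,
                        channel = 1L, t = 1L) {
  pc <- config_to(config)
  all_meas <- list()
  for (p in image_paths) {
    if (!file.exists(p)) stop("missing input image: '", p, "'")
    st <- read_stack(p)
    rois <- if (is.null(roi_path)) whole_image_rois(st) else
      read_rois(roi_path)
    seg <- segment_foci(st, rois, channel = channel, t = t, params = pc$seg)
    meas <- quantify_foci(seg$plane, seg$foci,
                          width_px = config$quantification$annulus_width_px,
                          exclude_other_foci =
                            config$quantification$exclude_other_foci)
    image_id <- tools::file_path_sans_ext(basename(p))
    meas <- cbind(data.frame(image_id = image_id,
                             stringsAsFactors = FALSE)[rep(1, nrow(meas)), ,
                                                       drop = FALSE], meas)
    rownames(meas) <- NULL
    if (nrow(meas) == 0)
      meas <- cbind(data.frame(image_id = character()),
                    quantify_foci(seg$plane, list()))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(focus_table(seg$foci),
                     file.path(outdir, paste0("foci_", image_id, ".csv")),
                     row.names = FALSE)
    all_meas[[p]] <- meas
  }
  combined <- do.call(rbind, all_meas)
  rownames(combined) <- NULL
  utils::write.csv(combined, file.path(outdir, "measurements.csv"),
                   row.names = FALSE)
  write_manifest(outdir, config, list(command = "segment",
                                      n_images = length(image_paths)))
  invisible(combined)
}

#' Compare strains from measurement tables
#'
#' Reads per-strain measurement CSVs (as written by [run_segment()]), pools
#' the configured intensity column, and runs the strain comparison:
#' box summaries, rank ANOVA, Dunn-Holm post-hoc. Writes `summaries.csv`,
#' `tests.csv`, a box plot `intensity_boxes.png`, and a manifest.
#'
#' @param measurement_csvs named character vector/list: strain label ->
#'   measurements CSV path.
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return The `strain_comparison`, invisibly.
#' @export
run_compare <- function(measurement_csvs, config = pipeline_config(),
                        outdir) {
  stopifnot(length(measurement_csvs) >= 2, !is.null(names(measurement_csvs)))
  col <- if (identical(config$statistics$value_type, "raw"))
    "mean_intensity" else "corrected_intensity"
  dists <- lapply(measurement_csvs, function(p) {
    if (!file.exists(p)) stop("missing measurements file: '", p, "'")
    utils::read.csv(p)[[col]]
  })
  cmp <- compare_strains(dists, alpha = config$statistics$alpha,
                         value_type = config$statistics$value_type)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cmp$summaries, file.path(outdir, "summaries.csv"),
                   row.names = FALSE)
  tests <- cmp$pairwise
  tests$omnibus_H <- cmp$omnibus$H
  tests$omnibus_p <- cmp$omnibus$p_value
  utils::write.csv(tests, file.path(outdir, "tests.csv"), row.names = FALSE)
  plot_intensity_boxes(dists, file.path(outdir, "intensity_boxes.png"))
  write_manifest(outdir, config, list(command = "compare"))
  invisible(cmp)
}

#' Run the time-lapse dynamics analysis
#'
#' Isolates the highest-contrast z-section per frame, corrects stage drift
#' by rigid-body registration, writes the temporal colour-coded projection
#' (PNG + LUT CSV), segments foci per aligned frame, links them into tracks
#' and summarises site persistence. Outputs: `projection.png`, `lut.csv`,
#' `tracks.csv`, `transforms.csv`, `dynamics_summary.csv`, manifest.
#'
#' @param stack_path time-lapse TIFF path.
#' @param roi_path optional ROI file (default: whole image).
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param channel analysis channel.
#' @return List with `tracks`, `summary`, `transforms`, invisibly.
#' @export
run_dynamics <- function(stack_path, roi_path = NULL,
                         config = pipeline_config(), outdir, channel = 1L) {
  if (!file.exists(stack_path)) stop("missing input image: '", stack_path, "'")
  st <- read_stack(stack_path)
  d <- dim(st$pixels)
  pc <- config_to(config)
  tk <- config$tracking
  frames <- lapply(seq_len(d[1]), function(t)
    get_plane(st, t = t, z = select_best_z(st, channel, t), channel = channel))
  reg <- register_rigid(frames, max_rotation = tk$max_rotation)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  proj <- temporal_projection(reg$aligned, pc$window)
  write_projection(proj, file.path(outdir, "projection.png"),
                   file.path(outdir, "lut.csv"))
  tf <- do.call(rbind, lapply(seq_along(reg$transforms), function(i)
    data.frame(frame = i, dx = reg$transforms[[i]]$dx,
               dy = reg$transforms[[i]]$dy,
               theta = reg$transforms[[i]]$theta)))
  utils::write.csv(tf, file.path(outdir, "transforms.csv"),
                   row.names = FALSE)
  rois <- if (is.null(roi_path)) whole_image_rois(st) else read_rois(roi_path)
  per_frame <- lapply(seq_along(reg$aligned), function(t) {
    plane <- reg$aligned[[t]]
    foci <- unlist(lapply(rois, function(r)
      extract_foci(threshold_roi(plane, r, pc$seg), pc$seg)),
      recursive = FALSE)
    if (length(foci) == 0)
      return(data.frame(y = numeric(0), x = numeric(0),
                        intensity = numeric(0)))
    meas <- quantify_foci(plane, foci,
                          width_px = config$quantification$annulus_width_px,
                          exclude_other_foci =
                            config$quantification$exclude_other_foci)
    data.frame(y = meas$centroid_y, x = meas$centroid_x,
               intensity = meas$corrected_intensity)
  })
  tracks <- track_foci(per_frame, link_radius_px = tk$link_radius_px,
                       max_gap = tk$max_gap)
  track_table(tracks, file.path(outdir, "tracks.csv"))
  summ <- if (length(tracks) > 0)
    dynamics_summary(tracks, site_radius_px = tk$site_radius_px,
                     static_threshold = tk$static_threshold,
                     min_span_frames = tk$min_span_frames) else
    list(per_track = data.frame(), static_fraction = NA_real_,
         median_lifetime_frames = NA_real_, n_tracks = 0L)
  sdf <- data.frame(n_tracks = summ$n_tracks,
                    static_fraction = summ$static_fraction,
                    median_lifetime_frames = summ$median_lifetime_frames)
  utils::write.csv(sdf, file.path(outdir, "dynamics_summary.csv"),
                   row.names = FALSE)
  write_manifest(outdir, config, list(command = "dynamics"))
  invisible(list(tracks = tracks, summary = summ, transforms = reg$transforms))
}

#' Simulate a synthetic scene to disk
#'
#' Builds a [scene_spec()] from the config's `scene` block (seeded by the
#' config seed), generates a static microcolony or a time lapse, and writes
#' `stack.tif` (+ companion metadata), the ground-truth tables and a
#' manifest.
#'
#' @param config a [pipeline_config()]; `config$scene` holds scene
#'   overrides.
#' @param outdir output directory.
#' @param mode `"static"` or `"timelapse"`.
#' @return The `(stack, truth)` list, invisibly.
#' @export
run_simulate <- function(config = pipeline_config(), outdir,
                         mode = c("static", "timelapse")) {
  mode <- match.arg(mode)
  spec <- do.call(scene_spec, c(config$scene,
                                list(seed = config$seed)[!("seed" %in%
                                  names(config$scene))]))
  sim <- if (mode == "static") generate_microcolony(spec) else
    generate_timelapse(spec)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_stack(sim$stack, file.path(outdir, "stack.tif"))
  export_ground_truth(sim$truth, file.path(outdir, "truth"))
  write_manifest(outdir, config, list(command = "simulate", mode = mode))
  invisible(sim)
}

#' Match detected foci to planted ground truth
#'
#' Greedy closest-pair matching within `radius` pixels; each detection and
#' each truth record is used at most once.
#'
#' @param detected,truth data frames with columns `y`, `x`.
#' @param radius maximum match distance in pixels.
#' @return List with `matches` (data frame `det`, `truth`, `dist`),
#'   `precision`, `recall`.
#' @export
match_detections <- function(detected, truth, radius = 3) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(matches = data.frame(det = integer(), truth = integer(),
                                     dist = numeric()),
                precision = if (nd == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0))
  cand <- expand.grid(det = seq_len(nd), truth = seq_len(nt))
  dist <- sqrt((detected$y[cand$det] - truth$y[cand$truth])^2 +
               (detected$x[cand$det] - truth$x[cand$truth])^2)
  keep <- dist <= radius
  cand <- cand[keep, , drop = FALSE]; dist <- dist[keep]
  ord <- order(dist, cand$det, cand$truth)
  used_d <- rep(FALSE, nd); used_t <- rep(FALSE, nt)
  rows <- list()
  for (k in ord) {
    d <- cand$det[k]; tr <- cand$truth[k]
    if (used_d[d] || used_t[tr]) next
    used_d[d] <- TRUE; used_t[tr] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(det = d, truth = tr,
                                           dist = dist[k])
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(det = integer(), truth = integer(), dist = numeric())
  list(matches = matches, precision = nrow(matches) / nd,
       recall = nrow(matches) / nt)
}

#' End-to-end parameter recovery on a synthetic scene
#'
#' Simulates a static microcolony, runs the full segmentation +
#' quantification pipeline on the noisy stack, and compares the result with
#' the planted ground truth: recovered foci-per-cell frequency, detection
#' precision and recall (matching radius 3 px), and the median relative
#' error of the annulus-corrected intensity against the same measurement
#' taken on the noise-free image. Writes `recovery.json` and a manifest.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return The recovery report list, invisibly.
#' @export
run_validate <- function(config = pipeline_config(), outdir) {
  pc <- config_to(config)
  spec <- do.call(scene_spec, c(config$scene,
                                list(seed = config$seed)[!("seed" %in%
                                  names(config$scene))]))
  sim <- generate_microcolony(spec)
  seg <- segment_foci(sim$stack, whole_image_rois(sim$stack),
                      params = pc$seg)
  meas <- quantify_foci(seg$plane, seg$foci,
                        width_px = config$quantification$annulus_width_px)
  m <- match_detections(data.frame(y = meas$centroid_y,
                                   x = meas$centroid_x),
                        sim$truth$foci, radius = 3)
  clean_plane <- sim$truth$clean[1, seg$z, 1, , ]
  clean_meas <- quantify_foci(clean_plane, seg$foci,
                              width_px =
                                config$quantification$annulus_width_px)
  rel_err <- abs(meas$corrected_intensity - clean_meas$corrected_intensity) /
    pmax(clean_meas$corrected_intensity, 1e-9)
  n_cells <- nrow(sim$truth$cells)
  report <- list(
    n_cells = n_cells,
    planted_foci = nrow(sim$truth$foci),
    detected_foci = nrow(meas),
    planted_frequency = if (n_cells > 0)
      nrow(sim$truth$foci) / n_cells else NA_real_,
    recovered_frequency = if (n_cells > 0)
      foci_per_cell(nrow(meas), n_cells)$foci_per_cell else NA_real_,
    precision = m$precision,
    recall = m$recall,
    median_intensity_rel_error = if (nrow(meas) > 0)
      stats::median(rel_err) else NA_real_)
  report$frequency_error <- report$recovered_frequency -
    report$planted_frequency
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(outdir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, config, list(command = "validate"))
  invisible(report)
}
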