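#' Link per-frame focus detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking: at each frame, all
#' (active track, detection) pairs within `link_radius_px` are assigned
#' closest-pair first, each track and each detection used at most once.
#' A track stays active across up to `max_gap` missing frames (a focus may
#' markedly diminish or disappear entirely for at least one frame and then
#' reappear), after which it is closed. Every detection belongs to exactly
#' one track; unlinked detections start new tracks. Deterministic: distance
#' ties break by track id, then detection order.
#'
#' @param per_frame_foci list over frames; each element a data frame with
#'   columns `y`, `x` and optionally `intensity` (zero-row frames allowed).
#' @param link_radius_px maximum linking distance in pixels, > 0.
#' @param max_gap maximum number of consecutive missing frames bridged.
#' @return List of `focus_track` objects, each with `track_id`, `entries`
#'   (data frame `frame`, `y`, `x`, `intensity`) and `gap_frames`.
#' @export
track_foci <- function(per_frame_foci, link_radius_px, max_gap = 1L) {
  stopifnot(link_radius_px > 0, max_gap >= 0)
  tracks <- list()        # finished + active; entries data frames
  last_pos <- matrix(numeric(0), 0, 2)
  last_frame <- integer(0)
  for (t in seq_along(per_frame_foci)) {
    det <- per_frame_foci[[t]]
    if (is.null(det)) det <- data.frame(y = numeric(0), x = numeric(0))
    ndet <- nrow(det)
    if (is.null(det$intensity)) det$intensity <- rep(NA_real_, ndet)
    active <- which(last_frame >= t - 1L - max_gap & last_frame < t)
    assigned_det <- rep(FALSE, ndet)
    if (length(active) > 0 && ndet > 0) {
      cand <- expand.grid(ai = seq_along(active), di = seq_len(ndet))
      dist <- sqrt((last_pos[active[cand$ai], 1] - det$y[cand$di])^2 +
                   (last_pos[active[cand$ai], 2] - det$x[cand$di])^2)
      keep <- dist <= link_radius_px
      cand <- cand[keep, , drop = FALSE]
      dist <- dist[keep]
      ord <- order(dist, active[cand$ai], cand$di)
      used_track <- rep(FALSE, length(active))
      for (k in ord) {
        ai <- cand$ai[k]; di <- cand$di[k]
        if (used_track[ai] || assigned_det[di]) next
        used_track[ai] <- TRUE
        assigned_det[di] <- TRUE
        id <- active[ai]
        tr <- tracks[[id]]
        if (t - last_frame[id] > 1L)
          tr$gap_frames <- c(tr$gap_frames,
                             seq(last_frame[id] + 1L, t - 1L))
        tr$entries <- rbind(tr$entries,
                            data.frame(frame = t, y = det$y[di],
                                       x = det$x[di],
                                       intensity = det$intensity[di]))
        tracks[[id]] <- tr
        last_pos[id, ] <- c(det$y[di], det$x[di])
        last_frame[id] <- t
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <- structure(
        list(track_id = length(tracks) + 1L,
             entries = data.frame(frame = t, y = det$y[di], x = det$x[di],
                                  intensity = det$intensity[di]),
             gap_frames = integer(0)),
        class = "focus_track")
      last_pos <- rbind(last_pos, c(det$y[di], det$x[di]))
      last_frame <- c(last_frame, t)
    }
  }
  tracks
}

# greedy site clustering: a detection joins the nearest existing site whose
# anchor (first detection of the site) lies within site_radius, else opens
# a new site; returns per-entry site index and site anchors
assign_sites <- function(entries, site_radius) {
  anchors <- matrix(numeric(0), 0, 2)
  site <- integer(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    p <- c(entries$y[i], entries$x[i])
    if (nrow(anchors) > 0) {
      d <- sqrt((anchors[, 1] - p[1])^2 + (anchors[, 2] - p[2])^2)
      j <- which.min(d)
      if (d[j] <= site_radius) {
        site[i] <- j
        next
      }
    }
    anchors <- rbind(anchors, p)
    site[i] <- nrow(anchors)
  }
  list(site = site, anchors = anchors)
}

#' Per-track site statistics and per-strain dynamics summary
#'
#' Operationalises the visual white-spot reading of temporal projections.
#' For each track, detections are clustered into sites of radius
#' `site_radius_px`; the modal site is the most-visited one (earliest on
#' ties). `site_persistence` is the fraction of the track's spanned frames
#' with a detection within `site_radius_px` of the modal site (single-frame
#' tracks score 1 by convention and are flagged short). A relocation is a
#' jump between consecutive linked detections larger than `site_radius_px`.
#' A track is called static when `site_persistence >= static_threshold` and
#' it spans at least `min_span_frames` frames; the span condition encodes
#' that a same-site focus must persist over many time points -- a brief
#' single assembly is not evidence of same-site reassembly.
#'
#' @param tracks list of `focus_track` objects from [track_foci()].
#' @param site_radius_px site clustering / relocation radius in pixels.
#' @param static_threshold minimum site persistence of a static track.
#' @param min_span_frames minimum spanned frames of a static track.
#' @return A list with `per_track` (data frame: `track_id`, `n_detections`,
#'   `span_frames`, `n_gaps`, `modal_site_y`, `modal_site_x`,
#'   `site_persistence`, `n_relocations`, `short`, `static`),
#'   `static_fraction`, `median_lifetime_frames` and `n_tracks`.
#' @export
dynamics_summary <- function(tracks, site_radius_px = 3,
                             static_threshold = 0.5,
                             min_span_frames = 8L) {
  stopifnot(length(tracks) >= 1)
  rows <- lapply(tracks, function(tr) {
    e <- tr$entries
    span <- max(e$frame) - min(e$frame) + 1L
    s <- assign_sites(e, site_radius_px)
    tab <- tabulate(s$site)
    modal <- which.max(tab)           # earliest site wins ties
    anchor <- s$anchors[modal, ]
    near <- sqrt((e$y - anchor[1])^2 + (e$x - anchor[2])^2) <= site_radius_px
    persistence <- length(unique(e$frame[near])) / span
    jumps <- 0L
    if (nrow(e) > 1) {
      dd <- sqrt(diff(e$y)^2 + diff(e$x)^2)
      jumps <- sum(dd > site_radius_px)
    }
    data.frame(track_id = tr$track_id, n_detections = nrow(e),
               span_frames = span, n_gaps = length(tr$gap_frames),
               modal_site_y = anchor[1], modal_site_x = anchor[2],
               site_persistence = persistence, n_relocations = jumps,
               short = span == 1L,
               static = persistence >= static_threshold &
                        span >= min_span_frames)
  })
  per_track <- do.call(rbind, rows)
  list(per_track = per_track,
       static_fraction = mean(per_track$static),
       median_lifetime_frames = stats::median(per_track$span_frames),
       n_tracks = nrow(per_track))
}

#' Write tracks as CSV
#'
#' One row per detection: `track_id`, `frame`, `y`, `x`, `intensity`,
#' `after_gap` (the detection directly follows one or more bridged frames).
#'
#' @param tracks list of `focus_track` objects.
#' @param path output CSV path (omit to just get the data frame).
#' @return The track table, invisibly when written.
#' @export
track_table <- function(tracks, path = NULL) {
  rows <- lapply(tracks, function(tr) {
    e <- tr$entries
    after_gap <- e$frame %in% (tr$gap_frames + 1L)
    cbind(data.frame(track_id = tr$track_id), e, after_gap = after_gap)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(), y = numeric(),
               x = numeric(), intensity = numeric(), after_gap = logical())
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
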