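det <- function(y, x) data.frame(y = y, x = x)

test_that("a stationary focus forms one fully persistent track", {
  frames <- replicate(10, det(12, 20), simplify = FALSE)
  tr <- track_foci(frames, link_radius_px = 3)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]$entries), 10)
  s <- dynamics_summary(tr, min_span_frames = 8)
  expect_equal(s$per_track$site_persistence, 1)
  expect_equal(s$per_track$n_relocations, 0L)
  expect_true(s$per_track$static)
  expect_equal(s$static_fraction, 1)
})

test_that("foci beyond the link radius stay separate tracks", {
  frames <- replicate(6, det(c(5, 40), c(5, 40)), simplify = FALSE)
  tr <- track_foci(frames, link_radius_px = 4)
  expect_length(tr, 2)
  expect_true(all(vapply(tr, function(t) nrow(t$entries), integer(1)) == 6))
})

test_that("a one-frame disappearance is bridged as a gap", {
  # present frames 1..5 at (10,10), absent frame 6, frames 7..10 nearby
  frames <- c(replicate(5, det(10, 10), simplify = FALSE),
              list(det(numeric(0), numeric(0))),
              replicate(4, det(10.4, 10.2), simplify = FALSE))
  tr <- track_foci(frames, link_radius_px = 2, max_gap = 1)
  expect_length(tr, 1)
  expect_identical(tr[[1]]$gap_frames, 6L)
  expect_equal(nrow(tr[[1]]$entries), 9)
  # with max_gap = 0 the same data split into two tracks
  tr0 <- track_foci(frames, link_radius_px = 2, max_gap = 0)
  expect_length(tr0, 2)
})

test_that("detections are conserved and frames never duplicated in a track", {
  withr::with_seed(14, {
    n_frames <- 12
    frames <- lapply(seq_len(n_frames), function(t) {
      k <- sample(0:5, 1)
      det(runif(k, 1, 50), runif(k, 1, 50))
    })
    tr <- track_foci(frames, link_radius_px = 6, max_gap = 1)
    total_in <- sum(vapply(frames, nrow, integer(1)))
    total_out <- sum(vapply(tr, function(t) nrow(t$entries), integer(1)))
    expect_identical(total_in, total_out)
    for (t in tr)
      expect_false(any(duplicated(t$entries$frame)))
  })
})

test_that("relocations are counted as jumps beyond the site radius", {
  frames <- c(replicate(5, det(10, 10), simplify = FALSE),
              replicate(5, det(10, 18), simplify = FALSE))
  tr <- track_foci(frames, link_radius_px = 10)
  expect_length(tr, 1)
  s <- dynamics_summary(tr, site_radius_px = 3, min_span_frames = 8)
  expect_equal(s$per_track$n_relocations, 1L)
  # persistence: modal site covers only half the span
  expect_equal(s$per_track$site_persistence, 0.5)
})

test_that("single-frame tracks are flagged short, persistence 1 by convention", {
  frames <- list(det(5, 5), det(numeric(0), numeric(0)),
                 det(numeric(0), numeric(0)), det(30, 30))
  tr <- track_foci(frames, link_radius_px = 3, max_gap = 1)
  s <- dynamics_summary(tr, min_span_frames = 8)
  expect_true(all(s$per_track$short))
  expect_true(all(s$per_track$site_persistence == 1))
  expect_false(any(s$per_track$static))   # span too short to call static
})

test_that("static and relocating regimes are separated end to end", {
  run_regime <- function(reloc, seed) {
    sp <- scene_spec(image_shape = c(160, 160), n_z = 1, n_cells = 16,
                     relocation_prob = reloc, n_frames = 21, seed = seed,
                     focus_prob_per_cell = 0.8)
    sim <- generate_timelapse(sp)
    per_frame <- segment_frames(sim$stack)
    tr <- track_foci(per_frame, link_radius_px = 5, max_gap = 1)
    dynamics_summary(tr)$static_fraction
  }
  st <- vapply(1:4, function(s) run_regime(0.2, 300 + s), numeric(1))
  re <- vapply(1:4, function(s) run_regime(0.8, 400 + s), numeric(1))
  expect_true(all(st > re))
})

test_that("track tables round-trip the linked structure", {
  frames <- c(replicate(3, det(c(4, 20), c(4, 20)), simplify = FALSE))
  tr <- track_foci(frames, link_radius_px = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  track_table(tr, path)
  df <- utils::read.csv(path)
  expect_identical(nrow(df), 6L)
  expect_identical(sort(unique(df$track_id)), c(1L, 2L))
})
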