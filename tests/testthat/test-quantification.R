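mk_focus <- function(ys, xs, id = 1L) {
  structure(list(id = id, roi_label = "r",
                 pixel_set = cbind(y = ys, x = xs),
                 area_px = length(ys),
                 centroid = c(y = mean(ys), x = mean(xs))),
            class = "focus")
}

test_that("object mean intensity matches direct summation", {
  plane <- matrix(0, 8, 8)
  plane[3, 3] <- 10; plane[3, 4] <- 20; plane[4, 3] <- 30; plane[4, 4] <- 40
  f <- mk_focus(c(3, 3, 4, 4), c(3, 4, 3, 4))
  expect_equal(measure_focus(plane, f), 25)
  expect_equal(measure_focus(matrix(7, 5, 5), mk_focus(c(2, 3), c(2, 2))), 7)
  withr::with_seed(3, {
    plane <- matrix(runif(100, 0, 1000), 10, 10)
    ys <- sample(1:10, 5, replace = TRUE); xs <- sample(1:10, 5, replace = TRUE)
    f <- mk_focus(ys, xs)
    s <- 0
    for (i in 1:5) s <- s + plane[ys[i], xs[i]]
    expect_equal(measure_focus(plane, f), s / 5)
    # sum conservation: mean * area equals the direct pixel sum
    expect_equal(measure_focus(plane, f) * f$area_px, s)
  })
})

test_that("one-pixel annulus around a 2x2 object is the 12-pixel ring", {
  plane <- matrix(10, 10, 10)
  plane[5:6, 5:6] <- 50
  f <- mk_focus(c(5, 5, 6, 6), c(5, 6, 5, 6))
  # hand enumeration: dilated 4x4 block rows/cols 4..7 minus the 4 object px
  expect_equal(annulus_background(plane, f), 10)
  expect_equal(measure_focus(plane, f) - annulus_background(plane, f), 40)
  ring <- setdiff(focipipe:::dilate_pixels(f$pixel_set, c(10, 10), 1),
                  (f$pixel_set[, 2] - 1) * 10 + f$pixel_set[, 1])
  expect_length(ring, 12)
})

test_that("background zero makes corrected equal raw; +c cancels exactly", {
  plane <- matrix(0, 9, 9)
  plane[4:5, 4:5] <- 33
  f <- mk_focus(c(4, 4, 5, 5), c(4, 5, 4, 5))
  m <- quantify_foci(plane, list(f))
  expect_equal(m$corrected_intensity, m$mean_intensity)
  m2 <- quantify_foci(plane + 123.5, list(f))
  expect_equal(m2$corrected_intensity, m$corrected_intensity)
  expect_equal(m2$mean_intensity, m$mean_intensity + 123.5)
  # multiplicative gain scales corrected linearly
  m3 <- quantify_foci(plane * 2.5, list(f))
  expect_equal(m3$corrected_intensity, 2.5 * m$corrected_intensity)
})

test_that("annulus excludes pixels of neighbouring foci", {
  plane <- matrix(10, 12, 12)
  plane[5:6, 5:6] <- 50
  plane[5:6, 7:8] <- 5000      # bright neighbour inside the annulus ring
  f1 <- mk_focus(c(5, 5, 6, 6), c(5, 6, 5, 6), id = 1L)
  f2 <- mk_focus(c(5, 5, 6, 6), c(7, 8, 7, 8), id = 2L)
  m <- quantify_foci(plane, list(f1, f2))
  expect_equal(m$background_mean[1], 10)   # neighbour pixels excluded
  # without exclusion the neighbour contaminates the ring
  m_noexcl <- quantify_foci(plane, list(f1, f2), exclude_other_foci = FALSE)
  expect_gt(m_noexcl$background_mean[1], 10)
})

test_that("degenerate annulus and empty pixel sets are contract errors", {
  plane <- matrix(1, 2, 2)
  f <- mk_focus(c(1, 1, 2, 2), c(1, 2, 1, 2))  # fills the whole image
  expect_error(annulus_background(plane, f), "degenerate annulus")
  f0 <- structure(list(id = 1L, roi_label = "r",
                       pixel_set = cbind(y = integer(0), x = integer(0)),
                       area_px = 0L, centroid = c(y = NA, x = NA)),
                  class = "focus")
  expect_error(measure_focus(plane, f0), "empty pixel set")
})

test_that("foci per cell is the exact unrounded ratio", {
  expect_equal(foci_per_cell(55, 100)$foci_per_cell, 0.55)
  expect_equal(foci_per_cell(0, 200)$foci_per_cell, 0)
  expect_equal(foci_per_cell(1, 3)$foci_per_cell, 1 / 3)
  expect_error(foci_per_cell(5, 0), "n_cells")
})

test_that("detected frequency recovers the planted per-cell probability", {
  sp <- scene_spec(image_shape = c(384, 384), n_z = 1, n_cells = 60,
                   focus_prob_per_cell = 0.55, seed = 42)
  sim <- generate_microcolony(sp)
  d <- dim(sim$stack$pixels)
  seg <- segment_foci(sim$stack,
                      roi_set(list(roi_rect("f", 1, 1, d[4], d[5]))))
  fr <- foci_per_cell(length(seg$foci), nrow(sim$truth$cells))
  p <- sp$focus_prob_per_cell
  tol <- 3 * sqrt(p * (1 - p) / sp$n_cells)
  expect_lt(abs(fr$foci_per_cell - p), tol + 0.02)
})
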