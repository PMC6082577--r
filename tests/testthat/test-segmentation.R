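test_that("planted 3x3 block on uniform background is segmented exactly", {
  plane <- matrix(100, 16, 16)
  plane[7:9, 7:9] <- 1000
  r <- roi_rect("r", 1, 1, 16, 16)
  bm <- threshold_roi(plane, r)
  # oracle: direct-summation mean/SD over all 256 ROI pixels
  st <- oracle_mean_sd(as.numeric(plane))
  expect_equal(st$mean, (247 * 100 + 9 * 1000) / 256)
  expect_equal(bm$threshold, st$mean + 2.2 * st$sd)
  # every pixel individually
  for (y in 1:16) for (x in 1:16)
    expect_identical(bm$mask[y, x], plane[y, x] > bm$threshold)
  expect_identical(sum(bm$mask), 9L)
  foci <- extract_foci(bm)
  expect_length(foci, 1)
  expect_identical(foci[[1]]$area_px, 9L)
  expect_equal(foci[[1]]$centroid, c(y = 8, x = 8))
})

test_that("uniform ROI yields an empty mask and zero foci", {
  plane <- matrix(42, 12, 12)
  bm <- threshold_roi(plane, roi_rect("u", 1, 1, 12, 12))
  expect_false(any(bm$mask))
  expect_length(extract_foci(bm), 0)
})

test_that("k_sd = 0 reduces to strictly-above-mean thresholding", {
  withr::with_seed(5, {
    plane <- matrix(sample(0:50, 100, replace = TRUE), 10, 10)
    bm <- threshold_roi(plane, roi_rect("r", 1, 1, 10, 10),
                        seg_params(k_sd = 0))
    expect_identical(bm$mask, plane > mean(plane))
  })
})

test_that("degenerate one-pixel ROI is rejected", {
  plane <- matrix(1:25, 5, 5)
  expect_error(
    threshold_roi(plane, roi("p", rbind(c(2, 2), c(2, 2.2), c(2.2, 2.2)))),
    "degenerate ROI")
})

test_that("size filter is strict and connectivity is configurable", {
  mask <- matrix(FALSE, 12, 12)
  mask[2:3, 2:4] <- TRUE               # area 6: must be discarded
  mask[7:9, 7:9] <- TRUE               # area 9: kept
  foci <- extract_foci(mask, seg_params(min_size_px = 6))
  expect_length(foci, 1)
  expect_identical(foci[[1]]$area_px, 9L)
  # two diagonally touching pixels: one component at 8-conn, two at 4-conn
  m2 <- matrix(FALSE, 5, 5)
  m2[2, 2] <- TRUE; m2[3, 3] <- TRUE
  expect_identical(max(label_components(m2, 8L)), 1L)
  expect_identical(max(label_components(m2, 4L)), 2L)
  expect_length(extract_foci(m2, seg_params()), 0)  # both below size 6
})

test_that("segmentation equals the brute-force oracle on random scenes", {
  withr::with_seed(99, {
    for (i in 1:25) {
      plane <- matrix(sample(0:300, 32 * 32, replace = TRUE), 32, 32)
      # plant a few bright blocks so foci exist sometimes
      for (b in seq_len(sample(0:3, 1))) {
        y <- sample(1:28, 1); x <- sample(1:28, 1)
        plane[y:(y + sample(1:4, 1)), x:(x + sample(1:4, 1))] <-
          sample(2000:4000, 1)
      }
      y1 <- sample(1:10, 1); x1 <- sample(1:10, 1)
      r <- roi_rect("r", y1, x1, y1 + sample(8:20, 1), x1 + sample(8:20, 1))
      conn <- sample(c(4L, 8L), 1)
      p <- seg_params(connectivity = conn)
      got <- foci_pixel_strings(extract_foci(threshold_roi(plane, r, p), p))
      want <- oracle_segment(plane, rasterize_roi(r, dim(plane)),
                             connectivity = conn)
      expect_identical(got, want)
    }
  })
})

test_that("mask is invariant under affine intensity maps a*I + b", {
  withr::with_seed(7, {
    plane <- matrix(rpois(400, 120), 20, 20)
    plane[5:7, 5:7] <- 900
    r <- roi_rect("r", 1, 1, 20, 20)
    base <- threshold_roi(plane, r)$mask
    for (ab in list(c(2, 0), c(1, 500), c(0.25, 37.5), c(3.7, 11))) {
      tr <- threshold_roi(plane * ab[1] + ab[2], r)$mask
      expect_identical(tr, base)
    }
  })
})

test_that("raising k_sd or min_size_px never adds pixels or foci", {
  withr::with_seed(21, {
    plane <- matrix(rpois(900, 100), 30, 30)
    plane[4:6, 4:7] <- 800; plane[20:24, 18:21] <- 600
    r <- roi_rect("r", 1, 1, 30, 30)
    prev_mask_n <- Inf; prev_foci <- Inf
    for (k in c(0, 1, 2.2, 3, 5)) {
      n <- sum(threshold_roi(plane, r, seg_params(k_sd = k))$mask)
      expect_lte(n, prev_mask_n)
      prev_mask_n <- n
    }
    bm <- threshold_roi(plane, r)
    for (ms in c(0, 3, 6, 10, 20)) {
      nf <- length(extract_foci(bm, seg_params(min_size_px = ms)))
      expect_lte(nf, prev_foci)
      prev_foci <- nf
    }
  })
})

test_that("segment_foci composes plane selection and per-ROI extraction", {
  px <- array(100, dim = c(1, 3, 1, 16, 16))
  px[1, 2, 1, 7:9, 7:9] <- 1000     # block only in the sharp slice
  st <- image_stack(px)
  rs <- roi_set(list(roi_rect("r", 1, 1, 16, 16)))
  seg <- segment_foci(st, rs)
  expect_identical(seg$z, 2L)
  expect_length(seg$foci, 1)
  expect_equal(seg$foci[[1]]$centroid, c(y = 8, x = 8))
  # repeated runs give identical results (determinism)
  seg2 <- segment_foci(st, rs)
  expect_identical(focus_table(seg$foci), focus_table(seg2$foci))
  # all-uniform stack: no foci in any ROI
  st0 <- image_stack(array(50, dim = c(1, 3, 1, 16, 16)))
  expect_length(segment_foci(st0, rs)$foci, 0)
})
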