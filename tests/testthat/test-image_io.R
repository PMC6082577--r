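test_that("stacks round-trip through TIFF losslessly, axes normalised", {
  withr::with_seed(11, {
    for (shape in list(c(2, 3, 2, 24, 17), c(1, 1, 1, 8, 8),
                       c(4, 1, 1, 12, 30))) {
      px <- array(sample(0:65535, prod(shape), replace = TRUE), dim = shape)
      st <- image_stack(px, pixel_size_um = 0.065, z_step_um = 0.25,
                        frame_interval_s = 90)
      path <- withr::local_tempfile(fileext = ".tif")
      write_stack(st, path)
      back <- read_stack(path)
      expect_identical(dim(back$pixels), as.integer(shape))
      expect_true(all(back$pixels == st$pixels))
      expect_equal(back$pixel_size_um, st$pixel_size_um)
      expect_equal(back$z_step_um, st$z_step_um)
      expect_equal(back$frame_interval_s, st$frame_interval_s)
      expect_identical(back$channel_names, st$channel_names)
    }
  })
})

test_that("full acquisition geometry (512 x 512, 11 z, 2 channels) reads back", {
  px <- array(0L, dim = c(1, 11, 2, 512, 512))
  px[1, 6, 1, 100, 200] <- 4321L
  st <- image_stack(px, channel_names = c("GFP", "DIC"))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_identical(dim(back$pixels), c(1L, 11L, 2L, 512L, 512L))
  expect_equal(back$pixels[1, 6, 1, 100, 200], 4321)
  expect_identical(back$channel_names, c("GFP", "DIC"))
})

test_that("a bare single-plane TIFF reads as a (1,1,1,y,x) stack", {
  m <- matrix(as.integer(round(seq(0, 60000, length.out = 35))), 5, 7)
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  st <- read_stack(path)
  expect_identical(dim(st$pixels), c(1L, 1L, 1L, 5L, 7L))
  expect_true(all(st$pixels[1, 1, 1, , ] == m))
})

test_that("overwriting an existing stack replaces its content", {
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(image_stack(matrix(1, 4, 4)), path)
  write_stack(image_stack(matrix(7, 4, 4)), path)
  expect_true(all(read_stack(path)$pixels == 7))
})

test_that("io contract errors: 16-bit range, missing file, bad axes", {
  expect_error(write_stack(image_stack(matrix(70000, 3, 3)), tempfile()),
               "65535")
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "no such file")
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(image_stack(matrix(0, 4, 4)), path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$axes <- "xyczt"
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_stack(path), "xyczt")
})

test_that("select_best_z picks the highest-SD slice, ties to lowest index", {
  px <- array(0, dim = c(1, 3, 1, 4, 4))
  px[1, 1, 1, , ] <- 5
  px[1, 2, 1, , ] <- matrix(c(0, 10), 4, 4)  # checkerboard-ish, nonzero SD
  px[1, 3, 1, , ] <- 7
  st <- image_stack(px)
  expect_identical(select_best_z(st), 2L)
  # additive offset leaves the choice unchanged
  st2 <- image_stack(px + 100)
  expect_identical(select_best_z(st2), 2L)
  # positive scaling too
  st3 <- image_stack(px * 3.5)
  expect_identical(select_best_z(st3), 2L)
  # single slice
  st1 <- image_stack(array(2, dim = c(1, 1, 1, 4, 4)))
  expect_identical(select_best_z(st1), 1L)
  expect_error(select_best_z(st, t = 5), "out of range")
})

test_that("ROI sets round-trip in both dialects; rect equals its polygon", {
  rs <- roi_set(list(
    roi("a", rbind(c(2, 2), c(2, 10), c(9, 6)), z_range = c(1, 3)),
    roi_rect("b", 3.5, 4, 11, 13)))
  for (ext in c(".tsv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_rois(rs, path)
    back <- read_rois(path)
    expect_length(back, 2)
    for (i in 1:2) {
      expect_identical(back[[i]]$label, rs[[i]]$label)
      expect_equal(back[[i]]$vertices, rs[[i]]$vertices)
      expect_identical(back[[i]]$z_range, rs[[i]]$z_range)
    }
  }
  # a rect record rasterises to the same pixel set as its explicit polygon
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("r\trect\t3,4;8,9\t1\t1", path)
  rect <- read_rois(path)[[1]]
  poly <- roi("r", rbind(c(3, 4), c(3, 9), c(8, 9), c(8, 4)))
  expect_identical(rasterize_roi(rect, c(16, 16)),
                   rasterize_roi(poly, c(16, 16)))
  # exhaustive: the rect footprint is exactly the integer box
  expect_identical(which(rasterize_roi(rect, c(16, 16)), arr.ind = TRUE)[, 1],
                   rep(3:8, times = 6))
})

test_that("empty and malformed ROI files behave as documented", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), path)
  expect_length(read_rois(path), 0)
  writeLines(c("# comment", "bad\tpolygon\tonly_two_fields"), path)
  expect_error(read_rois(path), "line 2")
})
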