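small_spec <- function(...) {
  args <- list(...)
  base <- list(image_shape = c(128, 128), n_z = 1, n_cells = 10, seed = 2)
  do.call(scene_spec, utils::modifyList(base, args))
}

test_that("fixed seed gives bit-identical scenes; new seeds differ", {
  a <- generate_microcolony(small_spec())
  b <- generate_microcolony(small_spec())
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_identical(a$truth$foci, b$truth$foci)
  c <- generate_microcolony(small_spec(seed = 3))
  expect_false(identical(a$stack$pixels, c$stack$pixels))
  # time lapse too
  ta <- generate_timelapse(small_spec(n_frames = 4))
  tb <- generate_timelapse(small_spec(n_frames = 4))
  expect_identical(ta$stack$pixels, tb$stack$pixels)
})

test_that("an empty scene matches the pure background noise model", {
  sp <- small_spec(image_shape = c(256, 256), n_cells = 0,
                   background_level = 200, read_noise_sd = 10)
  sim <- generate_microcolony(sp)
  px <- sim$stack$pixels
  # mean: Poisson(200) + N(0,10) -> 200; variance 200 + 100
  expect_lt(abs(mean(px) - 200) / 200, 0.01)
  expect_lt(abs(stats::var(as.numeric(px)) - 300) / 300, 0.1)
  expect_identical(nrow(sim$truth$cells), 0L)
  expect_identical(nrow(sim$truth$foci), 0L)
})

test_that("planted focus count is binomial in the cell count", {
  sp <- scene_spec(image_shape = c(512, 512), n_z = 1, n_cells = 200,
                   focus_prob_per_cell = 0.76, seed = 9)
  sim <- generate_microcolony(sp)
  n <- nrow(sim$truth$cells)
  expect_identical(n, 200L)
  k <- nrow(sim$truth$foci)
  expect_lt(abs(k - n * 0.76), 3 * sqrt(n * 0.76 * 0.24))
  # every focus lies inside its cell: within half length of the centre
  g <- focipipe:::cell_geometry(sp)
  for (i in seq_len(k)) {
    cell <- sim$truth$cells[sim$truth$cells$cell_id ==
                              sim$truth$foci$cell_id[i], ]
    d <- sqrt((cell$y - sim$truth$foci$y[i])^2 +
              (cell$x - sim$truth$foci$x[i])^2)
    expect_lt(d, g$len / 2)
  }
})

test_that("doubling the focus amplitude doubles the noiseless contrast", {
  base <- small_spec(focus_prob_per_cell = 1, n_cells = 6)
  none <- small_spec(focus_prob_per_cell = 0, n_cells = 6)
  twice <- small_spec(focus_prob_per_cell = 1, n_cells = 6,
                      focus_amplitude_meanlog = base$focus_amplitude_meanlog +
                        log(2))
  c0 <- generate_microcolony(none)$truth$clean
  c1 <- generate_microcolony(base)$truth$clean
  c2 <- generate_microcolony(twice)$truth$clean
  spots1 <- c1 - c0
  spots2 <- c2 - c0
  expect_gt(max(spots1), 0)
  expect_equal(spots2, 2 * spots1, tolerance = 1e-12)
})

test_that("relocation probability 0 pins every process to one site", {
  sp <- small_spec(n_frames = 21, relocation_prob = 0,
                   focus_prob_per_cell = 1, n_cells = 8)
  sim <- generate_timelapse(sp)
  expect_identical(nrow(sim$truth$relocations), 0L)
  sites <- unique(sim$truth$foci[, c("focus_id", "site_y", "site_x")])
  expect_identical(nrow(sites), length(unique(sim$truth$foci$focus_id)))
})

test_that("relocation probability 1 relocates at every reassembly", {
  sp <- small_spec(n_frames = 30, relocation_prob = 1,
                   focus_prob_per_cell = 1, n_cells = 8,
                   focus_lifetime_frames = 2, dropout_prob = 0)
  sim <- generate_timelapse(sp)
  # the site changes exactly at assembly boundaries (frame gaps) and
  # never within an assembly
  f <- sim$truth$foci
  for (id in unique(f$focus_id)) {
    e <- f[f$focus_id == id, ]
    e <- e[order(e$frame), ]
    if (nrow(e) < 2) next
    gap <- diff(e$frame) > 1
    site_changed <- (diff(e$site_y) != 0) | (diff(e$site_x) != 0)
    expect_identical(site_changed, gap)
  }
  expect_gt(nrow(sim$truth$relocations), 0)
})

test_that("recorded drift equals independently composed per-frame steps", {
  sp <- small_spec(n_frames = 6,
                   drift_per_frame = c(dx = 0.3, dy = -0.2, theta = 0.1))
  sim <- generate_timelapse(sp)
  dr <- sim$truth$drift
  step <- rigid_transform(0.3, -0.2, 0.1)
  cum <- rigid_transform()
  for (t in 1:6) {
    expect_equal(dr$dx[t], cum$dx, tolerance = 1e-12)
    expect_equal(dr$dy[t], cum$dy, tolerance = 1e-12)
    expect_equal(dr$theta[t], cum$theta, tolerance = 1e-12)
    cum <- compose_rigid(cum, step)
  }
  # rendered positions: frame coordinates are the drifted world coordinates
  f <- sim$truth$foci
  ctr <- c((128 + 1) / 2, (128 + 1) / 2)
  for (i in seq_len(min(nrow(f), 20))) {
    tf <- rigid_transform(dr$dx[f$frame[i]], dr$dy[f$frame[i]],
                          dr$theta[f$frame[i]])
    p <- transform_points(cbind(f$world_y[i], f$world_x[i]), tf, ctr)
    expect_equal(unname(c(f$y[i], f$x[i])), unname(as.numeric(p)),
                 tolerance = 1e-9)
  }
})

test_that("infeasible packing fails with a clear error", {
  expect_error(
    generate_microcolony(scene_spec(image_shape = c(64, 64), n_z = 1,
                                    n_cells = 500, seed = 1)),
    "infeasible packing")
})

test_that("ground truth exports round-trip", {
  sim <- generate_timelapse(small_spec(n_frames = 4))
  dir <- withr::local_tempdir()
  export_ground_truth(sim$truth, dir)
  back <- read_ground_truth(dir)
  expect_equal(back$cells, sim$truth$cells)
  expect_equal(back$foci, sim$truth$foci, tolerance = 1e-12)
  expect_equal(back$drift, sim$truth$drift)
  expect_equal(back$spec$n_cells, sim$truth$spec$n_cells)
  # empty scene: headers only
  sim0 <- generate_microcolony(small_spec(n_cells = 0))
  dir0 <- withr::local_tempdir()
  export_ground_truth(sim0$truth, dir0)
  f <- utils::read.csv(file.path(dir0, "foci.csv"))
  expect_identical(nrow(f), 0L)
  expect_true(all(c("focus_id", "cell_id", "y", "x", "amplitude") %in%
                  colnames(f)))
})
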