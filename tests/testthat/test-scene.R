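test_that("degenerate scene (no speckle, no contrast) renders a constant background", {
  cfg <- ceus_scene(frame_shape = c(40, 40), n_frames = 4,
                    lesion_axes = c(5, 4), lesion_contrast = 0,
                    speckle_scale = 0,
                    trajectory = list(type = "linear", start = c(20, 20),
                                      velocity = c(0, 0)))
  sq <- generate_sequence(cfg)
  for (f in sq$frames) {
    expect_equal(length(unique(as.vector(f))), 1L)
    expect_equal(f[1, 1], cfg$base_intensity)
  }
})

test_that("ground truth follows the analytic linear trajectory", {
  cfg <- ceus_scene(frame_shape = c(80, 80), n_frames = 12,
                    lesion_axes = c(5, 4),
                    trajectory = list(type = "linear", start = c(20, 20),
                                      velocity = c(1, 0)))
  sq <- generate_sequence(cfg)
  # after 10 steps the center has moved 10 px down the rows
  expect_equal(unname(sq$truth$center_row[11]), 30)
  expect_equal(unname(sq$truth$center_col[11]), 20)
  # constant box size for a rigid lesion
  expect_equal(length(unique(sq$truth$height)), 1L)
  expect_equal(length(unique(sq$truth$width)), 1L)
})

test_that("identical seed and config give bit-identical sequences", {
  cfg <- small_scene(seed = 7)
  expect_identical(generate_sequence(cfg)$frames, generate_sequence(cfg)$frames)
  expect_identical(generate_sequence(cfg)$truth, generate_sequence(cfg)$truth)
})

test_that("a trajectory leaving the frame is rejected naming the first bad frame", {
  cfg <- ceus_scene(frame_shape = c(40, 40), n_frames = 30,
                    lesion_axes = c(5, 4),
                    trajectory = list(type = "linear", start = c(20, 20),
                                      velocity = c(0, 2)))
  expect_error(generate_sequence(cfg), "frame [0-9]+")
})

test_that("the lesion is hypoechoic: interior darker than surrounding ring", {
  for (seed in 1:3) {
    sq <- generate_sequence(small_scene(seed = seed, n_frames = 2))
    f <- sq$frames[[1]]; tb <- sq$truth[1, ]
    interior <- f[(tb$row + 3):(tb$row + tb$height - 4),
                  (tb$col + 2):(tb$col + tb$width - 3)]
    ring <- f
    ring[(tb$row - 2):(tb$row + tb$height + 1),
         (tb$col - 2):(tb$col + tb$width + 1)] <- NA
    expect_lt(mean(interior), mean(ring, na.rm = TRUE))
  }
})

test_that("sinusoidal and random-walk trajectories stay on their analytic path", {
  cfg <- ceus_scene(frame_shape = c(96, 96), n_frames = 20, lesion_axes = c(5, 4),
                    trajectory = list(type = "sinusoidal", start = c(48, 20),
                                      velocity = c(0, 1), amplitude = 3,
                                      period = 10))
  sq <- generate_sequence(cfg)
  t <- 0:19
  expect_equal(sq$truth$center_row, 48 + 3 * sin(2 * pi * t / 10))
  expect_equal(sq$truth$center_col, 20 + t)
  # random walk: reproducible under the scene seed
  cfgrw <- ceus_scene(frame_shape = c(96, 96), n_frames = 10, lesion_axes = c(5, 4),
                      trajectory = list(type = "random_walk", start = c(48, 48),
                                        step_sd = 0.5), seed = 3)
  expect_identical(generate_sequence(cfgrw)$truth, generate_sequence(cfgrw)$truth)
})

test_that("RGB replication mode produces identical channels", {
  sq <- generate_sequence(small_scene(n_frames = 2, channels = 3))
  f <- sq$frames[[1]]
  expect_equal(dim(f)[3], 3L)
  expect_identical(f[, , 1], f[, , 2])
  expect_identical(f[, , 1], f[, , 3])
})

test_that("frames round-trip through PNG directories and multi-page TIFF", {
  sq <- generate_sequence(small_scene(n_frames = 3))
  dir_png <- tempfile("frames_")
  write_frames(sq, dir_png, format = "png")
  back <- read_frames(dir_png)
  expect_equal(length(back), 3L)
  expect_equal(back[[2]], sq$frames[[2]], tolerance = 1e-10)

  f_tif <- tempfile(fileext = ".tif")
  write_frames(sq, f_tif, format = "tiff")
  back2 <- read_frames(f_tif)
  expect_equal(back2[[3]], sq$frames[[3]], tolerance = 1e-10)
  unlink(dir_png, recursive = TRUE); unlink(f_tif)
})

test_that("box CSVs round-trip through the 0-based on-disk convention", {
  sq <- generate_sequence(small_scene(n_frames = 3))
  path <- tempfile(fileext = ".csv")
  write_boxes_csv(sq$truth, path)
  raw <- utils::read.csv(path)
  expect_equal(raw$frame[1], 0)                   # 0-based on disk
  expect_equal(raw$row[1], sq$truth$row[1] - 1)
  back <- read_boxes_csv(path)
  expect_equal(back$row, sq$truth$row)
  expect_equal(back$center_col, sq$truth$center_col)
  unlink(path)
})

test_that("wash-in gain rescales frames globally", {
  gains <- wash_in_curve(6, amplitude = 0.5, tau = 2)
  expect_equal(gains[1], 1)
  expect_true(all(diff(gains) > 0))
  cfg <- ceus_scene(frame_shape = c(40, 40), n_frames = 6, lesion_axes = c(5, 4),
                    lesion_contrast = 0, speckle_scale = 0,
                    trajectory = list(type = "linear", start = c(20, 20),
                                      velocity = c(0, 0)),
                    base_intensity = 100, wash_in = gains)
  sq <- generate_sequence(cfg)
  expect_equal(sapply(sq$frames, function(f) f[1, 1]), round(100 * gains))
})
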