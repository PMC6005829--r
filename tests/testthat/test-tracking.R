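test_that("marker segmentation matches a brute-force pixel oracle", {
  withr::with_seed(8, {
    for (i in 1:4) {
      cx <- runif(1, 10, 54); cy <- runif(1, 10, 38)
      frame <- disc_frame(cx, cy, radius = 5, width = 64, height = 48)
      got <- segment_marker(frame)
      ora <- oracle_centroid(frame)
      expect_true(got$found)
      expect_equal(got$x, ora$x, tolerance = 1e-8)
      expect_equal(got$y, ora$y, tolerance = 1e-8)
      expect_equal(got$area, ora$area)
      # and the weighted centroid sits on the true disc centre
      expect_lt(abs(got$x - cx), 0.5)
      expect_lt(abs(got$y - cy), 0.5)
    }
  })
})

test_that("segmentation picks the largest red component and rejects junk", {
  img <- array(0, dim = c(48, 64, 3))
  img[10:25, 5:20, 1] <- 1     # 256-px blob
  img[40:42, 50:52, 1] <- 1    # 9-px blob
  got <- segment_marker(img)
  expect_equal(got$x, mean(5:20))
  expect_equal(got$y, mean(10:25))
  # all-black frame
  expect_false(segment_marker(array(0, dim = c(48, 64, 3)))$found)
  # a green disc is not a marker
  green <- array(0, dim = c(48, 64, 3)); green[20:30, 20:30, 2] <- 1
  expect_false(segment_marker(green)$found)
  # largest component below min_area
  tiny <- array(0, dim = c(48, 64, 3)); tiny[5:6, 5:6, 1] <- 1
  expect_false(segment_marker(tiny)$found)
  expect_error(segment_marker(matrix(0, 4, 4)), "decode")
})

test_that("rendered trajectories are re-tracked to sub-pixel accuracy", {
  dir <- withr::local_tempdir()
  tr <- make_test_video(file.path(dir, "v1"), f_d = 20, zeta = 0.05,
                        duration = 1.5, noise_sigma = 0, seed = 1)
  cents <- track_frames(file.path(dir, "v1"))
  expect_equal(nrow(cents), nrow(tr))
  rec <- to_displacement(cents, crop = "none")
  expect_lt(sqrt(mean((rec$d - tr$d)^2)), 1)
})

test_that("short marker dropouts are bridged, long ones fail the sample", {
  dir <- withr::local_tempdir()
  make_test_video(file.path(dir, "v"), duration = 1, seed = 2)
  black <- array(0, dim = c(64, 192, 3))
  files <- sort(list.files(file.path(dir, "v"), pattern = "^frame_",
                           full.names = TRUE))
  for (f in files[100:101]) png::writePNG(black, f)
  cents <- track_frames(file.path(dir, "v"), max_gap = 5)
  expect_false(any(is.na(cents$x)))
  expect_equal(sum(!cents$found), 2)
  # interpolated positions lie between the neighbouring detections
  expect_true(all(cents$x[100:101] >= min(cents$x[c(99, 102)]) &
                  cents$x[100:101] <= max(cents$x[c(99, 102)])))
  for (f in files[120:149]) png::writePNG(black, f)
  expect_error(track_frames(file.path(dir, "v"), max_gap = 5),
               "tracking-failure")
})

test_that("displacement conversion centres, crops and projects correctly", {
  cents <- tibble::tibble(t = (0:4) / 240, x = c(10, 12, 10, 8, 10),
                          y = rep(3, 5))
  d <- to_displacement(cents, crop = "none")
  expect_equal(d$d, c(0, 2, 0, -2, 0))
  # invariant to a constant offset of the centroid series
  d2 <- to_displacement(dplyr::mutate(cents, x = x + 57.3), crop = "none")
  expect_equal(d2$d, d$d)
  # pure vertical motion projected on the principal axis equals centred y
  vert <- tibble::tibble(t = (0:9) / 240, x = rep(5, 10),
                         y = 20 + sin(1:10))
  dp <- to_displacement(vert, axis = "principal", crop = "none")
  ctr <- vert$y - mean(vert$y)
  expect_equal(abs(dp$d), abs(ctr), tolerance = 1e-9)
  # constant centroid has no vibration to analyze
  flat <- tibble::tibble(t = (0:9) / 240, x = rep(2, 10), y = rep(3, 10))
  expect_error(to_displacement(flat), "degenerate-trace")
  # default crop starts the trace at the largest excursion
  late <- tibble::tibble(t = (0:9) / 240,
                         x = c(0, 0, 0, 9, -6, 4, -2, 1, 0, 0), y = rep(1, 10))
  dl <- to_displacement(late, crop = "max")
  expect_equal(nrow(dl), 7)
})
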